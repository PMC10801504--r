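test_that("count_regions estimates integer reads from depth", {
  trk <- make_track(rep(2, 1000))
  reg <- GRanges("chr1", IRanges(1, 1000), region_id = "r1", kind = "gene_body")
  cm <- count_regions(reg, list(trk), 50)
  expect_identical(cm$counts["r1", "s1"], 40L)
  # zero coverage and identical tracks
  reg2 <- GRanges("chr1", IRanges(c(1, 2001), c(1000, 3000)),
                  region_id = c("r1", "r2"))
  cm2 <- count_regions(reg2, list(trk, trk), 50)
  expect_equal(cm2$counts[, 1], cm2$counts[, 2])
  expect_identical(unname(cm2$counts["r2", 1]), 0L)
  expect_error(count_regions(GRanges(), list(trk)), "region_id")
})

test_that("median-of-ratios size factors match the hand computation and DESeq2", {
  A <- c(100, 200, 300)
  # B = 2A elementwise: geometric means are A*sqrt(2), so the ratio medians
  # are 1/sqrt(2) and sqrt(2)
  expect_equal(unname(size_factors(cbind(A, B = 2 * A))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(size_factors(matrix(A, ncol = 1))), 1)
  set.seed(4)
  m <- matrix(rnbinom(600, mu = 150, size = 8), ncol = 6)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
  # fallback when no region is nonzero in every sample
  m0 <- rbind(c(4, 0), c(0, 6))
  expect_warning(sf <- size_factors(m0, library_size = c(1e6, 4e6)),
                 "library-size")
  expect_equal(unname(sf), c(1e6, 4e6) / sqrt(1e6 * 4e6))
})

test_that("diff_test: null behaviour, label swap, scaling invariance", {
  cond <- c("C", "C", "T", "T")
  flat <- matrix(100L, nrow = 5, ncol = 4,
                 dimnames = list(paste0("r", 1:5), NULL))
  res <- diff_test(flat, cond, "C", "T")
  expect_equal(res$log2fc, rep(0, 5))
  expect_true(all(res$p_value > 0.99))

  set.seed(12)
  m <- matrix(rnbinom(200, mu = 300, size = 15), ncol = 4,
              dimnames = list(paste0("r", 1:50), NULL))
  a <- diff_test(m, cond, "C", "T")
  b <- diff_test(m, cond, "T", "C")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  # scaling one sample's counts by k is absorbed by its size factor
  m2 <- m
  m2[, 1] <- m2[, 1] * 4L
  s <- diff_test(m2, cond, "C", "T")
  expect_equal(s$log2fc, a$log2fc, tolerance = 0.05)

  expect_error(diff_test(m, cond, "C", "X"), "not found")
})

test_that("an absent condition label and BH adjustment behave as declared", {
  res <- data.frame(region_id = paste0("r", 1:6),
                    log2fc = rnorm(6),
                    p_value = c(0.001, 0.01, 0.05, 0.2, 0.8, 1))
  kept <- significant(res)
  expect_equal(kept$region_id, c("r1", "r2", "r3"))   # 0.05 inclusive
  expect_equal(nrow(significant(res[0, ])), 0)
  expect_equal(nrow(significant(transform(res, p_value = 1))), 0)
  adj <- significant(res, adjust = "BH")
  expect_true(all(diff(significant(res, 1, "BH")$p_adjusted[
    order(significant(res, 1, "BH")$p_value)]) >= 0))
  expect_true(all(adj$p_adjusted >= res$p_value[seq_len(nrow(adj))]))
})

test_that("the Wald test is calibrated on a planted negative-binomial null", {
  set.seed(501)
  mu <- exp(runif(1500, log(50), log(2000)))
  counts <- sapply(1:4, function(j) rnbinom(1500, mu = mu, size = 20))
  rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  res <- diff_test(counts, c("C", "C", "T", "T"), "C", "T")
  expect_gt(mean(res$p_value <= 0.05), 0.02)
  expect_lt(mean(res$p_value <= 0.05), 0.09)
})

test_that("a strong planted effect is recovered with the right sign and size", {
  set.seed(502)
  hits <- replicate(50, {
    mu0 <- exp(runif(50, log(100), log(1000)))
    cm <- rbind(matrix(c(rnbinom(2, mu = 500, size = 20),
                         rnbinom(2, mu = 2000, size = 20)), nrow = 1),
                sapply(1:4, function(j) rnbinom(50, mu = mu0, size = 20)))
    rownames(cm) <- paste0("r", seq_len(nrow(cm)))
    r <- diff_test(cm, c("C", "C", "T", "T"), "C", "T")
    c(lfc = r$log2fc[1], sig = r$p_value[1] < 0.01)
  })
  expect_equal(mean(hits["lfc", ]), 2, tolerance = 0.1)
  expect_gte(mean(hits["sig", ]), 0.95)
})
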