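test_that("fpkm follows the standard definition and validates inputs", {
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_equal(fpkm(10, 500, 1e6), 20)
  expect_equal(fpkm(1, 1000, 1e7), 0.1)     # below the 0.2 discovery cutoff
  expect_error(fpkm(1, 0, 1e6))
  expect_error(fpkm(1, 500, 0))
  expect_error(fpkm(-1, 500, 1e6))
})

test_that("window_reads converts depth to estimated reads, zero off the extent", {
  trk <- make_track(rep(4, 500))
  expect_equal(window_reads(trk, GRanges("chr1:1-500"), 50), 40)
  expect_equal(window_reads(trk, GRanges("chr1:1000-1500"), 50), 0)
  trk2 <- make_track(c(rep(1, 50), rep(0, 450)))
  expect_equal(window_reads(trk2, GRanges("chr1:1-500"), 50), 1)
})

# Coverage: gene body [1000,3000) depth 1, then `n_hi` kb of depth 2, then 0.
hi_cov_track <- function(n_hi_bp, tail_bp = 2000) {
  make_track(c(rep(1, 3000), rep(2, n_hi_bp), rep(0, tail_bp)))
}

test_that("call_dog extends while windows pass and respects the minimum length", {
  gene <- make_gene(1001, 3000)
  # depth 2 over 500 bp at read length 50 = 20 reads -> FPKM 40 >> 0.2
  d <- call_dog(gene, hi_cov_track(6000), gene)
  expect_equal(d$length_bp, 6000)
  expect_equal(c(start(d), end(d)), c(3001, 9000))
  expect_equal(d$mean_fpkm, 40)
  # 7 windows = 3500 bp < 4000: no DoG
  expect_null(call_dog(gene, hi_cov_track(3500), gene))
  # exactly 8 windows = 4000 bp: inclusive minimum
  expect_equal(call_dog(gene, hi_cov_track(4000), gene)$length_bp, 4000)
  # zero coverage downstream: no DoG
  expect_null(call_dog(gene, make_track(c(rep(1, 3000), rep(0, 8000))), gene))
})

test_that("a downstream gene truncates the DoG at its TSS-side boundary", {
  gene <- make_gene(1001, 3000)
  trk <- hi_cov_track(10000)
  # '+' downstream gene starting 4500 bp past the TES blocks at its start
  ann <- c(gene, make_gene(7501, 9000, "+", "G2"))
  expect_equal(call_dog(gene, trk, ann)$length_bp, 4500)
  # boundary not a window multiple: partial window evaluated up to it
  ann2 <- c(gene, make_gene(7301, 9000, "+", "G2"))
  expect_equal(call_dog(gene, trk, ann2)$length_bp, 4300)
  # a '-' downstream gene blocks at its TSS side (its right edge), so the
  # DoG may cover its body
  ann3 <- c(gene, make_gene(6001, 7500, "-", "G2"))
  d3 <- call_dog(gene, trk, ann3)
  expect_equal(d3$length_bp, 4500)
  expect_true(end(d3) == 7500)
  # blocking leaves less than min_length: no DoG
  ann4 <- c(gene, make_gene(5001, 9000, "+", "G2"))
  expect_null(call_dog(gene, trk, ann4))
})

test_that("minus-strand genes mirror the extension leftwards", {
  gm <- make_gene(9001, 11000, "-", "GM")
  depth <- c(rep(0, 3000), rep(2, 6000), rep(1, 2000), rep(0, 1000))
  trk <- make_track(depth)
  d <- call_dog(gm, trk, gm)
  expect_equal(d$length_bp, 6000)
  expect_equal(c(start(d), end(d)), c(3001, 9000))
  expect_equal(as.character(strand(d)), "-")
  # upstream '+' gene blocks at its own start, i.e. the DoG can run over it
  ann <- c(gm, make_gene(4501, 5500, "+", "GB"))
  d2 <- call_dog(gm, trk, ann)
  expect_equal(start(d2), 4501)
  expect_equal(d2$length_bp, 4500)
})

test_that("call_dogs_all is deterministic, honours expressed_only, empty in/out", {
  sim <- simulate_dataset(simulation_config(n_genes = 20, seed = 5))
  trk <- sim$tracks$treated_rep1
  a <- call_dogs_all(sim$genes, trk)
  b <- call_dogs_all(sim$genes, trk)
  expect_identical(dogs_to_df(a), dogs_to_df(b))
  expect_length(call_dogs_all(GRanges(gene_id = character(0)), trk), 0)
  # an unexpressed gene is skipped under expressed_only even if a downstream
  # signal exists
  gene <- make_gene(1001, 3000)
  trk0 <- make_track(c(rep(0, 3000), rep(2, 6000)))
  expect_length(call_dogs_all(gene, trk0, expressed_only = TRUE), 0)
  expect_length(call_dogs_all(gene, trk0, expressed_only = FALSE), 1)
})

test_that("every called DoG starts at its parent TES and is >= min length", {
  for (seed in c(2, 9, 14)) {
    sim <- simulate_dataset(simulation_config(n_genes = 30, seed = seed,
                                              interference_fraction = 0.2))
    dogs <- call_dogs_all(sim$genes, sim$tracks$treated_rep1)
    expect_true(all(dogs$length_bp >= 4000))
    expect_equal(dogs$length_bp, width(dogs))
    tes <- gene_tes(sim$genes)[dogs$gene_id]
    minus <- as.character(strand(dogs)) == "-"
    expect_equal(start(dogs)[!minus], unname(tes[!minus]) + 1)
    expect_equal(end(dogs)[minus], unname(tes[minus]) - 1)
  }
})

test_that("caller agrees with the brute-force per-base oracle", {
  for (seed in 101:125) {
    sim <- simulate_dataset(simulation_config(
      n_genes = 6 + seed %% 10, seed = seed,
      interference_fraction = 0.3,
      dog_to_gene_coverage_ratio = c(0.25, 0.5, 0.8)[1 + seed %% 3]))
    trk <- sim$tracks$treated_rep1
    got <- dogs_to_df(call_dogs_all(sim$genes, trk))
    ref <- oracle_call_dogs(genes_to_df(sim$genes), as.numeric(trk$cov$chrS),
                            trk$library_size)
    expect_equal(got$gene_id, ref$gene_id, info = paste("seed", seed))
    expect_equal(got$s0, ref$s0, info = paste("seed", seed))
    expect_equal(got$e0, ref$e0, info = paste("seed", seed))
  }
})

test_that("stricter thresholds are monotone in count and length", {
  sim <- simulate_dataset(simulation_config(n_genes = 40, seed = 8,
                                            dog_to_gene_coverage_ratio = 0.3))
  trk <- sim$tracks$treated_rep1
  prev <- NULL
  for (mf in c(0.1, 0.2, 0.5, 1, 2)) {
    cur <- call_dogs_all(sim$genes, trk, dog_params(min_fpkm = mf))
    if (!is.null(prev)) {
      expect_lte(length(cur), length(prev))
      shared <- intersect(cur$gene_id, prev$gene_id)
      expect_true(all(cur$length_bp[match(shared, cur$gene_id)] <=
                      prev$length_bp[match(shared, prev$gene_id)]))
    }
    prev <- cur
  }
  n_prev <- -1L
  for (ml in c(8000, 6000, 4000, 2000)) {
    n <- length(call_dogs_all(sim$genes, trk,
                              dog_params(min_length_bp = ml, window_bp = 500)))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("merge_replicates unions by gene and keeps the farthest end", {
  g1 <- make_gene(1001, 3000)
  mk <- function(len, id = "G1", strand = "+") {
    d <- GRanges("chr1", IRanges(3001, 3000 + len), strand = strand,
                 gene_id = id, length_bp = len, mean_fpkm = 1, sample_id = "x")
    names(d) <- id
    d
  }
  m <- merge_replicates(list(mk(5000), mk(7000)))
  expect_equal(m$length_bp, 7000)
  expect_equal(end(m), 10000)
  # disjoint gene sets concatenate; empty set is the identity
  two <- merge_replicates(list(mk(5000), mk(4000, "G2")))
  expect_setequal(two$gene_id, c("G1", "G2"))
  expect_equal(dogs_to_df(merge_replicates(list(two, empty_set = two[0]))),
               dogs_to_df(two))
  # conflicting strand for one gene id is an error
  expect_error(merge_replicates(list(mk(5000), mk(5000, strand = "-"))),
               "conflicting")
})
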