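# A hand-built scene: parent gene G1 with a 10-kb DoG, a downstream gene G2
# inside the DoG span, and configurable peaks.
scene <- local({
  g1 <- make_gene(1001, 3000, "+", "G1")
  g2 <- make_gene(8001, 9500, "-", "G2")
  dog <- GRanges("chr1", IRanges(3001, 13000), strand = "+", gene_id = "G1",
                 length_bp = 10000, mean_fpkm = 2, sample_id = "s")
  names(dog) <- "G1"
  list(ann = c(g1, g2), dog = dog,
       peak_at = function(pos) GRanges("chr1", IRanges(pos - 149, pos + 150)))
})

test_that("downstream-interference filter needs both a covered gene and a peak", {
  # covered downstream gene + interior peak: discarded
  pk <- scene$peak_at(9001)   # inside both the DoG and G2
  kept <- filter_downstream_interference(scene$dog, pk, scene$ann)
  expect_length(kept, 0)
  expect_equal(attr(kept, "audit")$trigger_gene, "G2")
  # peak inside the DoG but no covered gene: kept
  ann1 <- scene$ann[1]
  expect_length(filter_downstream_interference(scene$dog, pk, ann1), 1)
  # covered gene but no peak anywhere in the DoG: kept
  pk_far <- scene$peak_at(50000)
  expect_length(filter_downstream_interference(scene$dog, pk_far, scene$ann), 1)
  # strict peak-only mode discards on the peak alone
  expect_length(filter_downstream_interference(scene$dog, pk, ann1,
                                               peak_only = TRUE), 0)
})

test_that("promoter-peak filter keeps DoGs whose parent promoter has a peak", {
  on_tss <- scene$peak_at(1001)
  expect_length(filter_promoter_peak(scene$dog, on_tss, scene$ann), 1)
  # nearest peak 10 kb away from the promoter window: discarded
  far <- scene$peak_at(11001)
  expect_length(filter_promoter_peak(scene$dog, far, scene$ann), 0)
  # empty peak set: vacuous promoter evidence, everything discarded
  expect_warning(none <- filter_promoter_peak(scene$dog, GRanges(), scene$ann),
                 "empty peak set")
  expect_length(none, 0)
  # widening the promoter window is monotone
  n_prev <- 0L
  for (w in c(100, 500, 5000, 12000)) {
    n <- length(filter_promoter_peak(scene$dog, far, scene$ann, w))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("filters are contractive, idempotent and order-independent", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 40, seed = 21, interference_fraction = 0.4,
    promoter_peak_fraction = 0.6, noise = "none", replicate_sigma = 0))
  dogs <- call_dogs_all(sim$genes, sim$tracks$treated_rep1)
  pk <- sim$peaks$treated
  f1 <- function(d) filter_downstream_interference(d, pk, sim$genes)
  f2 <- function(d) filter_promoter_peak(d, pk, sim$genes)
  a <- f1(dogs); b <- f2(dogs)
  expect_true(all(a$gene_id %in% dogs$gene_id))
  expect_true(all(b$gene_id %in% dogs$gene_id))
  expect_equal(dogs_to_df(f1(a)), dogs_to_df(a))   # idempotent
  expect_equal(dogs_to_df(f2(b)), dogs_to_df(b))
  expect_equal(dogs_to_df(f2(f1(dogs))), dogs_to_df(f1(f2(dogs))))  # commute
})

test_that("with zero noise, removals match the generator's planted truth", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 50, seed = 31, interference_fraction = 0.5,
    promoter_peak_fraction = 0.7, noise = "none", replicate_sigma = 0))
  tr <- sim$truth
  for (cond in c("control", "treated")) {
    dogs <- call_dogs_all(sim$genes, sim$tracks[[paste0(cond, "_rep1")]])
    expect_setequal(dogs$gene_id,
                    tr$gene_id[tr[[paste0("expected_call_", cond, "_bp")]] > 0])
    f1 <- filter_downstream_interference(dogs, sim$peaks[[cond]], sim$genes)
    expect_setequal(setdiff(dogs$gene_id, f1$gene_id),
                    tr$gene_id[tr[[paste0("expected_f1_removed_", cond)]]])
    f2 <- filter_promoter_peak(f1, sim$peaks[[cond]], sim$genes)
    expect_setequal(f2$gene_id,
                    intersect(f1$gene_id, tr$gene_id[tr$has_promoter_peak]))
  }
})
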