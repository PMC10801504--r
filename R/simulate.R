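## Synthetic datasets with planted truth.  The generator lays out a single
## linear chromosome of genes with sampled intergenic gaps, plants
## readthrough extensions downstream of a subset of genes (more, by default,
## under the "treated" condition than under "control"), adds interfering
## downstream genes with promoter peaks inside some planted DoG spans (the
## false-positive mode the ChIP-seq filters exist for), converts FPKM to
## expected per-base depth, and samples Poisson per-base counts per
## replicate.  Truth is recorded before any caller runs.

#' Configuration for the synthetic-data generator
#'
#' @param n_genes Number of regular genes.
#' @param gene_length_range_bp Min/max gene length (uniform).
#' @param intergenic_gap_range_bp Min/max intergenic gap (uniform); gaps are
#'   enlarged as needed so planted DoG spans never collide with neighbours.
#' @param expressed_fraction Fraction of genes with nonzero expression.
#' @param readthrough_fraction_treated,readthrough_fraction_control Fraction
#'   of expressed genes with a planted DoG under each condition.
#' @param control_shared_fraction Fraction of control DoG genes drawn from
#'   the treated DoG genes (the shared-DoG structure seen across conditions).
#' @param dog_length_range_bp Min/max planted DoG length.
#' @param dog_length_shape Exponent shaping the length draw
#'   (`min + (max-min) * u^shape`); 1 = uniform.
#' @param length_round_bp Planted lengths are rounded to multiples of this
#'   (the caller's window resolution), so planted and called lengths are
#'   directly comparable.  Default 500.
#' @param base_expression_fpkm_range Min/max gene-body FPKM (log-uniform).
#' @param dog_to_gene_coverage_ratio Depth of a DoG region relative to its
#'   parent gene body, in (0, 1].
#' @param noise `"poisson"` (per-base Poisson counts) or `"none"` (exact
#'   expected depth, possibly fractional).
#' @param background_fpkm Uniform background expression level.  Default 0.
#' @param n_replicates Replicates per condition.
#' @param library_size Total mapped reads per sample.
#' @param read_length_bp Read length.
#' @param interference_fraction Fraction of treated-DoG genes that get an
#'   opposite-strand interfering gene (own expression + promoter peak) at the
#'   distal end of their DoG span.
#' @param promoter_peak_fraction Fraction of expressed genes with a promoter
#'   peak (interfering genes always have one).
#' @param de_fraction Fraction of expressed genes with a planted gene-body
#'   fold change of `±de_log2fc` (genes carrying an interferer are kept at
#'   fold change 0 so their apparent-DoG geometry stays exact).
#' @param de_log2fc Magnitude of the planted log2 fold change.
#' @param replicate_sigma Log-normal sd of the per-replicate depth scaling
#'   (the biological-replicate overdispersion source).
#' @param chrom_name Chromosome name.
#' @param seed RNG seed; a fixed seed makes outputs byte-identical.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 100L,
                              gene_length_range_bp = c(2000L, 6000L),
                              intergenic_gap_range_bp = c(6000L, 12000L),
                              expressed_fraction = 0.9,
                              readthrough_fraction_treated = 0.3,
                              readthrough_fraction_control = 0.1,
                              control_shared_fraction = 0.6,
                              dog_length_range_bp = c(4000L, 10000L),
                              dog_length_shape = 1,
                              length_round_bp = 500L,
                              base_expression_fpkm_range = c(1, 20),
                              dog_to_gene_coverage_ratio = 0.5,
                              noise = c("poisson", "none"),
                              background_fpkm = 0,
                              n_replicates = 2L,
                              library_size = 2e7,
                              read_length_bp = 50L,
                              interference_fraction = 0.1,
                              promoter_peak_fraction = 0.9,
                              de_fraction = 0.2,
                              de_log2fc = 3,
                              replicate_sigma = 0.05,
                              chrom_name = "chrS",
                              seed = 1L) {
  noise <- match.arg(noise)
  fr <- c(expressed_fraction, readthrough_fraction_treated,
          readthrough_fraction_control, control_shared_fraction,
          interference_fraction, promoter_peak_fraction, de_fraction)
  stopifnot(all(fr >= 0 & fr <= 1),
            n_genes >= 1, n_replicates >= 1,
            diff(gene_length_range_bp) >= 0,
            diff(intergenic_gap_range_bp) >= 0,
            diff(dog_length_range_bp) >= 0,
            dog_length_range_bp[1] >= length_round_bp,
            diff(base_expression_fpkm_range) >= 0,
            base_expression_fpkm_range[1] > 0,
            dog_to_gene_coverage_ratio > 0, dog_to_gene_coverage_ratio <= 1,
            background_fpkm >= 0, library_size > 0, read_length_bp > 0,
            replicate_sigma >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_to <- function(x, unit) pmax(unit, as.integer(round(x / unit) * unit))

#' Generate a synthetic dataset with planted truth
#'
#' See [simulation_config()] for the knobs.  Returns in-memory objects and,
#' when `out_dir` is given, writes exactly the formats the pipeline consumes:
#' `genes.gtf`, one bedGraph per sample, one peak BED per condition,
#' `truth.tsv` and `samples.tsv`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return A list with `genes` (GRanges, interfering genes included),
#'   `tracks` (list of `"coverage_track"`, one per sample), `peaks` (list of
#'   GRanges per condition), `truth` (data.frame, one row per gene),
#'   `sample_sheet`, `config`, and `files` (paths, when written).
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_dataset_impl(config, out_dir))
}

simulate_dataset_impl <- function(cfg, out_dir) {
  ng <- cfg$n_genes
  glen <- round(runif(ng, cfg$gene_length_range_bp[1], cfg$gene_length_range_bp[2]))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  expressed <- runif(ng) < cfg$expressed_fraction
  lfpkm <- runif(ng, log(cfg$base_expression_fpkm_range[1]),
                 log(cfg$base_expression_fpkm_range[2]))
  fpkm0 <- ifelse(expressed, exp(lfpkm), 0)

  rt_t <- expressed & runif(ng) < cfg$readthrough_fraction_treated
  n_rt_c <- round(cfg$readthrough_fraction_control * sum(expressed))
  n_shared <- min(round(cfg$control_shared_fraction * n_rt_c), sum(rt_t))
  rt_c <- rep(FALSE, ng)
  if (n_shared > 0)
    rt_c[sample(which(rt_t), n_shared)] <- TRUE
  pool <- which(expressed & !rt_t)
  n_extra <- min(n_rt_c - n_shared, length(pool))
  if (n_extra > 0) rt_c[sample(pool, n_extra)] <- TRUE

  has_int <- rt_t & runif(ng) < cfg$interference_fraction
  lfc <- rep(0, ng)
  de <- expressed & !has_int & runif(ng) < cfg$de_fraction
  lfc[de] <- sample(c(-1, 1), sum(de), replace = TRUE) * cfg$de_log2fc
  fpkm_c <- fpkm0
  fpkm_t <- fpkm0 * 2^lfc

  u <- runif(ng)
  dog_len <- round_to(cfg$dog_length_range_bp[1] +
                        diff(cfg$dog_length_range_bp) * u^cfg$dog_length_shape,
                      cfg$length_round_bp)
  dog_len[!(rt_t | rt_c)] <- 0L
  ## interferer parents need room for a >= 4 kb call upstream of the interferer
  need <- has_int & dog_len < 6000L
  dog_len[need] <- round_to(pmin(6000L, max(cfg$dog_length_range_bp, 6000L)),
                            cfg$length_round_bp)
  int_len <- ifelse(has_int, round(runif(ng, 800, 1500)), 0L)
  has_peak <- expressed & runif(ng) < cfg$promoter_peak_fraction

  ## ---- layout (0-based half-open coordinates) -------------------------------
  margin <- 1000L
  dogspace <- ifelse(dog_len > 0, dog_len + margin, 0L)
  left_need <- ifelse(strand == "-", dogspace, 0L)   # leftward DoG space
  right_need <- ifelse(strand == "+", dogspace, 0L)  # rightward DoG space
  gaps <- round(runif(ng, cfg$intergenic_gap_range_bp[1], cfg$intergenic_gap_range_bp[2]))
  s0 <- integer(ng); e0 <- integer(ng)
  cursor <- max(2000L, left_need[1] + margin)
  for (i in seq_len(ng)) {
    if (i > 1L)
      cursor <- cursor + max(gaps[i], right_need[i - 1L] + left_need[i] + margin)
    s0[i] <- cursor
    e0[i] <- cursor + glen[i]
    cursor <- e0[i]
  }
  genome_len <- cursor + max(2000L, right_need[ng] + margin)

  ## interfering genes: opposite strand, distal end of the parent's DoG span
  ip <- which(has_int)
  int_s0 <- int_e0 <- integer(length(ip))
  for (k in seq_along(ip)) {
    i <- ip[k]
    if (strand[i] == "+") {
      int_e0[k] <- e0[i] + dog_len[i]
      int_s0[k] <- int_e0[k] - int_len[i]
    } else {
      int_s0[k] <- s0[i] - dog_len[i]
      int_e0[k] <- int_s0[k] + int_len[i]
    }
  }
  int_fpkm <- exp(runif(length(ip), log(cfg$base_expression_fpkm_range[1]),
                        log(cfg$base_expression_fpkm_range[2])))

  gene_id <- sprintf("SIMG%04d", seq_len(ng))
  int_id <- sprintf("SIMI%04d", seq_along(ip))
  all_s0 <- c(s0, int_s0); all_e0 <- c(e0, int_e0)
  all_strand <- c(strand, ifelse(strand[ip] == "+", "-", "+"))
  all_id <- c(gene_id, int_id)
  genes <- GRanges(cfg$chrom_name, IRanges(all_s0 + 1L, all_e0),
                   strand = all_strand, gene_id = all_id)
  names(genes) <- all_id
  genes <- sort(genes, ignore.strand = TRUE)

  ## ---- truth ---------------------------------------------------------------
  ratio <- cfg$dog_to_gene_coverage_ratio
  detectable <- function(f) ratio * f >= 0.2   # caller's default min FPKM
  exp_call_c <- ifelse(rt_c & detectable(fpkm_c), dog_len, 0L)
  exp_call_t <- ifelse(rt_t & detectable(fpkm_t), dog_len, 0L)
  truth <- data.frame(
    gene_id = gene_id, is_interferer = FALSE, parent_id = NA_character_,
    chrom = cfg$chrom_name, start = s0, end = e0, strand = strand,
    expressed = expressed, fpkm_control = fpkm_c, fpkm_treated = fpkm_t,
    gene_log2fc = lfc,
    dog_control_bp = ifelse(rt_c, dog_len, 0L),
    dog_treated_bp = ifelse(rt_t, dog_len, 0L),
    has_interferer = has_int, has_promoter_peak = has_peak,
    expected_call_control_bp = exp_call_c,
    expected_call_treated_bp = exp_call_t,
    expected_f1_removed_control = rt_c & has_int & exp_call_c > 0,
    expected_f1_removed_treated = has_int & exp_call_t > 0,
    stringsAsFactors = FALSE
  )
  if (length(ip) > 0L) {
    ## the interfering gene's own apparent "DoG": unstranded coverage runs
    ## from its TSS back across the parent's DoG span and gene body, stopping
    ## at the parent's TSS-side boundary
    app_len <- glen[ip] + dog_len[ip] - int_len[ip]
    app_c <- rt_c[ip] & detectable(fpkm_c[ip]) & fpkm_c[ip] >= 0.2
    app_t <- rt_t[ip] & detectable(fpkm_t[ip]) & fpkm_t[ip] >= 0.2
    truth_int <- data.frame(
      gene_id = int_id, is_interferer = TRUE, parent_id = gene_id[ip],
      chrom = cfg$chrom_name, start = int_s0, end = int_e0,
      strand = ifelse(strand[ip] == "+", "-", "+"),
      expressed = TRUE, fpkm_control = int_fpkm, fpkm_treated = int_fpkm,
      gene_log2fc = 0,
      dog_control_bp = 0L, dog_treated_bp = 0L,
      has_interferer = FALSE, has_promoter_peak = TRUE,
      expected_call_control_bp = ifelse(app_c, app_len, 0L),
      expected_call_treated_bp = ifelse(app_t, app_len, 0L),
      expected_f1_removed_control = app_c & has_peak[ip],
      expected_f1_removed_treated = app_t & has_peak[ip],
      stringsAsFactors = FALSE
    )
    truth <- rbind(truth, truth_int)
  }

  ## ---- peaks (identical for both conditions) -------------------------------
  tss0 <- ifelse(strand == "-", e0 - 1L, s0)
  int_tss0 <- ifelse(strand[ip] == "+", int_e0 - 1L, int_s0)
  peak_centers <- c(tss0[has_peak], int_tss0)
  peaks <- GRanges(cfg$chrom_name,
                   IRanges(peak_centers - 149L, peak_centers + 150L))
  peaks <- sort(peaks, ignore.strand = TRUE)

  ## ---- coverage ------------------------------------------------------------
  depth_factor <- (cfg$read_length_bp / 1000) * (cfg$library_size / 1e6)
  expected_depth <- function(cond) {
    lam <- rep(cfg$background_fpkm * depth_factor, genome_len)
    f <- if (cond == "treated") fpkm_t else fpkm_c
    rt <- if (cond == "treated") rt_t else rt_c
    for (i in seq_len(ng)) {
      if (f[i] > 0) lam[(s0[i] + 1L):e0[i]] <- lam[(s0[i] + 1L):e0[i]] + f[i] * depth_factor
      if (rt[i] && dog_len[i] > 0) {
        span <- if (strand[i] == "+") (e0[i] + 1L):(e0[i] + dog_len[i])
                else (s0[i] - dog_len[i] + 1L):s0[i]
        lam[span] <- lam[span] + ratio * f[i] * depth_factor
      }
    }
    for (k in seq_along(ip)) {
      span <- (int_s0[k] + 1L):int_e0[k]
      lam[span] <- lam[span] + int_fpkm[k] * depth_factor
    }
    lam
  }
  lam_by_cond <- list(control = expected_depth("control"),
                      treated = expected_depth("treated"))

  tracks <- list()
  sheet <- NULL
  for (cond in c("control", "treated")) {
    for (r in seq_len(cfg$n_replicates)) {
      sid <- sprintf("%s_rep%d", cond, r)
      scale <- if (cfg$replicate_sigma > 0)
        rlnorm(1, -cfg$replicate_sigma^2 / 2, cfg$replicate_sigma) else 1
      lam <- lam_by_cond[[cond]] * scale
      depth <- if (cfg$noise == "poisson") rpois(genome_len, lam) else lam
      cov <- setNames(list(Rle(depth)), cfg$chrom_name)
      tracks[[sid]] <- coverage_track(cov, cfg$library_size, sample_id = sid)
      sheet <- rbind(sheet, data.frame(
        sample_id = sid, condition = cond, replicate = r,
        coverage_path = paste0(sid, ".bedGraph"),
        library_size = cfg$library_size, read_length_bp = cfg$read_length_bp,
        stringsAsFactors = FALSE))
    }
  }

  out <- list(genes = genes, tracks = tracks,
              peaks = list(control = peaks, treated = peaks),
              truth = truth, sample_sheet = sheet, config = cfg)
  if (!is.null(out_dir)) out$files <- write_sim_dataset(out, out_dir)
  out
}

## Serialise a simulated dataset to the on-disk formats the pipeline reads.
write_sim_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  files$gtf <- file.path(out_dir, "genes.gtf")
  export_genes_gtf(sim$genes, files$gtf)
  for (cond in names(sim$peaks)) {
    p <- file.path(out_dir, sprintf("peaks_%s.bed", cond))
    rtracklayer::export(sim$peaks[[cond]], p, format = "bed")
    files[[paste0("peaks_", cond)]] <- p
  }
  for (sid in names(sim$tracks)) {
    p <- file.path(out_dir, paste0(sid, ".bedGraph"))
    export_track_bedgraph(sim$tracks[[sid]], p)
    files[[sid]] <- p
  }
  ## coverage paths stay relative to the sheet so the directory is relocatable
  files$sample_sheet <- file.path(out_dir, "samples.tsv")
  write.table(sim$sample_sheet, files$sample_sheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$truth <- file.path(out_dir, "truth.tsv")
  write.table(sim$truth, files$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  files
}

export_genes_gtf <- function(genes, path) {
  gr <- genes
  mcols(gr) <- DataFrame(source = "dogscan_sim", type = "gene",
                         gene_id = genes$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

export_track_bedgraph <- function(track, path) {
  grl <- lapply(names(track$cov), function(ch) {
    rle <- track$cov[[ch]]
    ends <- cumsum(runLength(rle))
    starts <- ends - runLength(rle) + 1L
    keep <- runValue(rle) != 0
    GRanges(ch, IRanges(starts[keep], ends[keep]), score = runValue(rle)[keep])
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' A two-condition dataset shaped like a transcription-inhibition study
#'
#' Two conditions x two replicates; the control condition has fewer and
#' weaker planted DoGs than the treated one, a configured fraction of DoG
#' genes is shared between conditions, and a small fraction of treated DoG
#' spans contains an interfering downstream gene.
#'
#' @param scale `"small"` (60 genes, quick end-to-end runs) or `"medium"`
#'   (200 genes).
#' @param seed RNG seed.
#' @return A [simulate_dataset()] result.
#' @export
make_paper_shaped_dataset <- function(scale = c("small", "medium"), seed = 1L) {
  scale <- match.arg(scale)
  cfg <- simulation_config(
    n_genes = if (scale == "small") 60L else 200L,
    readthrough_fraction_treated = 0.35,
    readthrough_fraction_control = 0.15,
    control_shared_fraction = 0.6,
    interference_fraction = 0.1,
    promoter_peak_fraction = 0.9,
    de_fraction = 0.3,
    de_log2fc = 3,
    noise = "poisson",
    seed = seed
  )
  simulate_dataset(cfg)
}
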