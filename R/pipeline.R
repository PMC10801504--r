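## End-to-end orchestration: discover -> merge -> filter -> diff -> correlate
## -> compare, with a manifest recording parameters, input checksums and
## per-stage counts so runs are auditable and reproducible.

#' Run the full DoG analysis pipeline
#'
#' @param config A list, or the path to a YAML file, with entries:
#'   \describe{
#'     \item{sample_sheet}{Path to the sample sheet TSV (see
#'       [read_sample_sheet()]).}
#'     \item{annotation}{Path to the gene annotation GTF.}
#'     \item{peaks}{Optional named list mapping condition label to a peak BED
#'       path; when absent the ChIP-seq filter stage is skipped with a notice
#'       in the manifest.}
#'     \item{control, treated}{The two condition labels.}
#'     \item{params}{Optional flat list of [dog_params()] fields.}
#'     \item{expressed_only}{Restrict discovery to expressed genes.
#'       Default `TRUE`.}
#'     \item{out_dir}{Output directory.}
#'   }
#' @param out_dir Overrides `config$out_dir`.
#' @return Invisibly, a list with the per-stage objects (`dogs_by_sample`,
#'   `merged`, `filtered`, `diff_dogs`, `diff_genes`, `correlation`,
#'   `comparison`, `manifest`).  On disk: `dogs/`, `filtered/`, `diff/`,
#'   `compare/`, `report.tsv` and `manifest.yaml` under `out_dir`; a
#'   `FAILED` marker file is left when a stage errors.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir
  stopifnot(!is.null(out_dir))
  params <- as_dog_params(config$params %||% list())
  expressed_only <- config$expressed_only %||% TRUE

  inputs <- c(sample_sheet = config$sample_sheet, annotation = config$annotation,
              unlist(config$peaks))
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0L)
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "FAILED")
  file.create(marker)
  on.exit(if (file.exists(marker)) NULL)  # marker removed only on success

  manifest <- list(
    package = paste("dogscan", as.character(packageVersion("dogscan"))),
    params = unclass(params),
    expressed_only = expressed_only,
    inputs = as.list(tools::md5sum(inputs)),
    stages = list()
  )

  sheet <- read_sample_sheet(config$sample_sheet)
  genes <- read_annotation(config$annotation)
  conds <- c(config$control, config$treated)
  if (!all(conds %in% sheet$condition))
    stop("condition label(s) absent from sample sheet: ",
         paste(setdiff(conds, sheet$condition), collapse = ", "))

  missing_cov <- sheet$coverage_path[!file.exists(sheet$coverage_path)]
  if (length(missing_cov) > 0L)
    stop("missing input file(s): ", paste(missing_cov, collapse = ", "))
  tracks <- lapply(seq_len(nrow(sheet)), function(i)
    read_coverage(sheet$coverage_path[i], sheet$library_size[i],
                  sample_id = sheet$sample_id[i]))
  names(tracks) <- sheet$sample_id

  ## -- discovery -------------------------------------------------------------
  dog_dir <- file.path(out_dir, "dogs")
  dir.create(dog_dir, showWarnings = FALSE)
  dogs_by_sample <- lapply(seq_len(nrow(sheet)), function(i) {
    d <- call_dogs_all(genes, tracks[[i]], params, expressed_only = expressed_only,
                       read_length_bp = sheet$read_length_bp[i])
    write_dogs_bed(d, file.path(dog_dir, paste0(sheet$sample_id[i], ".bed")))
    write_dogs_tsv(d, file.path(dog_dir, paste0(sheet$sample_id[i], ".tsv")))
    d
  })
  names(dogs_by_sample) <- sheet$sample_id
  manifest$stages$discovery <- lapply(dogs_by_sample, length)

  ## -- replicate union per condition ----------------------------------------
  merged <- lapply(setNames(conds, conds), function(cond) {
    m <- merge_replicates(dogs_by_sample[sheet$condition == cond], label = cond)
    write_dogs_bed(m, file.path(dog_dir, paste0("merged_", cond, ".bed")))
    m
  })
  manifest$stages$merge <- lapply(merged, length)

  ## -- ChIP-seq filters ------------------------------------------------------
  if (!is.null(config$peaks)) {
    filt_dir <- file.path(out_dir, "filtered")
    dir.create(filt_dir, showWarnings = FALSE)
    filtered <- lapply(setNames(conds, conds), function(cond) {
      pk <- read_peaks(config$peaks[[cond]], condition = cond)
      f1 <- filter_downstream_interference(merged[[cond]], pk, genes)
      f2 <- filter_promoter_peak(f1, pk, genes, params$promoter_window_bp)
      audit <- rbind(attr(f1, "audit"), attr(f2, "audit"))
      write.table(audit, file.path(filt_dir, paste0(cond, "_audit.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_dogs_bed(f2, file.path(filt_dir, paste0(cond, ".bed")))
      f2
    })
    manifest$stages$filter <- lapply(filtered, length)
  } else {
    filtered <- merged
    manifest$stages$filter <- "skipped: no peak files configured"
  }

  ## -- differential expression ----------------------------------------------
  diff_dir <- file.path(out_dir, "diff")
  dir.create(diff_dir, showWarnings = FALSE)
  union_dogs <- merge_replicates(unname(filtered), label = "union")
  res <- if (length(union_dogs) > 0L) {
    dog_regions <- granges(union_dogs)
    mcols(dog_regions) <- DataFrame(region_id = union_dogs$gene_id, kind = "dog")
    body <- genes[match(union_dogs$gene_id, genes$gene_id)]
    gene_regions <- granges(body)
    mcols(gene_regions) <- DataFrame(region_id = body$gene_id, kind = "gene_body")
    rl <- sheet$read_length_bp
    cm_dog <- count_regions(dog_regions, tracks, rl)
    cm_gene <- count_regions(gene_regions, tracks, rl)
    cm_dog$samples$condition <- cm_gene$samples$condition <- sheet$condition
    list(dogs = diff_test(cm_dog, control_label = config$control,
                          treated_label = config$treated),
         genes = diff_test(cm_gene, control_label = config$control,
                           treated_label = config$treated))
  } else list(dogs = NULL, genes = NULL)
  for (what in c("dogs", "genes")) {
    if (!is.null(res[[what]])) {
      tab <- res[[what]][order(res[[what]]$log2fc, decreasing = TRUE), ]
      write.table(tab, file.path(diff_dir, paste0(what, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest$stages$diff <- list(regions = length(union_dogs))

  ## -- gene/DoG correlation --------------------------------------------------
  cmp_dir <- file.path(out_dir, "compare")
  dir.create(cmp_dir, showWarnings = FALSE)
  correlation <- tryCatch({
    cr <- gene_dog_correlation(res$genes, res$dogs, params)
    write.table(cr$pairs, file.path(cmp_dir, "correlation_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cr
  }, error = function(e) conditionMessage(e))
  manifest$stages$correlate <-
    if (is.list(correlation)) {
      list(n_pairs = correlation$n, pearson_r = correlation$pearson_r)
    } else correlation

  ## -- set comparison --------------------------------------------------------
  shared <- common_dogs(filtered[[config$treated]], filtered[[config$control]])
  excl <- exclusive_dogs(filtered[[config$treated]], filtered[[config$control]])
  hist_edges <- seq(params$min_length_bp, params$min_length_bp + 10000, by = 1000)
  lh <- length_histogram(filtered[[config$treated]], hist_edges)
  write.table(data.frame(bin = names(lh), count = as.integer(lh)),
              file.path(cmp_dir, "length_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  membership <- data.frame(
    gene_id = union(dog_gene_ids(filtered[[config$treated]]),
                    dog_gene_ids(filtered[[config$control]])))
  membership$in_treated <- membership$gene_id %in% dog_gene_ids(filtered[[config$treated]])
  membership$in_control <- membership$gene_id %in% dog_gene_ids(filtered[[config$control]])
  write.table(membership, file.path(cmp_dir, "membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  comparison <- list(shared = shared, exclusive_treated = excl,
                     histogram = lh, membership = membership)
  manifest$stages$compare <- list(n_shared = length(shared),
                                  n_exclusive_treated = length(excl))

  report <- data.frame(
    metric = c(sprintf("dogs_%s", names(dogs_by_sample)),
               sprintf("merged_%s", conds),
               sprintf("filtered_%s", conds),
               "shared", "exclusive_treated"),
    value = c(vapply(dogs_by_sample, length, integer(1)),
              vapply(merged[conds], length, integer(1)),
              vapply(filtered[conds], length, integer(1)),
              length(shared), length(excl)))
  write.table(report, file.path(out_dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  file.remove(marker)

  invisible(list(dogs_by_sample = dogs_by_sample, merged = merged,
                 filtered = filtered, diff_dogs = res$dogs,
                 diff_genes = res$genes, correlation = correlation,
                 comparison = comparison, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
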