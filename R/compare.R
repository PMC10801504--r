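## Cross-condition / cross-cell-line DoG set algebra, length distributions,
## and the gene-versus-DoG expression correlation.  Set identity is by gene
## identifier (the Ensembl ID attached to each DoG), not by interval.

dog_gene_ids <- function(x) {
  if (is(x, "GRanges")) unique(as.character(x$gene_id)) else unique(as.character(x))
}

#' Genes with a DoG in both of two sets
#'
#' @param a,b DoG `GRanges` (or bare gene-id character vectors).
#' @return Character vector of shared gene ids; symmetric in its arguments.
#' @export
common_dogs <- function(a, b) {
  intersect(dog_gene_ids(a), dog_gene_ids(b))
}

#' Genes with a DoG exclusive to the treated set
#'
#' @param treated,control DoG `GRanges` (or gene-id character vectors).
#' @return Gene ids present in `treated` but not in `control`.
#' @export
exclusive_dogs <- function(treated, control) {
  setdiff(dog_gene_ids(treated), dog_gene_ids(control))
}

#' Overlap a DoG gene set with an external gene-symbol list
#'
#' External stress-response gene lists are usually published as symbols while
#' DoGs carry stable Ensembl-style ids, so a user-supplied mapping table is
#' applied first; unmapped ids are counted, not silently dropped into the
#' overlap.
#'
#' @param dogs Gene ids (or a DoG `GRanges`).
#' @param external Character vector of gene symbols.
#' @param id_map A `data.frame` whose first two columns map gene id to
#'   symbol, or a named character vector `c(gene_id = "SYMBOL", ...)`.
#' @return A list with `overlap` (shared symbols), `n_dogs`, `n_external`,
#'   `n_overlap`, and `n_unmapped`.
#' @export
overlap_with_gene_list <- function(dogs, external, id_map) {
  ids <- dog_gene_ids(dogs)
  if (is.data.frame(id_map)) {
    stopifnot(ncol(id_map) >= 2L)
    id_map <- setNames(as.character(id_map[[2L]]), as.character(id_map[[1L]]))
  }
  if (length(id_map) == 0L && (length(ids) > 0L || length(external) > 0L))
    stop("empty id_map with nonempty inputs")
  mapped <- id_map[ids]
  unmapped <- sum(is.na(mapped))
  if (unmapped > 0L)
    message(unmapped, " DoG gene id(s) without a symbol mapping")
  symbols <- unique(mapped[!is.na(mapped)])
  overlap <- intersect(symbols, unique(external))
  list(overlap = overlap, n_dogs = length(ids), n_external = length(unique(external)),
       n_overlap = length(overlap), n_unmapped = unmapped)
}

#' Histogram of DoG lengths
#'
#' Bins are half-open `[lo, hi)`, so a 5000-bp DoG with edges
#' `c(4000, 5000, 10000)` falls in the second bin.
#'
#' @param dogs A DoG `GRanges`.
#' @param bin_edges_bp Strictly increasing bin edges in bp.
#' @return Named integer vector of counts, one per bin.
#' @export
length_histogram <- function(dogs, bin_edges_bp) {
  stopifnot(length(bin_edges_bp) >= 2L, !is.unsorted(bin_edges_bp, strictly = TRUE))
  lens <- if (is(dogs, "GRanges")) dogs$length_bp else as.numeric(dogs)
  if (length(lens) > 0L && min(lens) < bin_edges_bp[1L])
    stop("DoG shorter than the first bin edge; edges must start at or below min_length_bp")
  idx <- findInterval(lens, bin_edges_bp, rightmost.closed = FALSE)
  nb <- length(bin_edges_bp) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  names(counts) <- paste0("[", bin_edges_bp[-length(bin_edges_bp)], ",",
                          bin_edges_bp[-1L], ")")
  counts
}

#' Classify log2 fold changes into expression classes
#'
#' Boundaries are inclusive: `log2fc >= fc_threshold` is `"Upregulated"`,
#' `log2fc <= -fc_threshold` is `"Downregulated"`, anything strictly between
#' is `"NoChange"`.
#'
#' @param log2fc Numeric vector.
#' @param fc_threshold Positive class boundary.  Default 1.2.
#' @return Factor with levels `Upregulated`, `Downregulated`, `NoChange`.
#' @export
classify_expression <- function(log2fc, fc_threshold = 1.2) {
  cls <- ifelse(log2fc >= fc_threshold, "Upregulated",
         ifelse(log2fc <= -fc_threshold, "Downregulated", "NoChange"))
  factor(cls, levels = c("Upregulated", "Downregulated", "NoChange"))
}

#' Gene-body versus DoG expression correlation
#'
#' Joins differential results for gene bodies and DoG regions by parent gene,
#' restricts to pairs significant in both (`p <= p_threshold`, inclusive),
#' computes the Pearson product-moment correlation of the two log2
#' fold-change vectors (two-sided t-distributed p-value), and classifies
#' every retained gene by its gene-body fold change.
#'
#' @param gene_results [diff_test()] output for gene bodies (`region_id` =
#'   gene id).
#' @param dog_results [diff_test()] output for the corresponding DoG regions.
#' @param params A [dog_params()]; supplies `p_threshold` and `fc_threshold`.
#' @return A list with `pairs` (data.frame: `gene_id`, `gene_log2fc`,
#'   `dog_log2fc`, `class`), `pearson_r`, `p_value`, `n`, and
#'   `class_percentages` (to one decimal, as conventionally reported).
#' @export
gene_dog_correlation <- function(gene_results, dog_results, params = dog_params()) {
  params <- as_dog_params(params)
  g <- gene_results[gene_results$p_value <= params$p_threshold, ]
  d <- dog_results[dog_results$p_value <= params$p_threshold, ]
  m <- merge(g[, c("region_id", "log2fc")], d[, c("region_id", "log2fc")],
             by = "region_id", suffixes = c("_gene", "_dog"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3L)
    stop("fewer than 3 significant gene/DoG pairs; correlation undefined")
  ct <- cor.test(m$log2fc_gene, m$log2fc_dog, method = "pearson")
  cls <- classify_expression(m$log2fc_gene, params$fc_threshold)
  pct <- round(100 * as.vector(table(cls)) / nrow(m), 1)
  names(pct) <- levels(cls)
  list(
    pairs = data.frame(gene_id = m$region_id, gene_log2fc = m$log2fc_gene,
                       dog_log2fc = m$log2fc_dog, class = cls,
                       stringsAsFactors = FALSE),
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(m),
    class_percentages = pct
  )
}
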