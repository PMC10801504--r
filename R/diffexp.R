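## Two-condition differential expression for DoG regions and gene bodies:
## region counts from coverage, median-of-ratios normalisation, and a
## moderated negative-binomial Wald test.

#' Count reads per region per sample
#'
#' Estimated read count = (summed per-base depth over the region) /
#' read length, rounded to the nearest integer.
#'
#' @param regions `GRanges` with a `region_id` metadata column (or names); an
#'   optional `kind` column distinguishes `"gene_body"` from `"dog"` regions.
#' @param tracks List of `"coverage_track"` objects, one per sample.
#' @param read_length_bp Read length(s); recycled over tracks.
#' @return A list of class `"region_counts"` with elements `counts` (regions
#'   x samples integer matrix), `regions`, and `samples` (a data.frame with
#'   `sample_id` and `library_size`).
#' @export
count_regions <- function(regions, tracks, read_length_bp = 50) {
  stopifnot(is(regions, "GRanges"))
  if (any(width(regions) <= 0)) stop("zero-length region")
  ids <- if (!is.null(regions$region_id)) regions$region_id else names(regions)
  if (is.null(ids)) stop("regions need a region_id column or names")
  read_length_bp <- rep_len(read_length_bp, length(tracks))
  chroms <- as.character(seqnames(regions))
  counts <- vapply(seq_along(tracks), function(j) {
    trk <- tracks[[j]]
    reads <- numeric(length(regions))
    for (ch in unique(chroms)) {
      i <- which(chroms == ch)
      reads[i] <- depth_sums(trk, ch, start(regions)[i], end(regions)[i])
    }
    as.integer(round(reads / read_length_bp[j]))
  }, integer(length(regions)))
  counts <- matrix(counts, nrow = length(regions),
                   dimnames = list(ids, vapply(tracks, `[[`, "", "sample_id")))
  structure(list(
    counts = counts,
    regions = regions,
    samples = data.frame(
      sample_id = colnames(counts),
      library_size = vapply(tracks, `[[`, numeric(1), "library_size"),
      stringsAsFactors = FALSE)
  ), class = "region_counts")
}

#' Median-of-ratios size factors
#'
#' The per-sample normalisation behind count-based differential expression:
#' each sample's factor is the median, over regions with nonzero counts in
#' every sample, of the ratio of its count to the region's geometric mean.
#' When no region is nonzero in all samples the factors fall back to
#' library-size ratios (scaled to geometric mean 1) with a warning.
#'
#' @param x A `"region_counts"` object or a bare counts matrix.
#' @param library_size Library sizes for the fallback when `x` is a matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x, library_size = NULL) {
  counts <- if (inherits(x, "region_counts")) x$counts else as.matrix(x)
  if (inherits(x, "region_counts")) library_size <- x$samples$library_size
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  logs <- log(counts)
  gm <- rowMeans(logs)
  use <- is.finite(gm)
  if (!any(use)) {
    warning("no region with nonzero counts in all samples; ",
            "falling back to library-size ratios")
    if (is.null(library_size)) stop("library sizes needed for the fallback")
    sf <- library_size / exp(mean(log(library_size)))
    return(setNames(sf, colnames(counts)))
  }
  sf <- apply(logs[use, , drop = FALSE], 2L, function(lc) exp(median(lc - gm[use])))
  setNames(sf, colnames(counts))
}

#' Moderated negative-binomial Wald test between two conditions
#'
#' Counts are normalised by median-of-ratios size factors; per region,
#' `log2fc = log2((mean treated + pseudocount) / (mean control + pseudocount))`
#' on the normalised scale.  The NB dispersion is estimated per region by
#' method of moments on the within-condition residuals, then moderated toward
#' the across-region mean (weight `moderation`, default 1 = common
#' dispersion) and floored at `dispersion_floor`; with two replicates per
#' condition a raw per-region estimate has one degree of freedom per
#' condition and is too unstable to calibrate a Wald test, which is why the
#' moderation exists.  The Wald statistic is `log2fc / SE(log2fc)` with the
#' standard error delta-propagated from the NB variance `mu + alpha * mu^2`
#' of each condition mean; p-values are two-sided normal tails.
#'
#' @param x A `"region_counts"` object (or counts matrix).
#' @param conditions Character vector assigning each sample (column) to a
#'   condition; taken from `x$samples$condition` when present.
#' @param control_label,treated_label The two condition labels; `log2fc` is
#'   treated over control.
#' @param pseudocount Added to both condition means before the ratio, keeping
#'   `log2fc` finite.  Default 1.
#' @param dispersion_floor Lower bound on the dispersion.  Default 0.01.
#' @param moderation Weight of the across-region mean dispersion in the
#'   per-region estimate, in `[0, 1]`.  Default 1.
#' @return A `data.frame` with `region_id`, `kind` (when available),
#'   `base_mean`, `log2fc`, `p_value`.
#' @export
diff_test <- function(x, conditions = NULL, control_label, treated_label,
                      pseudocount = 1, dispersion_floor = 0.01,
                      moderation = 1) {
  counts <- if (inherits(x, "region_counts")) x$counts else as.matrix(x)
  if (is.null(conditions) && inherits(x, "region_counts"))
    conditions <- x$samples$condition
  stopifnot(length(conditions) == ncol(counts), moderation >= 0, moderation <= 1)
  ctrl <- which(conditions == control_label)
  trt <- which(conditions == treated_label)
  if (length(ctrl) == 0L) stop("condition label '", control_label, "' not found")
  if (length(trt) == 0L) stop("condition label '", treated_label, "' not found")

  sf <- size_factors(if (inherits(x, "region_counts")) x else counts)
  n <- sweep(counts, 2L, sf, "/")
  mC <- rowMeans(n[, ctrl, drop = FALSE])
  mT <- rowMeans(n[, trt, drop = FALSE])
  log2fc <- log2((mT + pseudocount) / (mC + pseudocount))

  alpha <- moderated_dispersion(n, ctrl, trt, mC, mT,
                                floor = dispersion_floor, moderation = moderation)
  var_mC <- (mC + alpha * mC^2) / length(ctrl)
  var_mT <- (mT + alpha * mT^2) / length(trt)
  se <- sqrt(var_mC / (mC + pseudocount)^2 + var_mT / (mT + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))

  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  out <- data.frame(region_id = ids, base_mean = rowMeans(n),
                    log2fc = log2fc, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (inherits(x, "region_counts") && !is.null(x$regions$kind))
    out$kind <- x$regions$kind[match(out$region_id, x$regions$region_id)]
  out
}

## Per-region NB dispersion: method of moments on within-condition residuals
## (var = mu + alpha mu^2 per condition, averaged), truncated at zero, then
## shrunk toward the across-region mean and floored.
moderated_dispersion <- function(n, ctrl, trt, mC, mT, floor, moderation) {
  per_cond <- function(cols, m) {
    if (length(cols) < 2L) return(rep(NA_real_, nrow(n)))
    v <- apply(n[, cols, drop = FALSE], 1L, var)
    (v - m) / pmax(m, 1e-8)^2
  }
  raw <- rowMeans(cbind(per_cond(ctrl, mC), per_cond(trt, mT)), na.rm = TRUE)
  raw <- pmax(raw, 0)
  raw[!is.finite(raw)] <- NA_real_
  common <- mean(raw, na.rm = TRUE)
  if (!is.finite(common)) common <- floor
  a <- (1 - moderation) * raw + moderation * common
  a[!is.finite(a)] <- common
  pmax(a, floor)
}

#' Select significant results
#'
#' Keeps results with `p_value <= p_threshold` (inclusive).  With
#' `adjust = "BH"` the Benjamini-Hochberg adjusted p-value is thresholded
#' instead (and returned as column `p_adjusted`).
#'
#' @param results A `data.frame` from [diff_test()].
#' @param p_threshold Significance threshold, inclusive.  Default 0.05.
#' @param adjust `"none"` (raw p, the default) or `"BH"`.
#' @return The significant subset of `results`.
#' @export
significant <- function(results, p_threshold = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(results) == 0L) return(results)
  p <- results$p_value
  if (adjust == "BH") {
    results$p_adjusted <- p.adjust(p, method = "BH")
    p <- results$p_adjusted
  }
  results[p <= p_threshold, , drop = FALSE]
}
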