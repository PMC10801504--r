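#' Parameters for DoG discovery, filtering and classification
#'
#' Bundles the tunable thresholds of the pipeline.  Defaults follow common
#' practice for readthrough detection from coverage: a called DoG must be at
#' least 4 kb long, extension proceeds in 500-bp windows, and a window must
#' reach 0.2 FPKM to keep extending.
#'
#' @param min_length_bp Minimum emitted DoG length in bp (inclusive: a region
#'   of exactly `min_length_bp` is reported).  Default 4000.
#' @param window_bp Width of the extension window in bp.  Default 500.
#' @param min_fpkm Minimum FPKM a window must reach for the extension to
#'   continue.  Default 0.2.
#' @param promoter_window_bp Half-width in bp of the promoter interval
#'   `[tss - promoter_window_bp, tss + promoter_window_bp)` used by the
#'   promoter-peak filter.  Default 500.
#' @param fc_threshold Absolute log2 fold-change boundary (inclusive) between
#'   the "no change" class and the up/down classes.  Default 1.2.
#' @param p_threshold Significance threshold, inclusive (`p <= p_threshold`).
#'   Default 0.05.
#' @param max_gap_windows Number of consecutive below-threshold windows
#'   tolerated before extension stops.  Default 0 (the first failing window
#'   terminates the DoG).
#'
#' @return A list of class `"dog_params"`.
#' @examples
#' p <- dog_params()
#' p$min_length_bp
#' @export
dog_params <- function(min_length_bp = 4000L, window_bp = 500L, min_fpkm = 0.2,
                       promoter_window_bp = 500L, fc_threshold = 1.2,
                       p_threshold = 0.05, max_gap_windows = 0L) {
  min_length_bp <- as.integer(min_length_bp)
  window_bp <- as.integer(window_bp)
  stopifnot(
    window_bp > 0L,
    min_length_bp >= window_bp,
    min_fpkm >= 0,
    promoter_window_bp > 0,
    fc_threshold > 0,
    p_threshold > 0, p_threshold <= 1,
    max_gap_windows >= 0L
  )
  structure(list(
    min_length_bp = min_length_bp,
    window_bp = window_bp,
    min_fpkm = min_fpkm,
    promoter_window_bp = as.integer(promoter_window_bp),
    fc_threshold = fc_threshold,
    p_threshold = p_threshold,
    max_gap_windows = as.integer(max_gap_windows)
  ), class = "dog_params")
}

#' @export
print.dog_params <- function(x, ...) {
  cat("DoG parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_dog_params <- function(x) {
  if (inherits(x, "dog_params")) return(x)
  stopifnot(is.list(x))
  do.call(dog_params, x[intersect(names(x), names(formals(dog_params)))])
}
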