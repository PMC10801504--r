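#' FPKM of a region
#'
#' Standard definition: reads per kilobase of region per million mapped reads,
#' `read_count / ((region_length_bp/1000) * (library_size/1e6))`.
#'
#' @param read_count Estimated reads in the region (>= 0; may be fractional).
#' @param region_length_bp Region length in bp (> 0).
#' @param library_size Total mapped reads in the sample (> 0).
#' @return FPKM value(s), >= 0.  Arguments recycle like ordinary arithmetic.
#' @examples
#' fpkm(10, 500, 1e6)   # 20
#' fpkm(1, 1000, 1e7)   # 0.1
#' @export
fpkm <- function(read_count, region_length_bp, library_size) {
  if (any(region_length_bp <= 0)) stop("region_length_bp must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  read_count / ((region_length_bp / 1000) * (library_size / 1e6))
}

## Sum of per-base depth over 1-based closed [from, to] on one chromosome.
## Positions beyond the recorded extent contribute zero depth.
depth_sum <- function(track, chrom, from, to) {
  if (to < from) return(0)
  rle <- track$cov[[chrom]]
  if (is.null(rle)) return(0)
  n <- length(rle)
  from <- max(from, 1L)
  to <- min(to, n)
  if (to < from) return(0)
  sum(S4Vectors::window(rle, start = from, end = to))
}

## Vectorised window sums on one chromosome; windows beyond the extent are
## clipped (the clipped part counts as zero depth).
depth_sums <- function(track, chrom, from, to) {
  stopifnot(length(from) == length(to))
  if (length(from) == 0L) return(numeric(0))
  rle <- track$cov[[chrom]]
  out <- numeric(length(from))
  if (is.null(rle) || length(rle) == 0L) return(out)
  n <- length(rle)
  f <- pmax(from, 1L)
  t <- pmin(to, n)
  ok <- t >= f
  if (any(ok)) {
    v <- Views(rle, start = f[ok], end = t[ok])
    out[ok] <- viewSums(v)
  }
  out
}

#' Estimated read count of a window from per-base depth
#'
#' Coverage alone does not carry read counts; dividing the summed depth by the
#' read length recovers the expected number of reads that produced it.
#'
#' @param track A `"coverage_track"`.
#' @param window A single-range `GRanges` (or anything with one chromosome,
#'   start and end).  Windows beyond the recorded chromosome extent count as
#'   zero depth, not as an error.
#' @param read_length_bp Read length in bp (> 0); a sample-sheet column,
#'   default 50 there.
#' @return Estimated (possibly fractional) read count, >= 0.
#' @examples
#' trk <- coverage_track(list(chr1 = S4Vectors::Rle(4, 500)), library_size = 1e6)
#' window_reads(trk, GenomicRanges::GRanges("chr1:1-500"), 50)  # 40
#' @export
window_reads <- function(track, window, read_length_bp) {
  stopifnot(inherits(track, "coverage_track"), read_length_bp > 0)
  if (is(window, "GRanges")) {
    stopifnot(length(window) == 1L)
    chrom <- as.character(seqnames(window))
    from <- start(window); to <- end(window)
  } else {
    chrom <- window$chrom; from <- window$start; to <- window$end
  }
  depth_sum(track, chrom, from, to) / read_length_bp
}

## FPKM of each gene body in `genes` under `track`.
gene_body_fpkm <- function(genes, track, read_length_bp) {
  if (length(genes) == 0L) return(numeric(0))
  chroms <- as.character(seqnames(genes))
  reads <- numeric(length(genes))
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    reads[i] <- depth_sums(track, ch, start(genes)[i], end(genes)[i]) / read_length_bp
  }
  fpkm(reads, width(genes), track$library_size)
}
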