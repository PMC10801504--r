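## DoG discovery: windowed FPKM extension downstream of annotated 3' ends.
##
## Coordinates inside this file are reasoned about 0-based half-open (like
## BED) and converted to the 1-based GRanges convention only when ranges are
## built: for a '+' gene tes0 == end(gene); for a '-' gene tes0 ==
## start(gene) - 1, and the DoG grows leftwards.

## 0-based blocking boundary for extension downstream of `gene`.
## A neighbouring gene blocks at its TSS-side boundary (its start for '+',
## its end for '-'): reaching another gene's transcription start is the point
## where unstranded coverage can no longer be attributed to readthrough.
## In stranded mode only same-strand genes block.
blocking_boundary <- function(gene, neighbors, stranded = FALSE) {
  chrom <- as.character(seqnames(gene))
  gstrand <- as.character(strand(gene))
  nb <- neighbors[as.character(seqnames(neighbors)) == chrom]
  if (!is.null(names(nb)) && !is.null(names(gene)))
    nb <- nb[names(nb) != names(gene)]
  if (stranded) nb <- nb[as.character(strand(nb)) == gstrand]
  s0 <- start(nb) - 1L
  e0 <- end(nb)
  tss_side <- ifelse(as.character(strand(nb)) == "-", e0, s0)
  if (gstrand == "-") {
    tes0 <- start(gene) - 1L
    cand <- tss_side[s0 < tes0]          # body overlaps (-Inf, tes0)
    if (length(cand) == 0L) return(-Inf)
    max(pmin(cand, tes0))
  } else {
    tes0 <- end(gene)
    cand <- tss_side[e0 > tes0]          # body overlaps (tes0, Inf)
    if (length(cand) == 0L) return(Inf)
    min(pmax(cand, tes0))
  }
}

## Index of the last passing window given a pass/fail vector and a tolerance
## of `max_gap` consecutive failing windows; 0 when no window passes.
last_passing_window <- function(pass, max_gap = 0L) {
  last <- 0L
  streak <- 0L
  for (i in seq_along(pass)) {
    if (pass[i]) {
      last <- i
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak > max_gap) break
    }
  }
  last
}

#' Call a DoG downstream of one gene
#'
#' Starting at the gene's annotated 3' end (TES), consecutive non-overlapping
#' windows of `window_bp` are examined in the gene's 3' direction.  Extension
#' continues while the window FPKM (summed depth / read length, normalised by
#' window length and library size) is at least `min_fpkm` and the window does
#' not cross the TSS-side boundary of the nearest downstream gene (any strand
#' for unstranded tracks, same strand for stranded ones).  The window that
#' would cross such a boundary is evaluated as a partial window up to the
#' boundary, so a DoG truncated by a downstream gene need not be a multiple
#' of the window size.  A record is emitted only when the resulting region is
#' at least `min_length_bp` long (inclusive).
#'
#' @param gene A single-range `GRanges` with a `gene_id` (one element of a
#'   [read_annotation()] result).
#' @param track A `"coverage_track"`.
#' @param neighbors `GRanges` of the other annotated genes (the parent itself
#'   is ignored if present).
#' @param params A [dog_params()] object.
#' @param read_length_bp Read length used to convert depth to read counts.
#' @return A single-range DoG `GRanges` with metadata `gene_id`, `length_bp`,
#'   `mean_fpkm` (FPKM of the whole emitted region) and `sample_id`, or
#'   `NULL` when no DoG qualifies.
#' @export
call_dog <- function(gene, track, neighbors, params = dog_params(),
                     read_length_bp = 50) {
  stopifnot(is(gene, "GRanges"), length(gene) == 1L,
            inherits(track, "coverage_track"))
  params <- as_dog_params(params)
  w <- params$window_bp
  chrom <- as.character(seqnames(gene))
  minus <- as.character(strand(gene)) == "-"
  rle <- track$cov[[chrom]]
  chrlen <- if (is.null(rle)) 0L else length(rle)

  B <- blocking_boundary(gene, neighbors, stranded = track$stranded)
  if (minus) {
    tes0 <- start(gene) - 1L
    B <- max(B, 0)                      # evidence cannot precede the contig
    avail <- tes0 - B
  } else {
    tes0 <- end(gene)
    B <- min(B, chrlen)                 # no evidence beyond recorded extent
    avail <- B - tes0
  }
  if (avail < params$min_length_bp) return(NULL)   # cannot reach min length

  K <- avail %/% w                      # full windows
  part <- avail - K * w                 # partial window at the boundary
  if (minus) {
    from0 <- tes0 - seq_len(K) * w
    to0 <- from0 + w
    if (part > 0) { from0 <- c(from0, B); to0 <- c(to0, B + part) }
  } else {
    from0 <- tes0 + (seq_len(K) - 1L) * w
    to0 <- from0 + w
    if (part > 0) { from0 <- c(from0, tes0 + K * w); to0 <- c(to0, B) }
  }
  reads <- depth_sums(track, chrom, from0 + 1L, to0) / read_length_bp
  win_fpkm <- fpkm(pmax(reads, 0), to0 - from0, track$library_size)
  lp <- last_passing_window(win_fpkm >= params$min_fpkm, params$max_gap_windows)
  if (lp == 0L) return(NULL)
  len <- if (lp > K) avail else lp * w
  if (len < params$min_length_bp) return(NULL)

  reg <- if (minus) GRanges(chrom, IRanges(tes0 - len + 1L, tes0), strand = "-")
         else GRanges(chrom, IRanges(tes0 + 1L, tes0 + len), strand = "+")
  total_reads <- depth_sum(track, chrom, start(reg), end(reg)) / read_length_bp
  mcols(reg) <- DataFrame(gene_id = gene$gene_id, length_bp = len,
                          mean_fpkm = fpkm(total_reads, len, track$library_size),
                          sample_id = track$sample_id)
  names(reg) <- gene$gene_id
  reg
}

#' Call DoGs for every gene in an annotation
#'
#' @param annotation `GRanges` of gene spans (from [read_annotation()]).
#' @param track A `"coverage_track"`.
#' @param params A [dog_params()] object.
#' @param expressed_only When `TRUE`, only genes whose gene-body FPKM is at
#'   least `params$min_fpkm` are scanned (readthrough is only interpretable
#'   for transcriptionally active genes).
#' @param read_length_bp Read length used to convert depth to read counts.
#' @return A DoG `GRanges`, at most one range per gene, deterministic given
#'   its inputs.
#' @export
call_dogs_all <- function(annotation, track, params = dog_params(),
                          expressed_only = FALSE, read_length_bp = 50) {
  params <- as_dog_params(params)
  if (length(annotation) == 0L) return(empty_dogs())
  eligible <- seq_along(annotation)
  if (expressed_only) {
    gb <- gene_body_fpkm(annotation, track, read_length_bp)
    eligible <- which(gb >= params$min_fpkm)
  }
  calls <- lapply(eligible, function(i) {
    call_dog(annotation[i], track, annotation, params, read_length_bp)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0L) return(empty_dogs())
  out <- do.call(c, calls)
  sort(out, ignore.strand = TRUE)
}

empty_dogs <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(gene_id = character(0), length_bp = integer(0),
                         mean_fpkm = numeric(0), sample_id = character(0))
  gr
}

#' Merge DoG sets from replicates (union by gene)
#'
#' For a gene called in several replicates the merged region spans from the
#' TES to the farthest downstream end observed; its length is recomputed and
#' its `mean_fpkm` is the largest replicate value.
#'
#' @param dog_sets A list of DoG `GRanges` called against the same annotation.
#' @param label Optional label stored in the merged set's `sample_id` column.
#' @return A merged DoG `GRanges`.
#' @export
merge_replicates <- function(dog_sets, label = "merged") {
  dog_sets <- dog_sets[vapply(dog_sets, length, integer(1)) > 0L]
  if (length(dog_sets) == 0L) return(empty_dogs())
  all <- do.call(c, lapply(unname(dog_sets), function(g) { names(g) <- NULL; g }))
  pieces <- lapply(split(seq_along(all), all$gene_id), function(i) {
    g <- all[i]
    if (length(unique(as.character(strand(g)))) > 1L ||
        length(unique(as.character(seqnames(g)))) > 1L)
      stop("conflicting strand or chromosome for gene '", g$gene_id[1L],
           "' across replicates")
    reg <- GRanges(seqnames(g)[1L], IRanges(min(start(g)), max(end(g))),
                   strand = strand(g)[1L])
    mcols(reg) <- DataFrame(gene_id = g$gene_id[1L], length_bp = width(reg),
                            mean_fpkm = max(g$mean_fpkm), sample_id = label)
    reg
  })
  out <- do.call(c, unname(pieces))
  names(out) <- out$gene_id
  sort(out, ignore.strand = TRUE)
}
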