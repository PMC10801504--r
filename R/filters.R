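## RNAP II ChIP-seq filters.  Non-stranded RNA-seq cannot attribute coverage
## downstream of a gene to readthrough rather than to an independently
## transcribed downstream gene; promoter-proximal RNAP II pausing (a ChIP-seq
## peak 20-120 nt past the TSS of active genes) supplies the orthogonal
## evidence these two filters use.

#' Discard DoGs that look like transcription of a downstream gene
#'
#' A DoG is discarded when its region overlaps (by at least 1 bp) a gene
#' other than its parent *and* at least one RNAP II peak lies (at least 1 bp
#' overlap) within the DoG region — i.e. when the "readthrough" signal is
#' better explained by an active downstream gene.  With `peak_only = TRUE`
#' the stricter reading is applied: any peak inside the DoG region discards
#' it, covered gene or not.
#'
#' @param dogs A DoG `GRanges`.
#' @param peaks A peak `GRanges` from the same condition as the calls.
#' @param annotation Gene `GRanges` (from [read_annotation()]).
#' @param peak_only Apply the peak-only variant of the rule.  Default `FALSE`.
#' @return The surviving DoGs, unchanged and in order.  An `"audit"`
#'   attribute records, per discarded DoG, the triggering gene and peak.
#' @export
filter_downstream_interference <- function(dogs, peaks, annotation,
                                           peak_only = FALSE) {
  if (length(dogs) == 0L) return(dogs)
  others_hit <- findOverlaps(dogs, annotation, ignore.strand = TRUE)
  others_hit <- others_hit[
    dogs$gene_id[queryHits(others_hit)] != annotation$gene_id[subjectHits(others_hit)]]
  peak_hit <- findOverlaps(dogs, peaks, ignore.strand = TRUE)
  has_gene <- tabulate(queryHits(others_hit), length(dogs)) > 0L
  has_peak <- tabulate(queryHits(peak_hit), length(dogs)) > 0L
  drop <- if (peak_only) has_peak else has_gene & has_peak
  audit <- data.frame(
    gene_id = dogs$gene_id[drop],
    removed_by = rep("downstream_interference", sum(drop)),
    trigger_gene = vapply(which(drop), function(i) {
      g <- annotation$gene_id[subjectHits(others_hit)[queryHits(others_hit) == i]]
      if (length(g)) g[1L] else NA_character_
    }, character(1)),
    trigger_peak = vapply(which(drop), function(i) {
      p <- peaks[subjectHits(peak_hit)[queryHits(peak_hit) == i]]
      if (length(p)) as.character(p[1L]) else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE
  )
  out <- dogs[!drop]
  attr(out, "audit") <- audit
  out
}

#' Keep only DoGs whose parent gene has a promoter-proximal RNAP II peak
#'
#' A DoG is kept iff at least one peak overlaps the promoter interval
#' `[tss - promoter_window_bp, tss + promoter_window_bp)` of its parent gene
#' — evidence that the parent was transcriptionally engaged, so a readthrough
#' interpretation is plausible.  Order is preserved.
#'
#' @inheritParams filter_downstream_interference
#' @param promoter_window_bp Half-width of the promoter interval in bp.  The
#'   pausing signal sits 20-120 nt past the TSS; the 500 bp default tolerates
#'   peak-caller summit spread.
#' @return The surviving DoGs with an `"audit"` attribute for the removals.
#' @export
filter_promoter_peak <- function(dogs, peaks, annotation,
                                 promoter_window_bp = 500L) {
  stopifnot(promoter_window_bp > 0)
  if (length(dogs) == 0L) return(dogs)
  if (length(peaks) == 0L)
    warning("empty peak set: no promoter evidence, all DoGs discarded")
  parent <- match(dogs$gene_id, annotation$gene_id)
  if (anyNA(parent))
    stop("DoG parent gene(s) absent from annotation: ",
         paste(unique(dogs$gene_id[is.na(parent)]), collapse = ", "))
  tss0 <- gene_tss(annotation)[parent] - 1L     # 0-based position of the TSS base
  prom <- GRanges(seqnames(annotation)[parent],
                  IRanges(tss0 - promoter_window_bp + 1L,
                          tss0 + promoter_window_bp))
  keep <- countOverlaps(prom, peaks, ignore.strand = TRUE) > 0L
  audit <- data.frame(
    gene_id = dogs$gene_id[!keep],
    removed_by = rep("no_promoter_peak", sum(!keep)),
    trigger_gene = NA_character_[seq_len(sum(!keep))],
    trigger_peak = NA_character_[seq_len(sum(!keep))],
    stringsAsFactors = FALSE
  )
  out <- dogs[keep]
  attr(out, "audit") <- audit
  out
}
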