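suppressPackageStartupMessages(library(GenomicRanges))

# Brute-force reference implementation of the windowed DoG scan, kept fully
# independent of the package internals: plain numeric depth vectors, explicit
# per-window sums recomputed from scratch, and an explicit loop over
# neighbouring genes for the blocking boundary.  Used to cross-check
# call_dog()/call_dogs_all() boundary for boundary.

# genes_df: data.frame(gene_id, s0, e0, strand) in 0-based half-open coords.
oracle_call_dogs <- function(genes_df, depth, library_size, read_length = 50,
                             min_len = 4000, w = 500, min_fpkm = 0.2,
                             expressed_only = FALSE) {
  glen <- length(depth)
  win_fpkm <- function(a, b) {     # 0-based half-open window [a, b)
    if (b <= a) return(0)
    lo <- max(a + 1, 1); hi <- min(b, glen)
    reads <- if (hi >= lo) sum(depth[lo:hi]) / read_length else 0
    reads / (((b - a) / 1000) * (library_size / 1e6))
  }
  out <- NULL
  for (i in seq_len(nrow(genes_df))) {
    g <- genes_df[i, ]
    if (expressed_only && win_fpkm(g$s0, g$e0) < min_fpkm) next
    others <- genes_df[-i, ]
    tss_side <- ifelse(others$strand == "-", others$e0, others$s0)
    if (g$strand == "+") {
      tes0 <- g$e0
      cand <- tss_side[others$e0 > tes0]
      B <- min(c(pmax(cand, tes0), glen))
      last_end <- tes0
      k <- 0
      repeat {
        a <- tes0 + k * w
        if (a >= B) break
        b <- min(a + w, B)
        if (win_fpkm(a, b) < min_fpkm) break
        last_end <- b
        k <- k + 1
      }
      len <- last_end - tes0
      if (len >= min_len)
        out <- rbind(out, data.frame(gene_id = g$gene_id, s0 = tes0,
                                     e0 = tes0 + len, len = len))
    } else {
      tes0 <- g$s0
      cand <- tss_side[others$s0 < tes0]
      B <- max(c(pmin(cand, tes0), 0))
      last_start <- tes0
      k <- 0
      repeat {
        b <- tes0 - k * w
        if (b <= B) break
        a <- max(b - w, B)
        if (win_fpkm(a, b) < min_fpkm) break
        last_start <- a
        k <- k + 1
      }
      len <- tes0 - last_start
      if (len >= min_len)
        out <- rbind(out, data.frame(gene_id = g$gene_id, s0 = tes0 - len,
                                     e0 = tes0, len = len))
    }
  }
  if (is.null(out)) data.frame(gene_id = character(0), s0 = integer(0),
                               e0 = integer(0), len = integer(0))
  else out[order(out$gene_id), , drop = FALSE]
}

# GRanges gene annotation -> the 0-based data.frame the oracle consumes.
genes_to_df <- function(genes) {
  data.frame(gene_id = genes$gene_id,
             s0 = GenomicRanges::start(genes) - 1L,
             e0 = GenomicRanges::end(genes),
             strand = as.character(GenomicRanges::strand(genes)),
             stringsAsFactors = FALSE)
}

# DoG GRanges -> comparable 0-based table.
dogs_to_df <- function(dogs) {
  if (length(dogs) == 0L)
    return(data.frame(gene_id = character(0), s0 = integer(0),
                      e0 = integer(0), len = integer(0)))
  d <- data.frame(gene_id = dogs$gene_id,
                  s0 = GenomicRanges::start(dogs) - 1L,
                  e0 = GenomicRanges::end(dogs),
                  len = dogs$length_bp, stringsAsFactors = FALSE)
  d <- d[order(d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

make_track <- function(depth, library_size = 1e6, sample_id = "s1",
                       chrom = "chr1") {
  coverage_track(setNames(list(S4Vectors::Rle(depth)), chrom), library_size,
                 sample_id = sample_id)
}

make_gene <- function(start, end, strand = "+", id = "G1", chrom = "chr1") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand, gene_id = id)
  names(g) <- id
  g
}
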