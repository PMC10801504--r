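## File ingestion: GTF annotation, bedGraph coverage, BED peaks, sample sheet.
## All parsing is delegated to rtracklayer; this layer adds the validation and
## the gene-level summarisation the pipeline needs.  Internally everything
## lives in GRanges (1-based, closed); BED/bedGraph offsets are converted at
## the boundary by rtracklayer.

apply_chrom_alias <- function(gr, chrom_alias = NULL) {
  if (is.null(chrom_alias)) return(gr)
  if (is.character(chrom_alias) && length(chrom_alias) == 1L && file.exists(chrom_alias)) {
    tab <- read.delim(chrom_alias, header = FALSE, stringsAsFactors = FALSE)
    chrom_alias <- setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  }
  stopifnot(is.character(chrom_alias), !is.null(names(chrom_alias)))
  lv <- seqlevels(gr)
  hit <- lv %in% names(chrom_alias)
  lv[hit] <- chrom_alias[lv[hit]]
  seqlevels(gr) <- lv
  gr
}

#' Read a gene annotation from a GTF file
#'
#' Builds one record per `gene_id` spanning the union of all its rows (so a
#' multi-transcript gene gets its full transcribed span).  Chromosome names
#' are taken verbatim; supply `chrom_alias` to rename explicitly — no silent
#' "chr"-prefix harmonisation is done, since silent renaming hides data
#' errors.
#'
#' @param path Path to a GTF file (Ensembl-style attributes).
#' @param dialect Name of the attribute carrying the gene identifier.
#'   Default `"gene_id"`.
#' @param chrom_alias Optional named character vector (or two-column TSV path)
#'   mapping chromosome names in the file to the names used elsewhere.
#' @return A [GenomicRanges::GRanges] with one range per gene, metadata column
#'   `gene_id`, and names set to `gene_id`.  Genes annotated with conflicting
#'   strands across records are dropped with a warning.
#' @seealso [gene_tss()], [gene_tes()] for the strand-aware endpoints.
#' @export
read_annotation <- function(path, dialect = "gene_id", chrom_alias = NULL) {
  stopifnot(file.exists(path))
  if (validate_gtf_lines(path) == 0L) {
    warning("annotation file '", path, "' contains no records")
    return(GRanges(gene_id = character(0)))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ", conditionMessage(e))
  )
  if (length(gr) == 0L) {
    warning("annotation file '", path, "' contains no records")
    return(GRanges(gene_id = character(0)))
  }
  if (!dialect %in% names(mcols(gr)))
    stop("GTF records carry no '", dialect, "' attribute")
  gid <- as.character(mcols(gr)[[dialect]])
  if (anyNA(gid)) stop("GTF records with missing '", dialect, "' attribute")
  gr <- apply_chrom_alias(gr, chrom_alias)

  chrom <- as.character(seqnames(gr))
  std <- as.character(strand(gr))
  spans <- lapply(split(seq_along(gr), gid), function(i) {
    if (length(unique(std[i])) > 1L || length(unique(chrom[i])) > 1L) return(NULL)
    c(min(start(gr)[i]), max(end(gr)[i]), i[1L])
  })
  bad <- vapply(spans, is.null, logical(1))
  if (any(bad)) {
    warning("dropping ", sum(bad), " gene(s) with conflicting strand or chromosome: ",
            paste(names(spans)[bad], collapse = ", "))
    spans <- spans[!bad]
  }
  if (length(spans) == 0L) return(GRanges(gene_id = character(0)))
  m <- do.call(rbind, spans)
  out <- GRanges(chrom[m[, 3L]], IRanges(m[, 1L], m[, 2L]), strand = std[m[, 3L]],
                 gene_id = names(spans))
  names(out) <- out$gene_id
  sort(out, ignore.strand = TRUE)
}

## Cheap structural check so a malformed row is reported with its line number
## (rtracklayer's own errors do not carry one).
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|\\s*$)", lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ", length(f))
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L]))))
      stop("malformed GTF line ", i, ": non-numeric coordinates")
  }
  length(body)
}

#' Strand-aware transcription start / end positions
#'
#' For a `+` gene the TSS is the leftmost base and the TES (the annotated 3'
#' end, downstream of which a DoG begins) the rightmost; mirrored for `-`.
#' Positions are 1-based base coordinates.
#'
#' @param genes A `GRanges` of gene spans (as from [read_annotation()]).
#' @return Integer vector of positions, named by `gene_id` when present.
#' @export
gene_tss <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  setNames(as.integer(pos), names(genes))
}

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
  setNames(as.integer(pos), names(genes))
}

#' Build a coverage track
#'
#' A coverage track is a per-base depth signal (one run-length-encoded vector
#' per chromosome) plus the sample's total mapped-read count, which FPKM
#' normalisation needs and which cannot be recovered from coverage alone.
#'
#' @param cov An [S4Vectors::RleList]-like list of per-chromosome depth, or a
#'   `GRanges` with a `score` column of non-overlapping intervals.
#' @param library_size Total mapped reads for the sample (> 0).
#' @param sample_id Sample label.
#' @param stranded Whether the library preserves strand.  Default `FALSE`
#'   (single-end, non-stranded data is the motivating case).
#' @return A list of class `"coverage_track"`.
#' @export
coverage_track <- function(cov, library_size, sample_id = "sample",
                           stranded = FALSE) {
  stopifnot(is.numeric(library_size), length(library_size) == 1L, library_size > 0)
  if (is(cov, "GRanges")) {
    stopifnot("score" %in% names(mcols(cov)))
    cov <- coverage(cov, weight = "score")
  }
  if (is.list(cov)) cov <- methods::as(lapply(cov, Rle), "SimpleRleList")
  if (any(vapply(cov, function(r) any(runValue(r) < 0), logical(1))))
    stop("coverage contains negative values")
  structure(list(sample_id = as.character(sample_id), cov = cov,
                 library_size = as.numeric(library_size),
                 stranded = isTRUE(stranded)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s': %d chromosome(s), library size %.0f, %s\n",
              x$sample_id, length(x$cov), x$library_size,
              if (x$stranded) "stranded" else "unstranded"))
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' Reconstructs per-base depth from a bedGraph of non-overlapping intervals;
#' any region absent from the file has depth 0.
#'
#' @inheritParams read_annotation
#' @param path Path to a bedGraph file.
#' @param library_size Total mapped reads for the sample (> 0); taken from the
#'   sample sheet, never inferred from coverage.
#' @param sample_id Sample label.
#' @param stranded Strandedness flag stored on the track.
#' @return A `"coverage_track"`.
#' @export
read_coverage <- function(path, library_size, sample_id = basename(path),
                          stranded = FALSE, chrom_alias = NULL) {
  stopifnot(file.exists(path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("failed to parse bedGraph '", path, "': ",
                             conditionMessage(e))
  )
  gr <- apply_chrom_alias(gr, chrom_alias)
  if (length(gr) == 0L)
    return(coverage_track(methods::as(list(), "SimpleRleList"), library_size,
                          sample_id = sample_id, stranded = stranded))
  if (any(gr$score < 0)) {
    bad <- which(gr$score < 0)
    stop("negative coverage in '", path, "' at record(s) ",
         paste(head(bad, 5L), collapse = ", "))
  }
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0L) {
    stop("overlapping bedGraph intervals in '", path, "': records ",
         paste(unique(pmin(queryHits(hits), subjectHits(hits)))[1:min(5, length(hits))],
               collapse = ", "))
  }
  coverage_track(gr, library_size, sample_id = sample_id, stranded = stranded)
}

#' Read RNAP II ChIP-seq peaks from a BED file
#'
#' @inheritParams read_annotation
#' @param path Path to a BED3+ file of peak coordinates.
#' @param condition Optional condition label stored in the result's metadata.
#' @return A sorted `GRanges`; peaks on chromosomes absent from any annotation
#'   are retained (peaks need no annotation match).
#' @export
read_peaks <- function(path, condition = NULL, chrom_alias = NULL) {
  stopifnot(file.exists(path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("failed to parse BED '", path, "': ",
                             conditionMessage(e))
  )
  gr <- apply_chrom_alias(gr, chrom_alias)
  seqlevels(gr) <- sort(seqlevels(gr))
  gr <- sort(gr, ignore.strand = TRUE)
  if (!is.null(condition)) metadata(gr)$condition <- condition
  gr
}

#' Read the sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `condition`,
#' `replicate`, `coverage_path`, `library_size` and optionally
#' `read_length_bp` (default 50).  `library_size` is declared here rather than
#' inferred, because coverage files lose the unmapped/multi-mapped context.
#'
#' @param path Path to the TSV.
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  sheet <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "condition", "replicate", "coverage_path", "library_size")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0L)
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (any(sheet$library_size <= 0)) stop("library_size must be > 0")
  if (is.null(sheet$read_length_bp)) sheet$read_length_bp <- 50L
  ## relative coverage paths are resolved against the sheet's own directory,
  ## so a dataset directory is relocatable
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$coverage_path)
  sheet$coverage_path[rel] <- file.path(dirname(path), sheet$coverage_path[rel])
  sheet
}

#' Write a DoG set as BED6 and/or TSV
#'
#' The BED score encodes expression as `round(1000 * min(mean_fpkm, 1))`.
#' The TSV uses BED-style 0-based half-open coordinates so both files agree.
#'
#' @param dogs A DoG `GRanges` (see [call_dogs_all()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dogs_bed <- function(dogs, path) {
  out <- granges(dogs)
  mcols(out)$name <- dogs$gene_id
  mcols(out)$score <- round(1000 * pmin(dogs$mean_fpkm, 1))
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' @rdname write_dogs_bed
#' @export
write_dogs_tsv <- function(dogs, path) {
  df <- data.frame(
    gene_id = dogs$gene_id,
    chrom = as.character(seqnames(dogs)),
    start = start(dogs) - 1L,
    end = end(dogs),
    length_bp = dogs$length_bp,
    mean_fpkm = dogs$mean_fpkm,
    sample_id = if (is.null(dogs$sample_id)) NA_character_ else dogs$sample_id,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DoG BED file back into a DoG GRanges
#'
#' Inverse of [write_dogs_bed()]: `name` becomes `gene_id` and the score is
#' decoded to a (saturated) mean FPKM.
#'
#' @param path Path to a BED6 file written by [write_dogs_bed()].
#' @return A DoG `GRanges`.
#' @export
read_dogs_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mcols(gr) <- DataFrame(gene_id = gr$name, length_bp = width(gr),
                         mean_fpkm = gr$score / 1000)
  names(gr) <- gr$gene_id
  gr
}
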