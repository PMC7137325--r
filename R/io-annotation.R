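#' Transcript model collection
#'
#' A `transcript_db` holds gene annotation in 0-based half-open genomic
#' coordinates: one row per transcript (with its optional CDS span and a
#' TPM abundance) and one row per exon. 5'/3' UTR intervals are derived
#' from exons minus the CDS span on demand.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `tpm`, `cds_start`, `cds_end` (`NA` when the
#'   transcript is non-coding).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`.
#' @return object of class `transcript_db`.
#' @export
transcript_db <- function(transcripts, exons) {
  need_t <- c("transcript_id", "gene_id", "chrom", "strand", "tpm",
              "cds_start", "cds_end")
  need_e <- c("transcript_id", "start", "end")
  stopifnot(all(need_t %in% names(transcripts)), all(need_e %in% names(exons)))
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  if (nrow(exons) && any(exons$end <= exons$start))
    stop("validation error: exon with end <= start")
  if (any(!is.na(transcripts$tpm) & transcripts$tpm < 0))
    stop("tpm must be non-negative")
  ## exons within a transcript must be disjoint; CDS inside the exon union
  for (tid in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("validation error: overlapping exons in transcript ", tid)
    tr <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
    if (nrow(tr) == 1L && !is.na(tr$cds_start)) {
      inside <- any(ex$start <= tr$cds_start & tr$cds_start < ex$end) &&
        any(ex$start < tr$cds_end & tr$cds_end <= ex$end)
      if (!inside || tr$cds_start >= tr$cds_end)
        stop("validation error: CDS outside exons in transcript ", tid)
    }
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_db")
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("transcript_db:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

exons_of <- function(db, tid) {
  db$exons[db$exons$transcript_id == tid, , drop = FALSE]
}

#' Read a GENCODE-style GTF into a transcript_db
#'
#' GTF 1-based closed coordinates are converted to the package's 0-based
#' half-open convention. UTRs are not read from the file; they are derived
#' from exons minus the CDS span.
#'
#' @param path GTF file.
#' @param tpm optional data.frame (`transcript_id`, `tpm`) to populate
#'   abundances; transcripts absent from the table get `tpm = NA`.
#' @return a [transcript_db].
#' @export
read_annotation <- function(path, tpm = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  ex <- gr[typ == "exon"]
  if (!length(ex)) stop("GTF contains no exon features")
  exons <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE)
  tinfo <- data.frame(
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  tinfo <- tinfo[!duplicated(tinfo$transcript_id), , drop = FALSE]
  cds <- gr[typ == "CDS"]
  if (length(cds)) {
    cdf <- data.frame(
      transcript_id = as.character(S4Vectors::mcols(cds)$transcript_id),
      start = GenomicRanges::start(cds) - 1L,
      end = GenomicRanges::end(cds))
    cspan <- do.call(rbind, lapply(split(cdf, cdf$transcript_id), function(d)
      data.frame(transcript_id = d$transcript_id[1L],
                 cds_start = min(d$start), cds_end = max(d$end))))
  } else {
    cspan <- data.frame(transcript_id = character(0),
                        cds_start = integer(0), cds_end = integer(0))
  }
  tinfo$cds_start <- cspan$cds_start[match(tinfo$transcript_id, cspan$transcript_id)]
  tinfo$cds_end <- cspan$cds_end[match(tinfo$transcript_id, cspan$transcript_id)]
  tinfo$tpm <- if (is.null(tpm)) NA_real_ else
    tpm$tpm[match(tinfo$transcript_id, tpm$transcript_id)]
  transcript_db(tinfo, exons)
}

#' Write a transcript_db back to GTF (1-based closed on disk)
#' @param db a [transcript_db].
#' @param path output file.
#' @export
write_annotation <- function(db, path) {
  tr <- db$transcripts
  rows <- character(0)
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    ex <- exons_of(db, t$transcript_id)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id, t$transcript_id)
    feat <- function(type, s, e)
      sprintf("%s\teclipatlas\t%s\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, type, s + 1L, e, t$strand, attrs)
    rows <- c(rows, feat("transcript", min(ex$start), max(ex$end)),
              mapply(feat, "exon", ex$start, ex$end))
    if (!is.na(t$cds_start)) {
      cd <- intersect_with_span(ex, t$cds_start, t$cds_end)
      rows <- c(rows, mapply(feat, "CDS", cd$start, cd$end))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

## clip exon list to [s, e), dropping empty pieces
intersect_with_span <- function(ex, s, e) {
  out <- data.frame(start = pmax(ex$start, s), end = pmin(ex$end, e))
  out[out$start < out$end, , drop = FALSE]
}

## exon pieces strictly before s / at-or-after e (genomic orientation)
exons_before <- function(ex, s) {
  out <- data.frame(start = ex$start, end = pmin(ex$end, s))
  out[out$start < out$end, , drop = FALSE]
}
exons_after <- function(ex, e) {
  out <- data.frame(start = pmax(ex$start, e), end = ex$end)
  out[out$start < out$end, , drop = FALSE]
}

#' Genomic region intervals of one transcript
#'
#' Returns the CDS, 5'UTR and 3'UTR genomic intervals (derived from exons
#' minus the CDS span; empty for non-coding transcripts), plus introns.
#' UTR sidedness respects strand.
#'
#' @param db a [transcript_db]; `tid` a transcript id.
#' @return list of data.frames `cds`, `utr5`, `utr3`, `introns`, `exons`.
#' @export
transcript_regions <- function(db, tid) {
  t <- db$transcripts[db$transcripts$transcript_id == tid, , drop = FALSE]
  if (nrow(t) != 1L) stop("unknown transcript ", tid)
  ex <- exons_of(db, tid)
  introns <- if (nrow(ex) > 1L)
    data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L]) else
    data.frame(start = integer(0), end = integer(0))
  empty <- data.frame(start = integer(0), end = integer(0))
  if (is.na(t$cds_start)) {
    cds <- utr5 <- utr3 <- empty
  } else {
    cds <- intersect_with_span(ex, t$cds_start, t$cds_end)
    left <- exons_before(ex, t$cds_start)
    right <- exons_after(ex, t$cds_end)
    if (t$strand == "+") { utr5 <- left; utr3 <- right }
    else { utr5 <- right; utr3 <- left }
  }
  lapply(list(cds = cds, utr5 = utr5, utr3 = utr3, introns = introns,
              exons = ex[c("start", "end")]),
         function(d) {
           d$chrom <- rep(t$chrom, nrow(d))
           d$strand <- rep(t$strand, nrow(d))
           d
         })
}
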