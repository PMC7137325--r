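#' Extract branch-point search windows at 3' splice sites
#'
#' For every annotated intron (deduplicated by 3' splice site position
#' and strand), counts read 5' ends at each offset of the -50..-15
#' window upstream of the 3' splice site, measured 5' to 3' on the
#' transcript strand. Introns shorter than the window are truncated with
#' a warning.
#'
#' @param tx_db a [transcript_db].
#' @param reads data.frame with `chrom`, `pos5` (0-based genomic
#'   position of the strand-aware read 5' end), `strand`.
#' @param from,to window offsets (defaults -50, -15, both inclusive).
#' @return data.frame: `intron_id`, `chrom`, `strand`, `three_ss`,
#'   `offset`, `count` (one row per window offset).
#' @export
extract_bp_windows <- function(tx_db, reads, from = -50L, to = -15L) {
  introns <- annotation_introns(tx_db)
  out <- list()
  truncated <- 0L
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    ilen <- it$end - it$start
    lo <- from
    if (ilen < -from) { lo <- -ilen; truncated <- truncated + 1L }
    offs <- seq.int(lo, to)
    pos <- bp_window_positions(it$three_ss, it$strand, lo, to)
    sel <- reads$chrom == it$chrom & reads$strand == it$strand
    cnt <- tabulate(match(reads$pos5[sel], pos), nbins = length(pos))
    out[[i]] <- data.frame(intron_id = it$intron_id, chrom = it$chrom,
                           strand = it$strand, three_ss = it$three_ss,
                           offset = offs, count = cnt,
                           stringsAsFactors = FALSE)
  }
  if (truncated) warning(truncated, " intron(s) shorter than the window; truncated")
  do.call(rbind, out)
}

#' Call candidate branch points from truncation pileups
#'
#' A window yields a call when it holds at least `min_reads` read 5'
#' ends and a single offset carries strictly more than `min_fraction` of
#' them (such an offset is necessarily unique). The branch point is one
#' base 5' of the modal read start: reverse transcription terminates at
#' the branch adenosine, so reads begin at the next base.
#'
#' @param windows output of [extract_bp_windows].
#' @param min_reads minimum reads in the window (default 20).
#' @param min_fraction modal-fraction threshold, strict (default 0.5).
#' @return data.frame, one row per call: `intron_id`, `chrom`, `strand`,
#'   `three_ss`, `mode_offset`, `bp_offset`, `bp_pos` (0-based genomic),
#'   `n_region_reads`, `mode_fraction`.
#' @export
call_branchpoints <- function(windows, min_reads = 20L, min_fraction = 0.5) {
  calls <- list()
  by_intron <- split(windows, windows$intron_id)
  for (id in names(by_intron)) {
    w <- by_intron[[id]]
    n <- sum(w$count)
    if (n < min_reads) next
    mx <- max(w$count)
    if (mx <= min_fraction * n) next
    j <- which(w$count == mx)[1L]   # unique: mx > n/2
    mode_offset <- w$offset[j]
    bp_offset <- mode_offset - 1L
    mode_pos <- bp_window_positions(w$three_ss[1L], w$strand[1L],
                                    mode_offset, mode_offset)
    bp_pos <- if (w$strand[1L] == "+") mode_pos - 1L else mode_pos + 1L
    calls[[length(calls) + 1L]] <- data.frame(
      intron_id = id, chrom = w$chrom[1L], strand = w$strand[1L],
      three_ss = w$three_ss[1L], mode_offset = mode_offset,
      bp_offset = bp_offset, bp_pos = bp_pos, n_region_reads = n,
      mode_fraction = mx / n, stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(intron_id = character(0), chrom = character(0),
                      strand = character(0), three_ss = integer(0),
                      mode_offset = integer(0), bp_offset = integer(0),
                      bp_pos = integer(0), n_region_reads = integer(0),
                      mode_fraction = numeric(0)))
  do.call(rbind, calls)
}

#' Branch-point motif: position frequency matrix and information content
#'
#' Extracts 11-mers (5 nt flanking on either side) around each call,
#' anchored by default on the putative branch-point base (one base 5' of
#' the modal read start); `anchor = "read_start"` centers on the read
#' start instead. Sequences from minus-strand calls are
#' reverse-complemented. Information per column is
#' `2 + sum(f * log2(f))` bits.
#'
#' @param calls output of [call_branchpoints].
#' @param genome named character vector of chromosome sequences.
#' @param anchor `"bp"` or `"read_start"`.
#' @param flank flanking bases on each side (default 5).
#' @return list: `pfm` (4 x width count matrix), `information` (bits per
#'   column), `kmers`.
#' @export
branchpoint_motif <- function(calls, genome, anchor = c("bp", "read_start"),
                              flank = 5L) {
  anchor <- match.arg(anchor)
  if (nrow(calls) == 0L) stop("no branch-point calls")
  kmers <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    center <- if (anchor == "bp") cl$bp_pos else
      if (cl$strand == "+") cl$bp_pos + 1L else cl$bp_pos - 1L
    chrseq <- genome[[cl$chrom]]
    lo <- center - flank; hi <- center + flank
    if (lo < 0L || hi >= nchar(chrseq)) { skipped <- skipped + 1L; next }
    s <- substr(chrseq, lo + 1L, hi + 1L)
    if (cl$strand == "-") s <- revcomp(s)
    kmers <- c(kmers, s)
  }
  if (skipped) warning(skipped, " call(s) too close to sequence end; skipped")
  if (!length(kmers)) stop("no motif windows extractable")
  pfm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(kmers))
  pfm <- pfm[intersect(c("A", "C", "G", "T"), rownames(pfm)), , drop = FALSE]
  full <- matrix(0L, 4L, 2L * flank + 1L, dimnames = list(c("A", "C", "G", "T")))
  full[rownames(pfm), ] <- pfm
  f <- sweep(full, 2L, colSums(full), "/")
  info <- 2 + colSums(ifelse(f > 0, f * log2(f), 0))
  list(pfm = full, information = info, kmers = kmers)
}
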