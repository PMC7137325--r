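#' Simulate branch-point truncation reads
#'
#' For each annotated intron (3' splice sites deduplicated by position
#' and strand) a true branch point is placed on an adenosine within the
#' -50..-15 window upstream of the 3' splice site. `truncation_fraction`
#' of that intron's reads start exactly one base 3' of the branch point
#' (reverse transcription cannot read through the branch adenosine); the
#' rest start uniformly in the window. Introns without an A in the window
#' or excluded by `exclude` get uniform starts only and no truth entry.
#'
#' @param cfg a [sim_config] (`reads_per_intron`, `truncation_fraction`).
#' @param genome_ann output of [simulate_genome_annotation].
#' @param exclude intron ids excluded from the truth set.
#' @return list: `reads` (data.frame `read_id`, `chrom`, `pos5`,
#'   `strand`), `truth` (data.frame `intron_id`, `chrom`, `strand`,
#'   `three_ss`, `bp_pos`, `bp_offset`).
#' @export
simulate_branchpoint_reads <- function(cfg, genome_ann, exclude = character(0)) {
  if (cfg$truncation_fraction < 0 || cfg$truncation_fraction > 1)
    stop("truncation_fraction must lie in [0, 1]")
  introns <- annotation_introns(genome_ann$tx_db)
  if (any(introns$end - introns$start < 100L))
    stop("introns must be at least 100 nt")
  with_seed(cfg$seed + 3L, {
    reads <- list(); truth <- list()
    serial <- 0L
    for (i in seq_len(nrow(introns))) {
      it <- introns[i, ]
      wpos <- bp_window_positions(it$three_ss, it$strand)  # offsets -50..-15
      base <- substring(genome_ann$genome[[it$chrom]], wpos + 1L, wpos + 1L)
      want <- if (it$strand == "+") "A" else "T"
      cand <- which(base == want)
      n <- cfg$reads_per_intron
      plant <- length(cand) > 0L && !(it$intron_id %in% exclude)
      if (plant) {
        bp_i <- cand[sample.int(length(cand), 1L)]
        bp_pos <- wpos[bp_i]
        n_trunc <- stats::rbinom(1L, n, cfg$truncation_fraction)
        start_trunc <- if (it$strand == "+") bp_pos + 1L else bp_pos - 1L
        starts <- c(rep(start_trunc, n_trunc),
                    wpos[sample.int(length(wpos), n - n_trunc, replace = TRUE)])
        truth[[length(truth) + 1L]] <- data.frame(
          intron_id = it$intron_id, chrom = it$chrom, strand = it$strand,
          three_ss = it$three_ss, bp_pos = bp_pos,
          bp_offset = -(36L - bp_i + 15L), stringsAsFactors = FALSE)
      } else {
        starts <- wpos[sample.int(length(wpos), n, replace = TRUE)]
      }
      reads[[length(reads) + 1L]] <- data.frame(
        read_id = sprintf("bp_r%07d", serial + seq_along(starts)),
        chrom = it$chrom, pos5 = starts, strand = it$strand,
        stringsAsFactors = FALSE)
      serial <- serial + length(starts)
    }
    list(reads = do.call(rbind, reads),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(intron_id = character(0)))
  })
}

## genomic positions (0-based) of window offsets -50..-15, ordered by
## offset; three_ss = 0-based position of the first exonic base of the
## downstream exon on the transcript strand
bp_window_positions <- function(three_ss, strand, from = -50L, to = -15L) {
  k <- seq.int(from, to)
  if (strand == "+") three_ss + k else three_ss - k
}

## unique introns of an annotation with their 3' splice sites
annotation_introns <- function(tx_db) {
  out <- list()
  for (tid in tx_db$transcripts$transcript_id) {
    t <- tx_db$transcripts[tx_db$transcripts$transcript_id == tid, ]
    ex <- exons_of(tx_db, tid)
    if (nrow(ex) < 2L) next
    for (j in seq_len(nrow(ex) - 1L)) {
      s <- ex$end[j]; e <- ex$start[j + 1L]
      three_ss <- if (t$strand == "+") e else s - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = t$chrom, strand = t$strand, start = s, end = e,
        three_ss = three_ss, stringsAsFactors = FALSE)
    }
  }
  introns <- do.call(rbind, out)
  key <- paste(introns$chrom, introns$three_ss, introns$strand)
  introns <- introns[!duplicated(key), , drop = FALSE]
  introns$intron_id <- sprintf("intron_%s_%d_%s", introns$chrom,
                               introns$three_ss, introns$strand)
  introns
}
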