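#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames in 0-based half-open coordinates
#' (BED convention) with columns `chrom`, `start`, `end`, `strand` and
#' optionally `name` plus any metadata columns. This constructor validates
#' the coordinate invariants shared by every interval-typed input.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand character vector, `"+"` or `"-"`.
#' @param name optional labels.
#' @param ... further metadata columns recycled to length.
#' @return data.frame with one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+",
                              name = NA_character_, ...) {
  n <- max(length(chrom), length(start))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   name = rep_len(as.character(name), n),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must be integers")
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(df)
}

## IRanges view of a 0-based half-open interval table (shift to 1-based
## closed only inside overlap computations).
.iranges <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

#' Indices of query intervals overlapping any subject interval
#'
#' Overlap means at least one shared base, on the same chromosome.
#' Strand is compared only when `strand_mode` is not `"ignore"`.
#'
#' @param query,subject interval data frames (0-based half-open).
#' @param strand_mode `"ignore"`, `"same"` or `"opposite"`.
#' @return logical vector along `query` rows.
#' @export
overlaps_any <- function(query, subject, strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(query) == 0L) return(logical(0))
  hit <- logical(nrow(query))
  if (nrow(subject) == 0L) return(hit)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(.iranges(query[qi, , drop = FALSE]),
                                .iranges(subject[si, , drop = FALSE]))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    keep <- switch(strand_mode,
      ignore   = rep(TRUE, length(qh)),
      same     = query$strand[qi[qh]] == subject$strand[si[sh]],
      opposite = query$strand[qi[qh]] != subject$strand[si[sh]])
    hit[qi[unique(qh[keep])]] <- TRUE
  }
  hit
}

## All (query, subject) overlap pairs as a two-column index matrix.
overlap_pairs <- function(query, subject) {
  out <- list()
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (!length(si) || !length(qi)) next
    ov <- IRanges::findOverlaps(.iranges(query[qi, , drop = FALSE]),
                                .iranges(subject[si, , drop = FALSE]))
    out[[chr]] <- cbind(q = qi[S4Vectors::queryHits(ov)],
                        s = si[S4Vectors::subjectHits(ov)])
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2,
                                  dimnames = list(NULL, c("q", "s"))))
  do.call(rbind, out)
}
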