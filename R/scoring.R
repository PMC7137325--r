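#' Alignment penalty scoring parameters
#'
#' Mismatch penalties follow the quality-scaled scheme
#' `MN + floor((MX - MN) * min(Q, 40) / 40)` and gap penalties
#' `GO + N * GE` for a gap of length `N`. A read pair's score is the sum
#' over both mates; lower is better. `genomic_preference_margin` is the
#' pair-score margin (default 24, i.e. more than 2 top-quality mismatches
#' per read) by which a unique genomic mapping must beat the family
#' mapping to be preferred.
#'
#' @param MX,MN max/min mismatch penalty (defaults 6, 2).
#' @param GO,GE gap open / extend penalties (defaults 5, 3).
#' @param genomic_preference_margin pair-score margin (default 24).
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(MX = 6L, MN = 2L, GO = 5L, GE = 3L,
                           genomic_preference_margin = 24L) {
  stopifnot(MX >= MN, MN >= 0, GO >= 0, GE >= 0,
            genomic_preference_margin >= 0)
  structure(list(MX = as.integer(MX), MN = as.integer(MN),
                 GO = as.integer(GO), GE = as.integer(GE),
                 genomic_preference_margin = as.integer(genomic_preference_margin)),
            class = "scoring_params")
}

#' Penalty of one mate's alignment
#'
#' @param mismatch_q integer vector of Phred qualities at mismatched
#'   bases (0..41).
#' @param gap_len integer vector of gap lengths (>= 1).
#' @param params a [scoring_params].
#' @return integer penalty (0 for a perfect alignment).
#' @export
score_alignment <- function(mismatch_q, gap_len = integer(0),
                            params = scoring_params()) {
  if (length(mismatch_q) && any(mismatch_q < 0))
    stop("negative base quality")
  mm <- if (length(mismatch_q))
    sum(params$MN + floor((params$MX - params$MN) * pmin(mismatch_q, 40) / 40))
  else 0L
  gp <- if (length(gap_len)) sum(params$GO + gap_len * params$GE) else 0L
  as.integer(mm + gp)
}

## vectorized scoring over alignment table rows
score_rows <- function(aln, params = scoring_params()) {
  n <- nrow(aln)
  pen <- numeric(n)
  mmstr <- ifelse(is.na(aln$mismatches) | aln$mismatches == ".", "", aln$mismatches)
  parts <- strsplit(mmstr, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens > 0)) {
    row <- rep.int(seq_len(n), lens)
    q <- as.numeric(sub("^[0-9]+:", "", unlist(parts)))
    if (any(q < 0)) stop("negative base quality")
    p <- params$MN + floor((params$MX - params$MN) * pmin(q, 40) / 40)
    agg <- rowsum(p, row)
    pen[as.integer(rownames(agg))] <- agg[, 1L]
  }
  gstr <- ifelse(is.na(aln$gaps) | aln$gaps == ".", "", aln$gaps)
  gparts <- strsplit(gstr, ",", fixed = TRUE)
  glens <- lengths(gparts)
  if (any(glens > 0)) {
    row <- rep.int(seq_len(n), glens)
    gl <- as.numeric(unlist(gparts))
    agg <- rowsum(params$GO + gl * params$GE, row)
    pen[as.integer(rownames(agg))] <- pen[as.integer(rownames(agg))] + agg[, 1L]
  }
  as.integer(pen)
}
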