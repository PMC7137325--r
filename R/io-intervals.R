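#' Read BED / narrowPeak intervals
#'
#' BED coordinates are already 0-based half-open and are preserved as-is.
#' narrowPeak files additionally populate `fold_enrichment` (signalValue)
#' and `p_value` (converted from the -log10 pValue column). Strand `"."`
#' is mapped to `default_strand` with a warning (downstream antisense
#' logic requires a strand).
#'
#' @param path BED3+/BED6/narrowPeak file.
#' @param format `"auto"` (by extension), `"bed"` or `"narrowPeak"`.
#' @param default_strand strand substituted for `"."`.
#' @return interval data.frame (see [genomic_intervals]).
#' @export
read_intervals <- function(path, format = c("auto", "bed", "narrowPeak"),
                           default_strand = "+") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))  # empty file -> empty list
    return(genomic_intervals(character(0), integer(0), integer(0), character(0)))
  gr <- tryCatch({
    if (format == "narrowPeak")
      rtracklayer::import(path, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer"))
    else rtracklayer::import(path, format = "BED")
  }, error = function(e) stop("BED parse error in ", path, ": ",
                              conditionMessage(e)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    warning("strand '.' mapped to '", default_strand, "'")
    strand[strand == "*"] <- default_strand
  }
  md <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = strand,
                   name = if (!is.null(md$name)) as.character(md$name) else NA_character_,
                   score = if (!is.null(md$score)) as.numeric(md$score) else NA_real_,
                   stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    df$fold_enrichment <- md$signalValue
    df$p_value <- 10^(-md$pValue)
  }
  validate_intervals(df)
  df
}

#' Write intervals as BED6
#' @param x interval data.frame.
#' @param path output file.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   name, format(score, trim = TRUE), x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Keep only significant reproducible peaks
#'
#' Reproducible binding-site calls are retained when they satisfy the
#' fold-enrichment (>= 8) and significance (p <= 1e-3) thresholds against
#' the size-matched input.
#'
#' @param peaks interval data.frame with `fold_enrichment` and `p_value`.
#' @param min_fold,max_p thresholds.
#' @return filtered peak data.frame.
#' @export
significant_peaks <- function(peaks, min_fold = 8, max_p = 1e-3) {
  if (!all(c("fold_enrichment", "p_value") %in% names(peaks)))
    stop("peaks need fold_enrichment and p_value columns")
  peaks[peaks$fold_enrichment >= min_fold & peaks$p_value <= max_p, , drop = FALSE]
}
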