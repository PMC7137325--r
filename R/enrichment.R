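#' Relative information of one element
#'
#' The per-element contribution `p * log2(p/q)` to the Kullback-Leibler
#' divergence between the IP and input read-fraction distributions. May
#' be negative for depleted elements; the sum over a full partition is
#' non-negative.
#'
#' @param p fraction of total IP reads on the element, in (0, 1].
#' @param q fraction of total input reads on the element, in (0, 1].
#' @return numeric.
#' @export
relative_information <- function(p, q) {
  if (any(q <= 0)) stop("q must be positive after pseudocounting")
  if (any(p <= 0)) stop("p must be positive after pseudocounting")
  p * log2(p / q)
}

## pseudocount rule: add 1 read to any zero cell of a sample's count
## vector; the sample denominator is the sum of adjusted counts, so the
## adjusted fractions remain a proper distribution.
adjusted_fractions <- function(counts) {
  adj <- counts + (counts == 0)
  adj / sum(adj)
}

#' Per-element enrichment over a size-matched input
#'
#' Computes, for every element/region class, the IP vs input fold
#' enrichment and relative information per replicate and for the
#' replicate-merged value (average IP reads-per-million against input
#' RPM), plus a 2x2 significance test (element vs rest, pooled IP vs
#' input): Pearson's chi-square without continuity correction when all
#' observed and expected cells are >= 5, otherwise a two-sided Fisher's
#' exact test.
#'
#' @param ip1,ip2,input tallies from [tally_elements] (same pipeline,
#'   including the multi-family discard, is applied to the input sample).
#' @return data.frame, one row per element: counts, RPMs, folds,
#'   p-value, test used, relative information, canonical/divergent
#'   counts (from the pooled IP replicates).
#' @export
element_enrichment <- function(ip1, ip2, input) {
  if (ip1$total == 0 || ip2$total == 0 || input$total == 0)
    stop("zero total reads in a sample")
  elements <- sort(Reduce(union, list(ip1$counts$class, ip2$counts$class,
                                      input$counts$class)))
  cnt <- function(t, col = "count") {
    v <- t$counts[[col]][match(elements, t$counts$class)]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  c1 <- cnt(ip1); c2 <- cnt(ip2); ci <- cnt(input)
  p1 <- adjusted_fractions(c1); p2 <- adjusted_fractions(c2)
  q <- adjusted_fractions(ci)
  pm <- (p1 + p2) / 2
  tests <- two_by_two_tests(c1 + c2, ip1$total + ip2$total, ci, input$total)
  data.frame(
    element = elements,
    ip_rep1_count = c1, ip_rep2_count = c2, input_count = ci,
    ip_rep1_rpm = c1 / ip1$total * 1e6, ip_rep2_rpm = c2 / ip2$total * 1e6,
    input_rpm = ci / input$total * 1e6,
    fold_rep1 = p1 / q, fold_rep2 = p2 / q, fold_merged = pm / q,
    p_value = tests$p, test_used = tests$test,
    relinfo_rep1 = p1 * log2(p1 / q),
    relinfo_rep2 = p2 * log2(p2 / q),
    relinfo_merged = pm * log2(pm / q),
    canonical_count = cnt(ip1, "canonical") + cnt(ip2, "canonical"),
    divergent_count = cnt(ip1, "divergent") + cnt(ip2, "divergent"),
    stringsAsFactors = FALSE)
}

## element-vs-rest, IP-vs-input 2x2 per element; >=5 rule selects the test
two_by_two_tests <- function(ip_count, ip_total, in_count, in_total) {
  n <- length(ip_count)
  p <- numeric(n); test <- character(n)
  for (i in seq_len(n)) {
    m <- matrix(c(ip_count[i], ip_total - ip_count[i],
                  in_count[i], in_total - in_count[i]),
                nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (all(m >= 5) && all(expected >= 5)) {
      p[i] <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
      test[i] <- "chi2"
    } else {
      p[i] <- stats::fisher.test(m)$p.value
      test[i] <- "fisher"
    }
  }
  list(p = p, test = test)
}

#' Run the full family-aware quantification pipeline
#'
#' Assignment, PCR-duplicate removal, tallying and enrichment for two IP
#' replicates against one size-matched input. The input sample runs
#' through the identical assignment pipeline, including the multi-family
#' discard.
#'
#' @param ip1,ip2,input alignment tables.
#' @param db a [family_db].
#' @param tx_db a [transcript_db] (gene annotation for region classes).
#' @param rmsk RepeatMasker-style element intervals (family id in
#'   `name`), or `NULL`.
#' @param params a [scoring_params].
#' @return list: `table` (the enrichment data.frame), `assignments`
#'   (list of the three per-sample assignment tables), `tallies`.
#' @export
quantify_elements <- function(ip1, ip2, input, db, tx_db, rmsk = NULL,
                              params = scoring_params()) {
  index <- build_region_index(tx_db)
  run <- function(aln) deduplicate_pairs(assign_read_pairs(aln, db, params))
  asn <- lapply(list(ip1 = ip1, ip2 = ip2, input = input), run)
  tal <- lapply(asn, tally_elements, index = index, rmsk = rmsk,
                merged = db$merged)
  list(table = element_enrichment(tal$ip1, tal$ip2, tal$input),
       assignments = asn, tallies = tal)
}
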