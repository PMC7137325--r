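#' Pairwise peak overlap fraction
#'
#' Fraction of peaks in A overlapping (>= 1 base, strand-aware) a peak
#' in B, and vice versa; the larger of the two fractions is the overall
#' pairwise overlap.
#'
#' @param a,b nonempty stranded peak interval data.frames.
#' @return numeric in [0, 1].
#' @export
peak_overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty peak set")
  fa <- mean(overlaps_any(a, b, "same"))
  fb <- mean(overlaps_any(b, a, "same"))
  max(fa, fb)
}

#' Pairwise overlap matrix across datasets
#'
#' Datasets with fewer than `min_peaks` significant reproducible peaks
#' are excluded. The matrix is symmetric by construction (maximum of
#' both directions).
#'
#' @param peak_sets named list of peak interval data.frames.
#' @param min_peaks minimum peaks per dataset (default 100).
#' @return square numeric matrix, class `overlap_matrix` attributes.
#' @export
overlap_matrix <- function(peak_sets, min_peaks = 100L) {
  if (length(peak_sets) < 2L) stop("need at least 2 peak sets")
  keep <- vapply(peak_sets, nrow, integer(1)) >= min_peaks
  sets <- peak_sets[keep]
  if (length(sets) < 2L) stop("fewer than 2 datasets pass the peak filter")
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <- peak_overlap_fraction(sets[[i]], sets[[j]])
  }
  m
}

#' Unweighted running-sum enrichment of a labeled subset in a ranking
#'
#' Walks the ranked list adding `1/|labels|` at labeled items and
#' subtracting `1/(n - |labels|)` at unlabeled ones; the enrichment
#' score (ES) is the maximum deviation from zero (signed). Significance
#' comes from label permutations:
#' `p = (#{permutation ES >= observed} + 1) / (n_perm + 1)`.
#'
#' @param ranked character vector of item ids, ordered (best first).
#' @param label_set character vector, nonempty proper subset of
#'   `ranked`.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return list: `es`, `p_value`, `running_sum`, `n`, `n_labeled`.
#' @export
running_sum_enrichment <- function(ranked, label_set, n_perm = 10000L,
                                   seed = 1L) {
  n <- length(ranked)
  lab <- ranked %in% label_set
  k <- sum(lab)
  if (k == 0L || k == n) stop("label set must be a nonempty proper subset")
  es_of <- function(lab) {
    step <- ifelse(lab, 1 / sum(lab), -1 / (length(lab) - sum(lab)))
    rs <- cumsum(step)
    rs[which.max(abs(rs))]
  }
  es <- es_of(lab)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) es_of(sample(lab)), numeric(1))
  })
  step <- ifelse(lab, 1 / k, -1 / (n - k))
  list(es = es, p_value = (sum(perm >= es) + 1) / (n_perm + 1),
       running_sum = cumsum(step), n = n, n_labeled = k)
}

#' Accuracy / F1 sweep over relative-information cutoffs
#'
#' Each dataset contributes its most-enriched element's relative
#' information, whether that element's function is supported by
#' published annotation for the protein (`match`), and whether the
#' protein has any annotated element-linked function (`annotated`).
#' At a cutoff c: TP = above c and matching; FP = above c without
#' evidence; FN = at or below c but annotated; TN = at or below c and
#' unannotated. Accuracy = (TP+TN)/n, F1 = 2TP/(2TP+FP+FN); the argmax
#' cutoff (smallest on ties) is reported for both criteria.
#'
#' @param datasets data.frame with columns `dataset_id`, `relinfo`,
#'   `match` (logical), `annotated` (logical).
#' @return list: `sweep` (per-cutoff table), `best_accuracy_cutoff`,
#'   `best_f1_cutoff`.
#' @export
function_accuracy_sweep <- function(datasets) {
  need <- c("dataset_id", "relinfo", "match", "annotated")
  stopifnot(all(need %in% names(datasets)))
  if (nrow(datasets) == 0L || !any(datasets$annotated))
    stop("empty annotation table")
  if (any(datasets$match & !datasets$annotated))
    stop("a matching dataset must be annotated")
  cutoffs <- sort(unique(datasets$relinfo))
  n <- nrow(datasets)
  rows <- lapply(cutoffs, function(cut) {
    above <- datasets$relinfo > cut
    tp <- sum(above & datasets$match)
    fp <- sum(above & !datasets$match)
    fn <- sum(!above & datasets$annotated)
    tn <- sum(!above & !datasets$annotated)
    data.frame(cutoff = cut, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = (tp + tn) / n,
               f1 = if (2 * tp + fp + fn == 0) 0 else
                 2 * tp / (2 * tp + fp + fn))
  })
  sweep <- do.call(rbind, rows)
  list(sweep = sweep,
       best_accuracy_cutoff = sweep$cutoff[which.max(sweep$accuracy)],
       best_f1_cutoff = sweep$cutoff[which.max(sweep$f1)])
}

#' Association between two binary labelings
#'
#' 2x2 contingency of two memberships over a shared universe. The odds
#' ratio uses the Haldane-Anscombe 0.5 correction when any cell is
#' zero. Significance is Yates-corrected chi-square when all observed
#' and expected cells exceed 5, otherwise a two-sided Fisher's exact
#' test.
#'
#' @param membership_a,membership_b logical vectors over the same
#'   universe.
#' @return list: `odds_ratio`, `p_value`, `test_used`, `table`, `n`.
#' @export
contingency_association <- function(membership_a, membership_b) {
  stopifnot(length(membership_a) == length(membership_b))
  if (length(membership_a) == 0L) stop("empty universe")
  tab <- matrix(c(sum(membership_a & membership_b),
                  sum(membership_a & !membership_b),
                  sum(!membership_a & membership_b),
                  sum(!membership_a & !membership_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(a = c("yes", "no"), b = c("yes", "no")))
  ct <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab > 5) && all(expected > 5)) {
    p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
    test <- "yates_chi2"
  } else {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  }
  list(odds_ratio = or, p_value = p, test_used = test, table = tab,
       n = sum(tab))
}

#' Expression shift of element-bound genes after knockdown
#'
#' Two-sided Kolmogorov-Smirnov tests (no multiple-testing correction)
#' of the knockdown log2 fold-change distribution of genes with at
#' least one peak-bound antisense element against (i) genes carrying an
#' element without a peak and (ii) all expressed genes.
#'
#' @param log2fc data.frame with `log2fc` and `class` in
#'   `{bound, bgd_with_element, bgd}` (the `bgd` background comparison
#'   pools all classes, matching an all-expressed-genes background).
#' @return data.frame: one row per comparison with `D`, `p_value`, `n1`,
#'   `n2`.
#' @export
l1_expression_shift <- function(log2fc) {
  stopifnot(all(c("log2fc", "class") %in% names(log2fc)))
  g <- function(cl) log2fc$log2fc[log2fc$class == cl]
  bound <- g("bound"); with_el <- g("bgd_with_element")
  all_bgd <- log2fc$log2fc
  if (length(bound) < 2L || length(with_el) < 2L || length(all_bgd) < 2L)
    stop("each class needs at least 2 genes")
  one <- function(name, x, y) {
    kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
    data.frame(comparison = name, D = unname(kt$statistic),
               p_value = kt$p.value, n1 = length(x), n2 = length(y),
               stringsAsFactors = FALSE)
  }
  rbind(one("bound_vs_bgd_with_element", bound, with_el),
        one("bound_vs_bgd", bound, all_bgd))
}

#' Enrichment of RNA binding protein mRNAs among peak-bound genes
#'
#' Per dataset, the fraction of peak-containing genes that encode RBPs
#' is divided by the pooled background fraction (RBP share among all
#' peak-containing genes across datasets); a one-sample t test compares
#' the per-dataset folds against 1.
#'
#' @param peak_genes named list: dataset -> character vector of
#'   peak-containing gene ids.
#' @param rbp_genes character vector of RBP gene ids.
#' @return list: `folds` (named), `fold` (mean), `median_fraction`,
#'   `background_fraction`, `t`, `p_value`, `n_datasets`.
#' @export
rbp_target_enrichment <- function(peak_genes, rbp_genes) {
  if (length(peak_genes) < 2L) stop("need at least 2 datasets")
  nz <- vapply(peak_genes, length, integer(1)) > 0L
  if (any(!nz)) {
    warning(sum(!nz), " dataset(s) with zero peak-containing genes excluded")
    peak_genes <- peak_genes[nz]
    if (length(peak_genes) < 2L) stop("need at least 2 datasets")
  }
  pooled <- unique(unlist(peak_genes))
  bgd <- mean(pooled %in% rbp_genes)
  if (bgd == 0) stop("no RBP gene among peak-containing genes")
  fracs <- vapply(peak_genes, function(g) mean(g %in% rbp_genes), numeric(1))
  folds <- fracs / bgd
  if (stats::sd(folds) == 0) {
    tstat <- if (folds[1L] == 1) 0 else sign(folds[1L] - 1) * Inf
    pval <- if (folds[1L] == 1) 1 else 0
  } else {
    tt <- stats::t.test(folds, mu = 1)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  list(folds = folds, fold = mean(folds),
       median_fraction = stats::median(fracs), background_fraction = bgd,
       t = tstat, p_value = pval,
       n_datasets = length(peak_genes))
}
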