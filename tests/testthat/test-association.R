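test_that("overlap fraction takes the maximum of both directions", {
  a <- genomic_intervals("c", c(0L, 100L), c(50L, 150L), "+")
  expect_equal(peak_overlap_fraction(a, a), 1)
  b <- genomic_intervals("c", c(1000L, 2000L), c(1050L, 2050L), "+")
  expect_equal(peak_overlap_fraction(a, b), 0)
  # 10 peaks all inside B's 100; only those 10 of B hit: max(1, 0.1) = 1
  big_start <- seq(0L, by = 100L, length.out = 100L)
  B <- genomic_intervals("c", big_start, big_start + 50L, "+")
  A <- genomic_intervals("c", big_start[1:10] + 10L, big_start[1:10] + 40L, "+")
  expect_equal(peak_overlap_fraction(A, B), 1)
  # strand-aware: opposite strands never overlap
  bm <- a; bm$strand <- "-"
  expect_equal(peak_overlap_fraction(a, bm), 0)
  expect_error(peak_overlap_fraction(a[0, ], b), "empty")
})

test_that("overlap matrix filters small datasets and is symmetric in [0,1]", {
  cfg <- sim_config(seed = 16)
  fx <- simulate_association_fixtures(cfg, n_datasets = 4, n_peaks = 150,
                                      overlap = 0.4)
  sets <- fx$peak_sets
  sets$tiny <- sets[[1]][1:99, ]                 # 99 peaks -> excluded
  m <- overlap_matrix(sets, min_peaks = 100)
  expect_false("tiny" %in% rownames(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 1))
  # invariant to peak order
  sets2 <- lapply(fx$peak_sets, function(p) p[rev(seq_len(nrow(p))), ])
  expect_equal(unname(overlap_matrix(sets2, 100)), unname(m))
  expect_error(overlap_matrix(sets[1], 100), "at least 2")
})

test_that("running-sum enrichment matches direct evaluation and bounds", {
  # all labeled items first -> ES reaches +1
  rs <- running_sum_enrichment(letters[1:10], letters[1:3], n_perm = 200,
                               seed = 1)
  expect_equal(rs$es, 1)
  expect_gte(rs$p_value, 1 / 201)
  # single labeled item ranked last: brute-force running sum
  n <- 8
  rs2 <- running_sum_enrichment(letters[1:n], letters[n], n_perm = 200,
                                seed = 1)
  want <- cumsum(c(rep(-1 / (n - 1), n - 1), 1))
  expect_equal(rs2$running_sum, want)
  expect_equal(rs2$es, want[which.max(abs(want))])
  expect_equal(rs2$es, -1)  # the running sum bottoms out just before the hit
  # ES always within [-1, 1]; p >= 1/(n_perm+1)
  set.seed(6)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    lab <- sample(letters[1:12], k)
    r <- running_sum_enrichment(sample(letters[1:12]), lab, n_perm = 99,
                                seed = i)
    expect_true(r$es >= -1 && r$es <= 1)
    expect_gte(r$p_value, 1 / 100)
  }
  expect_error(running_sum_enrichment(letters[1:4], letters[1:4]), "subset")
  expect_error(running_sum_enrichment(letters[1:4], character(0)), "subset")
})

test_that("random labels give calibrated permutation p-values", {
  set.seed(8)
  ps <- replicate(60, {
    ranked <- sample(letters[1:20])
    running_sum_enrichment(ranked, sample(letters[1:20], 5), n_perm = 99,
                           seed = sample.int(1e6, 1))$p_value
  })
  # under the null, p is roughly uniform: mean near 0.5
  expect_gt(mean(ps), 0.3); expect_lt(mean(ps), 0.7)
})

test_that("accuracy/F1 sweep equals brute-force reclassification", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    d <- data.frame(dataset_id = sprintf("d%02d", 1:n),
                    relinfo = round(runif(n), 2),
                    annotated = runif(n) < 0.6)
    d$match <- d$annotated & runif(n) < 0.5
    sw <- function_accuracy_sweep(d)
    expect_true(all(sw$sweep$tp + sw$sweep$fp + sw$sweep$fn + sw$sweep$tn == n))
    for (j in seq_len(nrow(sw$sweep))) {
      cut <- sw$sweep$cutoff[j]
      above <- d$relinfo > cut
      expect_equal(sw$sweep$tp[j], sum(above & d$match))
      expect_equal(sw$sweep$fp[j], sum(above & !d$match))
      expect_equal(sw$sweep$fn[j], sum(!above & d$annotated))
      expect_equal(sw$sweep$tn[j], sum(!above & !d$annotated))
    }
    # at the largest cutoff nothing is above: accuracy = unannotated share
    last <- nrow(sw$sweep)
    expect_equal(sw$sweep$accuracy[last], mean(!d$annotated))
  }
  expect_error(function_accuracy_sweep(
    data.frame(dataset_id = "a", relinfo = 1, match = FALSE,
               annotated = FALSE)), "empty annotation")
})

test_that("contingency association matches the hypergeometric oracle and zero-cell rule", {
  # all-diagonal table: Haldane-Anscombe correction, Fisher p
  ca <- contingency_association(rep(c(TRUE, FALSE), each = 10),
                                rep(c(TRUE, FALSE), each = 10))
  expect_equal(ca$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_equal(ca$test_used, "fisher")
  # p equals fisher.test / Yates chisq.test on random small tables
  set.seed(10)
  for (i in 1:60) {
    a <- sample.int(30, 1); b <- sample.int(30, 1)
    c_ <- sample.int(30, 1); d <- sample.int(30, 1)
    ua <- rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c_, d))
    ub <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d))
    got <- contingency_association(ua, ub)
    m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (all(m > 5) && all(expected > 5)) {
      expect_equal(got$test_used, "yates_chi2")
      expect_equal(got$p_value,
                   suppressWarnings(chisq.test(m, correct = TRUE)$p.value))
    } else {
      expect_equal(got$test_used, "fisher")
      expect_equal(got$p_value, fisher.test(m)$p.value)
    }
  }
  # independence at large n: odds ratio near 1
  set.seed(11)
  x <- runif(20000) < 0.3; y <- runif(20000) < 0.4
  expect_equal(contingency_association(x, y)$odds_ratio, 1, tolerance = 0.15)
  expect_error(contingency_association(logical(0), logical(0)), "empty")
})

test_that("KS shift test detects planted shifts and matches exact enumeration", {
  # identical distributions: D = 0, p = 1
  df <- data.frame(log2fc = rep(c(1, 2, 3), 3),
                   class = rep(c("bound", "bgd_with_element", "bgd"), each = 3))
  ks <- l1_expression_shift(df)
  expect_true(all(ks$D[1] == 0))
  expect_equal(ks$p_value[1], 1)
  # planted -0.5 shift on bound genes is detected in most seeds
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s)
    fx <- simulate_association_fixtures(cfg, shift = 0.5, n_genes = 600)
    p <- l1_expression_shift(fx$log2fc)$p_value[1]
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / 20, 0.95)
  # D matches exact enumeration for tiny samples
  ecdf_d <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(vapply(v, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
  }
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(7)
    got <- suppressWarnings(ks.test(x, y))$statistic
    expect_equal(unname(got), ecdf_d(x, y))
  }
  expect_error(l1_expression_shift(
    data.frame(log2fc = 1, class = "bound")), "at least 2")
})

test_that("KS null p-values are calibrated at the 5% level", {
  set.seed(13)
  n_trials <- 2000L
  rej <- 0L
  for (i in seq_len(n_trials)) {
    x <- rnorm(40); y <- rnorm(40)
    rej <- rej + (suppressWarnings(ks.test(x, y)$p.value) < 0.05)
  }
  rate <- rej / n_trials
  expect_gt(rate, 0.025); expect_lt(rate, 0.075)
})

test_that("RBP-target enrichment recovers planted oversampling", {
  universe <- sprintf("g%04d", 1:1000)
  rbp <- universe[1:200]
  # RBP list covers every peak gene -> folds all 1, t = 0
  pg <- list(a = universe[1:50], b = universe[51:100])
  r <- rbp_target_enrichment(pg, universe)
  expect_true(all(r$folds == 1))
  expect_equal(r$t, 0)
  # planted 2x oversampling of RBP genes
  set.seed(14)
  mk <- function() {
    n <- 300
    w <- ifelse(universe %in% rbp, 2, 1)
    sample(universe, n, prob = w)
  }
  pg2 <- lapply(1:8, function(i) mk())
  names(pg2) <- sprintf("d%d", 1:8)
  r2 <- rbp_target_enrichment(pg2, rbp)
  # per-dataset fraction near 2*200/(2*200+800) = 1/3
  expect_equal(r2$median_fraction, 1 / 3, tolerance = 0.1)
  expect_error(rbp_target_enrichment(pg[1], rbp), "at least 2")
  # zero-gene datasets are excluded with a warning
  expect_warning(
    r3 <- rbp_target_enrichment(c(pg2, list(z = character(0))), rbp),
    "zero peak-containing")
  expect_equal(r3$n_datasets, 8L)
})
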