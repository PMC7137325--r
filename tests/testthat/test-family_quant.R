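test_that("mismatch and gap penalties follow the quality-scaled scheme", {
  p <- scoring_params()
  expect_equal(score_alignment(40L), 6L)          # min(Q,40)=40 forces MX
  expect_equal(score_alignment(20L), 4L)          # 2 + floor(4*0.5)
  expect_equal(score_alignment(41L), 6L)          # capped at 40
  expect_equal(score_alignment(integer(0), 2L), 11L)  # GO + 2*GE
  expect_equal(score_alignment(c(40L, 20L), c(1L, 3L)), 6L + 4L + 8L + 14L)
  expect_error(score_alignment(-1L), "negative")
})

test_that("penalty scores equal independent recomputation from raw strings", {
  set.seed(42)
  p <- scoring_params()
  for (i in 1:400) {
    L <- 30L
    ref <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    read_ch <- strsplit(ref, "")[[1]]
    nmm <- rpois(1, 2)
    mmpos <- sort(sample.int(L, min(nmm, L)))
    for (j in mmpos)
      read_ch[j] <- sample(setdiff(c("A", "C", "G", "T"), read_ch[j]), 1)
    qual <- sample(0:41, L, TRUE)
    gaps <- if (runif(1) < 0.3) sample.int(4, sample.int(2, 1), TRUE) else integer(0)
    got <- score_alignment(qual[mmpos], gaps, p)
    want <- oracle_score(paste(read_ch, collapse = ""), ref, qual, gaps = gaps)
    expect_equal(got, want)
  }
})

test_that("score_rows matches score_alignment row by row", {
  set.seed(7)
  rows <- do.call(rbind, lapply(1:50, function(i) {
    nmm <- rpois(1, 1.5)
    mm <- if (nmm == 0) "." else
      paste(sprintf("%d:%d", sort(sample.int(50, nmm)),
                    sample(0:41, nmm, TRUE)), collapse = ",")
    gp <- if (runif(1) < 0.3) paste(sample.int(3, 1), collapse = ",") else "."
    aln_row(sprintf("r%d:AA", i), 1L, "t", "family_transcript", 0L, 50L,
            mismatches = mm, gaps = gp)
  }))
  got <- eclipatlas:::score_rows(rows)
  mm <- eclipatlas:::parse_mismatches(rows$mismatches)
  gp <- eclipatlas:::parse_gaps(rows$gaps)
  want <- vapply(seq_len(nrow(rows)), function(i)
    score_alignment(mm[[i]]$q, gp[[i]]), integer(1))
  expect_equal(got, want)
})

test_that("assignment keeps strict-minimum mappings and discards multi-family ties", {
  db <- toy_family_db()
  # famA score 4 vs famB score 6 -> famA
  aln <- rbind(pair_aln("r1:AAAA", "L1_primary", mm1 = "3:20"),
               pair_aln("r1:AAAA", "Alu_primary", mm1 = "3:40"))
  a <- assign_read_pairs(aln, db)
  expect_equal(a$assigned_class, "L1")
  expect_equal(a$discard_reason, "none")
  # equal best across two families -> discarded
  aln2 <- rbind(pair_aln("r1:AAAA", "L1_primary", mm1 = "3:40"),
                pair_aln("r1:AAAA", "Alu_primary", mm1 = "9:40"))
  a2 <- assign_read_pairs(aln2, db)
  expect_equal(a2$discard_reason, "multi_family")
  expect_true(is.na(a2$assigned_class))
  # tie within a family resolves to the primary transcript
  aln3 <- rbind(pair_aln("r1:AAAA", "L1_ps1", mm1 = "3:40"),
                pair_aln("r1:AAAA", "L1_primary", mm1 = "9:40"))
  a3 <- assign_read_pairs(aln3, db)
  expect_equal(a3$target_id, "L1_primary")
  expect_equal(a3$assigned_class, "L1")
})

test_that("reverse-strand mappings count toward the antisense family", {
  db <- toy_family_db()
  a <- assign_read_pairs(pair_aln("r1:AAAA", "L1_primary", strand = "-"), db)
  expect_equal(a$assigned_class, "antisense_L1")
  # strand-merged family ignores strand
  dbm <- family_db(db$members, merged = "L1")
  am <- assign_read_pairs(pair_aln("r1:AAAA", "L1_primary", strand = "-"), dbm)
  expect_equal(am$assigned_class, "L1")
  # sense and antisense best hits are different families -> discard
  aln <- rbind(pair_aln("r1:AAAA", "L1_primary", strand = "+"),
               pair_aln("r1:AAAA", "L1_ps1", strand = "-"))
  expect_equal(assign_read_pairs(aln, db)$discard_reason, "multi_family")
})

test_that("genomic mapping wins only beyond the 24-point pair-score margin", {
  db <- toy_family_db()
  mk <- function(fam_mm) rbind(
    pair_aln("r1:AAAA", "L1_primary", mm1 = fam_mm),
    pair_aln("r1:AAAA", "chr5", kind = "genome", start = 1000L, uniq = TRUE))
  # family pair score 30 vs genomic 0: margin 30 > 24 -> genomic
  a <- assign_read_pairs(mk(paste(sprintf("%d:40", 1:5), collapse = ",")), db)
  expect_equal(a$kind, "genome")
  expect_equal(a$target_id, "chr5")
  # family pair score exactly 24 -> family retained (strict inequality)
  b <- assign_read_pairs(mk(paste(sprintf("%d:40", 1:4), collapse = ",")), db)
  expect_equal(b$kind, "family")
  # no family mapping at all -> genomic kept
  g <- assign_read_pairs(pair_aln("r1:AAAA", "chr5", kind = "genome",
                                  uniq = TRUE), db)
  expect_equal(g$kind, "genome")
  # non-unique genomic mappings never participate
  ng <- rbind(pair_aln("r1:AAAA", "L1_primary",
                       mm1 = paste(sprintf("%d:40", 1:5), collapse = ",")),
              pair_aln("r1:AAAA", "chr5", kind = "genome", uniq = FALSE))
  expect_equal(assign_read_pairs(ng, db)$kind, "family")
})

test_that("PCR duplicates collapse on (target, start, stop, UMI) and dedup is idempotent", {
  db <- toy_family_db()
  aln <- rbind(pair_aln("r1:AAAA", "L1_primary"),
               pair_aln("r2:AAAA", "L1_primary"),
               pair_aln("r3:AAAA", "L1_primary"),
               pair_aln("r4:CCCC", "L1_primary"),       # same coords, new UMI
               pair_aln("r5:AAAA", "L1_primary", start = 100L))
  a <- deduplicate_pairs(assign_read_pairs(aln, db))
  expect_equal(sum(a$discard_reason == "pcr_duplicate"), 2L)
  # survivor is the lexicographically smallest read id
  expect_equal(a$discard_reason[a$read_id == "r1:AAAA"], "none")
  expect_equal(a$discard_reason[a$read_id == "r4:CCCC"], "none")
  expect_identical(deduplicate_pairs(a), a)  # idempotent
  expect_identical(deduplicate_pairs(a[0, ]), a[0, ])  # empty in, empty out
  # missing UMI errors
  noumi <- assign_read_pairs(pair_aln("plain", "L1_primary"), db)
  expect_error(deduplicate_pairs(noumi), "UMI")
})

test_that("fragments classify by element overlap then the 11-class priority", {
  db <- toy_tx_db()
  idx <- build_region_index(db)
  rmsk <- genomic_intervals("chr1", c(1500L, 6000L), c(1600L, 6100L),
                            c("+", "-"), name = c("L1", "Alu"))
  frag <- function(s, e, strand = "+", chrom = "chr1")
    data.frame(chrom = chrom, start = s, end = e, strand = strand)
  # element overlap by >=1 base wins over any genic class
  expect_equal(annotate_genomic_fragment(frag(1599L, 1650L), idx, rmsk), "L1")
  # antisense to the element
  expect_equal(annotate_genomic_fragment(frag(1500L, 1550L, "-"), idx, rmsk),
               "antisense_L1")
  # CDS beats UTR when a fragment spans both
  expect_equal(annotate_genomic_fragment(frag(110L, 130L), idx), "CDS")
  # plain 5'UTR / 3'UTR on the plus-strand gene
  expect_equal(annotate_genomic_fragment(frag(100L, 115L), idx), "5utr")
  expect_equal(annotate_genomic_fragment(frag(2500L, 2550L), idx), "3utr")
  # dual-UTR class: spans 5'UTR of txP and nothing else UTR5-ward
  expect_equal(annotate_genomic_fragment(frag(105L, 2480L), idx), "CDS")
  # proximal (400 nt from the splice site) vs distal intron
  expect_equal(annotate_genomic_fragment(frag(650L, 660L), idx),
               "proximal_intron")
  expect_equal(annotate_genomic_fragment(frag(1850L, 1860L), idx),
               "distal_intron")
  # non-coding exon, antisense, intergenic
  expect_equal(annotate_genomic_fragment(frag(9100L, 9120L), idx),
               "noncoding_exon")
  expect_equal(annotate_genomic_fragment(frag(150L, 160L, "-"), idx),
               "antisense")
  expect_equal(annotate_genomic_fragment(frag(4000L, 4010L), idx),
               "intergenic")
  # minus-strand gene classifies on its own strand
  expect_equal(annotate_genomic_fragment(frag(7450L, 7480L, "-"), idx),
               "5utr")
})

test_that("dual-UTR fragments take the 5utr_3utr class before single UTRs", {
  # 3'UTR of t1 overlaps the 5'UTR of a downstream gene t2
  tr <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   chrom = "c1", strand = "+", tpm = 1,
                   cds_start = c(20L, 150L), cds_end = c(60L, 180L))
  ex <- data.frame(transcript_id = c("t1", "t2"),
                   start = c(0L, 80L), end = c(100L, 200L))
  idx <- build_region_index(transcript_db(tr, ex))
  got <- annotate_genomic_fragment(
    data.frame(chrom = "c1", start = 85L, end = 95L, strand = "+"), idx)
  expect_equal(got, "5utr_3utr")
  # touching a CDS still wins over the dual-UTR class
  got2 <- annotate_genomic_fragment(
    data.frame(chrom = "c1", start = 55L, end = 95L, strand = "+"), idx)
  expect_equal(got2, "CDS")
})

test_that("element tallies add family-assigned and element-overlapping genomic pairs", {
  db <- toy_family_db()
  tx <- toy_tx_db()
  idx <- build_region_index(tx)
  rmsk <- genomic_intervals("chr1", 1500L, 1600L, "+", name = "L1")
  aln <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      pair_aln(sprintf("f%02d:U%02d", i, i), "L1_primary"))),
    do.call(rbind, lapply(1:5, function(i)
      pair_aln(sprintf("g%02d:U%02d", i, i), "chr1", kind = "genome",
               start = 1450L + i, uniq = TRUE))),
    pair_aln("x1:UU", "chr1", kind = "genome", start = 130L, uniq = TRUE))
  a <- deduplicate_pairs(assign_read_pairs(aln, db))
  tal <- tally_elements(a, idx, rmsk)
  l1 <- tal$counts[tal$counts$class == "L1", ]
  expect_equal(l1$count, 15L)
  expect_equal(l1$canonical, 10L)
  expect_equal(l1$divergent, 5L)
  expect_equal(sum(tal$counts$count), tal$total)  # partition
  expect_equal(tal$total, 16L)
})

test_that("relative information follows p*log2(p/q)", {
  expect_equal(relative_information(0.3, 0.3), 0)
  expect_equal(relative_information(0.5, 0.25), 0.5)
  expect_equal(relative_information(0.1, 0.2), -0.1)
  expect_error(relative_information(0.1, 0), "positive")
})

test_that("enrichment folds, merged values and test selection are correct", {
  mk <- function(classes, counts, canonical = counts) {
    list(counts = data.frame(class = classes, count = counts,
                             canonical = canonical,
                             divergent = counts - canonical),
         total = sum(counts))
  }
  ip1 <- mk(c("famA", "rest"), c(90L, 10L))
  ip2 <- mk(c("famA", "rest"), c(90L, 10L))
  inp <- mk(c("famA", "rest"), c(50L, 50L))
  tab <- element_enrichment(ip1, ip2, inp)
  famA <- tab[tab$element == "famA", ]
  expect_equal(famA$fold_rep1, 1.8)           # 0.9 / 0.5
  expect_equal(famA$fold_merged, 1.8)
  # merged fold via average RPM: reps 200 and 400 RPM-equivalents vs 100
  ipA <- mk("famA", 2L); ipA$counts <- rbind(ipA$counts,
    data.frame(class = "rest", count = 8L, canonical = 8L, divergent = 0L))
  ipA$total <- 10L
  ipB <- mk("famA", 4L); ipB$counts <- rbind(ipB$counts,
    data.frame(class = "rest", count = 6L, canonical = 6L, divergent = 0L))
  ipB$total <- 10L
  inp2 <- mk(c("famA", "rest"), c(1L, 9L))
  t2 <- element_enrichment(ipA, ipB, inp2)
  expect_equal(t2$fold_merged[t2$element == "famA"], 3)
  # p-value equals the brute-force oracles on the pooled 2x2
  m <- matrix(c(180L, 20L, 50L, 50L), 2, byrow = TRUE)
  expect_equal(famA$p_value,
               suppressWarnings(chisq.test(m, correct = FALSE)$p.value))
  expect_equal(famA$test_used, "chi2")
  # small counts fall back to Fisher
  ip_s <- mk(c("famA", "rest"), c(2L, 98L))
  t3 <- element_enrichment(ip_s, ip_s, mk(c("famA", "rest"), c(1L, 99L)))
  expect_equal(t3$test_used[t3$element == "famA"], "fisher")
  expect_error(element_enrichment(ip1, ip2, mk("famA", 0L)), "zero total")
})

test_that("test selection obeys the >=5 rule on randomized tables", {
  set.seed(13)
  for (i in 1:100) {
    a <- sample.int(60, 1); b <- sample.int(60, 1)
    c_ <- sample.int(60, 1); d <- sample.int(60, 1)
    got <- eclipatlas:::two_by_two_tests(a, a + b, c_, c_ + d)
    m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    want <- if (all(m >= 5) && all(expected >= 5)) "chi2" else "fisher"
    expect_equal(got$test, want)
    oracle_p <- if (want == "chi2")
      suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    else fisher.test(m)$p.value
    expect_equal(got$p, oracle_p)
  }
})

test_that("KL divergence of adjusted fractions is non-negative on random tables", {
  set.seed(99)
  for (i in 1:100) {
    k <- sample(3:8, 1)
    ip <- rpois(k, 30); inp <- rpois(k, 30)
    if (sum(ip) == 0 || sum(inp) == 0) next
    p <- eclipatlas:::adjusted_fractions(ip)
    q <- eclipatlas:::adjusted_fractions(inp)
    expect_gte(sum(p * log2(p / q)), 0)
    expect_equal(sum(p), 1)
  }
})
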