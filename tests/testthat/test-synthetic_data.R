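test_that("family database generator is deterministic and correctly sized", {
  cfg <- sim_config(seed = 1, n_families = 3, pseudogenes_per_family = 2)
  db1 <- build_family_database(cfg)
  db2 <- build_family_database(cfg)
  expect_identical(as.character(db1$sequences), as.character(db2$sequences))
  expect_equal(nrow(db1$members), 9L)   # 3 families x (1 primary + 2 ps)
  expect_equal(length(unique(db1$members$family_id)), 3L)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_family_fasta(db1, f1); write_family_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
  # divergence 0 -> pseudogenes identical to the primary
  db0 <- build_family_database(sim_config(seed = 2, pseudogene_divergence = 0))
  expect_equal(as.character(db0$sequences[["FAM01_ps1"]]),
               as.character(db0$sequences[["FAM01_primary"]]))
  expect_error(
    build_family_database(sim_config(pseudogene_divergence = 0.6,
                                     element_divergence = 0.9)),
    "unassignable")
})

test_that("pseudogene divergence matches the configured substitution rate", {
  cfg <- sim_config(seed = 3, pseudogene_divergence = 0.05,
                    transcript_length = 2000)
  db <- build_family_database(cfg)
  p <- strsplit(as.character(db$sequences[["FAM01_primary"]]), "")[[1]]
  q <- strsplit(as.character(db$sequences[["FAM01_ps1"]]), "")[[1]]
  d <- mean(p != q)
  expect_gt(d, 0.03); expect_lt(d, 0.07)  # binomial tolerance at n=2000
})

test_that("simulated genome annotation is reproducible with stranded element copies", {
  cfg <- sim_config(seed = 4)
  db <- build_family_database(cfg)
  g1 <- simulate_genome_annotation(cfg, db)
  g2 <- simulate_genome_annotation(cfg, db)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$rmsk, g2$rmsk)
  expect_equal(nrow(g1$rmsk),
               cfg$n_sense_elements + cfg$n_antisense_elements)
  # antisense copies sit on the strand opposite their host gene
  anti <- g1$elements[g1$elements$strand != g1$elements$host_strand, ]
  expect_equal(nrow(anti), cfg$n_antisense_elements)
  # zero insertions -> empty element table
  g0 <- simulate_genome_annotation(
    sim_config(seed = 4, n_sense_elements = 0, n_antisense_elements = 0), db)
  expect_equal(nrow(g0$rmsk), 0L)
  # every gene has >= 2 exons and all three mRNA regions
  for (tid in g1$tx_db$transcripts$transcript_id) {
    r <- transcript_regions(g1$tx_db, tid)
    expect_gte(nrow(r$exons), 2L)
    expect_gt(sum(r$utr5$end - r$utr5$start), 0L)
    expect_gt(sum(r$cds$end - r$cds$start), 0L)
    expect_gt(sum(r$utr3$end - r$utr3$start), 0L)
  }
})

test_that("library truth tables are complete and sources follow configured shares", {
  cfg <- sim_config(seed = 5, depth = 20000, duplicate_rate = 0)
  db <- build_family_database(cfg)
  lib <- simulate_eclip_library(cfg, db)
  for (s in c("ip1", "ip2", "input")) {
    ids <- unique(lib[[s]]$read_id)
    tr <- lib$truth[lib$truth$sample == s, ]
    expect_setequal(ids, tr$read_id)            # truth complete
    expect_false(anyDuplicated(tr$read_id) > 0) # exactly once
  }
  # input family shares converge to configured abundances (equal families)
  tr <- lib$truth[lib$truth$sample == "input", ]
  share <- table(tr$true_class) / nrow(tr)
  expect_true(all(abs(share - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / nrow(tr))))
  # IP share of the enriched family ~ 5x its input share
  tri <- lib$truth[lib$truth$sample == "ip1", ]
  fold <- mean(tri$true_class == "FAM01") / mean(tr$true_class == "FAM01")
  expect_gt(fold, 4.5); expect_lt(fold, 5.5)
  expect_error(
    simulate_eclip_library(sim_config(enrichment = list(NOPE = 2)), db),
    "unknown family")
})

test_that("error-free reads match their source sequence exactly", {
  cfg <- sim_config(seed = 6, depth = 3000, per_base_error_rate = 0)
  db <- build_family_database(cfg)
  lib <- simulate_eclip_library(cfg, db)
  # a read maps to its own source with zero mismatches: for every pair
  # there is at least one mapping with an empty mismatch list
  perfect <- tapply(lib$ip1$mismatches == ".", lib$ip1$read_id, any)
  expect_true(all(perfect))
})

test_that("injected PCR duplicates disappear under deduplication", {
  cfg <- sim_config(seed = 7, depth = 4000, duplicate_rate = 0.5)
  db <- build_family_database(cfg)
  lib <- simulate_eclip_library(cfg, db)
  a <- deduplicate_pairs(assign_read_pairs(lib$ip1, db))
  kept <- sum(a$discard_reason == "none")
  # planted unique pairs = depth; collisions among random pairs are rare
  expect_gt(kept / cfg$depth, 0.99)
  expect_lte(kept, cfg$depth)
  expect_equal(nrow(a), round(cfg$depth * 1.5))
})

test_that("branch-point read simulator plants truncation pileups at adenosines", {
  cfg <- sim_config(seed = 8, n_genes = 10, truncation_fraction = 1)
  db <- build_family_database(cfg)
  ga <- simulate_genome_annotation(cfg, db)
  bp <- simulate_branchpoint_reads(cfg, ga)
  # truncation_fraction 1: all reads of a truth intron start at BP+1
  tr <- bp$truth
  for (i in seq_len(nrow(tr))) {
    start_exp <- if (tr$strand[i] == "+") tr$bp_pos[i] + 1L else tr$bp_pos[i] - 1L
    win <- eclipatlas:::bp_window_positions(tr$three_ss[i], tr$strand[i])
    sel <- bp$reads$strand == tr$strand[i] & bp$reads$pos5 %in% win
    # all window reads for this intron share the planted start
    near <- abs(bp$reads$pos5 - start_exp) <= 50 & sel
    expect_true(all(bp$reads$pos5[near] == start_exp))
    # the planted base is an A on the transcript strand
    base <- substr(ga$genome[[tr$chrom[i]]], tr$bp_pos[i] + 1L, tr$bp_pos[i] + 1L)
    expect_equal(base, if (tr$strand[i] == "+") "A" else "T")
    expect_true(tr$bp_offset[i] >= -50 && tr$bp_offset[i] <= -15)
  }
  # excluded introns get uniform starts and no truth entry
  all_introns <- eclipatlas:::annotation_introns(ga$tx_db)$intron_id
  bp2 <- simulate_branchpoint_reads(cfg, ga, exclude = all_introns)
  expect_equal(nrow(bp2$truth), 0L)
  expect_error(simulate_branchpoint_reads(
    sim_config(truncation_fraction = 1.2), ga), "truncation_fraction|rates")
})

test_that("A3SS simulator plants the bump where the truth says", {
  cfg <- sim_config(seed = 9, n_events = 10, n_native = 20)
  ds <- simulate_a3ss_dataset(cfg, bump_offset = -80)
  expect_equal(unique(ds$truth$bump_offset[ds$truth$responsive]), -80)
  expect_equal(sum(ds$truth$responsive), 10L)
  # all inclusion levels qualify as native by construction
  expect_true(all(ds$events$inclusion_level > 0.05 &
                  ds$events$inclusion_level < 0.95))
  expect_equal(nrow(ds$schema), 700L)
  expect_error(simulate_a3ss_dataset(cfg, bump_offset = -400), "outside")
  # zero responsive events
  ds0 <- simulate_a3ss_dataset(sim_config(seed = 9, n_events = 0, n_native = 5))
  expect_equal(sum(ds0$truth$responsive), 0L)
})

test_that("association fixtures plant overlap fractions and expression shifts", {
  cfg <- sim_config(seed = 10)
  fx <- simulate_association_fixtures(cfg, overlap = 1)
  expect_true(all(overlaps_any(fx$peak_sets[[1]], fx$peak_sets[[2]], "same")))
  fx2 <- simulate_association_fixtures(cfg, overlap = 0.5)
  got <- peak_overlap_fraction(fx2$peak_sets[[1]], fx2$peak_sets[[2]])
  expect_equal(got, 0.5, tolerance = 0.02)
  # planted shift 0: class means statistically indistinguishable
  fx0 <- simulate_association_fixtures(cfg, shift = 0, n_genes = 3000)
  ks <- l1_expression_shift(fx0$log2fc)
  expect_gt(min(ks$p_value), 1e-4)
  expect_error(simulate_association_fixtures(cfg, overlap = 1.5), "overlap")
  # determinism
  fxa <- simulate_association_fixtures(cfg)
  fxb <- simulate_association_fixtures(cfg)
  expect_identical(fxa, fxb)
})
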