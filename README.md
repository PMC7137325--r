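# eclipatlas

Family-aware quantification and positional analysis of eCLIP data.

Enhanced crosslinking and immunoprecipitation (eCLIP) maps where an RNA
binding protein (RBP) touches the transcriptome, using a size-matched
input library as background. Standard peak analysis discards
multi-mapping reads, yet much of the regulatory transcriptome — rRNA,
snRNA, snoRNA, tRNA, retrotransposable elements — is multicopy.
`eclipatlas` quantifies these elements by assigning each read pair to a
*family* of homologous reference transcripts, and implements the
positional analyses that build on such maps.

## What it computes

* **Family-aware assignment.** All mappings of a pair are scored by
  `sum[MN + floor((MX−MN)·min(Q,40)/40)] + sum[GO + N·GE]` over both
  mates (defaults MX=6, MN=2, GO=5, GE=3). Only minimum-score mappings
  survive; equal-best hits to multiple families are discarded; ties within
  a family go to the priority-1 primary transcript. A unique genomic
  mapping replaces the family hit only when it is better by **more than
  24** (over two top-quality mismatches per read). PCR duplicates collapse
  on (target, start, stop, UMI).
* **Element enrichment.** Per element *i*, fold `p_i/q_i` and relative
  information `p_i · log2(p_i/q_i)` (the element's share of the
  IP-vs-input Kullback–Leibler divergence), per replicate and merged by
  average RPM; significance from a 2×2 chi-square/Fisher rule.
* **Meta-gene / meta-exon profiles.** 162-bin meta-mRNA (13 5'UTR + 100
  CDS + 49 3'UTR) and splice-site-anchored panels (500 nt intron + 50 nt
  exon), with 100-fold bootstrap 5th/95th percentile bands, peak-count
  and bootstrap-floor filters, and min–max/max normalization.
* **Branch points.** Reverse transcription stops at the branch-point
  adenosine, so read 5' ends pile up one base 3' of it. Windows
  −50..−15 nt from each 3' splice site with ≥ 20 reads and one offset
  holding > 50% of them yield a single-nucleotide branch-point call,
  summarized as an 11-mer position frequency matrix with per-column
  information content.
* **Splicing maps.** Per A3SS event: (IP − input) RPM density plus a
  one-read pseudocount, normalized to sum to 1; a 2.5%-trimmed mean over
  events; and 0.5th/99.5th percentile control bands from 1000 draws out
  of native events (0.05 < inclusion < 0.95).
* **Association statistics.** Max-of-both-directions peak overlap
  fractions, unweighted running-sum enrichment with permutation p-values,
  accuracy/F1 cutoff sweeps, odds-ratio contingency tests
  (Yates/Fisher), Kolmogorov–Smirnov knockdown shift tests, and
  one-sample t enrichment of RBP mRNAs among peak-bound genes.
* **Synthetic data.** Generators for every input — family databases with
  diverged pseudogenes, a genome with embedded element copies, read
  libraries with UMIs/PCR duplicates/planted enrichment, branch-point
  truncation pileups, A3SS density bumps, association fixtures — all
  seeded and carrying planted ground truth.

## Worked example

```r
library(eclipatlas)

cfg <- sim_config(seed = 1, depth = 20000)     # planted 5x on family FAM01
db  <- build_family_database(cfg)              # 6 families x 4 transcripts
ga  <- simulate_genome_annotation(cfg, db)     # genes + embedded elements
lib <- simulate_eclip_library(cfg, db, ga)     # 2 IP replicates + input

res <- quantify_elements(lib$ip1, lib$ip2, lib$input, db, ga$tx_db, ga$rmsk)
subset(res$table, element == "FAM01",
       c(element, fold_merged, relinfo_merged, p_value, test_used))
#>   element fold_merged relinfo_merged p_value test_used
#> 8   FAM01     5.05002       1.503694       0      chi2
```

The planted 5-fold enrichment on `FAM01` comes back as a merged fold of
5.05 with strongly positive relative information (1.50 bits of the
dataset's IP/input divergence), significant by chi-square (p below double
precision here). Branch-point calling on simulated truncation reads:

```r
cfg <- sim_config(seed = 3, n_genes = 20)      # 40 introns, 70% truncation
ga  <- simulate_genome_annotation(cfg, build_family_database(cfg))
bp  <- simulate_branchpoint_reads(cfg, ga)
calls <- call_branchpoints(extract_bp_windows(ga$tx_db, bp$reads))
nrow(calls); mean(calls$bp_pos == bp$truth$bp_pos[match(calls$intron_id, bp$truth$intron_id)])
#> [1] 39
#> [1] 1
```

39 of 40 planted branch points are called (one falls under the strict
more-than-half rule by sampling noise) and every call lands on the exact
planted adenosine.

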