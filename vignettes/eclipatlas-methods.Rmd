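---
title: "Methods: family-aware eCLIP quantification and positional analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-aware eCLIP quantification and positional analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eclipatlas)
```

# Overview

Enhanced crosslinking and immunoprecipitation (eCLIP) maps the
transcriptome-wide binding sites of an RNA binding protein (RBP) by
sequencing RNA fragments crosslinked to the immunoprecipitated protein,
alongside a size-matched input library from the same lysate that serves as
the background control. Standard peak analysis works well on uniquely
mapping reads, but a large share of the regulatory transcriptome —
ribosomal and spliceosomal RNAs, snoRNAs, tRNAs, retrotransposable
elements — is multicopy: reads from these RNAs map to many near-identical
loci and are conventionally discarded.

`eclipatlas` implements an integrated set of analyses around this problem:

* **family-aware quantification** of multicopy elements, assigning
  multi-mapping read pairs to *families* of homologous reference
  transcripts rather than to single loci;
* **enrichment statistics** per element class, including a
  relative-information measure;
* **meta-gene and meta-exon profiles** of peak density with bootstrap
  confidence bands;
* **branch-point calling** from the 5'-end truncation pattern of reverse
  transcription;
* **splicing maps** of normalized crosslink density around alternative 3'
  splice site (A3SS) events; and
* **cross-dataset association statistics** (peak co-occurrence,
  running-sum enrichment, accuracy sweeps, contingency tests,
  knockdown expression shifts).

Every analysis can be exercised end-to-end on synthetic data with planted
ground truth, generated by the package itself; no downloads are required.

# Coordinate conventions

All genomic coordinates are 0-based half-open (the BED convention)
everywhere inside the package. Conversion to and from 1-based closed
coordinates happens only at the GTF boundary (`read_annotation`,
`write_annotation`) and when reading SAM (`read_alignments`). Strand `"."`
in BED input is mapped to a configurable default (with a warning) because
the antisense-family logic requires a strand.

Alignments are consumed as a plain tab-delimited table — one row per
reported mapping of one mate, with explicit mismatch qualities and gap
lengths — so the pipeline is fully testable without a BAM toolchain. A SAM
reader (via Rsamtools) reconstructs the same fields from MD tags, CIGAR
strings and base qualities.

# Family-aware assignment

## Scoring

Each mapping is scored by a penalty that mirrors quality-aware aligner
scoring: a mismatch at a base with Phred quality $Q$ costs
$MN + \lfloor (MX - MN)\,\min(Q,40)/40 \rfloor$ with defaults $MX=6$,
$MN=2$, and a gap of length $N$ costs $GO + N \cdot GE$ with $GO=5$,
$GE=3$. A pair's score is the sum over both mates; lower is better.

## Resolution rules

1. Only mappings achieving the pair's minimum score are kept.
2. Reverse-strand mappings count toward the family's *antisense*
   counterpart (except for strand-merged families such as simple repeats).
3. If the minimum-score mappings span more than one family the pair is
   discarded as ambiguous — this is deliberately conservative, since a
   read equally consistent with two element families carries no usable
   signal.
4. Within a family, ties resolve to the highest-priority transcript
   (priority 1 = primary transcript, pseudogenes rank lower), then to the
   lexicographically smallest transcript id, so results are deterministic.
5. A pair that also maps *uniquely* to the genome keeps the genomic
   mapping only when it beats the family pair score by strictly more than
   24 — i.e. more than two top-quality mismatches per read. At a margin of
   exactly 24 the family mapping is kept ("more than" is read strictly).
   Non-unique genomic mappings never participate. Pairs discarded as
   multi-family are not rescued by a genomic mapping: the ambiguity
   concerns the read's repeat identity, which a genomic location does not
   resolve.

PCR duplicates are removed after integration: pairs sharing mapping
target, start, stop and unique molecular identifier (UMI, carried in the
read name) are collapsed to one representative — the lexicographically
smallest read id, again for determinism.

## Region classes and element counts

Unique genomic fragments (spanning min start to max end over both mates)
that touch a RepeatMasker-style element by at least one base are counted
toward that element's family — sense or antisense according to the
relative strand. Everything else falls through a fixed priority order:
CDS; 5'UTR-and-3'UTR (a fragment touching both a 5'UTR and a 3'UTR, of
one transcript or two); 3'UTR; 5'UTR; proximal intronic (within 500 nt of
a splice site); distal intronic; the non-coding analogues of exonic and
intronic classes; antisense to an annotated transcript; intergenic.

Element counts are the sum of family-assigned pairs ("canonical" reads,
matching the reference element sequence) and element-overlapping unique
genomic pairs ("divergent" reads, matching a decayed genomic copy better
than the reference). The denominator for all fractions is the total
post-deduplication pair count.

## Enrichment and relative information

For element $i$, with $p_i$ and $q_i$ the fractions of total reads in IP
and input, the package reports the fold enrichment $p_i/q_i$ and the
relative information $p_i \log_2(p_i/q_i)$ — the element's contribution
to the Kullback–Leibler divergence between the IP and input read
distributions. It can be negative for depleted elements; the sum over the
full class partition is non-negative, which the test suite verifies on
random count tables. Zero counts receive a pseudocount of one read (the
sample's denominator is incremented accordingly, so fractions remain a
distribution); this is negligible at the simulated depths and only
guards against division by zero.

Two IP replicates are merged by averaging their reads-per-million before
comparing against the input, giving one overall fold and relative
information per dataset. Significance per element uses the 2x2 table
(element vs rest, pooled IP vs input): Pearson's chi-square without
continuity correction when all observed and expected cells are at least
5, otherwise a two-sided Fisher's exact test. (The Yates-corrected
chi-square appears only in the cross-dataset association module, where
annotation-based contingency tables use the analogous greater-than-5
rule.)

Whether the input sample should run through the identical pipeline
including the multi-family discard is not fully determined by the
method's description; we assume yes, so IP and input fractions are
measured on identically filtered read populations.

# Meta-gene and meta-exon profiles

Each gene is represented by its highest-TPM transcript (ties to the
lexicographically smallest id); genes below TPM 1 are excluded. The
meta-gene profile splits each representative mRNA into 162 bins — 13 for
the 5'UTR, 100 for the CDS, 49 for the 3'UTR — in *spliced* coordinates;
intronic peaks do not contribute. A bin's value is the fraction of its
nucleotides covered by at least one reproducible peak (binary occupancy),
averaged over genes. Genes lacking any of the three regions are excluded
(the method's treatment of UTR-less genes is not otherwise specified).

Bin mapping uses `floor(i * n_bins / len)` when the region is at least as
long as its bin count and nearest-nucleotide upsampling otherwise, so a
fully covered gene averages exactly 1 regardless of region lengths.

Confidence bands come from 100 bootstrap resamplings of genes (with
replacement), taking the 5th and 95th percentiles (nearest rank) per bin.
Datasets are retained for comparison only with at least 100
mRNA-overlapping peaks and a bootstrap floor — `max(boot_lo) >= 0.002`
peaks per gene (about 20 peaks in some bin) — then min–max normalized to
[0, 1]. Position–position Pearson correlations are computed across
retained datasets on the normalized profiles (a dataset–dataset
correlation matrix over positions is returned alongside).

The meta-exon profile anchors two 550-nt panels at every internal exon:
500 nt of upstream intron plus 50 nt of exon at the 3' splice site, and
50 nt of exon plus 500 nt of downstream intron at the 5' splice site, in
transcript orientation. Introns shorter than 1 kb contribute only the
half nearer each flank; exons shorter than 100 nt contribute half the
exon to each panel. Masked positions are excluded from that event's
denominator, so a position's value remains "fraction of contributing
events with a peak". The retention filter uses at least 100 peaks and a
0.0005 bootstrap floor, and normalization divides by the profile maximum.

Position-wise relative information along a single transcript uses the
same $p\log_2(p/q)$ form with per-position read-overlap fractions from a
single designated mate (the crosslink-proximal one). Positions with zero
reads in both IP and input are defined as 0 directly, so the track is
exactly invariant to uniform depth rescaling; the pseudocount applies
only where one sample alone is zero.

# Branch-point calling

Reverse transcription cannot read through the branch-point adenosine of
an excised intron lariat, so eCLIP reads of a spliceosomal helicase that
binds the intron after lariat formation accumulate 5' ends exactly one
base 3' of the branch point. The caller counts read 5' ends at offsets
-50..-15 (inclusive) from each annotated 3' splice site, deduplicating
splice sites shared by transcripts by (chromosome, position, strand). A
window yields a call when it holds at least 20 reads and one offset
carries strictly more than half of them (such an offset is necessarily
unique); the branch point is placed one base 5' of that modal read start.

The motif summary extracts 11-mers (5-nt flanks) around each call.
Because the method's description anchors on the read start while the
biologically meaningful base is the one before it, both anchors are
supported; the default anchors on the putative branch-point base, and the
two differ by exactly one position. Per column, information content is
$2 + \sum_b f_b \log_2 f_b$ bits. Windows overlapping exons of other
transcripts are not masked.

# Splicing maps at A3SS events

Per event, input read density is subtracted from IP density (each scaled
to reads per million), a pseudocount of one read per million is added at
every position, and the vector is normalized to sum to one so each event
weighs equally. Where in this chain the pseudocount enters is
underdetermined by the method's wording; adding it to IP and input
separately before subtraction makes the IP = input case degenerate (the
pseudocounts cancel and a zero vector cannot be sum-normalized), so the
default adds it to the subtracted density, and the pre-subtraction
variant is available via `pseudocount_where = "pre"`. The pseudocount is
scaled by the *input* library size, which keeps the vector invariant to
IP sequencing depth. Negative positions are retained; trimming handles
outliers.

The event region concatenates one 350-nt window per splice site — 300 nt
of intron then 50 nt of exon, 5' to 3' — distal 3' splice site first,
then proximal (700 positions for an A3SS event). The map is a trimmed
mean: at each position the highest and lowest 2.5% of values across
events (floor of `trim * n` per tail, so no trimming below n = 40) are
dropped before averaging. Control bands draw the responsive-class event
count from the native set (events with control-cell inclusion strictly
between 0.05 and 0.95) 1000 times — with replacement by default, valid
when the native set is small — and plot the 0.5th/99.5th percentiles.

# Association statistics

Peak co-occurrence between two datasets is the larger of the two directed
overlap fractions (share of A's peaks touching a B peak by at least one
base, strand-aware, and vice versa); datasets need at least 100
significant reproducible peaks (fold at least 8 versus input, p at most
1e-3). Enrichment of a labeled subset in a ranked list uses an unweighted
running sum (+1/|labels| on labeled items, -1/(n-|labels|) otherwise),
with the signed maximum deviation as enrichment score and a permutation
p-value (#{permutation ES >= observed}+1)/(n_perm+1).

The accuracy/F1 sweep classifies each dataset at every candidate
relative-information cutoff: true positives are datasets whose
most-enriched element exceeds the cutoff with published support for the
linked function; false positives exceed the cutoff without support; false
negatives fall below it despite an annotated function; true negatives
have neither. Ties in the argmax go to the smallest cutoff.

Contingency associations report the odds ratio (Haldane–Anscombe 0.5
correction when a cell is zero) with Yates-corrected chi-square when all
observed and expected cells exceed 5, else two-sided Fisher. Knockdown
expression shifts of element-bound genes use two-sided Kolmogorov–Smirnov
tests with no multiple-testing correction, comparing bound genes against
element-carrying-but-unbound genes and against all expressed genes. RBP
enrichment among peak-bound genes divides each dataset's RBP fraction by
the pooled background fraction and applies a one-sample t test of the
per-dataset folds against 1 (the method's wording leaves open whether the
test ran on fractions or folds; folds are used, and fractions are
reported alongside).

# The synthetic-data generators

All generators are pure functions of a `sim_config`: the same seed
reproduces every fixture byte for byte. The defaults are the conditions
the test suite and the acceptance script run under:

* 6 element families, each one primary transcript (600 nt) plus 3
  pseudogenes diverged at 5% per base — enough substitutions that family
  identity is unambiguous at 50-nt mate length;
* genomically embedded element copies diverged at double the pseudogene
  rate, so reads from them genuinely map better to the genome than to the
  family reference and exercise the canonical/divergent split and the
  24-point integration margin;
* a single-chromosome genome of three-exon genes on alternating strands
  with annotated UTRs and introns of 1.4/1.6 kb;
* 100,000 read pairs per sample (two IP replicates, one input), 50-nt
  mates, 10-nt UMIs, PCR duplicates injected at 10%, sequencing errors
  with qualities drawn from a {40, 20} mixture so both penalty regimes
  are exercised;
* a 5-fold planted IP enrichment on the first family, interpreted as the
  target IP/input share ratio (other sources are rescaled by a common
  factor so shares remain a distribution and the planted fold is
  recovered exactly in expectation);
* branch points planted on adenosines within the -50..-15 window, with
  70% of window reads truncating at branch point + 1;
* A3SS events (50 responsive + 150 native) with Poisson densities and a
  narrow planted IP bump at offset -80 from the proximal 3' splice site.

The simulations emulate the *statistical* structure the analyses assume —
multi-mapping ambiguity within a family, input-proportional sampling,
truncation pileups, planted density bumps — not the full texture of real
libraries: base qualities are two-valued, fragment lengths fixed, no
adapter or crosslink-induced deletion artifacts, and candidate alignments
are emitted only within a read's true family (random cross-family
sequences would not be reported by an aligner; multi-family ties are
exercised by constructed fixtures instead). Passing tests therefore
demonstrate correctness of the analytic rules, not robustness to every
artifact of real data.

Problem sizes in the tests (depth 1e5, 100 genes for profile and
branch-point runs, 1000 control draws) were chosen as the smallest sizes
at which the stochastic checks are comfortably stable.

# Numerical and edge-case choices

* Bootstrap and control-band percentiles use the nearest-rank convention
  (`quantile type = 1`).
* Trimmed-mean tail counts round down (`floor(trim * n)`).
* A window offset of exactly -50 or -15 is a valid branch-point offset
  (both ends inclusive); a modal fraction of exactly one half is not a
  call; a family-vs-genome margin of exactly 24 keeps the family.
* Constant profiles cannot be min–max normalized and are dropped with a
  flagged reason.
* Empty peak sets, empty paralog sets, zero totals and missing UMIs are
  errors, not silent results.

# Limitations

The package consumes peak calls, differential-splicing event tables and
knockdown fold-changes as inputs; it does not call peaks, run aligners or
fit differential models. The genomic integration rule assumes at most one
unique genomic mapping per pair. Hierarchical clustering of profiles and
figure aesthetics are out of scope.
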