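#' Simulation configuration
#'
#' One configuration object drives every generator, so that a fixed seed
#' reproduces every fixture byte-for-byte. Defaults describe the study
#' conditions the pipeline is validated under: 6 element families with 3
#' pseudogenes each diverged at 5% per base, genomically embedded element
#' copies diverged at twice that rate, 50 nt mates with 10 nt UMIs,
#' 100,000 read pairs per sample, a 5-fold IP enrichment planted on the
#' first family, and a 0.7 branch-point truncation fraction.
#'
#' @param seed integer RNG seed.
#' @param n_families number of element families.
#' @param pseudogenes_per_family diverged lower-priority members per family.
#' @param pseudogene_divergence per-base substitution rate of pseudogenes
#'   (must be < 0.5; families become unassignable beyond that).
#' @param element_divergence per-base substitution rate of genomically
#'   embedded element copies (default twice the pseudogene rate).
#' @param transcript_length family transcript length (nt).
#' @param element_length embedded element length (nt).
#' @param read_length mate length (nt).
#' @param umi_length UMI length (nt).
#' @param depth read pairs per sample.
#' @param per_base_error_rate sequencing substitution rate in [0, 1].
#' @param enrichment named list: family id -> planted IP/input fold.
#' @param duplicate_rate fraction of extra PCR-duplicate pairs injected.
#' @param truncation_fraction fraction of branch-point-window reads
#'   truncating exactly one base 3' of the branch point.
#' @param n_genes genes in the simulated genome.
#' @param n_sense_elements,n_antisense_elements embedded element copies.
#' @param genomic_share fraction of input reads from the genome (split
#'   `exon_share` : element share).
#' @param exon_share fraction of input reads from gene exons.
#' @param reads_per_intron branch-point reads per intron window.
#' @param n_events,n_native alternative 3' splice site event counts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 6L,
                       pseudogenes_per_family = 3L,
                       pseudogene_divergence = 0.05,
                       element_divergence = 2 * pseudogene_divergence,
                       transcript_length = 600L,
                       element_length = 250L,
                       read_length = 50L,
                       umi_length = 10L,
                       depth = 1e5,
                       per_base_error_rate = 0,
                       enrichment = list(FAM01 = 5),
                       duplicate_rate = 0.1,
                       truncation_fraction = 0.7,
                       n_genes = 8L,
                       n_sense_elements = 4L,
                       n_antisense_elements = 4L,
                       genomic_share = 0.3,
                       exon_share = 0.2,
                       reads_per_intron = 30L,
                       n_events = 50L,
                       n_native = 150L) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              pseudogenes_per_family = as.integer(pseudogenes_per_family),
              pseudogene_divergence = pseudogene_divergence,
              element_divergence = element_divergence,
              transcript_length = as.integer(transcript_length),
              element_length = as.integer(element_length),
              read_length = as.integer(read_length),
              umi_length = as.integer(umi_length),
              depth = as.integer(depth),
              per_base_error_rate = per_base_error_rate,
              enrichment = enrichment,
              duplicate_rate = duplicate_rate,
              truncation_fraction = truncation_fraction,
              n_genes = as.integer(n_genes),
              n_sense_elements = as.integer(n_sense_elements),
              n_antisense_elements = as.integer(n_antisense_elements),
              genomic_share = genomic_share, exon_share = exon_share,
              reads_per_intron = as.integer(reads_per_intron),
              n_events = as.integer(n_events), n_native = as.integer(n_native))
  rates <- c(cfg$pseudogene_divergence, cfg$element_divergence,
             cfg$per_base_error_rate, cfg$duplicate_rate,
             cfg$truncation_fraction, cfg$genomic_share, cfg$exon_share)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (any(unlist(enrichment) <= 0)) stop("enrichment folds must be positive")
  structure(cfg, class = "sim_config")
}

## evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

## substitute each base with prob `rate`, always to a different base
mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    cur <- match(ch[hit], BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_umis <- function(n, len) {
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
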