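#' Simulate a multicopy element family database
#'
#' Each family gets one priority-1 primary transcript of
#' `transcript_length` random bases and `pseudogenes_per_family`
#' lower-priority members diverged from the primary at the configured
#' per-base substitution rate. Deterministic under the config seed.
#'
#' @param cfg a [sim_config].
#' @return a [family_db] with sequences attached.
#' @export
build_family_database <- function(cfg) {
  stopifnot(cfg$n_families >= 1L)
  if (cfg$pseudogene_divergence >= 0.5)
    stop("divergence >= 0.5 would make families unassignable")
  with_seed(cfg$seed, {
    members <- list(); seqs <- character(0)
    for (i in seq_len(cfg$n_families)) {
      fam <- sprintf("FAM%02d", i)
      primary_id <- paste0(fam, "_primary")
      primary <- random_dna(cfg$transcript_length)
      ids <- primary_id; ss <- primary
      pr <- 1L
      for (j in seq_len(cfg$pseudogenes_per_family)) {
        ids <- c(ids, sprintf("%s_ps%d", fam, j))
        ss <- c(ss, mutate_dna(primary, cfg$pseudogene_divergence))
        pr <- c(pr, j + 1L)
      }
      members[[i]] <- data.frame(family_id = fam, transcript_id = ids,
                                 priority = pr, stringsAsFactors = FALSE)
      seqs <- c(seqs, stats::setNames(ss, ids))
    }
    family_db(do.call(rbind, members),
              sequences = Biostrings::DNAStringSet(seqs))
  })
}

#' Write family sequences as FASTA
#' @param db a [family_db] carrying sequences.
#' @param path output file.
#' @export
write_family_fasta <- function(db, path) {
  if (is.null(db$sequences)) stop("family_db has no sequences")
  Biostrings::writeXStringSet(db$sequences, path)
  invisible(path)
}

#' Simulate a genome with genes and embedded element copies
#'
#' Builds one chromosome carrying `n_genes` three-exon genes (100 nt
#' 5'UTR, split CDS, 100-150 nt 3'UTR, introns of 1.2-1.4 kb) on
#' alternating strands, then embeds decayed copies of family primaries
#' inside distal introns, sense or antisense to the host gene. Embedded
#' copies diverge from the family primary at `element_divergence`
#' (double the pseudogene rate by default), so reads from them map to
#' the genome better than to the family reference.
#'
#' @param cfg a [sim_config].
#' @param db a [family_db] from [build_family_database].
#' @return list: `genome` (named character vector of chromosome
#'   sequences), `tx_db` (a [transcript_db]), `rmsk` (element intervals,
#'   family in `name`), `elements` (placement bookkeeping incl. source
#'   offsets).
#' @export
simulate_genome_annotation <- function(cfg, db) {
  n_el <- cfg$n_sense_elements + cfg$n_antisense_elements
  with_seed(cfg$seed + 1L, {
    gap <- 300L
    e1 <- 150L; e2 <- 120L; e3 <- 200L
    i1 <- 1400L; i2 <- 1600L
    glen <- e1 + i1 + e2 + i2 + e3
    total <- cfg$n_genes * (glen + gap) + gap
    chrom <- "chrSim"
    seq_ch <- strsplit(random_dna(total), "", fixed = TRUE)[[1L]]
    tr <- list(); ex <- list()
    introns <- list()
    for (g in seq_len(cfg$n_genes)) {
      s <- gap + (g - 1L) * (glen + gap)
      strand <- if (g %% 2L == 1L) "+" else "-"
      gid <- sprintf("gene%03d", g); tid <- sprintf("tx%03d", g)
      starts <- c(s, s + e1 + i1, s + e1 + i1 + e2 + i2)
      ends <- starts + c(e1, e2, e3)
      cds <- if (strand == "+") c(starts[1] + 100L, starts[3] + 50L)
             else c(starts[1] + 100L, ends[3] - 100L)
      tr[[g]] <- data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
                            strand = strand, tpm = 10,
                            cds_start = cds[1], cds_end = cds[2],
                            stringsAsFactors = FALSE)
      ex[[g]] <- data.frame(transcript_id = tid, start = starts, end = ends,
                            stringsAsFactors = FALSE)
      introns[[g]] <- data.frame(gene = g, strand = strand,
                                 start = c(ends[1], ends[2]),
                                 end = c(starts[2], starts[3]))
    }
    introns <- do.call(rbind, introns)
    ## place elements in distal intron interiors, no two overlapping
    fams <- unique(db$members$family_id)
    placements <- list()
    if (n_el > 0L) {
      antisense <- c(rep(FALSE, cfg$n_sense_elements),
                     rep(TRUE, cfg$n_antisense_elements))
      occupied <- data.frame(start = integer(0), end = integer(0))
      for (k in seq_len(n_el)) {
        fam <- fams[((k - 1L) %% length(fams)) + 1L]
        primary <- as.character(db$sequences[[paste0(fam, "_primary")]])
        src_off <- 0L
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          it <- introns[sample.int(nrow(introns), 1L), ]
          ## keep copies in distal intron interiors (> 500 nt from splice sites)
          lo <- it$start + 500L; hi <- it$end - 500L - cfg$element_length
          if (hi <= lo) next
          pos <- lo + sample.int(hi - lo, 1L)
          if (nrow(occupied) &&
              any(pos < occupied$end & pos + cfg$element_length > occupied$start))
            next
          el_seq <- mutate_dna(substr(primary, src_off + 1L,
                                      src_off + cfg$element_length),
                               cfg$element_divergence)
          el_strand <- if (antisense[k]) flip_strand(it$strand) else it$strand
          ## sequence on the genome '+' strand
          plus_seq <- if (el_strand == "+") el_seq else revcomp(el_seq)
          seq_ch[(pos + 1L):(pos + cfg$element_length)] <-
            strsplit(plus_seq, "", fixed = TRUE)[[1L]]
          occupied <- rbind(occupied,
                            data.frame(start = pos, end = pos + cfg$element_length))
          placements[[k]] <- data.frame(
            chrom = chrom, start = pos, end = pos + cfg$element_length,
            strand = el_strand, name = fam, src_offset = src_off,
            host_strand = it$strand, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place element after 1000 attempts")
      }
    }
    rmsk <- if (length(placements))
      do.call(rbind, placements)[c("chrom", "start", "end", "strand", "name")]
    else genomic_intervals(character(0), integer(0), integer(0), character(0))
    elements <- if (length(placements)) do.call(rbind, placements)
                else NULL
    list(genome = stats::setNames(paste(seq_ch, collapse = ""), chrom),
         tx_db = transcript_db(do.call(rbind, tr), do.call(rbind, ex)),
         rmsk = rmsk, elements = elements)
  })
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")
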