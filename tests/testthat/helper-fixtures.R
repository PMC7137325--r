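# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# minimal annotation: one coding gene per strand, one non-coding transcript
toy_tx_db <- function() {
  transcripts <- data.frame(
    transcript_id = c("txP", "txM", "txN"),
    gene_id = c("gP", "gM", "gN"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    tpm = c(5, 5, 5),
    cds_start = c(120L, 5120L, NA),
    cds_end = c(2450L, 7380L, NA),
    stringsAsFactors = FALSE)
  # intron2 of txP is 1080 nt, long enough to carry a distal segment
  exons <- data.frame(
    transcript_id = c("txP", "txP", "txP", "txM", "txM", "txM", "txN", "txN"),
    start = c(100L, 1200L, 2400L, 5100L, 6200L, 7300L, 9000L, 10500L),
    end = c(250L, 1320L, 2600L, 5250L, 6320L, 7500L, 9200L, 10700L),
    stringsAsFactors = FALSE)
  transcript_db(transcripts, exons)
}

# two-family database with explicit priorities; sequences optional
toy_family_db <- function() {
  family_db(data.frame(
    family_id = c("L1", "L1", "Alu", "Alu"),
    transcript_id = c("L1_primary", "L1_ps1", "Alu_primary", "Alu_ps1"),
    priority = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE))
}

# one mate-level alignment row
aln_row <- function(read_id, mate, target, kind, start, end, strand = "+",
                    mismatches = ".", gaps = ".", uniq = FALSE) {
  data.frame(read_id = read_id, mate = mate, target_id = target,
             target_kind = kind, start = start, end = end, strand = strand,
             mismatches = mismatches, gaps = gaps, is_unique_genomic = uniq,
             stringsAsFactors = FALSE)
}

# both mates of a pair on one target, arbitrary mismatch strings
pair_aln <- function(read_id, target, kind = "family_transcript",
                     start = 0L, L = 50L, strand = "+",
                     mm1 = ".", mm2 = ".", uniq = FALSE) {
  rbind(aln_row(read_id, 1L, target, kind, start, start + L, strand, mm1,
                uniq = uniq),
        aln_row(read_id, 2L, target, kind, start + L, start + 2L * L, strand,
                mm2, uniq = uniq))
}

# independent penalty oracle working from raw read/reference strings
oracle_score <- function(read, ref, qual, MX = 6, MN = 2, GO = 5, GE = 3,
                         gaps = integer(0)) {
  rc <- strsplit(read, "")[[1]]
  fc <- strsplit(ref, "")[[1]]
  mm <- which(rc != fc)
  s <- 0
  for (i in mm) s <- s + MN + floor((MX - MN) * min(qual[i], 40) / 40)
  for (g in gaps) s <- s + GO + g * GE
  s
}
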