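#' Pick one representative transcript per gene
#'
#' The transcript with the highest TPM represents each gene (ties break
#' to the lexicographically smallest transcript id); genes whose best
#' transcript falls below `min_tpm` are excluded.
#'
#' @param db a [transcript_db] with populated `tpm`.
#' @param min_tpm expression threshold (default 1).
#' @return character vector of transcript ids, named by gene id.
#' @export
select_representative_transcripts <- function(db, min_tpm = 1) {
  tr <- db$transcripts
  tr <- tr[!is.na(tr$tpm), , drop = FALSE]
  tr <- tr[order(tr$gene_id, -tr$tpm, tr$transcript_id), , drop = FALSE]
  best <- tr[!duplicated(tr$gene_id), , drop = FALSE]
  best <- best[best$tpm >= min_tpm, , drop = FALSE]
  stats::setNames(best$transcript_id, best$gene_id)
}

## per-(chrom, strand) peak occupancy lookup: returns function(chrom,
## strand, pos0) -> logical
peak_occupancy <- function(peaks) {
  cov <- list()
  if (nrow(peaks)) {
    key <- paste(peaks$chrom, peaks$strand)
    for (k in unique(key)) {
      p <- peaks[key == k, , drop = FALSE]
      v <- logical(max(p$end))
      for (i in seq_len(nrow(p))) v[(p$start[i] + 1L):p$end[i]] <- TRUE
      cov[[k]] <- v
    }
  }
  function(chrom, strand, pos0) {
    v <- cov[[paste(chrom, strand)]]
    if (is.null(v)) return(rep(FALSE, length(pos0)))
    idx <- pos0 + 1L
    out <- idx >= 1L & idx <= length(v)
    out[out] <- v[idx[out]]
    out
  }
}

## spliced-coordinate (5'->3') genomic positions of a transcript
spliced_positions <- function(db, tid) {
  ex <- exons_of(db, tid)
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i)
    seq.int(ex$start[i], ex$end[i] - 1L)))
  strand <- db$transcripts$strand[db$transcripts$transcript_id == tid]
  if (strand == "-") rev(pos) else pos
}

## nucleotide occupancy vector -> n_bins bin values; downsampling maps
## nucleotide i (0-based) to bin floor(i*n_bins/len); upsampling takes
## the nearest nucleotide
bin_vector <- function(x, n_bins) {
  len <- length(x)
  if (len >= n_bins) {
    bin <- floor((seq_len(len) - 1L) * n_bins / len) + 1L
    as.numeric(tapply(x, factor(bin, levels = seq_len(n_bins)), mean))
  } else {
    x[floor((seq_len(n_bins) - 1L) * len / n_bins) + 1L]
  }
}

#' Meta-gene (meta-mRNA) peak-density profile
#'
#' Each representative transcript is split into 162 bins (13 for the
#' 5'UTR, 100 for the CDS, 49 for the 3'UTR) in spliced coordinates; a
#' bin's value is the fraction of its nucleotides covered by at least
#' one peak, averaged over genes. Genes missing any of the three regions
#' are excluded (count reported). 100 bootstrap resamplings of genes
#' give 5th/95th percentile bands (nearest rank).
#'
#' @param peaks stranded peak intervals.
#' @param db a [transcript_db].
#' @param representatives from [select_representative_transcripts].
#' @param bins region bin counts (5'UTR, CDS, 3'UTR).
#' @param n_boot bootstrap resamplings (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `meta_profile`: `values`, `boot_lo`,
#'   `boot_hi`, `n_units`, `n_excluded`, `n_peaks`, `kind`.
#' @export
metagene_profile <- function(peaks, db, representatives,
                             bins = c(13L, 100L, 49L), n_boot = 100L,
                             seed = 1L) {
  if (nrow(peaks) == 0L) stop("dataset has no peaks")
  occ <- peak_occupancy(peaks)
  mat <- list(); excluded <- 0L
  for (tid in representatives) {
    t <- db$transcripts[db$transcripts$transcript_id == tid, ]
    r <- transcript_regions(db, tid)
    lens <- c(sum(r$utr5$end - r$utr5$start), sum(r$cds$end - r$cds$start),
              sum(r$utr3$end - r$utr3$start))
    if (any(lens == 0L)) { excluded <- excluded + 1L; next }
    pos <- spliced_positions(db, tid)
    o <- occ(t$chrom, t$strand, pos)
    u5 <- o[seq_len(lens[1L])]
    cds <- o[lens[1L] + seq_len(lens[2L])]
    u3 <- o[lens[1L] + lens[2L] + seq_len(lens[3L])]
    mat[[length(mat) + 1L]] <- c(bin_vector(u5, bins[1L]),
                                 bin_vector(cds, bins[2L]),
                                 bin_vector(u3, bins[3L]))
  }
  if (!length(mat)) stop("no gene with all three regions annotated")
  m <- do.call(rbind, mat)
  n_peaks <- count_mrna_peaks(peaks, db, representatives)
  finish_profile(m, n_boot, seed, kind = "metagene", n_peaks = n_peaks,
                 n_excluded = excluded)
}

## peaks overlapping any representative transcript exon, same strand
count_mrna_peaks <- function(peaks, db, representatives) {
  ex <- do.call(rbind, lapply(representatives, function(tid) {
    t <- db$transcripts[db$transcripts$transcript_id == tid, ]
    e <- exons_of(db, tid)
    data.frame(chrom = t$chrom, start = e$start, end = e$end,
               strand = t$strand, stringsAsFactors = FALSE)
  }))
  sum(overlaps_any(peaks, ex, "same"))
}

finish_profile <- function(m, n_boot, seed, kind, n_peaks,
                           n_excluded = 0L) {
  values <- colMeans(m, na.rm = TRUE)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
      colMeans(m[idx, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(m)))
  })
  structure(list(
    values = values,
    boot_lo = apply(boot, 1L, stats::quantile, probs = 0.05, type = 1,
                    na.rm = TRUE),
    boot_hi = apply(boot, 1L, stats::quantile, probs = 0.95, type = 1,
                    na.rm = TRUE),
    n_units = nrow(m), n_excluded = n_excluded, n_peaks = n_peaks,
    kind = kind), class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile (", x$kind, "): ", length(x$values), " positions, ",
      x$n_units, " units, ", x$n_peaks, " peaks\n", sep = "")
  invisible(x)
}

#' Meta-exon profile anchored at internal-exon splice sites
#'
#' For every internal exon (first and last excluded) of the
#' representative transcripts, two panels are recorded in transcript
#' orientation: a 3' splice site panel (500 nt upstream intron + 50 nt
#' exon) and a 5' splice site panel (50 nt exon + 500 nt downstream
#' intron). The value at a position is the fraction of events with a
#' peak covering it. Introns shorter than 1 kb contribute only the half
#' nearer each flank; exons shorter than 100 nt contribute their nearer
#' half to each panel (masked positions are excluded from that event's
#' denominator). Bootstrap bands as in [metagene_profile].
#'
#' @inheritParams metagene_profile
#' @param flank_intron,flank_exon panel composition (defaults 500, 50).
#' @return a `meta_profile` (length `2 * (flank_intron + flank_exon)`).
#' @export
metaexon_profile <- function(peaks, db, representatives,
                             flank_intron = 500L, flank_exon = 50L,
                             n_boot = 100L, seed = 1L) {
  occ <- peak_occupancy(peaks)
  panel <- flank_intron + flank_exon
  rows <- list()
  for (tid in representatives) {
    t <- db$transcripts[db$transcripts$transcript_id == tid, ]
    ex <- exons_of(db, tid)
    if (nrow(ex) < 3L) next
    ## transcript orientation: exon k has upstream intron (5' side) and
    ## downstream intron (3' side)
    ord <- if (t$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    for (k in 2L:(nrow(ex) - 1L)) {
      i <- ord[k]
      e <- ex[i, ]
      elen <- e$end - e$start
      if (t$strand == "+") {
        up_len <- e$start - ex$end[i - 1L]
        dn_len <- ex$start[i + 1L] - e$end
        p3_int <- seq.int(e$start - flank_intron, e$start - 1L)   # 5'->3'
        p3_ex <- seq.int(e$start, e$start + flank_exon - 1L)
        p5_ex <- seq.int(e$end - flank_exon, e$end - 1L)
        p5_int <- seq.int(e$end, e$end + flank_intron - 1L)
        d3_int <- rev(seq_len(flank_intron))  # distance from 3'SS
        d3_ex <- seq_len(flank_exon)
        d5_ex <- rev(seq_len(flank_exon))
        d5_int <- seq_len(flank_intron)
      } else {
        up_len <- ex$start[i + 1L] - e$end
        dn_len <- e$start - ex$end[i - 1L]
        p3_int <- seq.int(e$end + flank_intron - 1L, e$end)       # 5'->3'
        p3_ex <- seq.int(e$end - 1L, e$end - flank_exon)
        p5_ex <- seq.int(e$start + flank_exon - 1L, e$start)
        p5_int <- seq.int(e$start - 1L, e$start - flank_intron)
        d3_int <- rev(seq_len(flank_intron))
        d3_ex <- seq_len(flank_exon)
        d5_ex <- rev(seq_len(flank_exon))
        d5_int <- seq_len(flank_intron)
      }
      v3 <- as.numeric(occ(t$chrom, t$strand, p3_int))
      v3e <- as.numeric(occ(t$chrom, t$strand, p3_ex))
      v5e <- as.numeric(occ(t$chrom, t$strand, p5_ex))
      v5 <- as.numeric(occ(t$chrom, t$strand, p5_int))
      ## masking: short introns give only the nearer half; short exons
      ## give half the exon to each panel
      if (up_len < 1000L) v3[d3_int > up_len %/% 2L] <- NA
      v3[d3_int > up_len] <- NA
      if (dn_len < 1000L) v5[d5_int > dn_len %/% 2L] <- NA
      v5[d5_int > dn_len] <- NA
      if (elen < 2L * flank_exon) {
        v3e[d3_ex > elen %/% 2L] <- NA
        v5e[d5_ex > elen %/% 2L] <- NA
      }
      rows[[length(rows) + 1L]] <- c(v3, v3e, v5e, v5)
    }
  }
  if (!length(rows)) stop("no internal exon among the representatives")
  finish_profile(do.call(rbind, rows), n_boot, seed, kind = "metaexon",
                 n_peaks = nrow(peaks))
}

#' Filter, normalize and cross-correlate a set of profiles
#'
#' Meta-gene datasets are kept when they have at least `min_peaks`
#' mRNA-overlapping peaks and the bootstrap 5th percentile reaches
#' `min_boot` (0.002 peaks per gene) at some position; retained profiles
#' are min-max normalized to span [0, 1]. Meta-exon datasets use the
#' 0.0005 cutoff and are divided by their maximum instead. A Pearson
#' correlation matrix across retained datasets at every position pair is
#' returned for the meta-gene kind.
#'
#' @param profiles named list of `meta_profile` objects.
#' @param kind `"metagene"` or `"metaexon"`.
#' @param min_peaks peak-count filter (default 100).
#' @param min_boot bootstrap-floor filter (defaults 0.002 / 0.0005).
#' @return list: `profiles` (retained, with `normalized_values`),
#'   `kept`, `dropped` (with reasons), `correlation` (position x
#'   position matrix, metagene only, `NULL` below 2 datasets).
#' @export
normalize_and_filter_profiles <- function(profiles,
                                          kind = c("metagene", "metaexon"),
                                          min_peaks = 100L,
                                          min_boot = NULL) {
  kind <- match.arg(kind)
  if (is.null(min_boot)) min_boot <- if (kind == "metagene") 0.002 else 5e-4
  kept <- character(0); dropped <- character(0); reasons <- character(0)
  out <- list()
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    if (p$n_peaks < min_peaks) {
      dropped <- c(dropped, nm); reasons <- c(reasons, "too_few_peaks"); next
    }
    if (max(p$boot_lo, na.rm = TRUE) < min_boot) {
      dropped <- c(dropped, nm); reasons <- c(reasons, "bootstrap_floor"); next
    }
    v <- p$values
    if (kind == "metagene") {
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) == 0) {
        dropped <- c(dropped, nm); reasons <- c(reasons, "constant_profile")
        next
      }
      p$normalized_values <- (v - rng[1L]) / diff(rng)
    } else {
      mx <- max(v, na.rm = TRUE)
      if (mx == 0) {
        dropped <- c(dropped, nm); reasons <- c(reasons, "constant_profile")
        next
      }
      p$normalized_values <- v / mx
    }
    out[[nm]] <- p
    kept <- c(kept, nm)
  }
  correlation <- NULL
  dataset_correlation <- NULL
  if (kind == "metagene" && length(out) >= 2L) {
    m <- do.call(rbind, lapply(out, `[[`, "normalized_values"))
    ## position x position, computed across datasets
    correlation <- suppressWarnings(stats::cor(m))
    ## dataset x dataset, computed across positions
    dataset_correlation <- suppressWarnings(stats::cor(t(m)))
  }
  list(profiles = out, kept = kept,
       dropped = data.frame(dataset = dropped, reason = reasons,
                            stringsAsFactors = FALSE),
       correlation = correlation,
       dataset_correlation = dataset_correlation)
}
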