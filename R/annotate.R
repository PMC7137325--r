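#' Build the genomic region index used for fragment classification
#'
#' Precomputes, from a [transcript_db], the interval sets behind the
#' 11-class annotation priority: CDS, 5'UTR+3'UTR, 3'UTR, 5'UTR, proximal
#' intronic (within `proximal_nt` of a splice site), distal intronic,
#' non-coding exonic, non-coding proximal/distal intronic, antisense to
#' annotated transcripts, intergenic.
#'
#' @param db a [transcript_db].
#' @param proximal_nt proximal-intron distance from a splice site
#'   (default 500).
#' @return list of interval data.frames, class `region_index`.
#' @export
build_region_index <- function(db, proximal_nt = 500L) {
  acc <- list(cds = list(), utr5 = list(), utr3 = list(),
              prox = list(), dist = list(), nc_exon = list(),
              nc_prox = list(), nc_dist = list(), span = list())
  for (i in seq_len(nrow(db$transcripts))) {
    t <- db$transcripts[i, ]
    r <- transcript_regions(db, t$transcript_id)
    coding <- !is.na(t$cds_start)
    ir <- split_introns(r$introns, proximal_nt)
    if (coding) {
      acc$cds[[i]] <- r$cds; acc$utr5[[i]] <- r$utr5; acc$utr3[[i]] <- r$utr3
      acc$prox[[i]] <- ir$prox; acc$dist[[i]] <- ir$dist
    } else {
      acc$nc_exon[[i]] <- r$exons
      acc$nc_prox[[i]] <- ir$prox; acc$nc_dist[[i]] <- ir$dist
    }
    acc$span[[i]] <- data.frame(start = min(r$exons$start),
                                end = max(r$exons$end),
                                chrom = t$chrom, strand = t$strand)
  }
  idx <- lapply(acc, function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (!length(l)) return(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), strand = character(0)))
    do.call(rbind, l)[c("chrom", "start", "end", "strand")]
  })
  structure(idx, class = "region_index")
}

## split intron list into proximal (within d of either splice site) and
## distal remainder pieces
split_introns <- function(introns, d) {
  prox <- list(); dist <- list()
  for (j in seq_len(nrow(introns))) {
    s <- introns$start[j]; e <- introns$end[j]
    if (e - s <= 2 * d) prox[[j]] <- data.frame(start = s, end = e)
    else {
      prox[[j]] <- data.frame(start = c(s, e - d), end = c(s + d, e))
      dist[[j]] <- data.frame(start = s + d, end = e - d)
    }
  }
  bind <- function(l, meta) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (!length(l)) return(data.frame(start = integer(0), end = integer(0),
                                      chrom = character(0), strand = character(0)))
    d <- do.call(rbind, l)
    d$chrom <- meta$chrom[1]; d$strand <- meta$strand[1]; d
  }
  list(prox = bind(prox, introns), dist = bind(dist, introns))
}

REGION_CLASSES <- c("CDS", "5utr_3utr", "3utr", "5utr", "proximal_intron",
                    "distal_intron", "noncoding_exon",
                    "noncoding_proximal_intron", "noncoding_distal_intron",
                    "antisense", "intergenic")

#' Classify genomic fragments
#'
#' A fragment overlapping (by at least one base) a RepeatMasker-style
#' element is assigned that element's family — to the sense family when
#' fragment and element strands agree, to the antisense counterpart
#' otherwise (strand-merged families ignore strand). Fragments not
#' touching an element fall through the 11-class priority order (see
#' [build_region_index]); sense classes require strand agreement with the
#' annotated transcript.
#'
#' @param frags interval data.frame of fragment spans.
#' @param index a `region_index` from [build_region_index].
#' @param rmsk element intervals with a `name` column holding the family
#'   id (may be empty).
#' @param merged character vector of strand-insensitive family ids.
#' @return character vector of class labels along `frags` rows.
#' @export
annotate_genomic_fragment <- function(frags, index, rmsk = NULL,
                                      merged = character(0)) {
  n <- nrow(frags)
  lab <- rep(NA_character_, n)
  if (!n) return(character(0))
  if (!is.null(rmsk) && nrow(rmsk)) {
    op <- overlap_pairs(frags, rmsk)
    if (nrow(op)) {
      w <- pmin(frags$end[op[, "q"]], rmsk$end[op[, "s"]]) -
        pmax(frags$start[op[, "q"]], rmsk$start[op[, "s"]])
      fam <- rmsk$name[op[, "s"]]
      el_lab <- ifelse(fam %in% merged | frags$strand[op[, "q"]] == rmsk$strand[op[, "s"]],
                       fam, antisense_family(fam))
      ## widest overlap wins, then lexicographically smallest label
      o <- order(op[, "q"], -w, el_lab)
      pick <- o[!duplicated(op[o, "q"])]
      lab[op[pick, "q"]] <- el_lab[pick]
    }
  }
  todo <- function() is.na(lab)
  hit <- function(set, mode) overlaps_any(frags, index[[set]], mode) & todo()
  lab[hit("cds", "same")] <- "CDS"
  both <- overlaps_any(frags, index$utr5, "same") &
    overlaps_any(frags, index$utr3, "same") & todo()
  lab[both] <- "5utr_3utr"
  lab[hit("utr3", "same")] <- "3utr"
  lab[hit("utr5", "same")] <- "5utr"
  lab[hit("prox", "same")] <- "proximal_intron"
  lab[hit("dist", "same")] <- "distal_intron"
  lab[hit("nc_exon", "same")] <- "noncoding_exon"
  lab[hit("nc_prox", "same")] <- "noncoding_proximal_intron"
  lab[hit("nc_dist", "same")] <- "noncoding_distal_intron"
  lab[hit("span", "opposite")] <- "antisense"
  lab[todo()] <- "intergenic"
  lab
}

#' Tally element and region-class counts for one sample
#'
#' Element counts are the sum of family-assigned read pairs (the
#' "canonical" route) plus unique-genomic pairs whose fragment overlaps
#' that element's RepeatMasker intervals (the "divergent" route).
#' Remaining genomic pairs are tallied into the 11 region classes. The
#' denominator for read fractions is the total number of post-dedup
#' pairs.
#'
#' @param assignments deduplicated assignment table
#'   ([assign_read_pairs] then [deduplicate_pairs]).
#' @param index a `region_index`.
#' @param rmsk element intervals (family id in `name`), or `NULL`.
#' @param merged strand-insensitive family ids.
#' @return list with `counts` (data.frame `class`, `count`, `canonical`,
#'   `divergent`) and `total` (denominator).
#' @export
tally_elements <- function(assignments, index, rmsk = NULL,
                           merged = character(0)) {
  a <- assignments[assignments$discard_reason == "none", , drop = FALSE]
  cls <- character(nrow(a))
  fam_rows <- a$kind == "family"
  cls[fam_rows] <- a$assigned_class[fam_rows]
  if (any(!fam_rows)) {
    frags <- data.frame(chrom = a$target_id[!fam_rows],
                        start = a$start[!fam_rows], end = a$end[!fam_rows],
                        strand = a$strand[!fam_rows])
    cls[!fam_rows] <- annotate_genomic_fragment(frags, index, rmsk, merged)
  }
  route <- ifelse(fam_rows, "canonical", "divergent")
  tab <- table(cls)
  canon <- table(cls[route == "canonical"])
  dive <- table(cls[route == "divergent"])
  classes <- sort(names(tab))
  counts <- data.frame(
    class = classes,
    count = as.integer(tab[classes]),
    canonical = as.integer(ifelse(is.na(canon[classes]), 0L, canon[classes])),
    divergent = as.integer(ifelse(is.na(dive[classes]), 0L, dive[classes])),
    stringsAsFactors = FALSE)
  list(counts = counts, total = nrow(a))
}
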