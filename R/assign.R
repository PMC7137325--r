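#' Resolve read-pair assignments across family and genomic mappings
#'
#' Implements the family-aware assignment rules for a full sample:
#' \enumerate{
#'   \item Per pair, only mappings achieving the minimum pair score (sum
#'     of both mates' mismatch and gap penalties) are kept.
#'   \item If the minimum-score mappings span more than one family, the
#'     pair is discarded (`multi_family`). Reverse-strand mappings count
#'     toward the family's antisense counterpart unless the family is
#'     strand-merged.
#'   \item Otherwise the pair is assigned via the highest-priority
#'     (lowest rank, then lexicographically smallest) transcript.
#'   \item A unique genomic mapping replaces the family assignment only
#'     when it beats the family pair score by strictly more than
#'     `genomic_preference_margin` (default 24); otherwise the family
#'     assignment is kept. Pairs with only one mapping kind keep it.
#' }
#'
#' @param aln alignment table (all mappings of all pairs; see
#'   [alignment-tables]).
#' @param db a [family_db].
#' @param params a [scoring_params].
#' @return assignment data.frame: one row per read pair with columns
#'   `read_id`, `umi`, `kind` (`family`/`genome`), `assigned_class`
#'   (family id, or `NA` for genomic pairs, classified later),
#'   `target_id`, `start`, `end`, `strand`, `pair_score`,
#'   `discard_reason` (`none`, `multi_family`).
#' @export
assign_read_pairs <- function(aln, db, params = scoring_params()) {
  if (nrow(aln) == 0L) stop("empty mapping list")
  validate_alignments(aln)
  pen <- score_rows(aln, params)

  fam <- collapse_pairs(aln, pen, aln$target_kind == "family_transcript")
  gen <- collapse_pairs(aln, pen,
                        aln$target_kind == "genome" & aln$is_unique_genomic)

  fam_res <- if (nrow(fam)) resolve_family_table(fam, db) else NULL

  ids <- union(if (!is.null(fam_res)) fam_res$read_id else character(0),
               gen$read_id)
  fi <- if (!is.null(fam_res)) match(ids, fam_res$read_id) else rep(NA_integer_, length(ids))
  gi <- match(ids, gen$read_id)

  out <- data.frame(read_id = ids, umi = umi_of(ids),
                    kind = NA_character_, assigned_class = NA_character_,
                    target_id = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    pair_score = NA_integer_, discard_reason = "none",
                    stringsAsFactors = FALSE)
  has_f <- !is.na(fi)
  has_g <- !is.na(gi)
  f_discard <- has_f
  f_discard[has_f] <- fam_res$multi_family[fi[has_f]]
  fam_score <- rep(NA_integer_, length(ids))
  if (any(has_f)) fam_score[has_f] <- fam_res$pair_score[fi[has_f]]
  gen_score <- rep(NA_integer_, length(ids))
  gen_score[has_g] <- gen$pair_score[gi[has_g]]
  ## genomic wins only with a strictly better score by > margin; pairs
  ## discarded as multi-family are not rescued by a genomic mapping
  margin_ok <- has_f & has_g & !f_discard &
    (fam_score - gen_score > params$genomic_preference_margin)
  use_gen <- has_g & (!has_f | margin_ok)
  use_fam <- has_f & !f_discard & !use_gen

  set <- function(cols, idx, src, sidx) {
    for (cl in names(cols)) out[[cl]][idx] <<- src[[cols[[cl]]]][sidx]
  }
  if (any(use_fam))
    set(list(target_id = "target_id", start = "start", end = "end",
             strand = "strand", pair_score = "pair_score",
             assigned_class = "assigned_class"),
        which(use_fam), fam_res, fi[use_fam])
  out$kind[use_fam] <- "family"
  if (any(use_gen))
    set(list(target_id = "target_id", start = "start", end = "end",
             strand = "strand", pair_score = "pair_score"),
        which(use_gen), gen, gi[use_gen])
  out$kind[use_gen] <- "genome"
  out$discard_reason[f_discard & !use_gen] <- "multi_family"
  out[order(out$read_id), , drop = FALSE]
}

## collapse mate-level rows to one row per (read pair, target):
## pair score = sum of mate penalties, span = min start .. max end
collapse_pairs <- function(aln, pen, sel) {
  a <- aln[sel, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(read_id = character(0), target_id = character(0),
                      strand = character(0), pair_score = integer(0),
                      start = integer(0), end = integer(0)))
  p <- pen[sel]
  key <- paste(a$read_id, a$target_id, sep = "\r")
  sc <- rowsum(p, key)
  o1 <- order(key, a$start)
  first <- o1[!duplicated(key[o1])]
  o2 <- order(key, -a$end)
  last <- o2[!duplicated(key[o2])]
  k1 <- key[first]
  data.frame(read_id = a$read_id[first], target_id = a$target_id[first],
             strand = a$strand[first],
             pair_score = as.integer(sc[match(k1, rownames(sc)), 1L]),
             start = a$start[first],
             end = a$end[last][match(k1, key[last])],
             stringsAsFactors = FALSE)
}

## family-level resolution on (pair, transcript) rows
resolve_family_table <- function(fam, db) {
  m <- match(fam$target_id, db$members$transcript_id)
  if (anyNA(m))
    stop("alignment targets not in family database: ",
         paste(head(unique(fam$target_id[is.na(m)])), collapse = ", "))
  base_fam <- db$members$family_id[m]
  priority <- db$members$priority[m]
  adj_fam <- ifelse(fam$strand == "-" & !(base_fam %in% db$merged),
                    antisense_family(base_fam), base_fam)
  ## keep only minimum-score mappings per pair
  o <- order(fam$read_id, fam$pair_score, priority, fam$target_id)
  f <- fam[o, , drop = FALSE]
  adj <- adj_fam[o]
  best <- f$pair_score[!duplicated(f$read_id)][
    match(f$read_id, unique(f$read_id))]
  is_min <- f$pair_score == best
  fm <- f[is_min, , drop = FALSE]
  adjm <- adj[is_min]
  ## multi-family: >1 distinct adjusted family among the minima
  ufk <- !duplicated(paste(fm$read_id, adjm, sep = "\r"))
  nfam <- rowsum(rep(1L, sum(ufk)), fm$read_id[ufk])
  multi <- nfam[, 1L] > 1L
  ## assignment = first minimum row (already ordered by priority, id)
  pick <- !duplicated(fm$read_id)
  res <- fm[pick, , drop = FALSE]
  res$assigned_class <- adjm[pick]
  res$multi_family <- multi[match(res$read_id, rownames(nfam))]
  res
}

umi_of <- function(read_id) {
  has <- grepl(":", read_id, fixed = TRUE)
  out <- rep(NA_character_, length(read_id))
  out[has] <- sub(".*:", "", read_id[has])
  out
}

#' Remove PCR duplicates
#'
#' Read pairs sharing mapping target, start and stop position and UMI are
#' PCR duplicates: all but one (the lexicographically smallest read id)
#' are marked `pcr_duplicate`. Idempotent. Pairs already discarded are
#' left untouched and do not shield duplicates.
#'
#' @param assignments assignment table from [assign_read_pairs].
#' @return the table with `discard_reason` updated.
#' @export
deduplicate_pairs <- function(assignments) {
  if (nrow(assignments) == 0L) return(assignments)
  live <- which(assignments$discard_reason == "none")
  if (!length(live)) return(assignments)
  a <- assignments[live, , drop = FALSE]
  if (anyNA(a$umi)) stop("missing UMI (no ':' separator in read id)")
  key <- paste(a$target_id, a$start, a$end, a$umi, sep = "\r")
  o <- order(key, a$read_id)
  dup <- duplicated(key[o])
  assignments$discard_reason[live[o][dup]] <- "pcr_duplicate"
  assignments
}
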