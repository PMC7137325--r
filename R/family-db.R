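#' Multicopy RNA element family database
#'
#' A family groups homologous reference transcripts (e.g. all 18S rRNA
#' copies and pseudogenes). Within a family each transcript carries a
#' priority rank; rank 1 is the primary transcript, pseudogenes rank
#' lower. Mapping to the reverse strand of a family member is counted as
#' a separate "antisense" family, except for families listed in `merged`
#' (simple repeats), which are counted strand-insensitively.
#'
#' @param members data.frame with columns `family_id`, `transcript_id`,
#'   `priority` (1 = primary; unique within a family).
#' @param merged character vector of strand-insensitive family ids.
#' @param sequences optional named [Biostrings::DNAStringSet] of member
#'   sequences.
#' @return object of class `family_db`.
#' @export
family_db <- function(members, merged = character(0), sequences = NULL) {
  stopifnot(all(c("family_id", "transcript_id", "priority") %in% names(members)))
  if (anyDuplicated(members$transcript_id))
    stop("each transcript must belong to exactly one family")
  for (f in unique(members$family_id)) {
    pr <- members$priority[members$family_id == f]
    if (anyDuplicated(pr)) stop("duplicate priority rank in family ", f)
  }
  structure(list(members = members, merged = merged, sequences = sequences),
            class = "family_db")
}

#' @export
print.family_db <- function(x, ...) {
  cat("family_db:", length(unique(x$members$family_id)), "families,",
      nrow(x$members), "transcripts",
      if (length(x$merged)) paste0(" (", length(x$merged),
                                   " strand-merged)") else "", "\n")
  invisible(x)
}

#' Antisense counterpart of a family id
#' @param family_id character vector.
#' @return character vector with the `antisense_` prefix applied.
#' @export
antisense_family <- function(family_id) paste0("antisense_", family_id)

#' Read/write the family membership table (family_id, transcript_id, priority)
#' @param path TSV path.
#' @param merged character vector of strand-insensitive families.
#' @return a [family_db].
#' @export
read_family_db <- function(path, merged = character(0)) {
  family_db(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE), merged = merged)
}

#' @rdname read_family_db
#' @param db a [family_db].
#' @export
write_family_db <- function(db, path) {
  write_table(db$members, path,
              schema = c("family_id", "transcript_id", "priority"),
              key = "transcript_id")
}
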