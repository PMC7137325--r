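#' Alignment tables
#'
#' The pipeline consumes alignment records as a plain tab-delimited table,
#' one row per reported mapping of one mate: columns `read_id`, `mate`
#' (1/2), `target_id`, `target_kind` (`family_transcript` or `genome`),
#' `start`, `end` (0-based half-open on the target), `strand` (fragment
#' strand on the target), `mismatches` (comma-separated `offset:Q` pairs,
#' `.` for none; Q is the Phred quality of the read base, 0..41), `gaps`
#' (comma-separated gap lengths, `.` for none) and `is_unique_genomic`
#' (0/1). UMIs ride in the read id after the final `:` (eCLIP places them
#' in read names after preprocessing). All mappings of a multi-mapped pair
#' appear as separate rows.
#'
#' @name alignment-tables
NULL

ALN_COLS <- c("read_id", "mate", "target_id", "target_kind", "start", "end",
              "strand", "mismatches", "gaps", "is_unique_genomic")

#' Read alignments from the tabular dialect or a SAM file
#'
#' SAM records must carry an MD tag and base qualities so that mismatch
#' positions and qualities can be reconstructed; otherwise the reader
#' errors and instructs use of the tabular dialect. Unmapped records are
#' skipped (counted in a message). SAM POS (1-based) is converted to the
#' 0-based half-open convention.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"table"` or `"sam"`.
#' @return data.frame of alignment records (see [alignment-tables]).
#' @export
read_alignments <- function(path, format = c("auto", "table", "sam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$|\\.bam$", path, ignore.case = TRUE)) "sam" else "table"
  if (format == "table") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c(read_id = "character", mate = "integer",
                                    target_id = "character", target_kind = "character",
                                    start = "integer", end = "integer",
                                    strand = "character", mismatches = "character",
                                    gaps = "character", is_unique_genomic = "integer"),
                     stringsAsFactors = FALSE)
    if (!all(ALN_COLS %in% names(df)))
      stop("alignment table missing columns: ",
           paste(setdiff(ALN_COLS, names(df)), collapse = ", "))
    df$is_unique_genomic <- df$is_unique_genomic != 0L
    validate_alignments(df)
    return(df)
  }
  read_alignments_sam(path)
}

validate_alignments <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  stopifnot(all(df$start < df$end), all(df$mate %in% c(1L, 2L)),
            all(df$strand %in% c("+", "-")),
            all(df$target_kind %in% c("family_transcript", "genome")))
  qs <- unlist(lapply(parse_mismatches(df$mismatches), `[[`, "q"))
  if (length(qs) && (any(qs < 0) || any(qs > 41)))
    stop("mismatch quality outside 0..41")
  gl <- unlist(parse_gaps(df$gaps))
  if (length(gl) && any(gl < 1)) stop("gap length must be >= 1")
  invisible(df)
}

## "12:40,30:20" -> list(offset=..., q=...); "." -> empty
parse_mismatches <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == ".", "", x), ","), function(p) {
    p <- p[nzchar(p)]
    if (!length(p)) return(list(offset = integer(0), q = integer(0)))
    m <- do.call(rbind, strsplit(p, ":", fixed = TRUE))
    list(offset = as.integer(m[, 1L]), q = as.integer(m[, 2L]))
  })
}

parse_gaps <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == ".", "", x), ","), function(p)
    as.integer(p[nzchar(p)]))
}

format_mismatches <- function(offsets, qs) {
  if (!length(offsets)) return(".")
  paste(sprintf("%d:%d", offsets, qs), collapse = ",")
}

#' Write an alignment table
#' @param df alignment data.frame.
#' @param path output file.
#' @export
write_alignments <- function(df, path) {
  out <- df[ALN_COLS]
  out$is_unique_genomic <- as.integer(out$is_unique_genomic)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## SAM reader: mismatches from MD + QUAL, gaps from CIGAR (I/D runs).
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM/BAM input requires the Rsamtools package; ",
         "alternatively provide the tabular alignment dialect")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qual"),
    tag = "MD")
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  mapped <- !is.na(b$pos)
  n_skip <- sum(!mapped)
  if (n_skip) message(n_skip, " unmapped record(s) skipped")
  if (!sum(mapped))
    return(stats::setNames(data.frame(matrix(ncol = length(ALN_COLS), nrow = 0)),
                           ALN_COLS))
  md <- b$tag$MD[mapped]
  if (is.null(md) || any(is.na(md)))
    stop("SAM records lack MD tags (mismatch information); ",
         "use the tabular alignment dialect instead")
  flag <- b$flag[mapped]
  cig <- b$cigar[mapped]
  qual <- as.character(b$qual[mapped])
  recs <- lapply(seq_along(cig), function(i) {
    mm <- md_to_mismatches(md[i], cig[i], qual[i])
    gaps <- cigar_gaps(cig[i])
    list(mm = mm, gaps = gaps)
  })
  ref_len <- vapply(cig, cigar_ref_len, integer(1), USE.NAMES = FALSE)
  data.frame(
    read_id = b$qname[mapped],
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    target_id = as.character(b$rname[mapped]),
    target_kind = "genome",
    start = b$pos[mapped] - 1L,
    end = b$pos[mapped] - 1L + ref_len,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mismatches = vapply(recs, function(r)
      format_mismatches(r$mm$offset, r$mm$q), character(1)),
    gaps = vapply(recs, function(r)
      if (length(r$gaps)) paste(r$gaps, collapse = ",") else ".", character(1)),
    is_unique_genomic = bitwAnd(flag, 256L) == 0L,
    stringsAsFactors = FALSE)
}

cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  list(len = len, op = op)
}

cigar_gaps <- function(cigar) {
  co <- cigar_ops(cigar)
  co$len[co$op %in% c("I", "D", "N")]
}

cigar_ref_len <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
}

## MD tag walk: offsets of substituted bases within the read (0-based),
## qualities looked up in the read QUAL string. Insertions (not in MD)
## are accounted for via the CIGAR when translating to read offsets.
md_to_mismatches <- function(md, cigar, qual) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  ref_off <- 0L
  mm_ref <- integer(0)
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) ref_off <- ref_off + as.integer(tk)
    else if (startsWith(tk, "^")) ref_off <- ref_off + nchar(tk) - 1L
    else { mm_ref <- c(mm_ref, ref_off); ref_off <- ref_off + 1L }
  }
  if (!length(mm_ref))
    return(list(offset = integer(0), q = integer(0)))
  ## map aligned-reference offsets (excluding deletions) to read offsets
  co <- cigar_ops(cigar)
  read_off <- integer(0)
  r <- 0L; q <- 0L  # r: ref-matched offset consumed (M/=/X), q: read offset
  for (i in seq_along(co$op)) {
    op <- co$op[i]; L <- co$len[i]
    if (op %in% c("M", "=", "X")) {
      sel <- mm_ref >= r & mm_ref < r + L
      read_off <- c(read_off, q + (mm_ref[sel] - r))
      r <- r + L; q <- q + L
    } else if (op %in% c("I", "S")) q <- q + L
    else if (op == "D") r <- r + L  # MD walks through deleted reference bases
  }
  qs <- utf8ToInt(qual)[read_off + 1L] - 33L
  list(offset = read_off, q = qs)
}
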