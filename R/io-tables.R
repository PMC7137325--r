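#' Write a result table deterministically
#'
#' Tab-delimited with header; rows sorted by the primary key so repeated
#' runs are byte-identical. The primary key must be unique.
#'
#' @param rows data.frame.
#' @param path output file.
#' @param schema expected column names, in order.
#' @param key primary-key column (default: first schema column).
#' @export
write_table <- function(rows, path, schema = names(rows), key = schema[1L]) {
  if (!identical(sort(names(rows)), sort(schema)))
    stop("schema mismatch: expected {", paste(schema, collapse = ", "),
         "}, got {", paste(names(rows), collapse = ", "), "}")
  rows <- rows[schema]
  if (anyDuplicated(rows[[key]]))
    stop("duplicate primary key in column ", key)
  rows <- rows[order(rows[[key]]), , drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table]
#' @param path file path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
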