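#' Read a key-value metadata table
#'
#' Reads a delimited table of key-value metadata (record identifier, key,
#' value), e.g. GEO Sample characteristics exported as TSV or CSV. Columns are
#' located by name in the header, falling back to the first three columns when
#' the named ones are absent. Rows whose key is empty after trimming are not
#' silently dropped: they are collected into a rejects report attached as the
#' `"rejects"` attribute (line number and reason).
#'
#' @param path path to a delimited text file (UTF-8).
#' @param sep field separator; `NULL` (default) picks `","` for `.csv` files
#'   and tab otherwise.
#' @param record_col,key_col,value_col column names to use (defaults
#'   `"record_id"`, `"key"`, `"value"`).
#' @param header does the file have a header row?
#' @return data.frame of records with columns `record_id`, `key`, `value` and
#'   attribute `rejects` (data.frame with columns `line`, `reason`); retrieve
#'   it with [rejects()].
#' @export
read_key_value_table <- function(path, sep = NULL,
                                 record_col = "record_id", key_col = "key",
                                 value_col = "value", header = TRUE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- tryCatch(
    read.delim(path, sep = sep, header = header, colClasses = "character",
               quote = "\"", comment.char = "", check.names = FALSE,
               fill = TRUE, encoding = "UTF-8"),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(raw) < 3L)
    stop("'", path, "' has ", ncol(raw), " column(s); need at least 3 ",
         "(record id, key, value)")
  cols <- c(record_col, key_col, value_col)
  if (all(cols %in% names(raw))) {
    raw <- raw[cols]
  } else {
    raw <- raw[, 1:3]
  }
  names(raw) <- c("record_id", "key", "value")
  raw$value[is.na(raw$value)] <- ""
  line_no <- seq_len(nrow(raw)) + as.integer(header)
  bad <- is.na(raw$key) | !nzchar(trimws(raw$key))
  rejects <- data.frame(line = line_no[bad],
                        reason = rep("empty key", sum(bad)),
                        stringsAsFactors = FALSE)
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Rejected rows of the last read
#' @param records result of [read_key_value_table()].
#' @return data.frame with columns `line` and `reason`.
#' @export
rejects <- function(records) {
  r <- attr(records, "rejects")
  if (is.null(r))
    r <- data.frame(line = integer(), reason = character(),
                    stringsAsFactors = FALSE)
  r
}

#' Read and write cluster assignment files
#'
#' Cluster files are two-column delimited text (key, cluster label), no header
#' by default, with `#`-prefixed comment lines ignored. A key listed under two
#' different labels is a format error, because partitions are disjoint by
#' definition. `write_cluster_file()` followed by `read_cluster_file()` is the
#' identity on partitions up to label renaming.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `read_cluster_file()` returns a [cluster_set];
#'   `write_cluster_file()` returns `path` invisibly.
#' @export
read_cluster_file <- function(path, sep = "\t") {
  lines <- tryCatch(readLines(path, encoding = "UTF-8", warn = FALSE),
                    error = function(e) stop("cannot read '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(cluster_set(list()))
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("cluster file '", path, "' has rows with fewer than 2 fields")
  key <- vapply(parts, `[[`, character(1), 1L)
  label <- vapply(parts, `[[`, character(1), 2L)
  df <- unique(data.frame(key = key, label = label, stringsAsFactors = FALSE))
  if (anyDuplicated(df$key)) {
    dup <- unique(df$key[duplicated(df$key)])
    stop("cluster file '", path, "' assigns key(s) to multiple labels: ",
         paste(dup, collapse = ", "))
  }
  as_cluster_set(df)
}

#' @param partition a [cluster_set] (or coercible).
#' @rdname read_cluster_file
#' @export
write_cluster_file <- function(partition, path, sep = "\t") {
  df <- as.data.frame(as_cluster_set(partition))
  write.table(df, path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
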