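#' Normalize a raw metadata key
#'
#' Lowercases, trims leading/trailing whitespace and collapses internal
#' whitespace runs to single spaces. Punctuation is preserved deliberately:
#' variants such as `"age (years)"`, `"age(yrs)"` and `"age_year"` differ only
#' in punctuation and separators, and that difference is signal for the
#' similarity measures rather than noise to be scrubbed.
#'
#' @param raw character vector of raw key (or value) strings.
#' @return character vector of normalized strings.
#' @examples
#' normalize_key("  Age (Years) ")  # "age (years)"
#' normalize_key("disease_state")   # unchanged
#' @export
normalize_key <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

new_key_corpus <- function(name, frequency, raw_forms, values) {
  stopifnot(length(name) == length(frequency),
            length(name) == length(raw_forms),
            length(name) == length(values))
  out <- data.frame(name = as.character(name),
                    frequency = as.integer(frequency),
                    stringsAsFactors = FALSE)
  out$raw_forms <- raw_forms
  out$values <- values
  class(out) <- c("key_corpus", "data.frame")
  validate_key_corpus(out)
}

validate_key_corpus <- function(corpus) {
  if (anyDuplicated(corpus$name))
    stop("key corpus must have unique normalized names; duplicated: ",
         paste(unique(corpus$name[duplicated(corpus$name)]), collapse = ", "))
  if (any(!nzchar(corpus$name)))
    stop("key corpus contains an empty key name")
  if (nrow(corpus) && any(corpus$frequency < 1L))
    stop("key frequencies must be >= 1")
  bad <- vapply(seq_len(nrow(corpus)), function(i) {
    !all(normalize_key(corpus$raw_forms[[i]]) == corpus$name[[i]])
  }, logical(1))
  if (any(bad))
    stop("raw forms do not normalize to their key name: ",
         paste(corpus$name[bad], collapse = ", "))
  corpus
}

#' Build a key corpus from key-value records
#'
#' Groups records by the normalized key name. Keys differing only in case or
#' whitespace are merged (their values pooled and original spellings retained
#' as `raw_forms`); keys differing in punctuation stay distinct. Each record
#' contributes one observation to the key's value multiset, so repeated
#' (record, key) pairs are kept as separate observations.
#'
#' @param records data.frame with columns `record_id`, `key`, `value`, e.g.
#'   from [read_key_value_table()].
#' @return a `key_corpus`: a data.frame with one row per distinct normalized
#'   key and columns `name`, `frequency`, plus list columns `raw_forms`
#'   (distinct original spellings) and `values` (named integer vector of value
#'   counts, most frequent first).
#' @seealso [select_category()], [corpus_records()]
#' @examples
#' recs <- data.frame(record_id = c("s1", "s2"), key = c("Age", "age"),
#'                    value = c("3", "5"))
#' aggregate_keys(recs)
#' @export
aggregate_keys <- function(records) {
  records <- as_kv_records(records)
  if (nrow(records) == 0L)
    return(new_key_corpus(character(), integer(), list(), list()))
  norm <- normalize_key(records$key)
  idx <- split(seq_len(nrow(records)), norm)
  nms <- names(idx)
  raw_forms <- lapply(idx, function(i) sort(unique(records$key[i])))
  values <- lapply(idx, function(i) value_counts(records$value[i]))
  freq <- vapply(idx, length, integer(1))
  new_key_corpus(nms, freq, unname(raw_forms), unname(values))
}

# value multiset as named counts, ordered most frequent first with
# alphabetical tie-break so downstream capping is deterministic
value_counts <- function(v) {
  v <- as.character(v)
  if (length(v) == 0L) return(setNames(integer(), character()))
  tab <- table(v)
  cnt <- as.integer(tab)
  nm <- names(tab)
  ord <- order(-cnt, nm)
  setNames(cnt[ord], nm[ord])
}

as_kv_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("record_id", "key", "value")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  records[need] <- lapply(records[need], as.character)
  records
}

#' Reconstruct key-value records from a corpus
#'
#' Inverse of [aggregate_keys()] up to record identifiers: emits one record
#' per value observation, cycling through the key's raw spellings so that
#' re-aggregating reproduces the corpus exactly.
#'
#' @param corpus a `key_corpus`.
#' @return data.frame with columns `record_id`, `key`, `value`.
#' @export
corpus_records <- function(corpus) {
  stopifnot(inherits(corpus, "key_corpus"))
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    vals <- corpus$values[[i]]
    v <- rep(names(vals), times = vals)
    n <- corpus$frequency[[i]]
    if (length(v) < n) v <- c(v, rep("", n - length(v)))
    raw <- corpus$raw_forms[[i]]
    data.frame(key = rep_len(raw, n), value = v[seq_len(n)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(record_id = character(), key = character(),
                      value = character(), stringsAsFactors = FALSE))
  data.frame(record_id = sprintf("r%d", seq_len(nrow(out))),
             key = out$key, value = out$value, stringsAsFactors = FALSE)
}

#' Select a key category by regular expression
#'
#' Restricts a corpus to the keys whose normalized name matches `pattern`
#' (case-insensitive, unanchored), mirroring the practice of carving a large
#' key inventory into per-category chunks ("age", "strain", ...) before
#' clustering each chunk separately.
#'
#' @param corpus a `key_corpus`.
#' @param pattern a regular expression.
#' @return the sub-corpus of matching keys.
#' @examples
#' recs <- data.frame(record_id = "s", key = c("age (yrs)", "patient age",
#'                    "gender"), value = "")
#' select_category(aggregate_keys(recs), "age")
#' @export
select_category <- function(corpus, pattern) {
  stopifnot(inherits(corpus, "key_corpus"))
  keep <- tryCatch(grepl(pattern, corpus$name, ignore.case = TRUE, perl = TRUE),
                   error = function(e)
                     stop("invalid regular expression '", pattern, "': ",
                          conditionMessage(e), call. = FALSE),
                   warning = function(w)
                     stop("invalid regular expression '", pattern, "'",
                          call. = FALSE))
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("key_corpus", "data.frame")
  out
}

#' @export
print.key_corpus <- function(x, ...) {
  cat(sprintf("key_corpus with %d keys (%d key-value observations)\n",
              nrow(x), sum(x$frequency)))
  if (nrow(x)) {
    shown <- head(x$name, 10L)
    cat("  ", paste(shown, collapse = ", "),
        if (nrow(x) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}
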