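#' Extract the core concept of a key name
#'
#' The core concept is the most informative part of a key name: the first verb
#' longer than four characters or, failing that, the first noun together with
#' an immediately preceding adjective. For example the core concept of
#' `"tissue isolated"` is `"isolated"` and that of `"primary tissue"` is
#' `"primary tissue"`. When the name contains neither such a verb nor a noun
#' (or the tagger fails), the full normalized name is used as a fallback head
#' so that every key still yields a usable concept. The head is then expanded
#' with synonyms from an offline dictionary.
#'
#' @param name a single key name.
#' @param tagger a tagger function as returned by [default_tagger()].
#' @param synonyms a `synonym_dict` from [load_synonyms()], or `NULL` to skip
#'   expansion.
#' @return a `core_concept`: list with elements `head` (string) and
#'   `synonyms` (character vector containing `head`).
#' @examples
#' extract_core_concept("tissue isolated")$head  # "isolated"
#' extract_core_concept("age")$head              # "age"
#' @export
extract_core_concept <- function(name, tagger = default_tagger(),
                                 synonyms = NULL) {
  norm <- normalize_key(name)
  toks <- tokenize_key(norm)
  tags <- tryCatch(tagger(toks), error = function(e) {
    message("tagger failed on '", name, "' (", conditionMessage(e),
            "); falling back to full name")
    NULL
  })
  head_str <- NULL
  if (!is.null(tags) && length(tags) == length(toks)) {
    verbs <- which(tags == "verb" & nchar(toks) > 4L)
    if (length(verbs)) {
      head_str <- toks[verbs[1L]]
    } else {
      nouns <- which(tags == "noun")
      if (length(nouns)) {
        i <- nouns[1L]
        head_str <- if (i > 1L && tags[i - 1L] == "adjective")
          paste(toks[i - 1L], toks[i]) else toks[i]
      }
    }
  }
  if (is.null(head_str) || !nzchar(head_str)) head_str <- norm
  syns <- sort(unique(c(head_str, synonym_lookup(synonyms, head_str))))
  structure(list(head = head_str, synonyms = syns), class = "core_concept")
}

#' Core-concept similarity
#'
#' Maximum Jaro-Winkler similarity over the cross product of the two
#' synonym-expanded concept sets. Two concepts sharing any term (including
#' via a shared synonym) score exactly 1; an empty synonym set scores 0
#' against anything.
#'
#' @param a,b `core_concept` objects from [extract_core_concept()].
#' @return similarity in \[0, 1\].
#' @export
core_similarity <- function(a, b) {
  stopifnot(inherits(a, "core_concept"), inherits(b, "core_concept"))
  jw_max_cross(a$synonyms, b$synonyms)
}
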