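#' Tokenize a key name
#'
#' Splits on whitespace and punctuation; punctuation characters are kept as
#' their own tokens (they are tagged `"other"` downstream and never selected
#' as a core concept).
#'
#' @param name a single key name.
#' @return character vector of tokens.
#' @export
tokenize_key <- function(name) {
  stopifnot(length(name) == 1L)
  x <- normalize_key(name)
  # pad punctuation with spaces so each mark becomes its own token
  x <- gsub("([[:punct:]])", " \\1 ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

# small closed lexicons; everything alphabetic and unknown defaults to noun,
# which is the right prior for metadata key vocabulary
.adjective_lexicon <- c(
  "primary", "parental", "original", "clinical", "pathological", "viral",
  "bacterial", "maternal", "paternal", "experimental", "gestational",
  "developmental", "advanced", "secondary", "healthy", "normal", "tumoral",
  "insect", "human", "dendritic"
)

# context/classifier tokens: noun adjuncts ("patient age") and generic
# classifiers ("disease status") that modify a concept without carrying it;
# tagged "other" so core-concept extraction skips past them to the head noun
.context_lexicon <- c(
  "patient", "sample", "donor", "host", "subject", "source",
  "type", "status", "group", "state", "unit", "category", "id", "name",
  "number", "info", "information"
)

.verb_lexicon <- c(
  "is", "was", "are", "has", "have", "use", "used", "obtained", "derived",
  "isolated", "harvested", "collected", "extracted", "treated", "injected",
  "infected", "exposed", "measured", "sampled", "grown", "cultured"
)

#' Lexicon-based part-of-speech tagger
#'
#' Returns a deterministic, dependency-free tagger suitable for short
#' metadata key names. Tokens are tagged with one of `"verb"`, `"noun"`,
#' `"adjective"` or `"other"`: non-alphabetic tokens are `"other"`, as are
#' generic context and classifier tokens ("patient", "sample", "status",
#' "type", ...) that modify a concept without carrying it; a small
#' adjective lexicon is checked first; verbs are recognized from a lexicon
#' plus the regular `-ed`/`-ing` suffixes; every remaining alphabetic token is
#' a noun, the dominant class in this vocabulary. Any function with the same
#' signature (character vector of tokens in, equal-length character vector of
#' tags out) can be injected in its place, e.g. an adapter for a full NLP
#' tagger.
#'
#' @return a tagger function: `function(tokens) tags`.
#' @examples
#' tag <- default_tagger()
#' tag(c("tissue", "isolated"))   # "noun" "verb"
#' @export
default_tagger <- function() {
  function(tokens) {
    vapply(tokens, function(tok) {
      if (!grepl("^[[:alpha:]]+$", tok)) return("other")
      if (tok %in% .context_lexicon) return("other")
      if (tok %in% .adjective_lexicon) return("adjective")
      if (tok %in% .verb_lexicon) return("verb")
      if (nchar(tok) > 4L && grepl("(ed|ing)$", tok)) return("verb")
      "noun"
    }, character(1), USE.NAMES = FALSE)
  }
}
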