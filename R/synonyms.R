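#' Load an offline synonym dictionary
#'
#' Reads a JSON object mapping a term to a list of synonyms, lowercases all
#' entries and applies the symmetric closure (if `a` lists `b`, then `b` also
#' lists `a`). A pinned local table keeps core-concept expansion fully
#' deterministic and reproducible, in contrast to querying an online
#' thesaurus.
#'
#' @param path path to a JSON file; the default loads the dictionary shipped
#'   with the package, which covers common metadata-key vocabulary (month/date,
#'   disease/illness, gender/sex, treatment/therapy, ...).
#' @return a `synonym_dict`: a named list of character vectors.
#' @export
load_synonyms <- function(path = system.file("extdata", "synonyms.json",
                                             package = "cutcluster")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)))
    stop("synonym file must be a JSON object mapping term -> [synonyms]")
  dict <- list()
  add <- function(term, syns) {
    term <- normalize_key(term)
    syns <- setdiff(normalize_key(as.character(syns)), "")
    dict[[term]] <<- sort(unique(c(dict[[term]], syns)))
  }
  for (term in names(raw)) {
    syns <- raw[[term]]
    add(term, syns)
    for (s in syns) add(s, term)   # symmetric closure
  }
  structure(dict, class = "synonym_dict")
}

#' Look up synonyms for a term
#'
#' @param dict a `synonym_dict` from [load_synonyms()], or `NULL` for no
#'   expansion.
#' @param term a single term (matched case-insensitively).
#' @return character vector of synonyms (possibly empty), excluding `term`
#'   itself.
#' @export
synonym_lookup <- function(dict, term) {
  if (is.null(dict)) return(character())
  stopifnot(inherits(dict, "synonym_dict"))
  syns <- dict[[normalize_key(term)]]
  if (is.null(syns)) character() else syns
}
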