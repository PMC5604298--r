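#' Seed concepts for the synthetic corpus generator
#'
#' Six concept families mirroring the most frequent sample-characteristics
#' categories in gene-expression repository metadata: age, cell line, disease,
#' strain, tissue and treatment. Each concept carries a canonical key name, a
#' synonym set used for synonym-substitution variants, and a value sampler:
#' `"numeric_unit"` concepts draw numbers with unit suffixes (ages), `"terms"`
#' concepts draw from a fixed term list (diseases, tissues, ...).
#'
#' @return list of concept definitions usable as the `concepts` field of
#'   [generator_config()].
#' @export
default_concepts <- function() {
  list(
    list(name = "age", synonyms = c("age"),
         value_kind = "numeric_unit", range = c(1, 90),
         units = c("years", "yrs", "months", "weeks")),
    list(name = "cell line", synonyms = c("cell line"),
         value_kind = "terms",
         terms = c("mcf-7", "hek293t", "k562", "ht-29", "u937")),
    list(name = "disease", synonyms = c("disease", "illness"),
         value_kind = "terms",
         terms = c("asthma", "cystic fibrosis", "multiple myeloma",
                   "type 2 diabetes", "influenza")),
    list(name = "strain", synonyms = c("strain"),
         value_kind = "terms",
         terms = c("balb/cj", "dba/2j", "fvb/nj", "cba/j", "akr/j")),
    list(name = "tissue", synonyms = c("tissue", "organ"),
         value_kind = "terms",
         terms = c("kidney", "lung", "hippocampus", "whole blood",
                   "jejunum")),
    list(name = "treatment", synonyms = c("treatment", "therapy"),
         value_kind = "terms",
         terms = c("dmso 0.1%", "tamoxifen 10 um", "doxorubicin 1 um",
                   "rapamycin 20 nm", "egf 50 ng/ml"))
  )
}

#' Configuration of the synthetic messy-metadata generator
#'
#' Defines the heterogeneity profile of a generated corpus. Each concept
#' yields its canonical key plus `variants_per_concept` perturbed variants;
#' the perturbation operators and their application probabilities emulate the
#' patterns documented in real repository metadata: character typos
#' (`typo_rate`), unit parentheticals such as "(years)" or "(yrs)"
#' (`unit_suffix_rate`, numeric concepts only), separator swaps between
#' space, underscore, slash and removal (`separator_swap_rate`), prefix or
#' suffix context tokens such as "patient" or "status" (`affix_rate`),
#' substitution of a concept synonym such as illness for disease
#' (`synonym_rate`), and compound keys joining two concepts, e.g. "age/sex"
#' (`compound_rate`).
#'
#' @param concepts list of concept definitions; see [default_concepts()].
#' @param variants_per_concept perturbed variants per concept (default 10).
#' @param typo_rate,unit_suffix_rate,separator_swap_rate,affix_rate,synonym_rate,compound_rate
#'   per-variant application probabilities, each in \[0, 1\].
#' @param values_per_key value observations drawn per key (default 3).
#' @param seed integer seed; the generator is fully reproducible from it, and
#'   each concept uses its own derived substream so adding a concept does not
#'   alter the output for existing ones.
#' @return a `generator_config`.
#' @export
generator_config <- function(concepts = default_concepts(),
                             variants_per_concept = 10L,
                             typo_rate = 0.1,
                             unit_suffix_rate = 0.3,
                             separator_swap_rate = 0.3,
                             affix_rate = 0.15,
                             synonym_rate = 0.1,
                             compound_rate = 0.05,
                             values_per_key = 3L,
                             seed = 1L) {
  rates <- c(typo_rate, unit_suffix_rate, separator_swap_rate, affix_rate,
             synonym_rate, compound_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  stopifnot(variants_per_concept >= 1L, values_per_key >= 1L,
            length(concepts) >= 1L)
  structure(list(concepts = concepts,
                 variants_per_concept = as.integer(variants_per_concept),
                 typo_rate = typo_rate, unit_suffix_rate = unit_suffix_rate,
                 separator_swap_rate = separator_swap_rate,
                 affix_rate = affix_rate, synonym_rate = synonym_rate,
                 compound_rate = compound_rate,
                 values_per_key = as.integer(values_per_key),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# run expr under a local RNG substream, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derived per-concept substream seed, kept within 32-bit integer range
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + i * 7919) %% 2147483647L
}

.unit_suffixes <- c("(years)", "(yrs)", "(y)", "(months)", "(in months)",
                    "(weeks)", "(days)")
.prefix_tokens <- c("patient", "sample", "donor", "host", "subject")
.suffix_tokens <- c("type", "status", "group", "state")

#' Apply one perturbation operator to a key name
#'
#' The operator families emulate documented real-world key heterogeneity:
#' `"typo"` applies a single character edit (adjacent swap, deletion or
#' duplication) at a random letter position; `"unit_suffix"` appends a unit
#' parenthetical such as "(yrs)"; `"separator_swap"` rewrites the token
#' separators to underscore, slash or nothing; `"affix"` adds a context
#' prefix ("patient", "donor", ...) or suffix ("status", "type", ...);
#' `"synonym"` replaces the name with a random other member of `synonyms`;
#' `"compound"` joins a second term with a slash. Randomness uses the current
#' RNG state; seed the session (or wrap in a substream) for reproducibility.
#'
#' @param name a single key name.
#' @param op one of `"typo"`, `"unit_suffix"`, `"separator_swap"`, `"affix"`,
#'   `"synonym"`, `"compound"`.
#' @param units candidate unit parentheticals for `"unit_suffix"`.
#' @param synonyms candidate replacements for `"synonym"`.
#' @param other second term for `"compound"`.
#' @return the perturbed, non-empty name.
#' @export
perturb <- function(name, op, units = .unit_suffixes, synonyms = character(),
                    other = NULL) {
  stopifnot(length(name) == 1L, nzchar(name))
  switch(op,
    typo = {
      chars <- strsplit(name, "")[[1]]
      letters_at <- which(grepl("[[:alpha:]]", chars))
      if (length(letters_at) < 2L) return(name)
      i <- sample(letters_at, 1L)
      kind <- sample(c("swap", "delete", "duplicate"), 1L)
      out <- switch(kind,
        swap = {
          j <- if (i < length(chars) && grepl("[[:alpha:]]", chars[i + 1L]))
            i + 1L else i - 1L
          tmp <- chars[i]; chars[i] <- chars[j]; chars[j] <- tmp
          paste(chars, collapse = "")
        },
        delete = paste(chars[-i], collapse = ""),
        duplicate = paste(append(chars, chars[i], after = i), collapse = ""))
      if (!nzchar(out)) name else out
    },
    unit_suffix = {
      u <- sample(units, 1L)
      if (runif(1) < 0.5) paste(name, u) else paste0(name, u)
    },
    separator_swap = {
      sep <- sample(c("_", "/", ""), 1L)
      gsub(" ", sep, name, fixed = TRUE)
    },
    affix = {
      if (runif(1) < 0.5) paste(sample(.prefix_tokens, 1L), name)
      else paste(name, sample(.suffix_tokens, 1L))
    },
    synonym = {
      alt <- setdiff(synonyms, name)
      if (length(alt) == 0L) name else sample(alt, 1L)
    },
    compound = {
      if (is.null(other) || !nzchar(other)) name
      else paste0(name, "/", other)
    },
    stop("unknown perturbation operator '", op, "'")
  )
}

sample_values <- function(concept, n) {
  switch(concept$value_kind,
    numeric_unit = {
      num <- sample(seq(concept$range[1], concept$range[2]), n, replace = TRUE)
      unit <- sample(concept$units, n, replace = TRUE)
      trimws(paste(num, unit))
    },
    terms = sample(concept$terms, n, replace = TRUE),
    stop("unknown value sampler '", concept$value_kind, "'")
  )
}

#' Generate a synthetic messy-metadata corpus with known clusters
#'
#' For each concept, emits the canonical key plus perturbed variants (see
#' [perturb()]), each carrying values drawn from the concept's sampler. The
#' reference partition groups all variants of a concept. Compound keys (e.g.
#' "age/sex") are assigned to their first concept's reference cluster — the
#' partition must stay disjoint — and additionally reported in the
#' `multi_membership` annotation, since such keys genuinely belong to more
#' than one category and are a known failure mode for any disjoint
#' clustering. Generation is fully reproducible from `config$seed`; each
#' concept draws from its own derived substream.
#'
#' @param config a [generator_config()].
#' @return list with elements `corpus` (a `key_corpus`), `reference` (a
#'   [cluster_set] over the corpus keys) and `multi_membership` (data.frame
#'   with columns `key`, `concepts`).
#' @examples
#' sim <- generate_corpus(generator_config(seed = 42))
#' sim$corpus
#' sim$reference
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  concepts <- config$concepts
  canon <- vapply(concepts, `[[`, character(1), "name")
  assigned <- character()      # key -> concept name, first writer wins
  records <- list()
  multi <- list()

  for (i in seq_along(concepts)) {
    concept <- concepts[[i]]
    res <- with_local_seed(substream_seed(config$seed, i), {
      keys <- normalize_key(concept$name)
      membership <- list()
      for (v in seq_len(config$variants_per_concept)) {
        nm <- concept$name
        extra <- concept$name
        if (runif(1) < config$synonym_rate)
          nm <- perturb(nm, "synonym", synonyms = concept$synonyms)
        if (runif(1) < config$affix_rate)
          nm <- perturb(nm, "affix")
        if (identical(concept$value_kind, "numeric_unit") &&
            runif(1) < config$unit_suffix_rate)
          nm <- perturb(nm, "unit_suffix")
        if (runif(1) < config$compound_rate) {
          other <- sample(setdiff(canon, concept$name), 1L)
          nm <- perturb(nm, "compound", other = other)
          extra <- c(concept$name, other)
        }
        if (runif(1) < config$separator_swap_rate)
          nm <- perturb(nm, "separator_swap")
        if (runif(1) < config$typo_rate)
          nm <- perturb(nm, "typo")
        nm <- normalize_key(nm)
        keys <- c(keys, nm)
        if (length(extra) > 1L) membership[[nm]] <- extra
      }
      keys <- unique(keys)
      vals <- lapply(keys, function(k) sample_values(concept,
                                                     config$values_per_key))
      list(keys = keys, vals = vals, membership = membership)
    })
    for (j in seq_along(res$keys)) {
      k <- res$keys[[j]]
      if (k %in% names(assigned)) next   # collided with an earlier concept
      assigned[k] <- concept$name
      records[[k]] <- data.frame(record_id = paste0("syn_", k,
                                                    seq_along(res$vals[[j]])),
                                 key = k, value = res$vals[[j]],
                                 stringsAsFactors = FALSE)
      mm <- res$membership[[k]]
      if (!is.null(mm))
        multi[[k]] <- data.frame(key = k,
                                 concepts = paste(mm, collapse = ";"),
                                 stringsAsFactors = FALSE)
    }
  }

  corpus <- aggregate_keys(do.call(rbind, unname(records)))
  reference <- cluster_set(split(names(assigned), unname(assigned)))
  multi_membership <- if (length(multi)) do.call(rbind, unname(multi)) else
    data.frame(key = character(), concepts = character(),
               stringsAsFactors = FALSE)
  rownames(multi_membership) <- NULL
  list(corpus = corpus, reference = reference,
       multi_membership = multi_membership)
}
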