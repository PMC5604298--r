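#' Similarity combination weights
#'
#' The overall similarity between two keys is the convex combination
#' `alpha * sim_name + beta * sim_core + gamma * sim_value`. The three weights
#' lie in \[0, 1\] and sum to 1, so the combination stays in \[0, 1\].
#'
#' @param alpha weight of the name similarity.
#' @param beta weight of the core-concept similarity.
#' @param gamma weight of the value similarity.
#' @return a `similarity_weights` object (named numeric vector).
#' @examples
#' similarity_weights(0.44, 0.01, 0.55)
#' @export
similarity_weights <- function(alpha, beta, gamma) {
  w <- c(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma))
  if (anyNA(w) || any(w < -1e-9) || any(w > 1 + 1e-9))
    stop("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(w)), ")")
  w <- pmin(pmax(w, 0), 1)
  structure(w, class = "similarity_weights")
}

#' @export
print.similarity_weights <- function(x, ...) {
  cat(sprintf("similarity weights: alpha = %.3f (name), beta = %.3f (core), gamma = %.3f (value)\n",
              x[["alpha"]], x[["beta"]], x[["gamma"]]))
  invisible(x)
}

#' Name similarity between two key names
#'
#' Jaro-Winkler similarity of the normalized lexical names.
#'
#' @param a,b key names (vectorized elementwise).
#' @return similarity in \[0, 1\].
#' @export
name_similarity <- function(a, b) {
  jaro_winkler(normalize_key(a), normalize_key(b))
}

# distinct values of a key, normalized, empty strings dropped, most frequent
# first, truncated at `cap`
top_values <- function(values, cap = 50L) {
  if (length(values) == 0L) return(character())
  if (is.null(names(values))) values <- value_counts(values)
  v <- normalize_key(names(values))
  keep <- nzchar(v)
  unique(v[keep])[seq_len(min(cap, sum(!duplicated(v[keep]))))]
}

#' Value similarity between two keys
#'
#' Maximum Jaro-Winkler similarity over all pairs of observed values of the
#' two keys. Values are normalized like key names before comparison, and each
#' key contributes at most `cap` distinct values (most frequent first) to
#' bound the quadratic comparison; `cap = Inf` compares every distinct value.
#' A key with no (non-empty) values scores 0 against anything: absence of
#' evidence is not similarity.
#'
#' @param a,b value multisets: named integer count vectors (as stored in a
#'   `key_corpus`) or plain character vectors of observations.
#' @param cap maximum distinct values per key (default 50).
#' @return similarity in \[0, 1\].
#' @examples
#' value_similarity(c("Male"), c("Male", "Female"))  # 1
#' @export
value_similarity <- function(a, b, cap = 50L) {
  jw_max_cross(top_values(a, cap), top_values(b, cap))
}

# component similarity matrices over a corpus; `which` controls what is
# computed so that zero-weight components cost nothing (in particular the
# tagger and synonym source are never touched when the core component is off)
component_matrices <- function(corpus, which = c("name", "core", "value"),
                               cap = 50L, tagger = default_tagger(),
                               synonyms = NULL) {
  stopifnot(inherits(corpus, "key_corpus"))
  n <- nrow(corpus)
  keys <- corpus$name
  out <- list()
  if ("name" %in% which) {
    m <- jw_self_matrix(keys)
    dimnames(m) <- list(keys, keys)
    out$name <- m
  }
  if ("core" %in% which) {
    concepts <- lapply(keys, extract_core_concept, tagger = tagger,
                       synonyms = synonyms)
    sets <- lapply(concepts, `[[`, "synonyms")
    m <- matrix(0, n, n, dimnames = list(keys, keys))
    for (i in seq_len(n)) {
      m[i, i] <- if (length(sets[[i]])) 1 else 0
      for (j in seq_len(i - 1L)) {
        v <- jw_max_cross(sets[[i]], sets[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
    out$core <- m
  }
  if ("value" %in% which) {
    tops <- lapply(corpus$values, top_values, cap = cap)
    m <- matrix(0, n, n, dimnames = list(keys, keys))
    for (i in seq_len(n)) {
      m[i, i] <- if (length(tops[[i]])) 1 else 0
      for (j in seq_len(i - 1L)) {
        v <- jw_max_cross(tops[[i]], tops[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
    out$value <- m
  }
  out
}

#' Combined similarity between two keys
#'
#' The weighted combination `alpha * sim_name + beta * sim_core +
#' gamma * sim_value` for a single pair of keys. Components with zero weight
#' are not computed, so with `beta = 0` the tagger and synonym dictionary are
#' never consulted. Identical keys (same name and values) score exactly 1.
#'
#' @param a,b keys: either key names (value similarity then compares empty
#'   sets) or lists with elements `name` and `values`.
#' @param weights a [similarity_weights] object.
#' @inheritParams value_similarity
#' @param tagger,synonyms core-concept extraction interfaces; see
#'   [extract_core_concept()].
#' @return similarity in \[0, 1\].
#' @export
combined_similarity <- function(a, b, weights, cap = 50L,
                                tagger = default_tagger(), synonyms = NULL) {
  if (!inherits(weights, "similarity_weights"))
    weights <- do.call(similarity_weights, as.list(unname(weights)))
  if (is.character(a)) a <- list(name = a, values = character())
  if (is.character(b)) b <- list(name = b, values = character())
  na <- normalize_key(a$name)
  nb <- normalize_key(b$name)
  if (identical(na, nb) &&
      identical(top_values(a$values, cap), top_values(b$values, cap)))
    return(1)
  s <- 0
  if (weights[["alpha"]] > 0)
    s <- s + weights[["alpha"]] * name_similarity(na, nb)
  if (weights[["beta"]] > 0) {
    ca <- extract_core_concept(na, tagger, synonyms)
    cb <- extract_core_concept(nb, tagger, synonyms)
    s <- s + weights[["beta"]] * core_similarity(ca, cb)
  }
  if (weights[["gamma"]] > 0)
    s <- s + weights[["gamma"]] * value_similarity(a$values, b$values, cap)
  min(max(s, 0), 1)
}

#' Pairwise similarity matrix over a key corpus
#'
#' Materializes the combined similarity for every unordered key pair. The
#' diagonal is 1 by reflexivity and the matrix is symmetric by construction;
#' only the `n (n - 1) / 2` distinct pairs are evaluated. Components with zero
#' weight are skipped entirely (with `beta = 0` the tagger and synonym source
#' are never invoked).
#'
#' @param corpus a `key_corpus`.
#' @inheritParams combined_similarity
#' @param keep_components also retain the three component matrices in the
#'   `"components"` attribute (needed by [similarity_table()]).
#' @return a `similarity_matrix`: symmetric numeric matrix with the key names
#'   as dimnames, entries in \[0, 1\], unit diagonal.
#' @export
similarity_matrix <- function(corpus, weights, cap = 50L,
                              tagger = default_tagger(), synonyms = NULL,
                              keep_components = FALSE) {
  stopifnot(inherits(corpus, "key_corpus"))
  if (!inherits(weights, "similarity_weights"))
    weights <- do.call(similarity_weights, as.list(unname(weights)))
  n <- nrow(corpus)
  keys <- corpus$name
  wanted <- c("name", "core", "value")[c(weights[["alpha"]] > 0,
                                         weights[["beta"]] > 0,
                                         weights[["gamma"]] > 0)]
  if (keep_components) wanted <- c("name", "core", "value")
  comp <- component_matrices(corpus, wanted, cap = cap, tagger = tagger,
                             synonyms = synonyms)
  m <- matrix(0, n, n, dimnames = list(keys, keys))
  if (!is.null(comp$name)) m <- m + weights[["alpha"]] * comp$name
  if (!is.null(comp$core) && weights[["beta"]] > 0)
    m <- m + weights[["beta"]] * comp$core
  if (!is.null(comp$value) && weights[["gamma"]] > 0)
    m <- m + weights[["gamma"]] * comp$value
  m <- pmin(pmax(m, 0), 1)
  diag(m) <- 1
  structure(m, class = c("similarity_matrix", class(matrix())),
            weights = weights,
            components = if (keep_components) comp else NULL)
}

#' Long-format similarity audit table
#'
#' One row per unordered key pair with the three component similarities and
#' the combined score; convenient for auditing why two keys were or were not
#' merged. Written as TSV when `path` is given.
#'
#' @inheritParams similarity_matrix
#' @param path optional output TSV path.
#' @return data.frame with columns `key_a`, `key_b`, `sim_name`, `sim_core`,
#'   `sim_value`, `sim_combined`.
#' @export
similarity_table <- function(corpus, weights, cap = 50L,
                             tagger = default_tagger(), synonyms = NULL,
                             path = NULL) {
  m <- similarity_matrix(corpus, weights, cap = cap, tagger = tagger,
                         synonyms = synonyms, keep_components = TRUE)
  comp <- attr(m, "components")
  keys <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(key_a = keys[idx[, 1L]], key_b = keys[idx[, 2L]],
                    sim_name = comp$name[idx], sim_core = comp$core[idx],
                    sim_value = comp$value[idx],
                    sim_combined = unclass(m)[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix over %d keys\n", nrow(x)))
  print(attr(x, "weights"))
  if (nrow(x) <= 8L) print(round(unclass(x), 3)) else {
    cat("  (use unclass() or [ to inspect entries)\n")
  }
  invisible(x)
}
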