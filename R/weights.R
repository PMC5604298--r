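#' Build labelled training pairs from a reference partition
#'
#' For every unordered pair of corpus keys, computes the three component
#' similarities (name, core concept, value) and a binary label: 1 when the
#' two keys share a cluster in the reference partition, else 0. This is the
#' training set for [fit_weights()].
#'
#' @param corpus a `key_corpus`; every key must appear in `reference`.
#' @param reference a [cluster_set] (or coercible) labelling the corpus keys.
#' @inheritParams similarity_matrix
#' @param max_pairs optional subsampling cap on the number of pairs
#'   (deterministic: pairs are kept in order); default keeps all pairs.
#' @return data.frame with columns `key_a`, `key_b`, `sim_name`, `sim_core`,
#'   `sim_value`, `label`.
#' @export
build_pair_labels <- function(corpus, reference, cap = 50L,
                              tagger = default_tagger(), synonyms = NULL,
                              max_pairs = Inf) {
  stopifnot(inherits(corpus, "key_corpus"))
  reference <- as_cluster_set(reference)
  lab <- partition_labels(reference)
  missing <- setdiff(corpus$name, names(lab))
  if (length(missing))
    stop("key(s) missing from the reference partition: ",
         paste(missing, collapse = ", "))
  comp <- component_matrices(corpus, c("name", "core", "value"), cap = cap,
                             tagger = tagger, synonyms = synonyms)
  keys <- corpus$name
  idx <- which(upper.tri(comp$name), arr.ind = TRUE)
  out <- data.frame(
    key_a = keys[idx[, 1L]], key_b = keys[idx[, 2L]],
    sim_name = comp$name[idx], sim_core = comp$core[idx],
    sim_value = comp$value[idx],
    label = as.integer(lab[keys[idx[, 1L]]] == lab[keys[idx[, 2L]]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (is.finite(max_pairs) && nrow(out) > max_pairs)
    out <- out[seq_len(max_pairs), , drop = FALSE]
  out
}

# Euclidean projection of a vector onto the probability simplex
# (sort-based algorithm; deterministic)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Fit similarity combination weights by constrained linear regression
#'
#' Regresses the binary co-cluster label on the three component similarities
#' (no intercept, matching the form of the weighted combination), takes the
#' minimum-norm least-squares solution, and projects it onto the probability
#' simplex so the result is a valid weight triple: non-negative and summing
#' to 1. The fit is fully deterministic; refitting the same pairs is
#' bit-identical.
#'
#' @param pairs a data.frame from [build_pair_labels()] (columns `sim_name`,
#'   `sim_core`, `sim_value`, `label`).
#' @return a [similarity_weights] object.
#' @export
fit_weights <- function(pairs) {
  need <- c("sim_name", "sim_core", "sim_value", "label")
  stopifnot(all(need %in% names(pairs)))
  y <- as.numeric(pairs$label)
  if (length(unique(y)) < 2L)
    stop("training pairs must contain both co-clustered (label 1) and ",
         "separated (label 0) pairs")
  X <- as.matrix(pairs[, c("sim_name", "sim_core", "sim_value")])
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  w <- project_simplex(as.numeric(beta))
  similarity_weights(w[1L], w[2L], w[3L])
}
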