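#' Precision and recall of one cluster against a reference cluster
#'
#' `cluster_precision` is the fraction of the computed cluster's keys that
#' fall in the reference cluster; `cluster_recall` is the fraction of the
#' reference cluster recovered.
#'
#' @param ci computed cluster (character vector of keys).
#' @param rj reference cluster (character vector of keys).
#' @return value in \[0, 1\].
#' @export
cluster_precision <- function(ci, rj) {
  stopifnot(length(ci) > 0L, length(rj) > 0L)
  length(intersect(ci, rj)) / length(ci)
}

#' @rdname cluster_precision
#' @export
cluster_recall <- function(ci, rj) {
  stopifnot(length(ci) > 0L, length(rj) > 0L)
  length(intersect(ci, rj)) / length(rj)
}

check_same_keys <- function(computed, reference) {
  a <- partition_keys(computed)
  b <- partition_keys(reference)
  if (!setequal(a, b))
    stop("partitions cover different key sets; symmetric difference: ",
         paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", "))
  invisible(length(a))
}

# |Ci ∩ Rj| contingency counts between two partitions
contingency <- function(computed, reference) {
  lab_c <- partition_labels(computed)
  lab_r <- partition_labels(reference)
  table(computed = lab_c[names(lab_r)], reference = unname(lab_r))
}

#' Clustering F-Score of a partition against a reference
#'
#' Each computed cluster is matched to the reference cluster maximizing the
#' harmonic mean of precision and recall; the per-cluster scores are averaged
#' weighted by cluster size. A degenerate 0/0 harmonic mean counts as 0. Note
#' the measure is not symmetric in its arguments.
#'
#' @param computed,reference [cluster_set] objects (or coercible) over the
#'   same key set.
#' @return F-Score in \[0, 1\]; 1 iff the partitions are identical.
#' @export
f_score <- function(computed, reference) {
  computed <- as_cluster_set(computed)
  reference <- as_cluster_set(reference)
  n <- check_same_keys(computed, reference)
  tab <- contingency(computed, reference)
  ci_size <- rowSums(tab)
  rj_size <- colSums(tab)
  P <- tab / ci_size
  R <- sweep(tab, 2L, rj_size, "/")
  H <- matrix(0, nrow(tab), ncol(tab))
  nz <- (P + R) > 0
  H[nz] <- 2 * P[nz] * R[nz] / (P[nz] + R[nz])
  per_cluster <- apply(H, 1L, max)
  sum(per_cluster * ci_size) / n
}

#' Normalized clustering entropy of a partition against a reference
#'
#' For each computed cluster, the entropy of the distribution of its keys
#' over the `M` reference clusters, normalized by `log M` (with
#' `0 log 0 := 0`); the per-cluster entropies are averaged weighted by
#' cluster size. 0 is best (every computed cluster pure), 1 worst (keys
#' spread evenly over all reference clusters). Requires `M >= 2`, otherwise
#' the normalization is undefined.
#'
#' @inheritParams f_score
#' @return entropy in \[0, 1\].
#' @export
cluster_entropy <- function(computed, reference) {
  computed <- as_cluster_set(computed)
  reference <- as_cluster_set(reference)
  n <- check_same_keys(computed, reference)
  M <- length(reference)
  if (M < 2L)
    stop("entropy normalization needs at least 2 reference clusters (M >= 2)")
  tab <- contingency(computed, reference)
  ci_size <- rowSums(tab)
  P <- tab / ci_size
  plogp <- ifelse(P > 0, P * log(P), 0)
  per_cluster <- -rowSums(plogp) / log(M)
  sum(per_cluster * ci_size) / n
}

#' Rand index between two partitions
#'
#' Fraction of key pairs on which the two partitions agree: pairs placed in
#' the same cluster by both (`TP`) plus pairs separated by both (`TN`), over
#' all `choose(|T|, 2)` pairs. Computed with pair-count contingency algebra;
#' requires at least two keys.
#'
#' @inheritParams f_score
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(computed, reference) {
  computed <- as_cluster_set(computed)
  reference <- as_cluster_set(reference)
  n <- check_same_keys(computed, reference)
  if (n < 2L) stop("Rand index needs at least 2 keys")
  tab <- contingency(computed, reference)
  tp <- sum(choose(tab, 2))
  same_c <- sum(choose(rowSums(tab), 2))
  same_r <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  tn <- total - same_c - same_r + tp
  (tp + tn) / total
}

#' Evaluate a computed partition against a reference
#'
#' Bundles the three partition-comparison metrics into one report.
#'
#' @inheritParams f_score
#' @return an `eval_report`: list with `f_score`, `entropy`, `rand_index`,
#'   `n_computed`, `n_reference`, `n_keys`.
#' @export
evaluate_clustering <- function(computed, reference) {
  computed <- as_cluster_set(computed)
  reference <- as_cluster_set(reference)
  structure(list(f_score = f_score(computed, reference),
                 entropy = cluster_entropy(computed, reference),
                 rand_index = rand_index(computed, reference),
                 n_computed = length(computed),
                 n_reference = length(reference),
                 n_keys = length(partition_keys(reference))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "clustering evaluation (%d computed vs %d reference clusters, %d keys)\n",
    x$n_computed, x$n_reference, x$n_keys))
  cat(sprintf("  F-Score:    %.4f  (1 best)\n", x$f_score))
  cat(sprintf("  Entropy:    %.4f  (0 best)\n", x$entropy))
  cat(sprintf("  Rand index: %.4f  (1 best)\n", x$rand_index))
  invisible(x)
}
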