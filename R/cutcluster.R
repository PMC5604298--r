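#' Cutting cost between two clusters
#'
#' The uniform criterion used for both cohesion and coupling: the sum of the
#' pairwise similarities between all (ordered) member pairs of the two
#' clusters, divided by the product of the cluster sizes. When both arguments
#' are the same cluster, the double sum runs over all ordered member pairs
#' including the diagonal, which is the reading under which a singleton's
#' cohesion is exactly 1.
#'
#' @param ci,cj character vectors of member key names.
#' @param sim a [similarity_matrix] (or any symmetric named matrix) covering
#'   all members.
#' @return mean pairwise similarity in \[0, 1\].
#' @examples
#' m <- matrix(c(1, .2, .6, .2, 1, .4, .6, .4, 1), 3,
#'             dimnames = list(c("a","b","c"), c("a","b","c")))
#' cut_cost(c("a", "b"), "c", m)  # (.6 + .4) / 2
#' @export
cut_cost <- function(ci, cj, sim) {
  ci <- as.character(ci)
  cj <- as.character(cj)
  stopifnot(length(ci) > 0L, length(cj) > 0L)
  unknown <- setdiff(c(ci, cj), rownames(sim))
  if (length(unknown))
    stop("member(s) not present in the similarity matrix: ",
         paste(unknown, collapse = ", "))
  sum(unclass(sim)[ci, cj, drop = FALSE]) / (length(ci) * length(cj))
}

#' Cohesion of a cluster
#'
#' `cut_cost(c, c, sim)`: mean pairwise similarity within the cluster,
#' diagonal included; 1 for singletons.
#'
#' @param c character vector of member key names.
#' @inheritParams cut_cost
#' @return cohesion in \[0, 1\].
#' @export
cohesion <- function(c, sim) cut_cost(c, c, sim)

#' Coupling between two distinct clusters
#'
#' `cut_cost(ci, cj, sim)` for distinct clusters; calling it with the same
#' member set is a caller bug and raises an error (use [cohesion()]).
#'
#' @inheritParams cut_cost
#' @return coupling in \[0, 1\].
#' @export
coupling <- function(ci, cj, sim) {
  if (setequal(ci, cj))
    stop("coupling() requires two distinct clusters; use cohesion()")
  cut_cost(ci, cj, sim)
}

#' Agglomerative clustering with a coupling-threshold cut
#'
#' Starts from one singleton cluster per key (cohesion 1; the coupling of two
#' singletons is their overall similarity) and repeatedly merges the selected
#' cluster pair until the selected pair's coupling falls below the threshold
#' `epsilon`, or a single cluster remains. Cohesion and coupling are
#' maintained incrementally with exact update formulas: merging clusters `s`
#' and `t` of sizes `ns`, `nt` gives
#' `cohesion(p) = (ns^2 coh_s + nt^2 coh_t + 2 ns nt coupling(s, t)) / (ns + nt)^2`
#' and `coupling(p, k) = (ns coupling(s, k) + nt coupling(t, k)) / (ns + nt)`,
#' algebraically identical to re-evaluating the cutting cost from scratch.
#'
#' Two pair-selection modes are available. `"global"` (default) merges the
#' globally maximal-coupling pair each iteration — standard average-linkage
#' agglomeration, fully determined by the criterion function and threshold.
#' `"cohesion-first"` first selects the cluster with the greatest cohesion,
#' then merges the maximal-coupling pair involving it. Ties (equal cohesion
#' or equal coupling) are broken by the lexicographically smallest cluster-id
#' pair, so results are deterministic.
#'
#' @param sim a [similarity_matrix] (or symmetric named matrix with unit
#'   diagonal).
#' @param epsilon coupling threshold in \[0, 1\]; merging continues while the
#'   selected coupling is `>= epsilon`. `epsilon = 0` merges everything into
#'   one cluster; values above the largest pairwise similarity leave every key
#'   a singleton. Default 0.5.
#' @param mode pair selection mode, `"global"` or `"cohesion-first"`.
#' @param verbose print one line per merge.
#' @return a list of class `cutcluster_fit`:
#'   \describe{
#'     \item{clusters}{a [cluster_set] with the final partition (labels
#'       `C1`, `C2`, ...)}
#'     \item{tree}{a `merge_tree`: `leaves` (key names), `merges` (data.frame
#'       with `step`, `left`, `right`, `new_id`, `coupling`, `size`), and the
#'       surviving `roots`}
#'     \item{epsilon, mode}{the parameters used}
#'   }
#' @seealso [cut_cluster()] for the end-to-end corpus interface,
#'   [merge_tree_list()] for a nested-list (JSON-ready) dendrogram.
#' @export
run_cutcluster <- function(sim, epsilon = 0.5,
                           mode = c("global", "cohesion-first"),
                           verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  keys <- rownames(sim)
  n <- length(keys)
  empty_tree <- structure(list(leaves = keys,
                               merges = data.frame(step = integer(),
                                                   left = integer(),
                                                   right = integer(),
                                                   new_id = integer(),
                                                   coupling = numeric(),
                                                   size = integer()),
                               roots = integer()),
                          class = "merge_tree")
  if (n == 0L)
    return(structure(list(clusters = cluster_set(list()), tree = empty_tree,
                          epsilon = epsilon, mode = mode),
                     class = "cutcluster_fit"))

  max_id <- 2L * n - 1L
  members <- vector("list", max_id)
  size <- integer(max_id)
  coh <- numeric(max_id)
  children <- vector("list", max_id)
  coup <- matrix(NA_real_, max_id, max_id)
  for (i in seq_len(n)) {
    members[[i]] <- keys[i]
    size[i] <- 1L
    coh[i] <- 1
  }
  if (n > 1L) coup[1:n, 1:n] <- unclass(sim)[keys, keys]
  active <- seq_len(n)
  next_id <- n + 1L
  merges <- vector("list", n - 1L)
  step <- 0L

  while (length(active) > 1L) {
    if (mode == "global") {
      sub <- coup[active, active, drop = FALSE]
      sub[lower.tri(sub, diag = TRUE)] <- -Inf
      best <- max(sub)
      if (best < epsilon) break
      cand <- which(sub == best, arr.ind = TRUE)
      ids <- cbind(active[cand[, 1L]], active[cand[, 2L]])
      ids <- t(apply(ids, 1L, sort))
      ord <- order(ids[, 1L], ids[, 2L])
      s_id <- ids[ord[1L], 1L]
      t_id <- ids[ord[1L], 2L]
    } else {
      star <- active[which(coh[active] == max(coh[active]))]
      star <- min(star)
      others <- setdiff(active, star)
      cvals <- coup[star, others]
      best <- max(cvals)
      if (best < epsilon) break
      t_other <- min(others[cvals == best])
      s_id <- min(star, t_other)
      t_id <- max(star, t_other)
    }

    p <- next_id
    next_id <- next_id + 1L
    ns <- size[s_id]; nt <- size[t_id]
    members[[p]] <- c(members[[s_id]], members[[t_id]])
    size[p] <- ns + nt
    coh[p] <- (ns^2 * coh[s_id] + nt^2 * coh[t_id] +
                 2 * ns * nt * coup[s_id, t_id]) / (ns + nt)^2
    children[[p]] <- c(s_id, t_id)
    rest <- setdiff(active, c(s_id, t_id))
    if (length(rest)) {
      newc <- (ns * coup[s_id, rest] + nt * coup[t_id, rest]) / (ns + nt)
      coup[p, rest] <- newc
      coup[rest, p] <- newc
    }
    step <- step + 1L
    merges[[step]] <- data.frame(step = step, left = s_id, right = t_id,
                                 new_id = p, coupling = coup[s_id, t_id],
                                 size = size[p])
    if (verbose)
      message(sprintf("merge %d: %d + %d -> %d (coupling %.4f, size %d)",
                      step, s_id, t_id, p, coup[s_id, t_id], size[p]))
    active <- c(rest, p)
  }

  merges <- if (step > 0L) do.call(rbind, merges[seq_len(step)]) else
    empty_tree$merges
  final <- sort(active)
  clusters <- cluster_set(setNames(members[final],
                                   sprintf("C%d", seq_along(final))))
  tree <- structure(list(leaves = keys, merges = merges, roots = final,
                         members = members[seq_len(next_id - 1L)],
                         children = children[seq_len(next_id - 1L)]),
                    class = "merge_tree")
  structure(list(clusters = clusters, tree = tree, epsilon = epsilon,
                 mode = mode),
            class = "cutcluster_fit")
}

#' Cluster a key corpus end to end
#'
#' Convenience wrapper: builds the similarity matrix for `corpus` under
#' `weights` and runs the agglomerative clustering.
#'
#' @inheritParams similarity_matrix
#' @inheritParams run_cutcluster
#' @return a `cutcluster_fit`; see [run_cutcluster()].
#' @examples
#' recs <- data.frame(record_id = "s",
#'                    key = c("age (yrs)", "age (years)", "gender"),
#'                    value = c("21", "63", "Male"))
#' fit <- cut_cluster(aggregate_keys(recs), similarity_weights(1, 0, 0))
#' fit$clusters
#' @export
cut_cluster <- function(corpus, weights, epsilon = 0.5, cap = 50L,
                        tagger = default_tagger(), synonyms = NULL,
                        mode = c("global", "cohesion-first"),
                        verbose = FALSE) {
  sim <- similarity_matrix(corpus, weights, cap = cap, tagger = tagger,
                           synonyms = synonyms)
  run_cutcluster(sim, epsilon = epsilon, mode = mode, verbose = verbose)
}

#' Merge tree as a nested list
#'
#' Converts a `merge_tree` to nested `{left, right, coupling}` lists (leaves
#' are key-name strings), one per surviving root; suitable for JSON export
#' with `jsonlite::toJSON()`.
#'
#' @param tree a `merge_tree` from [run_cutcluster()].
#' @return list of nested nodes, one per root.
#' @export
merge_tree_list <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  n_leaves <- length(tree$leaves)
  coupling_of <- setNames(tree$merges$coupling, tree$merges$new_id)
  build <- function(id) {
    if (id <= n_leaves) return(tree$leaves[id])
    ch <- tree$children[[id]]
    list(left = build(ch[1L]), right = build(ch[2L]),
         coupling = unname(coupling_of[as.character(id)]))
  }
  lapply(tree$roots, build)
}

#' @export
print.cutcluster_fit <- function(x, ...) {
  cat(sprintf("cutcluster fit (epsilon = %g, mode = %s): %d merges\n",
              x$epsilon, x$mode, nrow(x$tree$merges)))
  print(x$clusters)
  invisible(x)
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("merge_tree: %d leaves, %d merges, %d root cluster(s)\n",
              length(x$leaves), nrow(x$merges), length(x$roots)))
  invisible(x)
}
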