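#' Construct a partition of keys into clusters
#'
#' A `cluster_set` is a disjoint partition of a key set: a named list of
#' character vectors, one per cluster. Every key belongs to exactly one
#' cluster and clusters are non-empty.
#'
#' @param members named list of character vectors (cluster label -> member
#'   keys). Unnamed lists get labels `C1`, `C2`, ...
#' @return a `cluster_set`.
#' @examples
#' cluster_set(list(age = c("age", "age (yrs)"), sex = "gender"))
#' @export
cluster_set <- function(members) {
  stopifnot(is.list(members))
  members <- lapply(members, as.character)
  if (is.null(names(members)) || any(!nzchar(names(members))))
    names(members) <- sprintf("C%d", seq_along(members))
  if (anyDuplicated(names(members)))
    stop("cluster labels must be unique")
  sizes <- lengths(members)
  if (any(sizes == 0L)) stop("clusters must be non-empty")
  all_keys <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_keys)) {
    dup <- unique(all_keys[duplicated(all_keys)])
    stop("keys assigned to more than one cluster: ",
         paste(dup, collapse = ", "))
  }
  structure(members, class = "cluster_set")
}

#' Coerce to a cluster_set
#'
#' Accepts a named list of members, a data.frame with `key` and `label`
#' columns, or a named character/factor vector mapping key -> label.
#'
#' @param x object to coerce.
#' @return a `cluster_set`.
#' @export
as_cluster_set <- function(x) {
  if (inherits(x, "cluster_set")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("key", "label") %in% names(x)))
      stop("data.frame must have columns 'key' and 'label'")
    return(cluster_set(split(as.character(x$key), as.character(x$label))))
  }
  if ((is.character(x) || is.factor(x)) && !is.null(names(x)))
    return(cluster_set(split(names(x), as.character(x))))
  if (is.list(x)) return(cluster_set(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to cluster_set")
}

#' Keys covered by a partition
#' @param x a `cluster_set`.
#' @return character vector of all member keys.
#' @export
partition_keys <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  unlist(unclass(x), use.names = FALSE)
}

#' Key-to-label assignment of a partition
#' @param x a `cluster_set`.
#' @return named character vector mapping key to cluster label.
#' @export
partition_labels <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  setNames(rep(names(x), lengths(x)), partition_keys(x))
}

#' @export
as.data.frame.cluster_set <- function(x, ...) {
  lab <- partition_labels(x)
  data.frame(key = names(lab), label = unname(lab), stringsAsFactors = FALSE)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d keys\n",
              length(x), length(partition_keys(x))))
  for (lab in head(names(x), 8L)) {
    mem <- x[[lab]]
    cat(sprintf("  %s (%d): %s%s\n", lab, length(mem),
                paste(head(mem, 5L), collapse = ", "),
                if (length(mem) > 5L) ", ..." else ""))
  }
  if (length(x) > 8L) cat("  ...\n")
  invisible(x)
}
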