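# Independent oracles, deliberately written from the definitions with
# different code paths than the package (plain R, explicit loops).

# naive Jaro-Winkler straight from the definition
jw_ref <- function(a, b, p = 0.1, max_prefix = 4L) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  la <- length(sa); lb <- length(sb)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  window <- max(floor(max(la, lb) / 2) - 1, 0)
  bm <- rep(FALSE, lb)
  a_match <- integer(0)
  b_pos <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bm[j] && sa[i] == sb[j]) {
        bm[j] <- TRUE
        a_match <- c(a_match, i)
        b_pos <- c(b_pos, j)
        break
      }
    }
  }
  m <- length(a_match)
  if (m == 0) return(0)
  t <- sum(sa[a_match] != sb[sort(b_pos)]) / 2
  jaro <- (m / la + m / lb + (m - t) / m) / 3
  l <- 0
  while (l < min(max_prefix, la, lb) && sa[l + 1] == sb[l + 1]) l <- l + 1
  if (jaro > 0.7) jaro + l * p * (1 - jaro) else jaro
}

# cut cost recomputed from scratch with explicit loops
cut_ref <- function(ci, cj, sim) {
  s <- 0
  for (a in ci) for (b in cj) s <- s + sim[a, b]
  s / (length(ci) * length(cj))
}

# brute-force agglomeration: recompute every coupling from scratch each
# iteration, mirroring the package's id bookkeeping and tie-breaks
cutcluster_ref <- function(sim, epsilon) {
  keys <- rownames(sim)
  n <- length(keys)
  members <- as.list(keys)
  ids <- seq_len(n)
  next_id <- n + 1L
  repeat {
    if (length(ids) < 2L) break
    best <- -Inf; bi <- NULL
    for (x in seq_along(ids)) for (y in seq_along(ids)) {
      if (x >= y) next
      cv <- cut_ref(members[[x]], members[[y]], sim)
      pair <- sort(c(ids[x], ids[y]))
      if (cv > best ||
          (cv == best && (pair[1] < bi$pair[1] ||
                          (pair[1] == bi$pair[1] && pair[2] < bi$pair[2])))) {
        best <- cv
        bi <- list(x = x, y = y, pair = pair)
      }
    }
    if (best < epsilon) break
    xs <- which(ids == bi$pair[1])
    ys <- which(ids == bi$pair[2])
    merged <- c(members[[xs]], members[[ys]])
    keep <- setdiff(seq_along(ids), c(xs, ys))
    members <- c(members[keep], list(merged))
    ids <- c(ids[keep], next_id)
    next_id <- next_id + 1L
  }
  members
}

# exhaustive pair-loop partition metrics
rand_ref <- function(computed, reference) {
  lc <- partition_labels(computed)
  lr <- partition_labels(reference)
  keys <- names(lr)
  agree <- 0; total <- 0
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (i >= j) next
    total <- total + 1
    same_c <- lc[keys[i]] == lc[keys[j]]
    same_r <- lr[keys[i]] == lr[keys[j]]
    if (same_c == same_r) agree <- agree + 1
  }
  agree / total
}

f_score_ref <- function(computed, reference) {
  cs <- unclass(as_cluster_set(computed))
  rs <- unclass(as_cluster_set(reference))
  n <- length(unlist(cs))
  total <- 0
  for (ci in cs) {
    best <- 0
    for (rj in rs) {
      p <- length(intersect(ci, rj)) / length(ci)
      r <- length(intersect(ci, rj)) / length(rj)
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      best <- max(best, f)
    }
    total <- total + best * length(ci)
  }
  total / n
}

entropy_ref <- function(computed, reference) {
  cs <- unclass(as_cluster_set(computed))
  rs <- unclass(as_cluster_set(reference))
  n <- length(unlist(cs))
  M <- length(rs)
  total <- 0
  for (ci in cs) {
    e <- 0
    for (rj in rs) {
      p <- length(intersect(ci, rj)) / length(ci)
      if (p > 0) e <- e - p * log(p)
    }
    total <- total + (e / log(M)) * length(ci)
  }
  total / n
}

# random symmetric similarity matrix with unit diagonal
random_sim <- function(n, keys = paste0("k", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(keys, keys)
  m
}

# random partition of keys into at most kmax clusters (all clusters non-empty)
random_partition <- function(keys, kmax = 4L) {
  repeat {
    lab <- sample(seq_len(kmax), length(keys), replace = TRUE)
    if (length(unique(lab)) >= 1L) break
  }
  as_cluster_set(setNames(paste0("g", lab), keys))
}

# small in-memory record table
records_df <- function(...) {
  rows <- list(...)
  data.frame(record_id = vapply(rows, `[[`, character(1), 1L),
             key = vapply(rows, `[[`, character(1), 2L),
             value = vapply(rows, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}
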