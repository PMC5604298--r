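#' Jaro-Winkler string similarity
#'
#' Similarity in \[0, 1\] between pairs of strings, favouring shared prefixes.
#' The Jaro score counts characters matching within a window of
#' `floor(max(|a|, |b|) / 2) - 1` positions and penalizes transpositions; the
#' Winkler adjustment adds a bonus proportional to the length of the common
#' prefix (at most `max_prefix` characters, scaled by `prefix_scale`) whenever
#' the Jaro score exceeds 0.7. This metric is the workhorse of record matching
#' and is used here for every string comparison: key names, core concepts and
#' values.
#'
#' Two empty strings score 1; an empty string against a non-empty one scores 0.
#'
#' @param a,b character vectors of equal length; similarity is computed
#'   elementwise.
#' @param prefix_scale prefix bonus per shared leading character (default 0.1).
#' @param max_prefix maximum prefix length rewarded (default 4).
#' @return numeric vector of similarities in \[0, 1\].
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")   # 0.9611
#' jaro_winkler("age (years)", "age (yrs)")
#' @export
jaro_winkler <- function(a, b, prefix_scale = 0.1, max_prefix = 4L) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  jw_pairwise(a, b, prefix_scale, as.integer(max_prefix))
}
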