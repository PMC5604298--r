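syn_dict <- load_synonyms()

test_that("name similarity is Jaro-Winkler on normalized names", {
  expect_equal(name_similarity("age", "age"), 1)
  expect_equal(name_similarity("Age ", "AGE"), 1)
  v <- name_similarity("age (years)", "age (yrs)")
  expect_gt(v, 0.9)
  expect_lt(v, 1)
  expect_equal(v, jw_ref("age (years)", "age (yrs)"), tolerance = 1e-12)
})

test_that("core concepts follow the verb-else-noun-with-adjective rule", {
  expect_equal(extract_core_concept("tissue isolated")$head, "isolated")
  expect_equal(extract_core_concept("tissue derived")$head, "derived")
  expect_equal(extract_core_concept("age")$head, "age")
  expect_equal(extract_core_concept("age (yrs)")$head, "age")
  expect_equal(extract_core_concept("primary tissue")$head, "primary tissue")
  # nothing taggable as verb/noun falls back to the full normalized name
  expect_equal(extract_core_concept("123 (%)")$head, "123 (%)")
  # tagger failure falls back, with a message, not an error
  boom <- function(tokens) stop("no model")
  expect_message(cc <- extract_core_concept("tissue isolated", tagger = boom))
  expect_equal(cc$head, "tissue isolated")
})

test_that("head is always a member of its synonym set", {
  for (nm in c("age", "tissue isolated", "disease state", "month"))
    expect_true(extract_core_concept(nm, synonyms = syn_dict)$head %in%
                  extract_core_concept(nm, synonyms = syn_dict)$synonyms)
})

test_that("core similarity is max Jaro-Winkler over synonym-expanded sets", {
  a <- extract_core_concept("age")
  expect_equal(core_similarity(a, a), 1)
  # month and date are dictionary synonyms: shared term forces 1
  m <- extract_core_concept("month", synonyms = syn_dict)
  d <- extract_core_concept("date", synonyms = syn_dict)
  expect_equal(core_similarity(m, d), 1)
  # disjoint singleton sets reduce to plain Jaro-Winkler of the heads
  i <- extract_core_concept("tissue isolated")
  de <- extract_core_concept("tissue derived")
  expect_equal(core_similarity(i, de), jw_ref("isolated", "derived"),
               tolerance = 1e-12)
})

test_that("value similarity is the best value pair, 0 without evidence", {
  expect_equal(value_similarity(c("Male"), c("Male", "Female")), 1)
  expect_equal(value_similarity(character(), "x"), 0)
  expect_equal(value_similarity(character(), character()), 0)
  expect_equal(value_similarity("21 years", "21"),
               jw_ref("21 years", "21"), tolerance = 1e-12)
  # brute force over all pairs with the oracle
  va <- c("alpha", "beta", "gamma")
  vb <- c("betta", "delta")
  expect_equal(value_similarity(va, vb),
               max(outer(va, vb, Vectorize(jw_ref))), tolerance = 1e-12)
})

test_that("value cap keeps the most frequent values", {
  a <- setNames(c(5L, 1L), c("common", "rare"))
  b <- setNames(1L, "rare")
  expect_equal(value_similarity(a, b, cap = 2), 1)
  expect_lt(value_similarity(a, b, cap = 1), 1)   # "rare" capped away
})

test_that("weights are validated against the simplex", {
  w <- similarity_weights(0.44, 0.01, 0.55)
  expect_s3_class(w, "similarity_weights")
  expect_error(similarity_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(similarity_weights(-0.2, 0.6, 0.6), "\\[0, 1\\]")
})

test_that("combined similarity is the weighted component combination", {
  a <- list(name = "age (years)", values = c("21", "63"))
  b <- list(name = "age (yrs)", values = c("21 years"))
  # degenerate weights reduce to single components
  expect_equal(combined_similarity(a, b, similarity_weights(1, 0, 0)),
               name_similarity(a$name, b$name))
  expect_equal(combined_similarity(a, a, similarity_weights(0.2, 0.3, 0.5)), 1)
  # reference weights for an age-like category: manual recombination
  w <- similarity_weights(0.44, 0.01, 0.55)
  sn <- name_similarity(a$name, b$name)
  sc <- core_similarity(extract_core_concept(a$name),
                        extract_core_concept(b$name))
  sv <- value_similarity(a$values, b$values)
  expect_equal(combined_similarity(a, b, w),
               0.44 * sn + 0.01 * sc + 0.55 * sv, tolerance = 1e-12)
})

test_that("combined similarity is monotone in each component", {
  w <- similarity_weights(0.4, 0.2, 0.4)
  a <- list(name = "age", values = "21")
  b_far <- list(name = "strain", values = "dmso")
  b_val <- list(name = "strain", values = "21")      # raises value component
  b_name <- list(name = "aged", values = "dmso")     # raises name component
  base <- combined_similarity(a, b_far, w)
  expect_gte(combined_similarity(a, b_val, w), base)
  expect_gte(combined_similarity(a, b_name, w), base)
})

test_that("similarity matrix is symmetric, unit-diagonal and complete", {
  recs <- records_df(c("s", "age (mouse)", "3"), c("s", "mouse age", "4"),
                     c("s", "age (in month)", "5"), c("s", "age (month)", "6"),
                     c("s", "age (date)", "7"))
  corpus <- aggregate_keys(recs)
  m <- similarity_matrix(corpus, similarity_weights(1, 0, 0))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(1, 5))
  expect_true(all(m >= 0 & m <= 1))

  one <- aggregate_keys(records_df(c("s", "age", "1")))
  m1 <- similarity_matrix(one, similarity_weights(1, 0, 0))
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(m1[1, 1], 1)
  expect_equal(rownames(m1), "age")
})

test_that("the five printed age variants peak at the (in month)/(month) pair", {
  keys <- c("age (mouse)", "mouse age", "age (in month)", "age (month)",
            "age (date)")
  # brute-force all 10 pairs with the naive oracle
  best <- c(NA, NA); bv <- -1
  for (i in 1:4) for (j in (i + 1):5) {
    v <- jw_ref(keys[i], keys[j])
    if (v > bv) { bv <- v; best <- keys[c(i, j)] }
  }
  expect_setequal(best, c("age (in month)", "age (month)"))

  corpus <- aggregate_keys(data.frame(record_id = "s", key = keys, value = ""))
  m <- similarity_matrix(corpus, similarity_weights(1, 0, 0))
  mm <- unclass(m); diag(mm) <- -1
  idx <- which(mm == max(mm), arr.ind = TRUE)
  expect_setequal(rownames(m)[idx[1, ]], c("age (in month)", "age (month)"))
})

test_that("the audit table covers exactly n(n-1)/2 pairs", {
  sim <- generate_corpus(generator_config(seed = 4))
  n <- nrow(sim$corpus)
  tab <- similarity_table(sim$corpus, similarity_weights(0.5, 0.2, 0.3),
                          synonyms = syn_dict)
  expect_equal(nrow(tab), n * (n - 1) / 2)
  expect_true(all(abs(tab$sim_combined -
                        (0.5 * tab$sim_name + 0.2 * tab$sim_core +
                           0.3 * tab$sim_value)) < 1e-12))
})

test_that("with beta = 0 the tagger and synonym source are never consulted", {
  recs <- records_df(c("s", "age", "3"), c("s", "gender", "Male"))
  corpus <- aggregate_keys(recs)
  calls <- 0L
  counting <- function(tokens) {
    calls <<- calls + 1L
    rep("noun", length(tokens))
  }
  m <- similarity_matrix(corpus, similarity_weights(0.5, 0, 0.5),
                         tagger = counting)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(calls, 0L)
  similarity_matrix(corpus, similarity_weights(0.5, 0.5, 0),
                    tagger = counting)
  expect_gt(calls, 0L)
})
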