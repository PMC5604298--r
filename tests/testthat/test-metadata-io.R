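test_that("key-value tables parse with rejects reported, not dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("record_id\tkey\tvalue",
               "GSM549324\tgender\tMale",
               "GSM549325\t\t45",
               "GSM549326\ttissue\tliver"), path)
  recs <- read_key_value_table(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$record_id[1], "GSM549324")
  expect_equal(recs$key[1], "gender")
  expect_equal(recs$value[1], "Male")
  rej <- rejects(recs)
  expect_equal(nrow(rej), 1)
  expect_equal(rej$line, 3L)
  expect_match(rej$reason, "empty key")
})

test_that("empty input yields an empty record set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("record_id\tkey\tvalue", path)
  recs <- read_key_value_table(path)
  expect_equal(nrow(recs), 0)
  expect_equal(nrow(rejects(recs)), 0)
})

test_that("key normalization lowercases, trims and collapses whitespace only", {
  expect_equal(normalize_key("  Age (Years) "), "age (years)")
  expect_equal(normalize_key("disease_state"), "disease_state")
  expect_equal(normalize_key("AGE"), "age")
  expect_equal(normalize_key("a\t b"), "a b")
})

test_that("aggregation merges case/whitespace variants and counts frequency", {
  recs <- records_df(c("s1", "Age", "3"), c("s2", "age", "5"))
  corpus <- aggregate_keys(recs)
  expect_equal(nrow(corpus), 1)
  expect_equal(corpus$name, "age")
  expect_equal(corpus$frequency, 2L)
  expect_setequal(names(corpus$values[[1]]), c("3", "5"))
  expect_setequal(corpus$raw_forms[[1]], c("Age", "age"))

  expect_equal(nrow(aggregate_keys(recs[0, ])), 0)
})

test_that("corpus size equals the number of distinct normalized keys", {
  set.seed(5)
  ks <- replicate(80, paste(sample(c("age", "Age ", "sex", "strain", "a_b"),
                                   2, replace = TRUE), collapse = " "))
  recs <- data.frame(record_id = paste0("r", seq_along(ks)), key = ks,
                     value = "x", stringsAsFactors = FALSE)
  corpus <- aggregate_keys(recs)
  # independent one-liner for the expected count
  expect_equal(nrow(corpus),
               length(unique(trimws(gsub("\\s+", " ", tolower(ks))))))
})

test_that("aggregation is idempotent through record reconstruction", {
  recs <- records_df(c("s1", "Age", "3"), c("s2", "age", "5"),
                     c("s3", "tissue", "liver"), c("s4", "tissue", "liver"),
                     c("s5", "Tissue", "lung"))
  corpus <- aggregate_keys(recs)
  again <- aggregate_keys(corpus_records(corpus))
  expect_equal(again$name, corpus$name)
  expect_equal(again$frequency, corpus$frequency)
  expect_equal(again$values, corpus$values)
  expect_equal(again$raw_forms, corpus$raw_forms)
})

test_that("category selection is a case-insensitive sub-corpus filter", {
  recs <- records_df(c("s", "age (yrs)", ""), c("s", "Patient Age", ""),
                     c("s", "gender", ""))
  corpus <- aggregate_keys(recs)
  sel <- select_category(corpus, "age")
  expect_setequal(sel$name, c("age (yrs)", "patient age"))
  expect_equal(nrow(select_category(corpus, "zzz")), 0)
  expect_equal(select_category(corpus, ".*")$name, corpus$name)
  expect_error(select_category(corpus, "("), "regular expression")
})

test_that("regex selection of strain keys recovers the printed strain rows", {
  ref_path <- system.file("extdata", "printed_keys_reference.tsv",
                          package = "cutcluster")
  corpus_path <- system.file("extdata", "printed_keys_corpus.tsv",
                             package = "cutcluster")
  ref <- read.delim(ref_path, header = FALSE, col.names = c("key", "label"))
  corpus <- aggregate_keys(read_key_value_table(corpus_path))
  sel <- select_category(corpus, "strain")
  # independent count of printed keys containing "strain"
  expect_equal(nrow(sel), sum(grepl("strain", ref$key, ignore.case = TRUE)))
  # every key filed under a strain cluster matches the category regex
  expect_true(all(ref$key[startsWith(ref$label, "strain")] %in% sel$name))
})

test_that("cluster files round-trip up to label renaming", {
  part <- cluster_set(list(A = c("x", "y"), B = "z"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_file(part, path)
  expect_length(readLines(path), 3)
  back <- read_cluster_file(path)
  expect_equal(partition_labels(back)[c("x", "y", "z")],
               partition_labels(part)[c("x", "y", "z")])

  # same-cluster relation preserved for a larger random partition
  set.seed(2)
  keys <- paste0("k", 1:20)
  p2 <- random_partition(keys, 5)
  write_cluster_file(p2, path)
  b2 <- read_cluster_file(path)
  expect_equal(rand_index(b2, p2), 1)
})

test_that("a key under two labels is a cluster-file format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\tA", "x\tB", "y\tA"), path)
  expect_error(read_cluster_file(path), "multiple labels")
})

test_that("comments and empty cluster files are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", ""), path)
  expect_length(read_cluster_file(path), 0)
})
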