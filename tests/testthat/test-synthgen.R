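test_that("synth_spec validates its parameters", {
  expect_s3_class(synth_spec(n_individuals = 10), "synth_spec")
  expect_error(synth_spec(n_individuals = 0), class = "linkclust_config_error")
  expect_error(synth_spec(mix = c(substitution = 1)), class = "linkclust_config_error")
  expect_error(synth_spec(p_missing_row = 1.5), class = "linkclust_config_error")
  expect_error(synth_spec(file_attrs = list(c("ID", "Nope"))),
               class = "linkclust_config_error")
})

test_that("generation is deterministic under a fixed seed", {
  spec <- synth_spec(n_individuals = 15, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- generate_synthetic(spec, d1)
  out2 <- generate_synthetic(spec, d2)
  for (f in seq_along(out1$datasets)) {
    expect_identical(readLines(out1$datasets[[f]]$path),
                     readLines(out2$datasets[[f]]$path))
  }
  expect_identical(out1$truth, out2$truth)
  # generation does not disturb the caller's RNG stream
  set.seed(7); before <- runif(3)
  set.seed(7); generate_synthetic(spec, withr::local_tempdir()); after <- runif(3)
  expect_identical(before, after)
})

test_that("a Tables-style three-file fixture has the expected shape", {
  spec <- synth_spec(n_individuals = 5, n_files = 3, max_errors = 0,
                     p_missing_row = 0, seed = 11)
  out <- generate_synthetic(spec, withr::local_tempdir())
  expect_length(out$datasets, 3)
  # master file carries all 9 attributes, second file 4, third file 8
  widths <- vapply(out$datasets, function(d) sum(d$index_map >= 0), integer(1))
  expect_equal(widths, c(9L, 4L, 8L))
  records <- unify_records(out$datasets, out$schema)
  expect_equal(nrow(records), 15)
  expect_equal(common_attributes(out$datasets, out$schema),
               c("ID", "FirstName", "LastName"))
})

test_that("without corruption, same-individual records agree on shared attributes", {
  spec <- synth_spec(n_individuals = 12, max_errors = 0, p_missing_row = 0,
                     seed = 21)
  out <- generate_synthetic(spec, withr::local_tempdir())
  records <- unify_records(out$datasets, out$schema)
  truth <- dplyr::inner_join(records, out$truth, by = c("dataset", "row_ordinal"))
  for (attrib in c("FirstName", "LastName", "SSID")) {
    per_ind <- tapply(truth[[attrib]], truth$individual,
                      function(v) dplyr::n_distinct(v[!is.na(v)]))
    expect_true(all(per_ind == 1))
  }
})

test_that("clean generation at threshold 0 recovers the truth exactly", {
  spec <- synth_spec(n_individuals = 30, max_errors = 0, p_missing_row = 0.1,
                     seed = 31)
  out <- generate_synthetic(spec, withr::local_tempdir())
  res <- link_records(out$datasets, out$schema,
                      list(cmp_edit("FirstName"), cmp_edit("LastName")),
                      blocking_attr = "LastName", threshold = 0)
  scores <- evaluate_linkage(res, out$truth)
  expect_equal(scores$precision, 1)
  expect_equal(scores$recall, 1)
  expect_equal(scores$f1, 1)
})

test_that("typo corruption within the budget is fully recalled", {
  # one typo per record at most, confined to the compared name fields; the
  # clean master file anchors every individual, so threshold >= e links all
  spec <- synth_spec(n_individuals = 40, max_errors = 1,
                     mix = c(substitution = 0.6, insertion = 0.2, deletion = 0.2,
                             swap = 0, truncation = 0),
                     p_missing_row = 0.1, seed = 41)
  out <- generate_synthetic(spec, withr::local_tempdir())
  res <- link_records(out$datasets, out$schema,
                      list(cmp_edit("FirstName"), cmp_edit("LastName")),
                      blocking_attr = "LastName", threshold = 1, lmer_length = 1)
  scores <- evaluate_linkage(res, out$truth)
  expect_equal(scores$recall, 1)
})

test_that("swap and truncation corruptions are recovered by their comparators", {
  spec <- synth_spec(n_individuals = 25, max_errors = 1,
                     mix = c(substitution = 0, insertion = 0, deletion = 0,
                             swap = 1, truncation = 0),
                     p_missing_row = 0, seed = 51)
  out <- generate_synthetic(spec, withr::local_tempdir())
  # block on ID: a swapped record's LastName field holds a first name, so
  # name blocking could miss it, while the ID is shared across files
  res <- link_records(out$datasets, out$schema,
                      list(cmp_reversal("FirstName", "LastName")),
                      blocking_attr = "ID", threshold = 0, lmer_length = 1)
  expect_equal(evaluate_linkage(res, out$truth)$recall, 1)

  spec2 <- synth_spec(n_individuals = 25, max_errors = 1,
                      mix = c(substitution = 0, insertion = 0, deletion = 0,
                              swap = 0, truncation = 1),
                      p_missing_row = 0, seed = 52)
  out2 <- generate_synthetic(spec2, withr::local_tempdir())
  res2 <- link_records(out2$datasets, out2$schema,
                       list(cmp_edit("LastName"), cmp_truncation("FirstName", 1)),
                       blocking_attr = "LastName", threshold = 0, lmer_length = 1)
  expect_equal(evaluate_linkage(res2, out2$truth)$recall, 1)
})

test_that("pairwise evaluation scores degenerate clusterings correctly", {
  truth <- tibble::tibble(dataset = "d", row_ordinal = 0:5,
                          individual = c(1L, 1L, 2L, 2L, 3L, 3L))
  perfect <- tibble::tibble(cluster_id = c(1L, 1L, 2L, 2L, 3L, 3L),
                            dataset = "d", row_ordinal = 0:5)
  s <- evaluate_linkage(perfect, truth)
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))

  singletons <- tibble::tibble(cluster_id = 1:6, dataset = "d", row_ordinal = 0:5)
  s2 <- evaluate_linkage(singletons, truth)
  expect_equal(s2$recall, 0)
  expect_equal(s2$precision, 1) # no predicted pair, so none is wrong

  giant <- tibble::tibble(cluster_id = 1L, dataset = "d", row_ordinal = 0:5)
  s3 <- evaluate_linkage(giant, truth)
  expect_equal(s3$recall, 1)
  expect_lt(s3$precision, 1)

  expect_error(evaluate_linkage(perfect, truth[1:3, ]),
               class = "linkclust_config_error")
})

test_that("swap-corrupted pairs sit at the reversal distance the mix implies", {
  # a pure swap is free under reversal distance but costly under plain edit
  spec <- synth_spec(n_individuals = 10, max_errors = 1,
                     mix = c(substitution = 0, insertion = 0, deletion = 0,
                             swap = 1, truncation = 0),
                     p_missing_row = 0, seed = 61)
  out <- generate_synthetic(spec, withr::local_tempdir())
  records <- unify_records(out$datasets, out$schema)
  labelled <- dplyr::inner_join(records, out$truth, by = c("dataset", "row_ordinal"))
  master <- labelled[labelled$dataset == "Synth01.csv", ]
  other <- labelled[labelled$dataset == "Synth02.csv", ]
  m <- match(other$individual, master$individual)
  rd <- reversal_distance(master$FirstName[m], master$LastName[m],
                          other$FirstName, other$LastName)
  expect_true(all(rd == 0))
})
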