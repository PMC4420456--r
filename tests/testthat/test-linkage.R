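two_record_instance <- function() {
  tibble::tibble(
    record_uid = 0:1, dataset = c("a.csv", "b.csv"), row_ordinal = c(0L, 0L),
    FirstName = c("james", "hames"), LastName = c("rodriguez", "rodriuez")
  )
}

test_that("build_graph links pairs at or under the threshold", {
  recs <- two_record_instance()
  comps <- list(cmp_edit("FirstName"), cmp_edit("LastName"))
  pairs <- tibble::tibble(uid_a = 0L, uid_b = 1L)
  expect_equal(nrow(build_graph(pairs, recs, comps, k = 1)), 0)
  e2 <- build_graph(pairs, recs, comps, k = 2)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$distance, 2L)
  # threshold 0 links identical records only
  recs0 <- recs
  recs0$FirstName <- "james"; recs0$LastName <- "rodriguez"
  expect_equal(nrow(build_graph(pairs, recs0, comps, k = 0)), 1)
  expect_error(build_graph(pairs, recs, comps, k = -1),
               class = "linkclust_config_error")
})

test_that("the two-record example yields 2 clusters at k=1 and 1 at k=2", {
  recs <- two_record_instance()
  comps <- list(cmp_edit("FirstName"), cmp_edit("LastName"))
  at1 <- cluster_records(recs, comps, blocking_attr = "LastName", threshold = 1)
  at2 <- cluster_records(recs, comps, blocking_attr = "LastName", threshold = 2)
  expect_equal(glance(at1)$n_clusters, 2L)
  expect_equal(glance(at2)$n_clusters, 1L)
})

test_that("connected_components matches igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(105)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    vertices <- sample.int(500, n)
    m <- sample(0:(2 * n), 1)
    edges <- tibble::tibble(uid_a = sample(vertices, m, replace = TRUE),
                            uid_b = sample(vertices, m, replace = TRUE))
    edges <- edges[edges$uid_a != edges$uid_b, ]
    got <- connected_components(vertices, edges)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$uid_a), to = as.character(edges$uid_b)),
      directed = FALSE,
      vertices = data.frame(name = as.character(sort(vertices))))
    want <- igraph::components(g)$membership
    want_tbl <- tibble::tibble(record_uid = as.integer(names(want)),
                               component = as.integer(want))
    expect_true(same_partition(partition_of(got), partition_of(want_tbl)))
  }
  # components are numbered by smallest member, isolates included
  cc <- connected_components(c(4L, 1L, 9L, 2L),
                             tibble::tibble(uid_a = 9L, uid_b = 1L))
  expect_equal(cc$component[cc$record_uid == 1L], 1L)
  expect_equal(cc$component[cc$record_uid == 9L], 1L)
  expect_equal(cc$component[cc$record_uid == 2L], 2L)
  expect_equal(cc$component[cc$record_uid == 4L], 3L)
})

test_that("single_linkage_oracle handles degenerate cases", {
  recs <- random_instance(5)
  comps <- list(cmp_edit("FirstName"), cmp_edit("LastName"))
  # huge threshold chains everything into one cluster
  big <- single_linkage_oracle(recs, comps, k = 100)
  expect_equal(length(unique(big$component)), 1)
  # k = 0 on distinct records gives singletons
  set.seed(106)
  distinct <- random_instance(6, dup_rate = 0)
  zero <- single_linkage_oracle(distinct, comps, k = 0)
  expect_equal(length(unique(zero$component)), 6)
  empty <- single_linkage_oracle(recs[0, ], comps, k = 1)
  expect_equal(nrow(empty), 0)
})

test_that("blocked pipeline equals the all-pairs single-linkage oracle", {
  comps <- list(cmp_edit("FirstName"), cmp_edit("LastName"))
  set.seed(107)
  for (i in 1:25) {
    recs <- random_instance(50)
    k <- sample(0:2, 1)
    res <- cluster_records(recs, comps, blocking_attr = "LastName",
                           threshold = k, lmer_length = 1)
    exact <- exact_match_clusters(recs, c("FirstName", "LastName"))
    reps <- recs[recs$record_uid %in% exact$representative_uid, ]
    oracle <- single_linkage_oracle(reps, comps, k = k)
    expanded <- expand_clusters(oracle, exact)
    expect_true(same_partition(partition_of(res$assignments, "cluster_id"),
                               partition_of(expanded, "cluster_id")))
    # conservation on every run
    expect_setequal(res$assignments$record_uid, recs$record_uid)
  }
})

test_that("raising the threshold only coarsens the partition", {
  comps <- list(cmp_edit("FirstName"), cmp_edit("LastName"))
  set.seed(108)
  for (i in 1:10) {
    recs <- random_instance(40)
    parts <- lapply(0:3, function(k) {
      res <- cluster_records(recs, comps, blocking_attr = "LastName",
                             threshold = k, lmer_length = 1)
      res$assignments
    })
    for (k in 1:3) {
      fine <- parts[[k]]
      coarse <- parts[[k + 1]]
      merged <- dplyr::inner_join(fine, coarse, by = "record_uid",
                                  suffix = c("_fine", "_coarse"))
      crossings <- merged |>
        dplyr::distinct(.data$cluster_id_fine, .data$cluster_id_coarse) |>
        dplyr::count(.data$cluster_id_fine)
      expect_true(all(crossings$n == 1))
    }
  }
})

test_that("expand_clusters restores exact duplicates and checks consistency", {
  exact <- tibble::tibble(record_uid = 0:4,
                          exact_cluster = c(1L, 1L, 2L, 3L, 3L),
                          representative_uid = c(0L, 0L, 2L, 3L, 3L))
  components <- tibble::tibble(record_uid = c(0L, 2L, 3L),
                               component = c(1L, 1L, 2L))
  out <- expand_clusters(components, exact)
  expect_setequal(out$record_uid, 0:4)
  expect_equal(out$cluster_id[match(0:4, out$record_uid)],
               c(1L, 1L, 1L, 2L, 2L))
  # all-singleton exact clusters: expansion is the identity on membership
  singl <- tibble::tibble(record_uid = 0:2, exact_cluster = 1:3,
                          representative_uid = 0:2)
  comp2 <- tibble::tibble(record_uid = 0:2, component = c(1L, 1L, 2L))
  out2 <- expand_clusters(comp2, singl)
  expect_equal(out2$cluster_id[match(0:2, out2$record_uid)], c(1L, 1L, 2L))
  # a representative with no component assignment is an internal error
  expect_error(expand_clusters(comp2[1:2, ], singl),
               class = "linkclust_internal_error")
})

test_that("the full worked example reproduces the published clustering", {
  res <- link_records(example_datasets(), example_schema(),
                      example_comparisons(), blocking_attr = "LastName",
                      threshold = 1, avg_block_len = 7)
  tidied <- tidy(res)
  expect_equal(dplyr::n_distinct(tidied$cluster_id), 6)
  expect_true(same_partition(partition_keys(tidied),
                             expected_example_membership()))
  # record counts survive the pipeline
  expect_equal(nrow(tidied), 15)
  expect_equal(glance(res)$n_exact_clusters, 11L)
})

test_that("the pipeline is deterministic and conserves records", {
  res1 <- link_records(example_datasets(), example_schema(),
                       example_comparisons(), "LastName", threshold = 1)
  res2 <- link_records(example_datasets(), example_schema(),
                       example_comparisons(), "LastName", threshold = 1)
  expect_identical(tidy(res1), tidy(res2))
  expect_equal(sum(table(res1$assignments$cluster_id)), 15)
  expect_false(anyDuplicated(res1$assignments$record_uid) > 0)
})

test_that("empty input produces an empty result", {
  schema <- attribute_schema(c("A", "B"))
  empty <- write_tmp_csv(character(0))
  res <- link_records(list(dataset_spec(empty, c(0, 1))), schema,
                      list(cmp_edit("A")), blocking_attr = "A")
  expect_equal(glance(res)$n_records, 0L)
  expect_equal(nrow(tidy(res)), 0)
})

test_that("comparisons outside the common attributes are rejected", {
  expect_error(
    link_records(example_datasets(), example_schema(),
                 list(cmp_edit("SSN")), blocking_attr = "LastName"),
    class = "linkclust_config_error")
  expect_error(
    link_records(example_datasets(), example_schema(),
                 example_comparisons(), blocking_attr = "SSN"),
    class = "linkclust_config_error")
})
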