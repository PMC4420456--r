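#' Score candidate pairs and keep threshold edges
#'
#' Computes the record distance once per candidate pair and keeps the pairs
#' within the threshold: an edge `(i, j)` exists iff
#' `record_distance(i, j) <= k` (inclusive -- a pair with exactly `k` errors
#' is linked). The result is the edge list of a simple graph over the
#' representatives.
#'
#' @param pairs Candidate pair tibble (`uid_a`, `uid_b`).
#' @param reps Representative record tibble.
#' @param comparisons List of [comparison_spec] objects.
#' @param k Threshold: how many errors the linkage endures (integer >= 0).
#' @param missing Missing-value policy, `"ignore"` or `"empty"`.
#' @return `pairs` filtered to edges, with a `distance` column.
#' @export
build_graph <- function(pairs, reps, comparisons, k, missing = c("ignore", "empty")) {
  missing <- match.arg(missing)
  comparisons <- check_comparisons(comparisons, attr_columns(reps))
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 0L) {
    abort("threshold `k` must be a single integer >= 0", class = "linkclust_config_error")
  }
  d <- pair_distances(reps, pairs, comparisons, missing)
  out <- pairs
  out$distance <- d
  dplyr::filter(out, .data$distance <= k)
}

#' Connected components by union-find
#'
#' Each connected component of the threshold graph is one individual's
#' cluster of representatives. Implemented with a disjoint-set forest with
#' path halving; isolated vertices form singleton components. Components are
#' numbered 1, 2, ... by their smallest member uid.
#'
#' @param vertices Integer vector of vertex uids.
#' @param edges Tibble with columns `uid_a`, `uid_b` (subset of `vertices`).
#' @return A tibble `record_uid`, `component`.
#' @export
connected_components <- function(vertices, edges) {
  vertices <- sort(unique(as.integer(vertices)))
  n <- length(vertices)
  if (n == 0) return(tibble::tibble(record_uid = integer(0), component = integer(0)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0) {
    ia <- match(as.integer(edges$uid_a), vertices)
    ib <- match(as.integer(edges$uid_b), vertices)
    if (anyNA(ia) || anyNA(ib)) {
      abort("edge endpoints must all appear in `vertices`",
            class = "linkclust_internal_error")
    }
    for (e in seq_along(ia)) {
      ra <- find(ia[e]); rb <- find(ib[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # vertices are sorted, so the root index order is the smallest-member order
  comp <- match(roots, sort(unique(roots)))
  tibble::tibble(record_uid = vertices, component = comp)
}

#' All-pairs single-linkage clustering (test oracle)
#'
#' Reference implementation without blocking: computes every pairwise record
#' distance, builds the single-linkage dendrogram (`stats::hclust`), and cuts
#' it at height `k`, keeping merges at height `<= k`. Equivalent to the
#' connected components of the exhaustive threshold graph; intended for small
#' instances (a few hundred representatives).
#'
#' @inheritParams build_graph
#' @return A tibble `record_uid`, `component` (components numbered by
#'   smallest member uid).
#' @export
single_linkage_oracle <- function(reps, comparisons, k, missing = c("ignore", "empty")) {
  missing <- match.arg(missing)
  check_records(reps)
  comparisons <- check_comparisons(comparisons, attr_columns(reps))
  n <- nrow(reps)
  if (n == 0) return(tibble::tibble(record_uid = integer(0), component = integer(0)))
  reps <- dplyr::arrange(reps, .data$record_uid)
  if (n == 1) return(tibble::tibble(record_uid = reps$record_uid, component = 1L))
  idx <- t(utils::combn(n, 2))
  pairs <- tibble::tibble(uid_a = reps$record_uid[idx[, 1]],
                          uid_b = reps$record_uid[idx[, 2]])
  d <- pair_distances(reps, pairs, comparisons, missing)
  m <- matrix(0, n, n)
  m[cbind(idx[, 1], idx[, 2])] <- d
  m[cbind(idx[, 2], idx[, 1])] <- d
  hc <- stats::hclust(stats::as.dist(m), method = "single")
  grp <- stats::cutree(hc, h = as.numeric(k))
  # renumber so component ids follow the smallest member uid
  comp <- match(grp, unique(grp[order(reps$record_uid)]))
  tibble::tibble(record_uid = reps$record_uid, component = comp)
}

#' Expand representative components into the final partition
#'
#' Replaces every representative in a component by its full exact-duplicate
#' group, yielding the final clusters of input records.
#'
#' @param components Tibble `record_uid`, `component` over representatives.
#' @param exact Exact-cluster tibble from [exact_match_clusters()].
#' @return A tibble `record_uid`, `cluster_id` covering every input record,
#'   cluster ids 1, 2, ... by ascending smallest member uid.
#' @export
expand_clusters <- function(components, exact) {
  missing_rep <- setdiff(unique(exact$representative_uid), components$record_uid)
  if (length(missing_rep)) {
    abort("internal: representatives without a component assignment",
          class = "linkclust_internal_error")
  }
  orphan <- setdiff(components$record_uid, exact$representative_uid)
  if (length(orphan)) {
    abort("internal: component vertex with no exact cluster",
          class = "linkclust_internal_error")
  }
  out <- exact |>
    dplyr::inner_join(components, by = c(representative_uid = "record_uid")) |>
    dplyr::group_by(.data$component) |>
    dplyr::mutate(cluster_min = min(.data$record_uid)) |>
    dplyr::ungroup()
  out$cluster_id <- dplyr::dense_rank(out$cluster_min)
  out |>
    dplyr::arrange(.data$cluster_id, .data$record_uid) |>
    dplyr::select("record_uid", "cluster_id")
}

#' Cluster unified records into individuals
#'
#' The full linkage engine on an in-memory record table: exact-duplicate
#' clustering, l-mer blocking over the representatives, per-pair distance
#' scoring, threshold-graph connected components, and expansion back to all
#' records. Deterministic for fixed input and configuration.
#'
#' @param records Unified record tibble (from [unify_records()] or built
#'   directly; must have unique `record_uid`, `dataset`, `row_ordinal` and one
#'   character column per attribute).
#' @param comparisons List of [comparison_spec] objects; their sum is the
#'   record distance compared to `threshold`.
#' @param blocking_attr Attribute used for l-mer blocking (the paper's tool
#'   blocks on the last name by default choice of its authors; any reliable
#'   common attribute works).
#' @param threshold Maximum total error count on a linked pair (default 1).
#' @param avg_block_len Approximate average length of the blocking attribute,
#'   used to derive the l-mer length (default 7).
#' @param lmer_length Optional explicit l-mer length, overriding
#'   [default_lmer_length()].
#' @param exact_attrs Attributes for the exact-duplicate phase. Defaults to
#'   the common attributes recorded by [unify_records()], or to all attribute
#'   columns for a hand-built table.
#' @param missing Missing-value policy for comparisons (`"ignore"`: a
#'   comparison touching `NA` contributes 0; `"empty"`: `NA` compares as
#'   `""`).
#' @param verbose If `TRUE`, log per-phase counts with `message()`.
#' @return A `linkage_result` object; see [tidy.linkage_result()],
#'   [glance.linkage_result()], [write_clusters()].
#' @examples
#' recs <- tibble::tibble(
#'   record_uid = 0:1, dataset = "ex", row_ordinal = 0:1,
#'   FirstName = c("james", "hames"), LastName = c("rodriguez", "rodriuez"))
#' res <- cluster_records(recs, list(cmp_edit("FirstName"), cmp_edit("LastName")),
#'                        blocking_attr = "LastName", threshold = 1)
#' glance(res)$n_clusters # 2: the pair has 2 errors, one more than endured
#' @export
cluster_records <- function(records, comparisons, blocking_attr,
                            threshold = 1L, avg_block_len = 7L,
                            lmer_length = NULL, exact_attrs = NULL,
                            missing = c("ignore", "empty"), verbose = FALSE) {
  missing <- match.arg(missing)
  check_records(records)
  attrs <- attr_columns(records)
  comparisons <- check_comparisons(comparisons, attrs)
  threshold <- as.integer(threshold)
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0L) {
    abort("`threshold` must be a single integer >= 0", class = "linkclust_config_error")
  }
  exact_attrs <- exact_attrs %||% attr(records, "common_attrs") %||% attrs
  l <- if (is.null(lmer_length)) default_lmer_length(avg_block_len, threshold)
       else as.integer(lmer_length)

  if (nrow(records) == 0) {
    empty <- tibble::tibble(record_uid = integer(0), cluster_id = integer(0))
    counts <- c(records = 0, exact_clusters = 0, blocks = 0,
                candidate_pairs = 0, edges = 0, clusters = 0)
    if (isTRUE(verbose)) log_run(counts)
    return(new_linkage_result(records, empty, comparisons, blocking_attr,
                              threshold, l, missing, counts))
  }

  exact <- exact_match_clusters(records, exact_attrs)
  reps <- records[records$record_uid %in% exact$representative_uid, , drop = FALSE]
  blocks <- build_blocks(reps, blocking_attr, l)
  pairs <- candidate_pairs(blocks)
  edges <- build_graph(pairs, reps, comparisons, threshold, missing)
  components <- connected_components(reps$record_uid, edges)
  assignments <- expand_clusters(components, exact)
  counts <- c(records = nrow(records), exact_clusters = max(exact$exact_cluster),
              blocks = dplyr::n_distinct(blocks$key), candidate_pairs = nrow(pairs),
              edges = nrow(edges), clusters = max(assignments$cluster_id))
  if (isTRUE(verbose)) log_run(counts)
  new_linkage_result(records, assignments, comparisons, blocking_attr,
                     threshold, l, missing, counts)
}

#' Run the whole linkage pipeline from files
#'
#' Reads and unifies the input files, then clusters them with
#' [cluster_records()]. This is the three-phase tool in one call: input and
#' schema mapping, parameterised linkage, clustered output.
#'
#' @inheritParams unify_records
#' @inheritParams cluster_records
#' @return A `linkage_result` object.
#' @export
link_records <- function(specs, schema, comparisons, blocking_attr,
                         threshold = 1L, avg_block_len = 7L, lmer_length = NULL,
                         exact_attrs = NULL, missing = c("ignore", "empty"),
                         verbose = FALSE) {
  records <- unify_records(specs, schema)
  common <- attr(records, "common_attrs")
  for (cmp in as_comparison_list(comparisons)) {
    out_of_common <- setdiff(cmp$attrs, common)
    if (length(out_of_common)) {
      abort(paste0("comparison '", format(cmp),
                   "' uses attribute(s) not common to all datasets: ",
                   paste(out_of_common, collapse = ", ")),
            class = "linkclust_config_error")
    }
  }
  if (!as.character(blocking_attr)[1] %in% common) {
    abort(paste0("blocking attribute '", blocking_attr,
                 "' is not common to all datasets"),
          class = "linkclust_config_error")
  }
  cluster_records(records, comparisons, blocking_attr, threshold = threshold,
                  avg_block_len = avg_block_len, lmer_length = lmer_length,
                  exact_attrs = exact_attrs, missing = missing, verbose = verbose)
}

log_run <- function(counts) {
  message("linkclust: ", paste(names(counts), unname(counts), sep = " = ",
                               collapse = ", "))
  invisible(counts)
}
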