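new_linkage_result <- function(records, assignments, comparisons, blocking_attr,
                               threshold, lmer_length, missing, counts) {
  structure(
    list(records = records, assignments = assignments,
         comparisons = comparisons, blocking_attr = blocking_attr,
         threshold = threshold, lmer_length = lmer_length,
         missing = missing, counts = counts),
    class = "linkage_result"
  )
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result>\n")
  cat("  records:   ", x$counts[["records"]], "\n", sep = "")
  cat("  clusters:  ", x$counts[["clusters"]], " (", x$counts[["exact_clusters"]],
      " exact-duplicate groups)\n", sep = "")
  cat("  threshold: ", x$threshold, " error(s); blocking on '", x$blocking_attr,
      "' with l = ", x$lmer_length, "\n", sep = "")
  cat("  comparisons: ",
      paste(vapply(x$comparisons, format, character(1)), collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a linkage result into one row per record
#'
#' Returns the final partition as a tibble: `cluster_id`, `record_uid`,
#' `dataset`, `row_ordinal`, then the attribute columns. Rows are ordered by
#' cluster id, then by dataset load order and line number within a cluster.
#'
#' @param x A `linkage_result`.
#' @param ... Unused.
#' @return A tibble with `nrow(records)` rows.
#' @export
tidy.linkage_result <- function(x, ...) {
  recs <- x$records
  ds_order <- attr(recs, "dataset_order") %||% unique(recs$dataset)
  out <- dplyr::inner_join(x$assignments, recs, by = "record_uid")
  out$._ds <- match(out$dataset, ds_order)
  out <- dplyr::arrange(out, .data$cluster_id, .data$._ds, .data$row_ordinal)
  out$._ds <- NULL
  tibble::as_tibble(out[, c("cluster_id", "record_uid", "dataset", "row_ordinal",
                            attr_columns(recs))])
}

#' One-row summary of a linkage run
#'
#' @param x A `linkage_result`.
#' @param ... Unused.
#' @return A one-row tibble: record/cluster/block/pair/edge counts, the
#'   threshold, l-mer length, and the largest cluster size.
#' @export
glance.linkage_result <- function(x, ...) {
  sizes <- if (nrow(x$assignments)) table(x$assignments$cluster_id) else integer(0)
  tibble::tibble(
    n_records = as.integer(x$counts[["records"]]),
    n_exact_clusters = as.integer(x$counts[["exact_clusters"]]),
    n_blocks = as.integer(x$counts[["blocks"]]),
    n_candidate_pairs = as.integer(x$counts[["candidate_pairs"]]),
    n_edges = as.integer(x$counts[["edges"]]),
    n_clusters = as.integer(x$counts[["clusters"]]),
    largest_cluster = if (length(sizes)) as.integer(max(sizes)) else 0L,
    threshold = x$threshold,
    lmer_length = x$lmer_length
  )
}

#' Plot the cluster-size distribution of a linkage result
#'
#' Bar chart of how many clusters have 1, 2, 3, ... member records --
#' the quickest visual check that linkage neither shattered every individual
#' into singletons nor chained everyone together.
#'
#' @param object A `linkage_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_result <- function(object, ...) {
  sizes <- object$assignments |>
    dplyr::count(.data$cluster_id, name = "size") |>
    dplyr::count(.data$size, name = "n_clusters")
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$size), y = .data$n_clusters)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster size (records)", y = "number of clusters",
                  title = paste0("Cluster sizes at threshold ", object$threshold)) +
    ggplot2::theme_minimal()
}

#' Write the clustered output file
#'
#' Writes the final clusters as delimited text with a header: `Cluster ID`,
#' `File Name`, then the canonical attributes in schema order -- one row per
#' input record, missing values rendered as empty fields, values in their
#' normalised (lower-case) form.
#'
#' @param result A `linkage_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, path) {
  stopifnot(inherits(result, "linkage_result"))
  out <- tidy(result)
  out <- out[, c("cluster_id", "dataset", attr_columns(result$records))]
  names(out)[1:2] <- c("Cluster ID", "File Name")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a clustered output file back
#'
#' Re-reads a file written by [write_clusters()]; empty fields become `NA`.
#' Useful for round-trip checks on cluster membership.
#'
#' @param path File written by [write_clusters()].
#' @return A tibble with `Cluster ID`, `File Name` and attribute columns.
#' @export
read_clusters <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    `Cluster ID` = readr::col_integer(),
    .default = readr::col_character()
  ), na = "", progress = FALSE, show_col_types = FALSE)
}
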