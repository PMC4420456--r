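#' Exact-duplicate clusters
#'
#' Partitions the unified records into groups identical (as normalised text)
#' on the exact-match attributes. Real data carry few errors, so most
#' cross-file duplicates are caught here; only each group's first record (the
#' representative, smallest `record_uid`) enters blocking and linkage. Two
#' `NA` values compare equal for this grouping.
#'
#' @param records Unified record tibble (see [unify_records()]).
#' @param exact_attrs Character vector of attribute names to match on
#'   (non-empty). Typically the common attributes of all files.
#' @return A tibble `record_uid`, `exact_cluster` (1-based id ordered by
#'   representative uid), `representative_uid`, ordered by uid.
#' @examples
#' recs <- tibble::tibble(record_uid = 0:2, dataset = "a", row_ordinal = 0:2,
#'                        FirstName = c("risa", "risa", "maile"),
#'                        LastName = c("pierce", "pierce", "kramer"))
#' exact_match_clusters(recs, c("FirstName", "LastName"))
#' @export
exact_match_clusters <- function(records, exact_attrs) {
  check_records(records)
  exact_attrs <- as.character(exact_attrs)
  if (length(exact_attrs) == 0) {
    abort("`exact_attrs` must name at least one attribute",
          class = "linkclust_config_error")
  }
  bad <- setdiff(exact_attrs, attr_columns(records))
  if (length(bad)) {
    abort(paste0("unknown exact-match attribute(s): ", paste(bad, collapse = ", ")),
          class = "linkclust_config_error")
  }
  out <- records |>
    dplyr::arrange(.data$record_uid) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(exact_attrs))) |>
    dplyr::mutate(representative_uid = min(.data$record_uid)) |>
    dplyr::ungroup() |>
    dplyr::mutate(exact_cluster = dplyr::dense_rank(.data$representative_uid)) |>
    dplyr::select("record_uid", "exact_cluster", "representative_uid")
  out
}

#' Enumerate l-mers of a value
#'
#' All contiguous substrings of length `l`, left to right (a value of length
#' `L >= l` yields `L - l + 1` keys, repeats included). A value shorter than
#' `l` yields itself as the single key, so short strings still land in a
#' block.
#'
#' @param value A single string.
#' @param l Substring length, integer >= 1.
#' @return Character vector of keys (empty for `NA` input).
#' @examples
#' lmers("pierce", 3) # "pie" "ier" "erc" "rce"
#' @export
lmers <- function(value, l) {
  l <- as.integer(l)
  if (length(l) != 1 || is.na(l) || l < 1L) {
    abort("`l` must be a single integer >= 1", class = "linkclust_config_error")
  }
  value <- as.character(value)[1]
  if (is.na(value)) return(character(0))
  L <- nchar(value)
  if (L < l) return(value)
  starts <- seq_len(L - l + 1L)
  substring(value, starts, starts + l - 1L)
}

#' Default l-mer length for a threshold
#'
#' Two strings of roughly the average blocking-field length that differ by at
#' most `k` edits are cut by those edits into at most `k + 1` untouched runs;
#' by pigeonhole one run of length `floor((avg - k) / (k + 1))` survives in
#' both, so strings within the threshold are guaranteed to share a block.
#' The result is clamped to `[2, avg_block_len]` (and to >= 1 overall).
#'
#' @param avg_block_len Approximate average length of the blocking attribute
#'   (default 7 in a linkage run).
#' @param k Linkage threshold (errors endured), integer >= 0.
#' @return A single positive integer `l`.
#' @examples
#' default_lmer_length(7, 1) # 3
#' default_lmer_length(7, 0) # 7
#' @export
default_lmer_length <- function(avg_block_len, k) {
  avg_block_len <- as.integer(avg_block_len)
  k <- as.integer(k)
  if (length(avg_block_len) != 1 || is.na(avg_block_len) || avg_block_len < 1L) {
    abort("`avg_block_len` must be a single integer >= 1",
          class = "linkclust_config_error")
  }
  if (length(k) != 1 || is.na(k) || k < 0L) {
    abort("threshold `k` must be a single integer >= 0",
          class = "linkclust_config_error")
  }
  max(1L, min(avg_block_len, max(2L, (avg_block_len - k) %/% (k + 1L))))
}

#' Build l-mer blocks over representative records
#'
#' Each representative joins one block per distinct l-mer of its
#' blocking-attribute value; comparisons later happen only within blocks.
#' Representatives whose blocking value is missing are gathered in one
#' reserved block (key `""`) rather than dropped, trading a few extra
#' comparisons for recall.
#'
#' @param reps Tibble of representative records (subset of the unified
#'   records).
#' @param blocking_attr Attribute name to block on (e.g. `"LastName"`).
#' @param l l-mer length, integer >= 1.
#' @return A tibble `key`, `record_uid` (one row per block membership).
#' @export
build_blocks <- function(reps, blocking_attr, l) {
  check_records(reps)
  blocking_attr <- as.character(blocking_attr)[1]
  if (!blocking_attr %in% attr_columns(reps)) {
    abort(paste0("unknown blocking attribute: ", blocking_attr),
          class = "linkclust_config_error")
  }
  vals <- reps[[blocking_attr]]
  keys <- lapply(vals, function(v) {
    if (is.na(v)) "" else unique(lmers(v, l))
  })
  tibble::tibble(
    key = unlist(keys, use.names = FALSE) %||% character(0),
    record_uid = rep(reps$record_uid, lengths(keys))
  )
}

#' Candidate pairs from blocks
#'
#' The union over blocks of all within-block pairs, with duplicates (a pair
#' sharing several blocks) and self-pairs removed -- the edge set before
#' distance filtering, in graph terms a simple graph.
#'
#' @param blocks Block membership tibble from [build_blocks()].
#' @return A tibble `uid_a`, `uid_b` with `uid_a < uid_b`, ordered.
#' @export
candidate_pairs <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble::tibble(uid_a = integer(0), uid_b = integer(0)))
  }
  pairs <- dplyr::inner_join(blocks, blocks, by = "key",
                             relationship = "many-to-many",
                             suffix = c("_a", "_b")) |>
    dplyr::filter(.data$record_uid_a < .data$record_uid_b) |>
    dplyr::distinct(uid_a = .data$record_uid_a, uid_b = .data$record_uid_b) |>
    dplyr::arrange(.data$uid_a, .data$uid_b)
  pairs
}
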