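#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, and substitutions
#' (all unit cost) transforming one string into the other. Vectorised;
#' arguments are recycled to a common length. `NA` in either argument yields
#' `NA` -- missing-value policy is applied at the record level
#' (see [record_distance()]).
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' edit_distance("computer", "conuterr") # 3
#' edit_distance("james", "hames")       # 1
#' @export
edit_distance <- function(a, b) {
  v <- recycle2(as.character(a), as.character(b))
  levenshtein_cpp(v[[1]], v[[2]])
}

#' Reversal (field-swap) edit distance
#'
#' Handles first/last name swaps: each record's two attribute values are
#' concatenated with a comma, and the distance is the smaller of the edit
#' distance to the other record's concatenation and to its swapped
#' concatenation.
#'
#' @param a1,a2 The two attribute values of the first record.
#' @param b1,b2 The two attribute values of the second record.
#' @return Integer vector of distances.
#' @examples
#' reversal_distance("James", "Hudson", "Hudson", "Hames") # 1
#' @export
reversal_distance <- function(a1, a2, b1, b2) {
  v <- Map(as.character, list(a1, a2, b1, b2))
  n <- max(lengths(v))
  v <- lapply(v, rep_len, n)
  a <- paste(v[[1]], v[[2]], sep = ",")
  a[is.na(v[[1]]) | is.na(v[[2]])] <- NA_character_
  fwd <- paste(v[[3]], v[[4]], sep = ",")
  rev <- paste(v[[4]], v[[3]], sep = ",")
  na_b <- is.na(v[[3]]) | is.na(v[[4]])
  fwd[na_b] <- NA_character_
  rev[na_b] <- NA_character_
  pmin(levenshtein_cpp(a, fwd), levenshtein_cpp(a, rev))
}

#' Truncated edit distance
#'
#' Edit distance restricted to the first `t` characters of each value; a value
#' shorter than `t` is used whole. Handles sources that keep only initials.
#'
#' @param a,b Character vectors.
#' @param t Truncation count, a single integer >= 1.
#' @return Integer vector of distances.
#' @examples
#' truncated_distance("James", "J", 1) # 0
#' @export
truncated_distance <- function(a, b, t) {
  t <- as.integer(t)
  if (length(t) != 1 || is.na(t) || t < 1L) {
    abort("truncation count `t` must be a single integer >= 1",
          class = "linkclust_config_error")
  }
  edit_distance(substr(as.character(a), 1L, t), substr(as.character(b), 1L, t))
}

recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  if ((length(a) != n && length(a) != 1) || (length(b) != n && length(b) != 1)) {
    abort("arguments must have equal length or length 1",
          class = "linkclust_config_error")
  }
  list(rep_len(a, n), rep_len(b, n))
}

#' Comparison specifications
#'
#' A linkage run scores each candidate record pair with a sum of per-attribute
#' comparisons. Three methods are supported: plain edit distance on one
#' attribute (`cmp_edit()`), reversal distance on an attribute pair
#' (`cmp_reversal()`, for swapped fields), and truncated edit distance
#' (`cmp_truncation()`, for initials-only sources).
#'
#' @param attr,attr_a,attr_b Canonical attribute name(s); for `cmp_reversal()`
#'   the two attributes must differ.
#' @param count Truncation count (integer >= 1).
#' @return A list of class `comparison_spec`.
#' @examples
#' comps <- list(cmp_edit("LastName"), cmp_truncation("FirstName", 1))
#' @name comparison_spec
NULL

#' @rdname comparison_spec
#' @export
cmp_edit <- function(attr) {
  new_comparison("edit", attrs = as.character(attr)[1])
}

#' @rdname comparison_spec
#' @export
cmp_reversal <- function(attr_a, attr_b) {
  attr_a <- as.character(attr_a)[1]; attr_b <- as.character(attr_b)[1]
  if (identical(attr_a, attr_b)) {
    abort("reversal comparison needs two distinct attributes",
          class = "linkclust_config_error")
  }
  new_comparison("reversal", attrs = c(attr_a, attr_b))
}

#' @rdname comparison_spec
#' @export
cmp_truncation <- function(attr, count) {
  count <- as.integer(count)
  if (length(count) != 1 || is.na(count) || count < 1L) {
    abort("truncation count must be a single integer >= 1",
          class = "linkclust_config_error")
  }
  new_comparison("truncation", attrs = as.character(attr)[1], count = count)
}

new_comparison <- function(method, attrs, count = NULL) {
  structure(list(method = method, attrs = attrs, count = count),
            class = "comparison_spec")
}

#' @export
format.comparison_spec <- function(x, ...) {
  switch(x$method,
    edit = paste0("edit:", x$attrs),
    reversal = paste0("reversal:", x$attrs[1], ",", x$attrs[2]),
    truncation = paste0("truncation:", x$attrs, ":", x$count)
  )
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat("<comparison> ", format(x), "\n", sep = "")
  invisible(x)
}

as_comparison_list <- function(comparisons) {
  if (inherits(comparisons, "comparison_spec")) comparisons <- list(comparisons)
  if (!is.list(comparisons) || length(comparisons) == 0 ||
      !all(vapply(comparisons, inherits, logical(1), "comparison_spec"))) {
    abort("`comparisons` must be a non-empty list of comparison specs (cmp_edit() etc.)",
          class = "linkclust_config_error")
  }
  comparisons
}

check_comparisons <- function(comparisons, attrs) {
  comparisons <- as_comparison_list(comparisons)
  for (cmp in comparisons) {
    missing <- setdiff(cmp$attrs, attrs)
    if (length(missing)) {
      abort(paste0("comparison '", format(cmp), "' refers to unknown attribute(s): ",
                   paste(missing, collapse = ", ")),
            class = "linkclust_config_error")
    }
  }
  comparisons
}

# Per-pair contribution of one comparison, given the two records' attribute
# vectors. `missing` policy: "ignore" -> a comparison with any NA input
# contributes 0; "empty" -> NA is treated as the empty string.
comparison_contrib <- function(cmp, va, vb, missing) {
  if (missing == "empty") {
    va <- lapply(va, function(x) dplyr::coalesce(x, ""))
    vb <- lapply(vb, function(x) dplyr::coalesce(x, ""))
  }
  d <- switch(cmp$method,
    edit = edit_distance(va[[1]], vb[[1]]),
    truncation = truncated_distance(va[[1]], vb[[1]], cmp$count),
    reversal = reversal_distance(va[[1]], va[[2]], vb[[1]], vb[[2]])
  )
  dplyr::coalesce(d, 0L)
}

# Vectorised record distance over a table of uid pairs.
pair_distances <- function(records, pairs, comparisons, missing = "ignore") {
  if (nrow(pairs) == 0) return(integer(0))
  ia <- match(pairs$uid_a, records$record_uid)
  ib <- match(pairs$uid_b, records$record_uid)
  total <- integer(nrow(pairs))
  for (cmp in comparisons) {
    va <- lapply(cmp$attrs, function(a) records[[a]][ia])
    vb <- lapply(cmp$attrs, function(a) records[[a]][ib])
    total <- total + comparison_contrib(cmp, va, vb, missing)
  }
  total
}

#' Total distance between two records
#'
#' Sums the configured per-attribute comparisons between two records; the
#' result is the error count compared against the linkage threshold. By
#' default a comparison touching a missing (`NA`) value contributes 0 errors,
#' so sparse sources are never penalised for attributes they do not carry;
#' `missing = "empty"` instead treats `NA` as the empty string.
#'
#' @param record_a,record_b One-row data frames (or named lists/vectors) with
#'   the compared attribute fields.
#' @param comparisons List of [comparison_spec] objects.
#' @param missing `"ignore"` (default) or `"empty"`.
#' @return A single non-negative integer.
#' @examples
#' a <- tibble::tibble(FirstName = "james", LastName = "rodriguez")
#' b <- tibble::tibble(FirstName = "hames", LastName = "rodriuez")
#' record_distance(a, b, list(cmp_edit("FirstName"), cmp_edit("LastName"))) # 2
#' @export
record_distance <- function(record_a, record_b, comparisons,
                            missing = c("ignore", "empty")) {
  missing <- match.arg(missing)
  comparisons <- as_comparison_list(comparisons)
  record_a <- as.list(record_a); record_b <- as.list(record_b)
  attrs <- unique(unlist(lapply(comparisons, `[[`, "attrs")))
  for (a in attrs) {
    if (is.null(record_a[[a]]) || is.null(record_b[[a]])) {
      abort(paste0("both records must carry compared attribute '", a, "'"),
            class = "linkclust_config_error")
    }
  }
  total <- 0L
  for (cmp in comparisons) {
    va <- lapply(cmp$attrs, function(a) as.character(record_a[[a]])[1])
    vb <- lapply(cmp$attrs, function(a) as.character(record_b[[a]])[1])
    total <- total + comparison_contrib(cmp, va, vb, missing)
  }
  total
}
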