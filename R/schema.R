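#' Define the canonical attribute schema
#'
#' Record linkage across files with different column layouts needs one shared,
#' ordered list of attribute names (e.g. `ID`, `FirstName`, `LastName`, ...).
#' Every input file is mapped onto this schema; its order is the output column
#' order.
#'
#' @param names Character vector of unique, non-empty attribute names.
#' @return A character vector of class `attribute_schema`.
#' @examples
#' attribute_schema(c("ID", "FirstName", "LastName", "SSN"))
#' @export
attribute_schema <- function(names) {
  names <- as.character(names)
  if (length(names) == 0 || anyNA(names) || any(!nzchar(names))) {
    abort("schema attribute names must be non-empty", class = "linkclust_config_error")
  }
  if (anyDuplicated(names)) {
    abort("schema attribute names must be unique", class = "linkclust_config_error")
  }
  structure(names, class = c("attribute_schema", "character"))
}

#' Describe one input file and its column mapping
#'
#' Each dataset is a header-less delimited text file whose columns are mapped,
#' attribute by attribute, onto the canonical schema. An index of `-1` marks an
#' attribute the file does not carry; such values become missing (`NA`) on the
#' unified schema.
#'
#' @param path Path to the delimited text file (`.csv`/`.txt`, comma-separated,
#'   one record per line, no header unless `skip_header`).
#' @param index_map Integer vector, one entry per schema attribute: the 0-based
#'   source column index, or `-1` if the attribute is absent from this file.
#' @param label Dataset label used in the output (defaults to the file name).
#' @param skip_header If `TRUE`, the first line of the file is dropped.
#' @return A list of class `dataset_spec`.
#' @examples
#' dataset_spec("Input02.csv", c(0, 1, 2, 3, -1, -1, -1, -1, -1))
#' @export
dataset_spec <- function(path, index_map, label = basename(path), skip_header = FALSE) {
  index_map <- as.integer(index_map)
  if (anyNA(index_map) || any(index_map < -1L)) {
    abort("index_map entries must be >= 0, or -1 for an absent attribute",
          class = "linkclust_config_error")
  }
  mapped <- index_map[index_map >= 0L]
  if (length(mapped) == 0) {
    abort(paste0("dataset '", label, "': at least one attribute must be mapped"),
          class = "linkclust_config_error")
  }
  if (anyDuplicated(mapped)) {
    abort(paste0("dataset '", label, "': mapped column indices must be unique"),
          class = "linkclust_config_error")
  }
  structure(
    list(path = path, index_map = index_map, label = as.character(label),
         skip_header = isTRUE(skip_header)),
    class = "dataset_spec"
  )
}

#' Normalise an attribute value
#'
#' Trims surrounding whitespace and folds to lower case, so matching is
#' case-insensitive; empty strings become `NA` (the missing marker).
#' Idempotent. Values are always text -- leading zeros are preserved verbatim.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @examples
#' normalize_value(c("Mcclain", "  RISA ", ""))
#' @export
normalize_value <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

#' Read one dataset onto the canonical schema
#'
#' Reads a header-less comma-separated file and aligns its columns to the
#' schema through the spec's `index_map`. Values are normalised
#' ([normalize_value()]); unmapped attributes are `NA`.
#'
#' @param spec A [dataset_spec()].
#' @param schema An [attribute_schema()].
#' @return A tibble with columns `dataset`, `row_ordinal` (0-based line number)
#'   and one character column per schema attribute. No `record_uid` yet --
#'   uids are assigned globally by [unify_records()].
#' @export
read_dataset <- function(spec, schema) {
  stopifnot(inherits(spec, "dataset_spec"))
  schema <- as_schema(schema)
  if (length(spec$index_map) != length(schema)) {
    abort(paste0("dataset '", spec$label, "': index_map has ", length(spec$index_map),
                 " entries but the schema has ", length(schema), " attributes"),
          class = "linkclust_config_error")
  }
  if (!file.exists(spec$path)) {
    abort(paste0("input file not found: ", spec$path), class = "linkclust_input_error")
  }
  raw <- suppressWarnings(readr::read_csv(
    spec$path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    skip = if (spec$skip_header) 1L else 0L,
    na = character(), progress = FALSE, show_col_types = FALSE
  ))
  need <- max(spec$index_map) + 1L
  if (nrow(raw) == 0) {
    vals <- rep(list(character(0)), length(schema))
    names(vals) <- as.character(schema)
    return(dplyr::bind_cols(
      tibble::tibble(dataset = character(0), row_ordinal = integer(0)),
      tibble::as_tibble(vals)
    ))
  }
  nfields <- readr::count_fields(spec$path, readr::tokenizer_csv(),
                                 skip = if (spec$skip_header) 1L else 0L)
  bad <- which(nfields < need)
  if (length(bad)) {
    abort(paste0("parse error in '", spec$label, "', line ", bad[1],
                 ": expected at least ", need, " comma-separated fields"),
          class = "linkclust_parse_error")
  }
  vals <- lapply(seq_along(schema), function(i) {
    idx <- spec$index_map[i]
    if (idx < 0L) rep(NA_character_, nrow(raw)) else normalize_value(raw[[idx + 1L]])
  })
  names(vals) <- as.character(schema)
  out <- tibble::tibble(
    dataset = rep(spec$label, nrow(raw)),
    row_ordinal = seq_len(nrow(raw)) - 1L
  )
  dplyr::bind_cols(out, tibble::as_tibble(vals))
}

#' Merge all datasets into one unified record table
#'
#' Concatenates the datasets, in the given order, as if they were one file, and
#' assigns each record a global `record_uid` (0-based, in load order). The set
#' of attributes mapped in every dataset is attached as
#' `attr(, "common_attrs")` -- linkage comparisons operate on these.
#'
#' @param specs A list of [dataset_spec()] objects (labels must be unique).
#' @param schema An [attribute_schema()].
#' @return A tibble of unified records: `record_uid`, `dataset`, `row_ordinal`,
#'   then one column per schema attribute.
#' @export
unify_records <- function(specs, schema) {
  specs <- as_spec_list(specs)
  schema <- as_schema(schema)
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    abort("dataset labels must be unique across inputs", class = "linkclust_config_error")
  }
  parts <- lapply(specs, read_dataset, schema = schema)
  out <- dplyr::bind_rows(parts)
  out <- dplyr::bind_cols(tibble::tibble(record_uid = seq_len(nrow(out)) - 1L), out)
  attr(out, "common_attrs") <- common_attributes(specs, schema)
  attr(out, "dataset_order") <- labels
  out
}

#' Attributes mapped in every dataset
#'
#' Linkage comparisons and default exact matching work on the attributes shared
#' by all input files.
#'
#' @inheritParams unify_records
#' @return Character vector of attribute names mapped (index != -1) in every
#'   dataset, in schema order.
#' @export
common_attributes <- function(specs, schema) {
  specs <- as_spec_list(specs)
  schema <- as_schema(schema)
  if (length(specs) == 0) abort("at least one dataset is required",
                                class = "linkclust_config_error")
  keep <- rep(TRUE, length(schema))
  for (s in specs) {
    if (length(s$index_map) != length(schema)) {
      abort(paste0("dataset '", s$label, "': index_map length does not match schema"),
            class = "linkclust_config_error")
    }
    keep <- keep & (s$index_map >= 0L)
  }
  as.character(schema)[keep]
}

as_schema <- function(schema) {
  if (inherits(schema, "attribute_schema")) schema else attribute_schema(schema)
}

as_spec_list <- function(specs) {
  if (inherits(specs, "dataset_spec")) specs <- list(specs)
  if (!is.list(specs) || !all(vapply(specs, inherits, logical(1), "dataset_spec"))) {
    abort("`specs` must be a dataset_spec or a list of them",
          class = "linkclust_config_error")
  }
  specs
}

# attribute columns of a unified record tibble
attr_columns <- function(records) {
  setdiff(names(records), c("record_uid", "dataset", "row_ordinal"))
}

check_records <- function(records) {
  if (!is.data.frame(records) || !all(c("record_uid", "dataset", "row_ordinal") %in% names(records))) {
    abort("`records` must be a unified record tibble (see unify_records())",
          class = "linkclust_config_error")
  }
  if (anyDuplicated(records$record_uid)) {
    abort("record_uid values must be unique", class = "linkclust_config_error")
  }
  invisible(records)
}
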