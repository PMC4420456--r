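#' Parse a comparison from its compact text form
#'
#' The CLI and config files write comparisons as `edit:ATTR`,
#' `reversal:ATTR_A,ATTR_B`, or `truncation:ATTR:COUNT`.
#'
#' @param text A single comparison string.
#' @return A [comparison_spec].
#' @examples
#' parse_comparison("truncation:FirstName:1")
#' @export
parse_comparison <- function(text) {
  parts <- strsplit(as.character(text)[1], ":", fixed = TRUE)[[1]]
  method <- tolower(parts[1])
  if (method == "edit" && length(parts) == 2) {
    return(cmp_edit(parts[2]))
  }
  if (method == "reversal" && length(parts) == 2) {
    ab <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    if (length(ab) == 2) return(cmp_reversal(trimws(ab[1]), trimws(ab[2])))
  }
  if (method == "truncation" && length(parts) == 3) {
    count <- suppressWarnings(as.integer(parts[3]))
    if (is.na(count) || count < 1L) {
      abort(paste0("comparison '", text, "': truncation count must be an integer >= 1"),
            class = "linkclust_config_error")
    }
    return(cmp_truncation(parts[2], count))
  }
  abort(paste0("cannot parse comparison '", text,
               "'; expected edit:ATTR, reversal:A,B or truncation:ATTR:COUNT"),
        class = "linkclust_config_error")
}

#' Assemble and validate a full run configuration
#'
#' Cross-checks every field the linkage run needs: dataset specs against the
#' schema, comparisons and the blocking attribute against the common
#' attributes. Defaults mirror the original tool: threshold 1,
#' average blocking-field length 7.
#'
#' @param datasets List of [dataset_spec()] objects.
#' @param attributes Canonical attribute names ([attribute_schema()] or
#'   character vector).
#' @param comparisons List of [comparison_spec] objects or compact strings.
#' @param blocking_attr Attribute name to block on.
#' @param threshold Error threshold (default 1).
#' @param avg_block_len Average blocking-field length (default 7).
#' @param lmer_length Optional explicit l-mer length.
#' @param exact_attrs Optional exact-match attribute names.
#' @param output Optional output file path for [write_clusters()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(datasets, attributes, comparisons, blocking_attr,
                       threshold = 1L, avg_block_len = 7L, lmer_length = NULL,
                       exact_attrs = NULL, output = NULL) {
  schema <- as_schema(attributes)
  datasets <- as_spec_list(datasets)
  for (s in datasets) {
    if (length(s$index_map) != length(schema)) {
      abort(paste0("dataset '", s$label, "': index_map has ", length(s$index_map),
                   " entries for ", length(schema), " attributes"),
            class = "linkclust_config_error")
    }
  }
  comparisons <- lapply(comparisons, function(cmp) {
    if (is.character(cmp)) parse_comparison(cmp) else cmp
  })
  common <- common_attributes(datasets, schema)
  comparisons <- check_comparisons(comparisons, common)
  blocking_attr <- as.character(blocking_attr)[1]
  if (!blocking_attr %in% common) {
    abort(paste0("blocking attribute '", blocking_attr,
                 "' is not a common attribute (common: ",
                 paste(common, collapse = ", "), ")"),
          class = "linkclust_config_error")
  }
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L) {
    abort("field `threshold` must be an integer >= 0", class = "linkclust_config_error")
  }
  if (!is.null(exact_attrs)) {
    bad <- setdiff(as.character(exact_attrs), as.character(schema))
    if (length(bad)) {
      abort(paste0("field `exact_attrs` names unknown attribute(s): ",
                   paste(bad, collapse = ", ")),
            class = "linkclust_config_error")
    }
  }
  structure(
    list(datasets = datasets, schema = schema, comparisons = comparisons,
         blocking_attr = blocking_attr, threshold = threshold,
         avg_block_len = as.integer(avg_block_len),
         lmer_length = if (is.null(lmer_length)) NULL else as.integer(lmer_length),
         exact_attrs = exact_attrs, output = output),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file carries the same keys as the CLI flags: `attributes` (list),
#' `inputs` (list of `path` / optional `label` / `map` / optional
#' `skip_header`), `comparisons` (compact strings), `block_attr`, and
#' optional `threshold`, `avg_block_len`, `lmer_length`, `exact_attrs`,
#' `output`. Relative input paths are resolved against the config file's
#' directory.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "linkclust_input_error")
  }
  y <- yaml::read_yaml(path)
  for (field in c("attributes", "inputs", "comparisons", "block_attr")) {
    if (is.null(y[[field]])) {
      abort(paste0("config is missing required field `", field, "`"),
            class = "linkclust_config_error")
    }
  }
  base <- dirname(normalizePath(path))
  datasets <- lapply(y$inputs, function(inp) {
    if (is.null(inp$path) || is.null(inp$map)) {
      abort("each entry of `inputs` needs `path` and `map`",
            class = "linkclust_config_error")
    }
    p <- inp$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    dataset_spec(p, unlist(inp$map), label = inp$label %||% basename(inp$path),
                 skip_header = isTRUE(inp$skip_header))
  })
  run_config(
    datasets = datasets,
    attributes = unlist(y$attributes),
    comparisons = as.list(unlist(y$comparisons)),
    blocking_attr = y$block_attr,
    threshold = y$threshold %||% 1L,
    avg_block_len = y$avg_block_len %||% 7L,
    lmer_length = y$lmer_length,
    exact_attrs = if (is.null(y$exact_attrs)) NULL else unlist(y$exact_attrs),
    output = y$output
  )
}

#' Execute a validated run configuration
#'
#' Runs the full pipeline described by a `run_config` and, if the config sets
#' `output`, writes the clustered file.
#'
#' @param config A `run_config` (see [run_config()], [read_run_config()]).
#' @param verbose Log per-phase counts.
#' @return The `linkage_result`, invisibly if an output file was written.
#' @export
execute_config <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  res <- link_records(
    config$datasets, config$schema, config$comparisons, config$blocking_attr,
    threshold = config$threshold, avg_block_len = config$avg_block_len,
    lmer_length = config$lmer_length, exact_attrs = config$exact_attrs,
    verbose = verbose
  )
  if (!is.null(config$output)) {
    write_clusters(res, config$output)
    return(invisible(res))
  }
  res
}
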