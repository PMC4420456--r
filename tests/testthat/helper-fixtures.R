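# Shared fixtures: the three-file worked example shipped in extdata, and
# random-instance builders for the property suites.

example_schema <- function() {
  attribute_schema(c("ID", "FirstName", "LastName", "SSN", "DateOfBirth",
                     "Gender", "SchoolID", "MiddleName", "SSID"))
}

example_datasets <- function() {
  extdata <- system.file("extdata", package = "linkclust")
  list(
    dataset_spec(file.path(extdata, "Input01.csv"), c(0, 1, 2, 3, 4, 5, 6, 7, 8)),
    dataset_spec(file.path(extdata, "Input02.csv"), c(0, 1, 2, 3, -1, -1, -1, -1, -1)),
    dataset_spec(file.path(extdata, "Input03.csv"), c(0, 1, 2, -1, 3, 4, 5, 6, 7))
  )
}

example_comparisons <- function() {
  list(cmp_edit("LastName"), cmp_truncation("FirstName", 1))
}

# Expected final partition of the worked example, as {file, row} sets
# (membership only; row order within clusters is not asserted).
expected_example_membership <- function() {
  list(
    c("Input01.csv:0", "Input02.csv:0", "Input03.csv:0"),
    c("Input01.csv:1", "Input02.csv:1", "Input03.csv:1"),
    c("Input01.csv:2", "Input02.csv:2", "Input03.csv:2"),
    c("Input01.csv:3", "Input02.csv:3"),
    c("Input01.csv:4", "Input03.csv:3"),
    c("Input02.csv:4", "Input03.csv:4")
  )
}

# Canonical form of a partition: sorted list of sorted member keys, so two
# partitions can be compared with expect_setequal semantics.
partition_keys <- function(tidied) {
  keys <- paste0(tidied$dataset, ":", tidied$row_ordinal)
  parts <- split(keys, tidied$cluster_id)
  unname(lapply(parts, sort))
}

partition_of <- function(assignments, id_col = "component") {
  parts <- split(assignments$record_uid, assignments[[id_col]])
  unname(lapply(parts, sort))
}

same_partition <- function(a, b) {
  setequal(lapply(a, paste, collapse = "|"), lapply(b, paste, collapse = "|"))
}

random_string <- function(len, alphabet = letters[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A hand-built unified record table of n records with random short names;
# some exact duplicates are injected so the exact-match phase is exercised.
random_instance <- function(n, alphabet = letters[1:6], dup_rate = 0.2) {
  first <- vapply(seq_len(n), function(i) random_string(sample(4:8, 1), alphabet),
                  character(1))
  last <- vapply(seq_len(n), function(i) random_string(sample(4:8, 1), alphabet),
                 character(1))
  ndup <- floor(n * dup_rate)
  if (ndup > 0 && n > ndup) {
    src <- sample(seq_len(n - ndup), ndup, replace = TRUE)
    tgt <- seq.int(n - ndup + 1L, n)
    first[tgt] <- first[src]
    last[tgt] <- last[src]
  }
  tibble::tibble(record_uid = seq_len(n) - 1L, dataset = "rand",
                 row_ordinal = seq_len(n) - 1L,
                 FirstName = first, LastName = last)
}

# Brute-force recursive Levenshtein distance: the independent oracle for the
# dynamic-programming implementation, usable only at tiny lengths.
lev_brute <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  rest_a <- substr(a, 2, nchar(a))
  rest_b <- substr(b, 2, nchar(b))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_brute(rest_a, b) + 1L,
      lev_brute(a, rest_b) + 1L,
      lev_brute(rest_a, rest_b) + cost)
}

all_strings_up_to <- function(max_len, alphabet) {
  out <- ""
  acc <- list("")
  for (len in seq_len(max_len)) {
    prev <- acc[[len]]
    acc[[len + 1L]] <- as.vector(outer(prev, alphabet, paste0))
  }
  unlist(acc)
}

write_tmp_csv <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
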