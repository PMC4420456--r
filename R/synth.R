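# Built-in name vocabularies keep the generator download-free; 60 x 60
# first/last combinations are sampled without replacement so distinct
# individuals always differ on the compared name attributes.
.first_names <- c(
  "risa", "maile", "kimberly", "kamal", "yvonne", "kelsie", "james", "maria",
  "robert", "linda", "michael", "barbara", "william", "elizabeth", "david",
  "jennifer", "richard", "susan", "joseph", "jessica", "thomas", "sarah",
  "charles", "karen", "christopher", "nancy", "daniel", "lisa", "matthew",
  "betty", "anthony", "margaret", "mark", "sandra", "donald", "ashley",
  "steven", "dorothy", "paul", "emily", "andrew", "donna", "joshua", "carol",
  "kenneth", "ruth", "kevin", "sharon", "brian", "laura", "george", "amanda",
  "edward", "stephanie", "ronald", "cynthia", "timothy", "kathleen", "jason",
  "amy")
.last_names <- c(
  "pierce", "kramer", "battle", "mcclain", "vaughan", "mueller", "rodriguez",
  "hudson", "smith", "johnson", "williams", "brown", "jones", "garcia",
  "miller", "davis", "martinez", "hernandez", "lopez", "gonzalez", "wilson",
  "anderson", "thomas", "taylor", "moore", "jackson", "martin", "lee",
  "perez", "thompson", "white", "harris", "sanchez", "clark", "ramirez",
  "lewis", "robinson", "walker", "young", "allen", "king", "wright", "scott",
  "torres", "nguyen", "hill", "flores", "green", "adams", "nelson", "baker",
  "hall", "rivera", "campbell", "mitchell", "carter", "roberts", "gomez",
  "phillips", "evans")

.canonical_schema <- c("ID", "FirstName", "LastName", "SSN", "DateOfBirth",
                       "Gender", "SchoolID", "MiddleName", "SSID")

# Per-file attribute subsets emulating a full registry, an initials-and-SSN
# extract, and a no-SSN extract (the shapes of the worked example's three
# files).
.default_file_attrs <- list(
  c("ID", "FirstName", "LastName", "SSN", "DateOfBirth", "Gender", "SchoolID",
    "MiddleName", "SSID"),
  c("ID", "FirstName", "LastName", "SSN"),
  c("ID", "FirstName", "LastName", "DateOfBirth", "Gender", "SchoolID",
    "MiddleName", "SSID")
)

#' Specify a synthetic multi-file person dataset
#'
#' Describes the ground truth the generator emits: `n_individuals` people
#' spread over `n_files` files with differing attribute subsets, with
#' controlled corruption of the name fields. The first file is a clean,
#' complete master source; later files may drop individuals and corrupt
#' records, emulating the error kinds the three comparison methods target
#' (typos, swapped first/last names, truncation to an initial).
#'
#' @param n_individuals Number of distinct people (<= 3600).
#' @param n_files Number of files (default 3).
#' @param file_attrs Optional list of per-file attribute subsets (character
#'   vectors over the built-in 9-attribute schema); defaults to shapes like a
#'   full registry plus two partial extracts.
#' @param max_errors Per-record corruption budget `e`: each record in a
#'   corrupted file receives between 0 and `e` operations (default 1).
#' @param mix Named probabilities for the corruption operations
#'   `substitution`, `insertion`, `deletion`, `swap` (first/last name),
#'   `truncation` (first name to initial); must sum to 1.
#' @param p_missing_row Probability an individual is absent from a given
#'   non-master file (default 0.1).
#' @param corrupt_first_file If `TRUE`, the first file is corrupted like the
#'   others (default `FALSE`: it is a clean master).
#' @param seed Integer seed fixing the full output (default 1).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_individuals = 50L, n_files = 3L, file_attrs = NULL,
                       max_errors = 1L,
                       mix = c(substitution = 0.5, insertion = 0.2,
                               deletion = 0.2, swap = 0.05, truncation = 0.05),
                       p_missing_row = 0.1, corrupt_first_file = FALSE,
                       seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  n_files <- as.integer(n_files)
  if (n_individuals < 1L || n_individuals > 3600L) {
    abort("`n_individuals` must be between 1 and 3600", class = "linkclust_config_error")
  }
  if (n_files < 1L) abort("`n_files` must be >= 1", class = "linkclust_config_error")
  file_attrs <- file_attrs %||%
    rep_len(.default_file_attrs, n_files)[seq_len(n_files)]
  if (length(file_attrs) != n_files) {
    abort("`file_attrs` must have one attribute subset per file",
          class = "linkclust_config_error")
  }
  for (fa in file_attrs) {
    bad <- setdiff(fa, .canonical_schema)
    if (length(bad)) {
      abort(paste0("unknown attribute(s) in file_attrs: ", paste(bad, collapse = ", ")),
            class = "linkclust_config_error")
    }
  }
  need <- c("substitution", "insertion", "deletion", "swap", "truncation")
  if (!all(need %in% names(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("`mix` must be non-negative probabilities over substitution, insertion, deletion, swap, truncation summing to 1",
          class = "linkclust_config_error")
  }
  if (max_errors < 0L) abort("`max_errors` must be >= 0", class = "linkclust_config_error")
  if (p_missing_row < 0 || p_missing_row > 1) {
    abort("`p_missing_row` must be in [0, 1]", class = "linkclust_config_error")
  }
  structure(
    list(n_individuals = n_individuals, n_files = n_files,
         file_attrs = file_attrs, max_errors = as.integer(max_errors),
         mix = mix[need], p_missing_row = p_missing_row,
         corrupt_first_file = isTRUE(corrupt_first_file), seed = as.integer(seed)),
    class = "synth_spec"
  )
}

rand_digits <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(0:9, width, replace = TRUE), collapse = "")
  }, character(1))
}

# one clean record per individual, all lower case (corruption operates after
# normalisation, so injected error counts equal measured edit distances)
synth_individuals <- function(n) {
  combos <- sample.int(length(.first_names) * length(.last_names), n)
  fi <- ((combos - 1L) %% length(.first_names)) + 1L
  li <- ((combos - 1L) %/% length(.first_names)) + 1L
  tibble::tibble(
    individual = seq_len(n),
    ID = as.character(seq_len(n)),
    FirstName = .first_names[fi],
    LastName = .last_names[li],
    SSN = rand_digits(n, 9),
    DateOfBirth = sprintf("%02d%02d%04d", sample(1:12, n, TRUE),
                          sample(1:28, n, TRUE), sample(1950:2010, n, TRUE)),
    Gender = sample(c("m", "f"), n, TRUE),
    SchoolID = rand_digits(n, 4),
    MiddleName = sample(.first_names, n, TRUE),
    SSID = rand_digits(n, 10)
  )
}

apply_typo <- function(value, op) {
  chars <- strsplit(value, "")[[1]]
  alphabet <- letters
  if (length(chars) == 0) return(sample(alphabet, 1))
  pos <- sample.int(length(chars), 1)
  if (op == "substitution") {
    repl <- sample(setdiff(alphabet, chars[pos]), 1)
    chars[pos] <- repl
  } else if (op == "insertion") {
    chars <- append(chars, sample(alphabet, 1), after = pos - 1L)
  } else if (op == "deletion" && length(chars) > 1) {
    chars <- chars[-pos]
  }
  paste(chars, collapse = "")
}

corrupt_record <- function(rec, spec) {
  n_err <- sample.int(spec$max_errors + 1L, 1) - 1L
  if (n_err == 0L) return(rec)
  ops <- sample(names(spec$mix), n_err, replace = TRUE, prob = spec$mix)
  for (op in ops) {
    if (op == "swap") {
      tmp <- rec$FirstName; rec$FirstName <- rec$LastName; rec$LastName <- tmp
    } else if (op == "truncation") {
      rec$FirstName <- substr(rec$FirstName, 1, 1)
    } else {
      field <- sample(c("FirstName", "LastName"), 1)
      rec[[field]] <- apply_typo(rec[[field]], op)
    }
  }
  rec
}

#' Generate synthetic person files with ground truth
#'
#' Writes `n_files` header-less comma-separated files under `dir`, each
#' carrying its own attribute subset of the built-in 9-attribute schema,
#' plus a `truth.csv` sidecar mapping each written row to its individual.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return A list: `datasets` (list of [dataset_spec()] ready for
#'   [link_records()]), `schema` (the canonical [attribute_schema()]),
#'   `truth` (tibble `dataset`, `row_ordinal`, `individual`), `truth_path`.
#' @examples
#' \donttest{
#' out <- generate_synthetic(synth_spec(n_individuals = 10, seed = 42),
#'                           dir = tempfile("synth"))
#' res <- link_records(out$datasets, out$schema,
#'                     list(cmp_edit("FirstName"), cmp_edit("LastName")),
#'                     blocking_attr = "LastName", threshold = 2)
#' evaluate_linkage(res, out$truth)
#' }
#' @export
generate_synthetic <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)

  people <- synth_individuals(spec$n_individuals)
  datasets <- vector("list", spec$n_files)
  truth_parts <- vector("list", spec$n_files)
  for (f in seq_len(spec$n_files)) {
    attrs <- spec$file_attrs[[f]]
    is_master <- (f == 1L) && !spec$corrupt_first_file
    keep <- if (is_master) rep(TRUE, nrow(people))
            else stats::runif(nrow(people)) >= spec$p_missing_row
    rows <- people[keep, , drop = FALSE]
    if (!is_master && spec$max_errors > 0L && nrow(rows) > 0) {
      for (i in seq_len(nrow(rows))) {
        rec <- as.list(rows[i, c("FirstName", "LastName")])
        rec <- corrupt_record(rec, spec)
        rows$FirstName[i] <- rec$FirstName
        rows$LastName[i] <- rec$LastName
      }
    }
    label <- sprintf("Synth%02d.csv", f)
    path <- file.path(dir, label)
    body <- rows[, attrs, drop = FALSE]
    readr::write_csv(body, path, col_names = FALSE, na = "")
    index_map <- ifelse(.canonical_schema %in% attrs,
                        match(.canonical_schema, attrs) - 1L, -1L)
    index_map[is.na(index_map)] <- -1L
    datasets[[f]] <- dataset_spec(path, index_map, label = label)
    truth_parts[[f]] <- tibble::tibble(
      dataset = label,
      row_ordinal = seq_len(nrow(rows)) - 1L,
      individual = rows$individual
    )
  }
  truth <- dplyr::bind_rows(truth_parts)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(truth, truth_path)
  list(datasets = datasets, schema = attribute_schema(.canonical_schema),
       truth = truth, truth_path = truth_path)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Pairwise precision, recall and F1 against ground truth
#'
#' Scores a clustering against known individual labels over record pairs: of
#' all pairs placed in one cluster, how many truly belong to one individual
#' (precision), and of all true same-individual pairs, how many were linked
#' (recall). Conventions: precision is 1 when no pair was predicted, recall
#' is 1 when the truth has no duplicate.
#'
#' @param result A `linkage_result`, or a tibble with columns `cluster_id`,
#'   `dataset`, `row_ordinal`.
#' @param truth Tibble `dataset`, `row_ordinal`, `individual` covering every
#'   record.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_linkage <- function(result, truth) {
  assigned <- if (inherits(result, "linkage_result")) tidy(result) else result
  stopifnot(all(c("cluster_id", "dataset", "row_ordinal") %in% names(assigned)),
            all(c("dataset", "row_ordinal", "individual") %in% names(truth)))
  joined <- dplyr::inner_join(
    assigned[, c("cluster_id", "dataset", "row_ordinal")],
    truth, by = c("dataset", "row_ordinal")
  )
  if (nrow(joined) != nrow(assigned)) {
    abort("truth labels must cover every clustered record",
          class = "linkclust_config_error")
  }
  pairs_of <- function(n) n * (n - 1) / 2
  pred <- sum(pairs_of(table(joined$cluster_id)))
  true <- sum(pairs_of(table(joined$individual)))
  tp <- joined |>
    dplyr::count(.data$cluster_id, .data$individual) |>
    dplyr::summarise(tp = sum(pairs_of(.data$n))) |>
    dplyr::pull(tp)
  fp <- pred - tp
  fn <- true - tp
  precision <- if (pred == 0) 1 else tp / pred
  recall <- if (true == 0) 1 else tp / true
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}
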