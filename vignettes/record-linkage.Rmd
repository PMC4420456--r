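---
title: "Methods: single-linkage record linkage with l-mer blocking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-linkage record linkage with l-mer blocking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkclust)
```

## The problem and the model

Multiple files describe overlapping sets of people, each with its own column
layout: some carry a social-security number, some only initials, some no
date of birth. `linkclust` treats linkage as a clustering problem on the
union of all records. Two records are *linked* when their total comparison
distance is at most an error threshold $k$; an individual's cluster is a
connected component of the link graph — equivalently a single-linkage
hierarchical cluster, because single linkage merges two groups exactly when
their closest pair is within the cut height. The package computes the
components directly (union-find with path halving) and ships the all-pairs
`single_linkage_oracle()` (built on `stats::hclust` + `cutree`) purely as an
independent cross-check used by the test suite.

The inclusive edge rule (distance $\le k$, not $< k$) is forced by the
intended threshold semantics: $k$ is "how many errors the linkage endures",
so a pair with exactly $k$ errors must be linked. `cutree(h = k)` keeps
merges at height $\le k$, so the oracle and the graph agree on ties.

## Distances

All values are normalised at ingest: trimmed, lower-cased, empty fields
become `NA`. Values are always text — leading zeros in identifiers are
preserved verbatim, the information-lossless choice (`"001524"` and `"1524"`
stay distinct values; in practice this never changes membership because
identifier columns are compared for equality, not parsed as numbers).

Three comparison methods, each contributing a non-negative integer:

* `edit_distance(a, b)` — Levenshtein distance, unit costs for insertion,
  deletion, substitution. Implemented as a two-row dynamic programme in C++;
  the test suite checks it exhaustively against a brute-force recursion (all
  string pairs up to length 3 over `{a,b,c}`) and against `utils::adist`
  (all pairs up to length 6).
* `reversal_distance(a1, a2, b1, b2)` — the two attribute values of each
  record are concatenated with a comma, and the distance is
  `min(ed(a1,a2 ; b1,b2), ed(a1,a2 ; b2,b1))`. The comma separator matters
  only up to a constant and makes the concatenation unambiguous. We compare
  the concatenations rather than the swapped fields pairwise; the two
  readings agree on pure swaps, and the concatenation reading degrades more
  gracefully when a typo co-occurs with a swap.
* `truncated_distance(a, b, t)` — edit distance of the length-`t` prefixes,
  a value shorter than `t` being used whole. With `t = 1` this matches
  initials-only sources at zero cost.

`record_distance()` is the sum of the configured comparisons.

**Missing values.** A comparison any of whose inputs is `NA` contributes 0
by default. A file that simply does not carry an attribute must not be
penalised for it — any penalty would split clusters that sparse sources
should join (the worked example's initials-and-SSN file lacks five of the
nine attributes). The alternative policy `missing = "empty"` treats `NA` as
`""`, which charges the full length of the present value; it is exposed for
users who want missingness to count as disagreement, but it is not the
default precisely because it breaks the sparse-file case.

## Exact matching

Records identical on the exact-match attributes are collapsed first and only
representatives (the first record of each group, by global uid) proceed;
real data carry few errors, so this removes most duplicates cheaply. The
default exact-match attribute set is the *common* attributes — those mapped
in every file. Matching on all nine canonical attributes would be stricter
but mostly useless across files with different layouts, since a present
value never equals `NA`; matching on common attributes reproduces the
intended behaviour on the worked example (15 records collapse to 11
groups). The set is configurable (`exact_attrs`) because including an ID
column is semantically questionable when IDs are not coordinated across
sources. Two `NA`s compare equal in this grouping, so records from files
sharing a missingness pattern can still be exact duplicates.

## Blocking

Comparing all representative pairs is quadratic; blocking on the distinct
l-mers (substrings of length $l$) of one attribute restricts comparisons to
records sharing an l-mer. A value of length $L \ge l$ occupies at most
$L - l + 1$ blocks; shorter values fall back to a single whole-value key, and
representatives with a missing blocking value share one reserved block
rather than being dropped — extra comparisons are a fair price for not
silently losing records.

The default $l$ is derived by pigeonhole: $k$ edits cut a string into at
most $k + 1$ untouched runs, so two strings of roughly the average length
`avg` within $k$ edits share a run of length
$\lfloor (avg - k)/(k + 1) \rfloor$. We clamp to $[2, avg]$ (degenerate
configurations with `avg = 1` use $l = 1$): below 2 the blocks approach the
full cross product; above `avg` typical values would produce no key at all
except through the short-string fallback. With the defaults (`avg = 7`,
`k = 1`) this gives $l = 3$. The user can override `lmer_length` directly.
Blocking is a speed optimisation, not part of the model: any pair sharing a
block and within the threshold ends up in one cluster, but pairs sharing no
block are never scored. With $l = 1$, blocking is exhaustive up to pairs
sharing no character at all.

## Threshold 0 and truncation

A threshold of 0 links only pairs at distance 0. Note this is exactness
*with respect to the configured comparisons*: under
`cmp_truncation("FirstName", 1)`, the records `(r, pierce)` and
`(risa, pierce)` are at distance 0 and merge even at $k = 0$. Exact
clustering on raw values is obtained by using plain edit comparisons (or by
the exact-match phase alone).

## Synthetic data

`generate_synthetic()` writes a multi-file fixture with known individual
labels so the pipeline can be evaluated without external data. Its defaults
are fixed design choices:

* Three files shaped like a full registry, an initials-and-SSN extract and a
  no-SSN extract — the schema-heterogeneity pattern the mapper must handle.
* The first file is a clean, complete master source; the other files drop
  each individual with probability 0.1 and corrupt each kept record with at
  most `max_errors = 1` operation drawn from the mix 0.5 substitution /
  0.2 insertion / 0.2 deletion / 0.05 first–last swap / 0.05 truncation of
  the first name to its initial. A clean master is realistic (registry vs.
  noisy extracts) and gives the budget condition a sharp meaning: every
  corrupted copy lies within `max_errors` edits of its master record, so at
  threshold $\ge$ `max_errors` pairwise recall is 1 through the master by
  single linkage.
* Names come from built-in 60-name vocabularies; first/last pairs are
  sampled without replacement, so distinct individuals always differ on the
  compared name attributes and clean generation at threshold 0 recovers the
  truth exactly.
* Corruption is applied to already-normalised (lower-case) values, so
  injected error counts equal measured edit distances.

What the generator does **not** emulate: phonetic misspellings with
Soundex-like structure, realistic name/age distributions, correlated errors
across fields, or coordinated IDs gone wrong. Passing the recovery tests
therefore shows the machinery is correct under the stated error model, not
that any particular accuracy carries over to real registry data — on real
data the comparison set, blocking attribute and threshold must be chosen
from knowledge of the sources.

`evaluate_linkage()` scores pairwise: precision is the fraction of
same-cluster pairs that are truly same-individual, recall the converse, with
the conventions precision = 1 when no pair is predicted and recall = 1 when
the truth has no duplicate pair.

## Numerical and design notes

* Distances are integers; no floating-point tolerances enter the model.
  The single-linkage oracle compares integer heights with `cutree`, where
  ties are unambiguous.
* Cluster ids are assigned 1, 2, … by ascending smallest member uid; rows
  within a cluster are ordered by dataset load order, then line number.
  Output comparison in tests is order-insensitive on membership.
* Candidate pairs are deduplicated before scoring, so each pair's distance
  is computed exactly once; the union-find ignores edge insertion order,
  making runs byte-for-byte reproducible.
* Degenerate inputs: empty files yield an empty result (and a header-only
  output file); a single record is its own cluster; records whose blocking
  value is missing pair only within the reserved block.

## Problem sizes in the test suite

The suites run at desk scale, chosen to exercise every code path while
keeping the default test run quick: exhaustive edit-distance verification to
string length 6 over a 3-letter alphabet (about 1.2 million pairs against
`utils::adist`), 100 random 50-record instances for the blocked-pipeline vs.
single-linkage-oracle equivalence with $l = 1$, threshold sweeps
$k \in \{0,1,2,3\}$ on 40-record instances for the coarsening property, and
synthetic-recovery runs with 25–40 individuals over three files.

## Known limitations

* Single-attribute l-mer blocking only; no sorted-neighbourhood, LSH or
  multi-attribute blocking. A poorly chosen blocking attribute (short,
  error-prone, or frequently missing) costs recall or speed.
* Exactly three comparison methods; no phonetic (Soundex, Jaro–Winkler) or
  probabilistic (Fellegi–Sunter) comparators, and no data standardisation
  of names or addresses — inputs are linked as given, after case folding.
* Single-linkage chaining: with a generous threshold, one noisy record can
  bridge two true individuals into one cluster. The threshold is the only
  guard; inspect `glance()$largest_cluster` when tuning.
* Comparisons are byte-wise on UTF-8 text; multi-byte characters count per
  byte in distances, which slightly overweights non-ASCII typos.
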