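validate_kb_entries <- function(entries) {
  need <- c("length_diff_pct", "identity_pct", "diagonals_pct")
  if (!all(need %in% names(entries)))
    abort(paste0("knowledge base needs columns: ", paste(need, collapse = ", ")))
  entries <- as_tibble(entries)[need]
  ok <- is.finite(entries$length_diff_pct) & entries$length_diff_pct >= 0 &
    is.finite(entries$identity_pct) & entries$identity_pct >= 0 &
    entries$identity_pct <= 100 &
    is.finite(entries$diagonals_pct) & entries$diagonals_pct > 0 &
    entries$diagonals_pct <= 100
  if (!all(ok))
    abort(sprintf("invalid knowledge-base entry at row %d", which(!ok)[1]))
  if (anyDuplicated(entries[c("length_diff_pct", "identity_pct")]))
    abort("duplicate (length_diff_pct, identity_pct) keys in knowledge base")
  entries
}

#' Create a knowledge base
#'
#' The knowledge base maps similarity features of a sequence pair --
#' percent length difference and percent identity -- to the percentage of
#' dynamic-programming diagonals that must be filled for an optimal banded
#' alignment. Lookup is exact-match first, then nearest neighbour within a
#' per-dimension tolerance window.
#'
#' @param entries Tibble with columns `length_diff_pct`, `identity_pct`,
#'   `diagonals_pct` (may be empty).
#' @param tolerance_pct Closest-match window applied per dimension, in
#'   percentage points (default 3, the permissive end of the 2-3 range).
#' @return A `bandmsa_kb` object.
#' @export
kb_new <- function(entries = tibble(length_diff_pct = numeric(),
                                    identity_pct = numeric(),
                                    diagonals_pct = numeric()),
                   tolerance_pct = 3) {
  structure(
    list(entries = validate_kb_entries(entries),
         tolerance_pct = tolerance_pct),
    class = "bandmsa_kb"
  )
}

#' @export
print.bandmsa_kb <- function(x, ...) {
  cat("<knowledge base>", nrow(x$entries), "entries, tolerance +/-",
      x$tolerance_pct, "%\n")
  print(x$entries, n = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bandmsa_kb <- function(x, ...) x$entries

#' Load a knowledge base from CSV
#'
#' The file format is a CSV with header
#' `length_diff_pct,identity_pct,diagonals_pct`. Round-trips losslessly with
#' [kb_save()], preserving entry order.
#'
#' @param path CSV file path.
#' @param tolerance_pct Per-dimension closest-match window (default 3).
#' @return A `bandmsa_kb`.
#' @export
kb_load <- function(path, tolerance_pct = 3) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- tryCatch(
    suppressWarnings(  # parse problems are re-raised as errors below
      readr::read_csv(path,
                      col_types = readr::cols(.default = readr::col_double()))
    ),
    error = function(e) abort(paste0("malformed knowledge-base file: ",
                                     conditionMessage(e)))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    abort(sprintf("malformed knowledge-base row at line %d", probs$row[1] + 1L))
  kb_new(df, tolerance_pct = tolerance_pct)
}

#' Save a knowledge base to CSV
#'
#' @param kb A `bandmsa_kb`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
kb_save <- function(kb, path) {
  stopifnot(inherits(kb, "bandmsa_kb"))
  readr::write_csv(kb$entries, path)
  invisible(path)
}

#' The packaged sample knowledge base
#'
#' Twelve (length difference %, identity %, diagonals %) triples obtained
#' from training on similar-DNA datasets; shipped as packaged data for
#' immediate use and as a worked example of the file format. The values are
#' artifacts of a particular training set, not re-derivable constants.
#'
#' @param tolerance_pct Per-dimension closest-match window (default 3).
#' @return A `bandmsa_kb` with 12 entries.
#' @examples
#' kb <- kb_table1()
#' kb_lookup(kb, length_diff_pct = 0.30, identity_pct = 99.20)
#' @export
kb_table1 <- function(tolerance_pct = 3) {
  path <- system.file("extdata", "kb_table1.csv", package = "bandmsa",
                      mustWork = TRUE)
  kb_load(path, tolerance_pct = tolerance_pct)
}

#' Look up the diagonals percentage for a feature pair
#'
#' Checks for an exact match on both features first; failing that, searches
#' for the closest match: among entries within `tolerance_pct` on *both*
#' dimensions, the one minimising unweighted Euclidean distance in
#' (length difference, identity) space wins, ties broken by first-loaded
#' entry. When nothing qualifies the lookup is a miss.
#'
#' @param kb A `bandmsa_kb`.
#' @param length_diff_pct,identity_pct Query features (percent).
#' @return One-row tibble with `diagonals_pct` (`NA` on a miss) and `match`
#'   (`"exact"`, `"nn"`, or `"miss"`).
#' @export
kb_lookup <- function(kb, length_diff_pct, identity_pct) {
  stopifnot(inherits(kb, "bandmsa_kb"),
            is.finite(length_diff_pct), is.finite(identity_pct))
  e <- kb$entries
  if (nrow(e) == 0)
    return(tibble(diagonals_pct = NA_real_, match = "miss"))
  exact <- which(e$length_diff_pct == length_diff_pct &
                   e$identity_pct == identity_pct)
  if (length(exact) > 0)
    return(tibble(diagonals_pct = e$diagonals_pct[exact[1]], match = "exact"))
  tol <- kb$tolerance_pct
  dl <- abs(e$length_diff_pct - length_diff_pct)
  di <- abs(e$identity_pct - identity_pct)
  cand <- which(dl <= tol & di <= tol)
  if (length(cand) == 0)
    return(tibble(diagonals_pct = NA_real_, match = "miss"))
  dist2 <- dl[cand]^2 + di[cand]^2
  best <- cand[which.min(dist2)]  # which.min takes the first == smallest index
  tibble(diagonals_pct = e$diagonals_pct[best], match = "nn")
}

#' Learn a new feature-to-diagonals mapping
#'
#' Appends the entry, or replaces the stored value when the exact feature
#' key already exists (last write wins). Typically fed by
#' [min_band_oracle()] or [estimate_band_dotplot()] run on the most distant
#' segment pair of a dataset.
#'
#' @param kb A `bandmsa_kb`.
#' @param length_diff_pct,identity_pct Feature key (percent).
#' @param diagonals_pct Diagonals percentage to store (0 < value <= 100).
#' @return The updated `bandmsa_kb`.
#' @export
kb_learn <- function(kb, length_diff_pct, identity_pct, diagonals_pct) {
  stopifnot(inherits(kb, "bandmsa_kb"))
  e <- kb$entries
  hit <- which(e$length_diff_pct == length_diff_pct &
                 e$identity_pct == identity_pct)
  if (length(hit) > 0) {
    e$diagonals_pct[hit[1]] <- diagonals_pct
  } else {
    e <- bind_rows(e, tibble(length_diff_pct = length_diff_pct,
                             identity_pct = identity_pct,
                             diagonals_pct = diagonals_pct))
  }
  kb_new(e, tolerance_pct = kb$tolerance_pct)
}

#' Conservative knowledge-base query for a dataset
#'
#' Combines per-pair similarity features into the single worst-case query
#' used for the whole dataset: the highest length difference and the lowest
#' identity over all pairs (the components may come from different pairs).
#' Using the most distant combination guarantees the retrieved band is wide
#' enough for every pairwise alignment in the run.
#'
#' @param features Tibble with columns `identity_pct` and
#'   `length_diff_pct`, one row per sequence pair (non-empty).
#' @return One-row tibble with `length_diff_pct` (max) and `identity_pct`
#'   (min).
#' @export
select_query_features <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) > 0,
            all(c("identity_pct", "length_diff_pct") %in% names(features)))
  tibble(
    length_diff_pct = max(features$length_diff_pct),
    identity_pct = min(features$identity_pct)
  )
}

#' Convert a diagonals percentage to an integer band width
#'
#' `d = ceiling(pct / 100 * max(len_a, len_b))`.
#'
#' @param diagonals_pct Percentage of diagonals to fill.
#' @param len_a,len_b Lengths of the strings to be aligned.
#' @return Integer `d`.
#' @export
diagonals_pct_to_d <- function(diagonals_pct, len_a, len_b) {
  as.integer(ceiling(diagonals_pct / 100 * max(len_a, len_b)))
}
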