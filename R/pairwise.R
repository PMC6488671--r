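#' Scoring parameters for global alignment
#'
#' Linear gap penalties. `N` is always scored as a mismatch, against every
#' residue including another `N`.
#'
#' @param match Integer reward for an identical residue pair (default +1).
#' @param mismatch Integer penalty for a non-identical pair (default -1).
#' @param gap Integer penalty per gapped residue (default -2; must be < 0).
#' @return A `scoring_params` object.
#' @export
scoring_params <- function(match = 1L, mismatch = -1L, gap = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch); gap <- as.integer(gap)
  if (!match > mismatch) abort("match must exceed mismatch")
  if (!gap < 0) abort("gap penalty must be negative")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_params")
}

#' Diagonal band specification
#'
#' A banded alignment evaluates only cells `(i, j)` with `|j - i| <= d + k`,
#' where `d` is the number of extra diagonals on each side of the main
#' diagonal and `k` is the absolute length difference of the two strings
#' (the slack needed so the terminal cell is always reachable).
#'
#' @param d Non-negative integer diagonal count.
#' @param k Non-negative integer length difference; usually computed from
#'   the strings by [align_banded()], which checks consistency.
#' @return A `band_spec` object.
#' @export
band_spec <- function(d, k = NA_integer_) {
  d <- as.integer(d)
  if (is.na(d) || d < 0) abort("d must be a non-negative integer")
  structure(list(d = d, k = as.integer(k)), class = "band_spec")
}

new_pairwise_alignment <- function(lst) {
  structure(lst, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "| columns", nchar(x$aligned_a),
      "| cells filled", format(x$cells_filled, big.mark = ","), "\n")
  if (nchar(x$aligned_a) <= 80) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Full Needleman-Wunsch global alignment
#'
#' Computes the global optimum under linear gap scoring, filling the entire
#' `(len(a)+1) x (len(b)+1)` dynamic-programming matrix. Traceback ties are
#' broken deterministically: diagonal, then up (gap in `b`), then left (gap
#' in `a`).
#'
#' @param a,b Non-empty character strings.
#' @param scoring A [scoring_params()] object.
#' @return A `pairwise_alignment`: `aligned_a`, `aligned_b` (equal-length
#'   gapped strings), `score`, and `cells_filled`.
#' @examples
#' align_full("ACGT", "AGT", scoring_params())
#' @export
align_full <- function(a, b, scoring = scoring_params()) {
  stopifnot(nzchar(a), nzchar(b), inherits(scoring, "scoring_params"))
  r <- nw_full_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap)
  new_pairwise_alignment(r)
}

#' Banded Needleman-Wunsch global alignment
#'
#' Restricts the dynamic program to cells `(i, j)` with `|j - i| <= d + k`,
#' `k = |len(a) - len(b)|`, so the work is `O(m k) + O(2 m d)` instead of
#' `O(m^2)`. When the optimal full-matrix path lies inside the band the
#' score equals [align_full()]'s; traceback tie-breaks are identical.
#'
#' @param a,b Non-empty character strings.
#' @param scoring A [scoring_params()] object.
#' @param band A [band_spec()] or a single non-negative integer `d`. If the
#'   spec carries a non-`NA` `k` it must equal `|len(a) - len(b)|`.
#' @return A `pairwise_alignment` with `cells_filled` equal to the number of
#'   band cells evaluated, plus the `d` and `k` used.
#' @examples
#' align_banded("ACGTACGT", "ACGACGT", scoring_params(), band_spec(2))
#' @export
align_banded <- function(a, b, scoring = scoring_params(), band = band_spec(0)) {
  stopifnot(nzchar(a), nzchar(b), inherits(scoring, "scoring_params"))
  if (is.numeric(band)) band <- band_spec(band)
  stopifnot(inherits(band, "band_spec"))
  k <- abs(nchar(a) - nchar(b))
  if (!is.na(band$k) && band$k != k)
    abort(sprintf("band k (%d) does not match |len(a) - len(b)| = %d",
                  band$k, k))
  r <- nw_banded_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap,
                     band$d)
  new_pairwise_alignment(r)
}

#' Estimate the alignment band from a word-match dot plot
#'
#' Builds the exact word-match dot plot of `a` vs `b` (all shared words of
#' length `word_size`) and keeps diagonals carrying at least `min_hits`
#' matches. Among those, diagonals are accumulated in decreasing hit-count
#' order until they jointly hold `mass_frac` of all retained word matches:
#' for similar sequences the true alignment path dominates the hit mass, so
#' isolated chance repeats on distant diagonals are excluded, while for
#' dissimilar sequences the mass is spread out and the band honestly widens
#' towards the full matrix. Returns `d` = the largest absolute diagonal
#' offset among the accumulated diagonals plus a safety `margin`. With no
#' qualifying word matches the full matrix is returned (`d = max(len)`)
#' with a warning.
#'
#' @param a,b Character strings.
#' @param word_size Exact word length (default 8).
#' @param min_hits Minimum word matches a diagonal needs to count
#'   (default 2).
#' @param mass_frac Fraction of the retained hit mass the band must cover
#'   (default 0.9).
#' @param margin Safety margin added to the largest offset (default
#'   `word_size`).
#' @return A [band_spec()] with `k` filled in.
#' @export
estimate_band_dotplot <- function(a, b, word_size = 8, min_hits = 2,
                                  mass_frac = 0.9, margin = word_size) {
  stopifnot(nzchar(a), nzchar(b))
  word_size <- as.integer(word_size)
  if (word_size < 1) abort("word_size must be >= 1")
  la <- nchar(a); lb <- nchar(b)
  k <- abs(la - lb)
  fallback <- function() {
    warn("no qualifying word matches; falling back to the full matrix")
    band_spec(max(la, lb), k)
  }
  if (la < word_size || lb < word_size) return(fallback())
  wa <- tibble(
    i = 0:(la - word_size),
    word = substring(a, 1:(la - word_size + 1), word_size:la)
  )
  wb <- tibble(
    j = 0:(lb - word_size),
    word = substring(b, 1:(lb - word_size + 1), word_size:lb)
  )
  hits <- inner_join(wa, wb, by = "word", relationship = "many-to-many")
  if (nrow(hits) == 0) return(fallback())
  counts <- hits |>
    mutate(offset = .data$j - .data$i) |>
    dplyr::count(.data$offset) |>
    filter(.data$n >= min_hits)
  if (nrow(counts) == 0) return(fallback())
  counts <- counts |>
    arrange(desc(.data$n), abs(.data$offset), .data$offset) |>
    mutate(cum = cumsum(.data$n))
  need <- mass_frac * sum(counts$n)
  taken <- counts[seq_len(which(counts$cum >= need)[1]), ]
  band_spec(max(abs(taken$offset)) + as.integer(margin), k)
}

#' Smallest band reproducing the full-matrix optimum
#'
#' Finds, by doubling then bisection on `d` (valid because the banded score
#' is non-decreasing in `d`), the smallest `d` such that
#' [align_banded()] attains [align_full()]'s score. Used to populate the
#' knowledge base from training data.
#'
#' @param a,b Character strings, each at most 20 kb (full-DP guard).
#' @param scoring A [scoring_params()] object.
#' @return The minimal integer `d*`.
#' @export
min_band_oracle <- function(a, b, scoring = scoring_params()) {
  stopifnot(nzchar(a), nzchar(b))
  if (max(nchar(a), nchar(b)) > 20000)
    abort("min_band_oracle guard: sequences must be <= 20 kb")
  target <- align_full(a, b, scoring)$score
  sc <- function(d) align_banded(a, b, scoring, band_spec(d))$score
  if (sc(0) == target) return(0L)
  lo <- 0L  # known insufficient
  hi <- 1L
  while (sc(hi) < target) {
    lo <- hi
    hi <- hi * 2L
    if (hi > max(nchar(a), nchar(b))) {
      hi <- max(nchar(a), nchar(b))
      break
    }
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (sc(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Re-score a gapped pair under scoring parameters
#'
#' Columns with gaps in both rows score 0; single-gap columns score the gap
#' penalty; residue columns score match/mismatch (`N` always mismatches).
#' Used to audit alignments and during refinement.
#'
#' @param x,y Equal-length gapped strings.
#' @param scoring A [scoring_params()] object.
#' @return Integer score.
#' @export
score_gapped_pair <- function(x, y, scoring = scoring_params()) {
  stopifnot(nchar(x) == nchar(y))
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  gx <- cx == "-"; gy <- cy == "-"
  both <- !gx & !gy
  m <- sum(both & cx == cy & cx != "N")
  mm <- sum(both) - m
  g <- sum(xor(gx, gy))
  m * scoring$match + mm * scoring$mismatch + g * scoring$gap
}
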