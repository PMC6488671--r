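#' Build a suffix tree over a sequence
#'
#' Constructs an Ukkonen suffix tree (online, amortised linear time) over
#' `text` with a terminal sentinel appended, supporting substring occurrence
#' queries in time linear in the pattern length.
#'
#' @param text A non-empty character string; must not contain the sentinel.
#' @param sentinel Unique terminal character appended before construction
#'   (default `"$"`; never part of the validated nucleotide alphabet).
#' @return A `suffix_index` object.
#' @examples
#' idx <- suffix_index("BANANA")
#' find_occurrences(idx, "ANA")
#' @export
suffix_index <- function(text, sentinel = "$") {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) abort("cannot index an empty string")
  if (nchar(sentinel) != 1) abort("sentinel must be a single character")
  if (grepl(sentinel, text, fixed = TRUE))
    abort("text contains the sentinel character")
  ptr <- st_build_cpp(paste0(text, sentinel))
  structure(
    list(ptr = ptr, text = text, n = nchar(text), sentinel = sentinel),
    class = "suffix_index"
  )
}

#' @export
print.suffix_index <- function(x, ...) {
  cat("<suffix_index> text length", x$n, "(+ sentinel),",
      st_n_leaves_cpp(x$ptr), "leaves\n")
  invisible(x)
}

#' Number of leaves in a suffix tree
#'
#' Equals `nchar(text) + 1` (every suffix of the sentinel-terminated text is
#' spelled by exactly one root-to-leaf path).
#' @param index A `suffix_index`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(index) {
  stopifnot(inherits(index, "suffix_index"))
  st_n_leaves_cpp(index$ptr)
}

#' Vertically partitioned suffix index
#'
#' Map-style variant of [suffix_index()]: every suffix is keyed by its
#' prefix of length `prefix_length`, and one sub-structure per distinct key
#' is built independently from that key's start positions. Query answers are
#' identical to the monolithic tree. The per-key map work can run on a
#' serial or multicore backend; results are independent of the backend.
#'
#' @param text Non-empty character string.
#' @param prefix_length Key length (>= 1). Keys longer than a trailing
#'   suffix are truncated to that suffix.
#' @param backend `"serial"` (default) or `"multicore"`.
#' @param workers Worker count for the multicore backend.
#' @return A `suffix_index_forest` object.
#' @export
suffix_index_partitioned <- function(text, prefix_length, backend = c("serial", "multicore"),
                                     workers = 2L) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  prefix_length <- as.integer(prefix_length)
  if (is.na(prefix_length) || prefix_length < 1)
    abort("prefix_length must be >= 1")
  backend <- match.arg(backend)
  n <- nchar(text)
  starts <- 0:(n - 1L)
  keys <- substring(text, starts + 1L, pmin(starts + prefix_length, n))
  groups <- split(starts, keys)
  # per-key structure: the key's start positions, sorted (built per key by
  # the map backend; each query verifies candidates against the shared text)
  build_one <- function(st) sort(st)
  forest <- if (backend == "multicore" && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(groups, build_one, mc.cores = workers)
    setNames(res, names(groups))
  } else {
    lapply(groups, build_one)
  }
  structure(
    list(forest = forest, text = text, n = n, prefix_length = prefix_length),
    class = "suffix_index_forest"
  )
}

#' Find all occurrences of a pattern
#'
#' Returns the sorted 0-based start positions at which `pattern` occurs in
#' the indexed text (empty integer vector when absent).
#'
#' @param index A `suffix_index` or `suffix_index_forest`.
#' @param pattern Non-empty character string.
#' @return Sorted integer vector of 0-based start positions.
#' @export
find_occurrences <- function(index, pattern) {
  UseMethod("find_occurrences")
}

#' @export
find_occurrences.suffix_index <- function(index, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (!nzchar(pattern)) abort("pattern must be non-empty")
  sort(st_find_cpp(index$ptr, pattern))
}

#' @export
find_occurrences.suffix_index_forest <- function(index, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (!nzchar(pattern)) abort("pattern must be non-empty")
  q <- nchar(pattern)
  p <- index$prefix_length
  if (q <= p) {
    keys <- names(index$forest)
    hit <- keys[substr(keys, 1, q) == pattern & nchar(keys) >= q]
    out <- unlist(index$forest[hit], use.names = FALSE)
    if (is.null(out)) out <- integer(0)
    return(sort(out))
  }
  cand <- index$forest[[substr(pattern, 1, p)]]
  if (is.null(cand)) return(integer(0))
  cand <- cand[cand + q <= index$n]
  if (length(cand) == 0) return(integer(0))
  keep <- substring(index$text, cand + 1L, cand + q) == pattern
  sort(cand[keep])
}

# expected greedy MEM coverage of a pair with per-column identity q and
# minimum seed w, under a geometric run-length model:
#   f(q) = q^w * (w - (w - 1) q),  monotone increasing on [0, 1]
coverage_model <- function(q, w) q^w * (w - (w - 1) * q)

# expected coverage of an unrelated query by chance matches against a
# partner of length L: per-position seed probability under a uniform
# 4-letter null, each chance seed covering about w residues
null_coverage <- function(w, partner_len) {
  p0 <- 1 - (1 - 4^(-w))^max(0, partner_len - w + 1)
  l0 <- w + 1 / 3  # mean extension beyond the seed under the null
  (p0 * l0) / (p0 * l0 + (1 - p0))
}

# calibrated percent identity from an observed coverage fraction: subtract
# the chance-match coverage expected for an unrelated pair, then invert the
# run-length model
identity_from_coverage <- function(cov, w, partner_len = NULL) {
  vapply(cov, function(cv) {
    if (!is.null(partner_len)) {
      c0 <- null_coverage(w, partner_len)
      cv <- (cv - c0) / (1 - c0)
    }
    if (!is.finite(cv) || cv <= 0) return(0)
    if (cv >= 1) return(100)
    100 * stats::uniroot(function(q) coverage_model(q, w) - cv,
                         interval = c(0, 1), tol = 1e-9)$root
  }, numeric(1))
}

#' Match segments of one sequence against a partner's suffix tree
#'
#' For each segment of sequence A, reports whether the segment occurs
#' verbatim in the indexed partner sequence B (`matched`), an estimated
#' percent identity for unmatched segments (greedy maximal-exact-match
#' coverage with minimum seed length `min_seed`, calibrated to percent
#' identity under a geometric match-run model), and the percent length
#' difference against the positional counterpart segment of B (only the
#' final segment of a sequence can differ in length).
#'
#' @param index `suffix_index` built over the partner sequence B.
#' @param segments Tibble of A's segments from [partition_segments()].
#' @param segment_size The segment size used for both sequences.
#' @param min_seed Minimum exact-match seed length for the coverage
#'   estimate (default 8).
#' @return Tibble with columns `seq_id`, `index`, `matched`, `identity_pct`,
#'   `length_diff_pct`.
#' @export
match_segments <- function(index, segments, segment_size, min_seed = 8) {
  stopifnot(inherits(index, "suffix_index"))
  lb <- index$n
  n_seg_b <- ceiling(lb / segment_size)
  seg_len_b <- function(i) {
    if (i >= n_seg_b) return(0L)
    min(segment_size, lb - i * segment_size)
  }
  rows <- purrr::map_dfr(seq_len(nrow(segments)), function(r) {
    seg <- segments$seg[r]
    i <- segments$index[r]
    la <- nchar(seg)
    matched <- st_contains_cpp(index$ptr, seg)
    if (matched) {
      idp <- 100
    } else {
      cov <- st_coverage_cpp(index$ptr, seg, as.integer(min_seed))[1] / la
      idp <- identity_from_coverage(cov, min_seed, partner_len = lb)
    }
    lbi <- seg_len_b(i)
    ldp <- if (max(la, lbi) == 0) 0 else 100 * abs(la - lbi) / max(la, lbi)
    tibble(seq_id = segments$seq_id[r], index = i, matched = matched,
           identity_pct = idp, length_diff_pct = ldp)
  })
  rows
}

#' Alignment-free similarity features of a sequence pair
#'
#' The knowledge-base query key: percent identity and percent length
#' difference, computed without alignment. Identity is the greedy
#' maximal-exact-match coverage of the shorter sequence against the suffix
#' tree of the longer (minimum seed length `min_seed`, non-overlapping on
#' the query), calibrated to percent identity under a geometric match-run
#' model; length difference is `100 |la - lb| / max(la, lb)`.
#'
#' @param a,b Character strings (sequences).
#' @param min_seed Minimum exact-match seed length (default 8).
#' @return One-row tibble with `identity_pct` and `length_diff_pct`.
#' @examples
#' pair_similarity("ACGTACGTACGT", "ACGTACGTACGT")
#' @export
pair_similarity <- function(a, b, min_seed = 8) {
  stopifnot(nzchar(a), nzchar(b))
  if (nchar(a) <= nchar(b)) { short <- a; long <- b } else { short <- b; long <- a }
  idx <- suffix_index(long)
  cov <- st_coverage_cpp(idx$ptr, short, as.integer(min_seed))[1] / nchar(short)
  tibble(
    identity_pct = identity_from_coverage(cov, min_seed,
                                          partner_len = nchar(long)),
    length_diff_pct = 100 * abs(nchar(a) - nchar(b)) / max(nchar(a), nchar(b))
  )
}
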