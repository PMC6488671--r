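# coerce an alignment argument to a named character vector of gapped rows
as_msa_rows <- function(x) {
  if (inherits(x, "bandmsa_msa")) return(x$rows)
  if (is.data.frame(x)) {
    col <- intersect(c("aligned", "seq"), names(x))
    if (length(col) == 0 || !"id" %in% names(x))
      abort("alignment data frame needs columns id and aligned (or seq)")
    return(setNames(x[[col[1]]], x$id))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  abort("cannot interpret object as a multiple alignment")
}

#' Score one column of a row pair
#'
#' Per-column pair value of the sum-of-pairs score: 2 when both symbols are
#' residues that are correctly aligned (paired the same way as in the
#' reference), 1 when exactly one symbol is a gap, 0 otherwise (including a
#' residue pair that the reference does not pair, and a gap-gap column).
#'
#' @param x,y Single symbols from `A, C, G, T, U, N, -`.
#' @param paired Whether the reference alignment pairs these two residues
#'   (ignored when either symbol is a gap).
#' @return Integer 0, 1 or 2.
#' @export
column_pair_score <- function(x, y, paired = TRUE) {
  ok <- c("A", "C", "G", "T", "U", "N", "-")
  if (!(x %in% ok) || !(y %in% ok))
    abort("illegal alignment symbol")
  gx <- x == "-"; gy <- y == "-"
  if (gx && gy) return(0L)
  if (gx || gy) return(1L)
  if (isTRUE(paired)) 2L else 0L
}

# per-column pair-value totals of an alignment, judged against reference
# residue pairings; rows and ref rows are named gapped character vectors
sp_column_totals <- function(rows, ref_rows) {
  ids <- names(rows)
  n <- length(ids)
  C <- nchar(rows[1])
  mats <- lapply(rows, function(r) strsplit(r, "")[[1]])
  gaps <- lapply(mats, function(ch) ch == "-")
  pos <- lapply(gaps, function(g) cumsum(!g))
  # reference column index of each residue, per row
  refcol <- lapply(ids, function(id) {
    ch <- strsplit(ref_rows[id], "")[[1]]
    which(ch != "-")
  })
  names(refcol) <- ids
  total <- numeric(C)
  for (r in 1:(n - 1)) {
    for (s in (r + 1):n) {
      gr <- gaps[[r]]; gs <- gaps[[s]]
      both <- !gr & !gs
      one <- xor(gr, gs)
      v <- numeric(C)
      v[one] <- 1
      if (any(both)) {
        pr <- pos[[r]][both]; ps <- pos[[s]][both]
        v[both] <- 2 * (refcol[[ids[r]]][pr] == refcol[[ids[s]]][ps])
      }
      total <- total + v
    }
  }
  total
}

#' Average sum-of-pairs score against a reference alignment
#'
#' For each column of the test alignment, the column score `S_i` is the sum
#' over all row pairs of the pair value (2 for a residue pair aligned
#' exactly as in the reference, 1 for a single gap, 0 otherwise), normalised
#' by `2 * choose(n, 2)` so `S_i` lies in `[0, 1]`. The reference column
#' scores `S_ri` are computed the same way on the reference itself, and the
#' average SP score is `sum(S_i) / sum(S_ri)`. A test identical to the
#' reference scores exactly 1.
#'
#' @param test,reference Alignments over the same sequence ids whose rows
#'   degap to identical strings: `bandmsa_msa` objects, tibbles with `id`
#'   and `aligned` columns, or named character vectors.
#' @return A single number in `[0, 1]` scaled so that 1 reproduces every
#'   reference residue pairing.
#' @examples
#' ref <- c(a = "AC-GT", b = "ACGGT")
#' average_sp_score(ref, ref)
#' @export
average_sp_score <- function(test, reference) {
  tr <- as_msa_rows(test)
  rr <- as_msa_rows(reference)
  if (!setequal(names(tr), names(rr)))
    abort("test and reference carry different sequence ids")
  rr <- rr[names(tr)]
  if (length(unique(nchar(tr))) != 1 || length(unique(nchar(rr))) != 1)
    abort("alignment rows must have equal length")
  dg <- function(z) gsub("-", "", z)
  if (!identical(dg(unname(tr)), dg(unname(rr))))
    abort("test and reference rows degap to different sequences")
  s_test <- sp_column_totals(tr, rr)
  s_ref <- sp_column_totals(rr, rr)
  sum(s_test) / sum(s_ref)
}

#' Detailed sum-of-pairs report
#'
#' @inheritParams average_sp_score
#' @return One-row tibble with `avg_sp_score`, `columns` (test alignment
#'   width) and `pairs` (number of row pairs).
#' @export
sp_score_report <- function(test, reference) {
  tr <- as_msa_rows(test)
  n <- length(tr)
  tibble(
    avg_sp_score = average_sp_score(test, reference),
    columns = unname(nchar(tr[1])),
    pairs = choose(n, 2)
  )
}
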