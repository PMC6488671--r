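# independent oracles and small generators used across the suite

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force occurrence scan (oracle for suffix-tree queries)
naive_occurrences <- function(text, pattern) {
  n <- nchar(text); m <- nchar(pattern)
  if (m > n) return(integer(0))
  starts <- 1:(n - m + 1)
  as.integer(starts[substring(text, starts, starts + m - 1) == pattern] - 1L)
}

# exhaustive global-alignment score by recursion with memoisation
# (oracle for Needleman-Wunsch on short strings)
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  la <- nchar(a); lb <- nchar(b)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- array(NA_real_, dim = c(la + 1, lb + 1))
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) {
      0
    } else {
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
        best <- max(best, rec(i - 1, j - 1) + s)
      }
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(la, lb)
}

# independent sum-of-pairs scorer: plain double loop over columns and row
# pairs, residue pairings judged against the reference column map
sp_score_loop <- function(test_rows, ref_rows) {
  ids <- names(test_rows)
  ref_rows <- ref_rows[ids]
  tch <- lapply(test_rows, function(r) strsplit(r, "")[[1]])
  rch <- lapply(ref_rows, function(r) strsplit(r, "")[[1]])
  refcol <- lapply(rch, function(ch) which(ch != "-"))
  col_total <- function(chs, colmap) {
    C <- length(chs[[1]])
    pos <- lapply(chs, function(ch) cumsum(ch != "-"))
    tot <- 0
    for (cc in seq_len(C)) {
      for (r in 1:(length(ids) - 1)) {
        for (s in (r + 1):length(ids)) {
          xr <- chs[[r]][cc]; xs <- chs[[s]][cc]
          if (xr == "-" && xs == "-") next
          if (xr == "-" || xs == "-") { tot <- tot + 1; next }
          pr <- colmap[[r]][pos[[r]][cc]]
          ps <- colmap[[s]][pos[[s]][cc]]
          if (pr == ps) tot <- tot + 2
        }
      }
    }
    tot
  }
  col_total(tch, refcol) / col_total(rch, refcol)
}

degap <- function(x) gsub("-", "", x)

# named gapped rows from an msa object or tidy alignment tibble
tidyr_rows <- function(x) {
  if (inherits(x, "bandmsa_msa")) return(x$rows)
  if (is.data.frame(x)) return(stats::setNames(x$aligned, x$id))
  x
}

fasta_tempfile <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
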