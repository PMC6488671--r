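# partition two sequences into the same number of positional segments; the
# final segment of each sequence absorbs its remainder (so every segment is
# at least segment_size long and only the last pair can differ in length)
partition_pair <- function(a, b, segment_size) {
  la <- nchar(a); lb <- nchar(b)
  nseg <- max(1L, floor(min(la, lb) / segment_size))
  starts <- (seq_len(nseg) - 1L) * segment_size
  cut_one <- function(s, len) {
    ends <- c(starts[-1], len)
    substring(s, starts + 1L, ends)
  }
  tibble(index = seq_len(nseg) - 1L,
         seg_a = cut_one(a, la), seg_b = cut_one(b, lb))
}

normalize_pair_ids <- function(id_a, id_b) {
  swap <- id_a > id_b
  lo <- ifelse(swap, id_b, id_a)
  hi <- ifelse(swap, id_a, id_b)
  tibble(id_a = lo, id_b = hi)
}

#' Pairwise similarity features for every sequence pair
#'
#' Computes [pair_similarity()] for all `choose(n, 2)` pairs; the result
#' feeds [build_guide_order()] and [select_query_features()].
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param min_seed Minimum exact-match seed length (default 8).
#' @return Tibble with `id_a`, `id_b` (lexicographically ordered within each
#'   row), `identity_pct`, `length_diff_pct`.
#' @export
all_pair_features <- function(x, min_seed = 8) {
  stopifnot(is.data.frame(x), nrow(x) >= 2)
  idx <- utils::combn(nrow(x), 2)
  purrr::map_dfr(seq_len(ncol(idx)), function(c0) {
    i <- idx[1, c0]; j <- idx[2, c0]
    ids <- normalize_pair_ids(x$id[i], x$id[j])
    dplyr::bind_cols(ids, pair_similarity(x$seq[i], x$seq[j],
                                          min_seed = min_seed))
  })
}

#' Build the guide order from pairwise similarity features
#'
#' The guide order is the join schedule of the progressive alignment: all
#' sequence pairs sorted by ascending distance (`100 - identity_pct`), ties
#' broken lexicographically on the pair ids, so the most closely related
#' pair is aligned first.
#'
#' @param features Tibble with `id_a`, `id_b`, `identity_pct` (and
#'   optionally `length_diff_pct`) for all `choose(n, 2)` pairs.
#' @return Tibble `id_a`, `id_b`, `distance`, sorted.
#' @export
build_guide_order <- function(features) {
  stopifnot(all(c("id_a", "id_b", "identity_pct") %in% names(features)))
  ids <- unique(c(features$id_a, features$id_b))
  if (nrow(features) != choose(length(ids), 2))
    abort("features must cover every sequence pair exactly once")
  features |>
    mutate(distance = 100 - .data$identity_pct) |>
    select("id_a", "id_b", "distance") |>
    arrange(.data$distance, .data$id_a, .data$id_b)
}

#' Segment-wise banded pairwise alignment
#'
#' Aligns two sequences by cutting both into positional segments
#' ([partition_pair()]); segments that are identical between the two
#' sequences are copied verbatim at zero DP cost, and the remaining segments
#' are aligned with [align_banded()] at
#' `d = ceiling(band_pct / 100 * segment length)`. Per-segment work is a
#' pure map over (sequence id, segment index) keys -- serial or multicore --
#' and the per-segment alignments are concatenated in key order, so the
#' result is independent of the backend.
#'
#' @param a,b Character strings.
#' @param band_pct Percentage of diagonals to fill (from the knowledge base
#'   or the dot-plot estimate).
#' @param scoring A [scoring_params()] object.
#' @param segment_size Segment length (default 1000).
#' @param backend `"serial"` (default) or `"multicore"`.
#' @param workers Worker count for the multicore backend.
#' @return A `pairwise_alignment` with summed `cells_filled`, plus counts of
#'   copied and DP-aligned segments.
#' @export
align_pair_segmented <- function(a, b, band_pct, scoring = scoring_params(),
                                 segment_size = 1000,
                                 backend = c("serial", "multicore"),
                                 workers = 2L) {
  backend <- match.arg(backend)
  segs <- partition_pair(a, b, segment_size)
  align_one <- function(i) {
    sa <- segs$seg_a[i]; sb <- segs$seg_b[i]
    if (sa == sb) {
      return(list(aligned_a = sa, aligned_b = sb, score = NA_integer_,
                  cells_filled = 0, copied = TRUE))
    }
    d <- diagonals_pct_to_d(band_pct, nchar(sa), nchar(sb))
    r <- align_banded(sa, sb, scoring, band_spec(d))
    r$copied <- FALSE
    r
  }
  parts <- if (backend == "multicore" && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(segs)), align_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(segs)), align_one)
  }
  aligned_a <- paste(vapply(parts, `[[`, character(1), "aligned_a"),
                     collapse = "")
  aligned_b <- paste(vapply(parts, `[[`, character(1), "aligned_b"),
                     collapse = "")
  out <- new_pairwise_alignment(list(
    aligned_a = aligned_a, aligned_b = aligned_b,
    score = score_gapped_pair(aligned_a, aligned_b, scoring),
    cells_filled = sum(vapply(parts, `[[`, numeric(1), "cells_filled"))
  ))
  out$segments_copied <- sum(vapply(parts, `[[`, logical(1), "copied"))
  out$segments_aligned <- nrow(segs) - out$segments_copied
  out
}

# construct an msa object from named gapped rows
new_msa <- function(rows, report = NULL) {
  structure(list(rows = rows, report = report), class = "bandmsa_msa")
}

#' @export
print.bandmsa_msa <- function(x, ...) {
  cat("<multiple alignment>", length(x$rows), "rows x", nchar(x$rows[1]),
      "columns\n")
  if (!is.null(x$report))
    cat("  cells filled:", format(x$report$total_cells, big.mark = ","),
        "| band:", x$report$band_pct, "% | KB",
        if (isTRUE(x$report$kb_hit)) "hit" else "miss", "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bandmsa_msa <- function(x, ...) tibble(id = names(x$rows),
                                            aligned = unname(x$rows))

#' @exportS3Method generics::glance
glance.bandmsa_msa <- function(x, ...) {
  tibble(
    n_sequences = length(x$rows),
    columns = nchar(x$rows[1]),
    total_cells = if (is.null(x$report)) NA_real_ else x$report$total_cells,
    band_pct = if (is.null(x$report)) NA_real_ else x$report$band_pct,
    kb_hit = if (is.null(x$report)) NA else x$report$kb_hit,
    dotlet_runs = if (is.null(x$report)) NA_integer_ else x$report$dotlet_runs
  )
}

#' Merge a newcomer's pairwise alignment into a profile
#'
#' Implements once-a-gap-always-a-gap column propagation: gaps the pairwise
#' alignment inserts into the representative become gap columns in every
#' existing profile row, and the newcomer row inherits a gap in every
#' profile column the pairwise alignment did not create.
#'
#' @param profile Named character vector of equal-length gapped rows.
#' @param aln A `pairwise_alignment` of the representative's *degapped* row
#'   (`aligned_a`) against the newcomer (`aligned_b`).
#' @param rep_id Id of the representative row (must exist in `profile`).
#' @param new_id Id for the newcomer row.
#' @return Named character vector: the enlarged profile.
#' @export
merge_into_profile <- function(profile, aln, rep_id, new_id) {
  if (!rep_id %in% names(profile)) abort("representative not in profile")
  rep_prof <- strsplit(profile[[rep_id]], "")[[1]]
  pair_rep <- strsplit(aln$aligned_a, "")[[1]]
  pair_new <- strsplit(aln$aligned_b, "")[[1]]
  if (paste(rep_prof[rep_prof != "-"], collapse = "") !=
      paste(pair_rep[pair_rep != "-"], collapse = ""))
    abort("pairwise alignment was not computed against the representative's degapped row")
  np <- length(rep_prof); nq <- length(pair_rep)
  # output column plan: src_prof[c] = profile column or NA, new_char[c]
  src_prof <- integer(0); new_char <- character(0)
  i <- 1L; j <- 1L
  while (i <= np || j <= nq) {
    if (i <= np && rep_prof[i] == "-") {
      src_prof <- c(src_prof, i); new_char <- c(new_char, "-"); i <- i + 1L
    } else if (j <= nq && pair_rep[j] == "-") {
      src_prof <- c(src_prof, NA_integer_)
      new_char <- c(new_char, pair_new[j]); j <- j + 1L
    } else if (i <= np && j <= nq) {
      src_prof <- c(src_prof, i); new_char <- c(new_char, pair_new[j])
      i <- i + 1L; j <- j + 1L
    } else {
      abort("profile merge ran out of columns (internal error)")
    }
  }
  out <- vapply(profile, function(row) {
    ch <- strsplit(row, "")[[1]]
    paste(ifelse(is.na(src_prof), "-", ch[replace(src_prof, is.na(src_prof), 1L)]),
          collapse = "")
  }, character(1))
  out[[new_id]] <- paste(new_char, collapse = "")
  out
}

drop_all_gap_columns <- function(rows) {
  chm <- do.call(rbind, strsplit(unname(rows), ""))
  keep <- colSums(chm != "-") > 0
  if (all(keep)) return(rows)
  setNames(apply(chm[, keep, drop = FALSE], 1, paste, collapse = ""),
           names(rows))
}

# majority-residue consensus (gaps ignored; ties broken alphabetically);
# columns where every row is a gap contribute nothing
consensus_string <- function(rows) {
  chm <- do.call(rbind, strsplit(unname(rows), ""))
  cons <- apply(chm, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[tab == tab[1]][1]
  })
  list(string = paste(cons[!is.na(cons)], collapse = ""),
       cols = which(!is.na(cons)))
}

#' Refine a multiple alignment
#'
#' Removes all-gap columns, then performs one leave-one-out pass in guide
#' order: each row is degapped and re-aligned (banded, same band policy)
#' against the consensus of the remaining rows; the re-alignment is accepted
#' only if the row's summed pair score against the remaining rows does not
#' decrease. The refined alignment therefore never scores worse than its
#' input, and every row still degaps to its original sequence.
#'
#' @param msa A `bandmsa_msa` or named character vector of gapped rows.
#' @param scoring A [scoring_params()] object.
#' @param band_pct Diagonals percentage for the re-alignments.
#' @param order Optional character vector of row ids giving the pass order
#'   (defaults to row order).
#' @return A `bandmsa_msa` (report of the input is preserved, with refine
#'   statistics added when present).
#' @export
refine_msa <- function(msa, scoring = scoring_params(), band_pct = 100,
                       order = NULL) {
  rows <- if (inherits(msa, "bandmsa_msa")) msa$rows else msa
  rows <- drop_all_gap_columns(rows)
  if (is.null(order)) order <- names(rows)
  accepted <- 0L
  cells <- 0
  for (id in order) {
    others <- rows[setdiff(names(rows), id)]
    if (length(others) == 0) break
    cons <- consensus_string(others)
    raw <- gsub("-", "", rows[[id]])
    # a row already identical to the consensus cannot improve; skip its DP
    if (identical(raw, cons$string) && identical(rows[[id]], raw)) next
    d <- diagonals_pct_to_d(band_pct, nchar(raw), nchar(cons$string))
    aln <- align_banded(raw, cons$string, scoring, band_spec(d))
    cells <- cells + aln$cells_filled
    # project: consensus columns index others' retained columns
    cand <- project_onto_consensus(others, cons, aln, id)
    old_score <- sum(vapply(others, score_gapped_pair, numeric(1),
                            y = rows[[id]], scoring = scoring))
    new_score <- sum(vapply(cand$others, score_gapped_pair, numeric(1),
                            y = cand$row, scoring = scoring))
    if (new_score >= old_score && !identical(cand$row, rows[[id]])) {
      rows <- c(cand$others, setNames(cand$row, id))[names(rows)]
      rows <- drop_all_gap_columns(rows)
      accepted <- accepted + 1L
    }
  }
  rows <- drop_all_gap_columns(rows)
  report <- if (inherits(msa, "bandmsa_msa")) msa$report else NULL
  if (!is.null(report)) {
    report$refine_accepted <- accepted
    report$refine_cells <- cells
    report$total_cells <- report$total_cells + cells
  }
  new_msa(rows, report)
}

# re-embed a row aligned against the consensus of the other rows: gap
# columns the alignment adds to the consensus become new gap columns in the
# other rows (consensus column c corresponds to profile column cons$cols[c])
project_onto_consensus <- function(others, cons, aln, id) {
  a_row <- strsplit(aln$aligned_a, "")[[1]]   # the degapped row, re-gapped
  c_row <- strsplit(aln$aligned_b, "")[[1]]   # consensus with new gaps
  np <- nchar(others[[1]])
  src <- integer(0); row_char <- character(0)
  ci <- 0L   # consensus residues consumed
  pi <- 1L   # profile column cursor
  for (t in seq_along(c_row)) {
    if (c_row[t] == "-") {
      src <- c(src, NA_integer_); row_char <- c(row_char, a_row[t])
    } else {
      ci <- ci + 1L
      target <- cons$cols[ci]
      while (pi < target) {  # profile columns skipped by the consensus
        src <- c(src, pi); row_char <- c(row_char, "-"); pi <- pi + 1L
      }
      src <- c(src, pi); row_char <- c(row_char, a_row[t]); pi <- pi + 1L
    }
  }
  while (pi <= np) {
    src <- c(src, pi); row_char <- c(row_char, "-"); pi <- pi + 1L
  }
  new_others <- vapply(others, function(row) {
    ch <- strsplit(row, "")[[1]]
    paste(ifelse(is.na(src), "-", ch[replace(src, is.na(src), 1L)]),
          collapse = "")
  }, character(1))
  list(others = new_others, row = paste(row_char, collapse = ""))
}

#' Progressive multiple sequence alignment
#'
#' Runs the full pipeline: pairwise similarity features from per-pair suffix
#' trees, the conservative knowledge-base query
#' ([select_query_features()]), knowledge-base lookup for the dataset-level
#' band (on a miss, a dot-plot estimate on the most distant segment pair is
#' computed and learned back into the knowledge base), guide-order
#' construction, progressive merges with gap propagation, and one
#' refinement pass.
#'
#' @param x Tibble with columns `id` and `seq` (>= 2 sequences, as from
#'   [read_fasta()]).
#' @param kb A `bandmsa_kb`, or `NULL` for an empty knowledge base (the
#'   learning path then runs once).
#' @param scoring A [scoring_params()] object.
#' @param segment_size Segment length (default 1000).
#' @param word_size Dot-plot word length (default 8).
#' @param min_seed Minimum seed for identity estimates (default 8).
#' @param backend,workers Per-segment map backend, see
#'   [align_pair_segmented()].
#' @param refine Run the refinement pass (default `TRUE`).
#' @return A `bandmsa_msa`; `$report` carries the run audit (features,
#'   query, KB hit/miss, band, per-stage cells filled, updated knowledge
#'   base).
#' @examples
#' fam <- generate_family(m = 200, n_sequences = 3,
#'                        target_identity_pct = 95, seed = 1)
#' msa <- run_msa(fam$sequences, segment_size = 100)
#' glance(msa)
#' @export
run_msa <- function(x, kb = NULL, scoring = scoring_params(),
                    segment_size = 1000, word_size = 8, min_seed = 8,
                    backend = c("serial", "multicore"), workers = 2L,
                    refine = TRUE) {
  backend <- match.arg(backend)
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (nrow(x) < 2) abort("need at least 2 sequences")
  if (anyDuplicated(x$id)) abort("sequence ids must be unique")
  if (is.null(kb)) kb <- kb_new()
  stopifnot(inherits(kb, "bandmsa_kb"))
  kb_size_before <- nrow(kb$entries)

  features <- all_pair_features(x, min_seed = min_seed)
  query <- select_query_features(features)
  hit <- kb_lookup(kb, query$length_diff_pct, query$identity_pct)
  dotlet_runs <- 0L
  if (hit$match == "miss") {
    # learning path: dot-plot band estimate on the most distant segment pair
    worst <- features |>
      arrange(.data$identity_pct, desc(.data$length_diff_pct),
              .data$id_a, .data$id_b) |>
      slice(1)
    a <- x$seq[x$id == worst$id_a]
    b <- x$seq[x$id == worst$id_b]
    segs <- partition_pair(a, b, segment_size)
    seg_feats <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      pair_similarity(segs$seg_a[i], segs$seg_b[i], min_seed = min_seed)
    })
    wseg <- order(seg_feats$identity_pct, -seg_feats$length_diff_pct)[1]
    band <- withCallingHandlers(
      estimate_band_dotplot(segs$seg_a[wseg], segs$seg_b[wseg],
                            word_size = word_size),
      warning = function(w) invokeRestart("muffleWarning")
    )
    dotlet_runs <- 1L
    seglen <- max(nchar(segs$seg_a[wseg]), nchar(segs$seg_b[wseg]))
    band_pct <- min(100, 100 * max(band$d, 1L) / seglen)
    kb <- kb_learn(kb, query$length_diff_pct, query$identity_pct, band_pct)
  } else {
    band_pct <- hit$diagonals_pct
  }

  guide <- build_guide_order(features)
  # merge order: sequences in order of first appearance along the guide
  appearance <- unique(c(rbind(guide$id_a, guide$id_b)))
  seq_of <- setNames(x$seq, x$id)
  sim <- function(p, q) {
    ids <- normalize_pair_ids(p, q)
    features$identity_pct[features$id_a == ids$id_a &
                            features$id_b == ids$id_b]
  }

  first <- guide[1, ]
  aln0 <- align_pair_segmented(seq_of[[first$id_a]], seq_of[[first$id_b]],
                               band_pct, scoring, segment_size,
                               backend = backend, workers = workers)
  profile <- setNames(c(aln0$aligned_a, aln0$aligned_b),
                      c(first$id_a, first$id_b))
  merge_log <- tibble(
    newcomer = first$id_b, representative = first$id_a,
    cells = aln0$cells_filled, segments_copied = aln0$segments_copied,
    segments_aligned = aln0$segments_aligned
  )
  for (id in appearance) {
    if (id %in% names(profile)) next
    merged <- names(profile)
    sims <- vapply(merged, function(mid) sim(mid, id), numeric(1))
    rep_id <- merged[order(-sims, merged)][1]
    aln <- align_pair_segmented(gsub("-", "", profile[[rep_id]]),
                                seq_of[[id]], band_pct, scoring,
                                segment_size, backend = backend,
                                workers = workers)
    profile <- merge_into_profile(profile, aln, rep_id, id)
    merge_log <- bind_rows(merge_log, tibble(
      newcomer = id, representative = rep_id, cells = aln$cells_filled,
      segments_copied = aln$segments_copied,
      segments_aligned = aln$segments_aligned
    ))
  }
  profile <- drop_all_gap_columns(profile[x$id])

  report <- list(
    n_sequences = nrow(x), segment_size = segment_size,
    features = features, query = query,
    kb_hit = hit$match != "miss", kb_match = hit$match,
    band_pct = band_pct, dotlet_runs = dotlet_runs,
    kb_size_before = kb_size_before, kb_size_after = nrow(kb$entries),
    merges = merge_log, merge_cells = sum(merge_log$cells),
    refine_accepted = NA_integer_, refine_cells = 0,
    total_cells = sum(merge_log$cells),
    kb = kb
  )
  out <- new_msa(profile, report)
  if (refine) out <- refine_msa(out, scoring, band_pct, order = appearance)
  out
}
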