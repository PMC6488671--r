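BASES <- c("A", "C", "G", "T")

random_dna <- function(m) paste(sample(BASES, m, replace = TRUE), collapse = "")

# geometric indel lengths with the given mean (support 1, 2, ...)
rindel_len <- function(n, mean_len) {
  if (mean_len <= 1) return(rep(1L, n))
  rgeom(n, prob = 1 / mean_len) + 1L
}

#' Mutate a sequence with substitutions and indels
#'
#' Applies, in one pass over the base sequence: substitutions (per-base
#' probability `sub_rate`, drawing uniformly from the three alternative
#' bases), deletions (per-base start probability `del_rate`, geometric
#' length), and insertions (per-slot probability `ins_rate`, geometric
#' length, uniform random bases). The returned edit trace reconstructs the
#' true pairwise alignment of base and mutant exactly.
#'
#' @param base Character string over `A, C, G, T`.
#' @param sub_rate,ins_rate,del_rate Per-base event probabilities in
#'   `[0, 1]`.
#' @param indel_mean Mean indel length (geometric; default 3).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `seq` (the mutant), and a trace: `kept` (logical per
#'   base position; `FALSE` = deleted), `residue` (the mutant residue at
#'   each kept base position) and `ins` (list of `nchar(base) + 1` inserted
#'   strings, one per inter-base slot).
#' @export
mutate_seq <- function(base, sub_rate, ins_rate = 0, del_rate = 0,
                       indel_mean = 3, seed = NULL) {
  for (r in c(sub_rate, ins_rate, del_rate))
    if (!is.finite(r) || r < 0 || r > 1) abort("rates must lie in [0, 1]")
  run <- function() {
    m <- nchar(base)
    ch <- strsplit(base, "")[[1]]
    residue <- ch
    # substitutions: uniform over the 3 alternative bases
    sub_at <- which(runif(m) < sub_rate)
    if (length(sub_at) > 0) {
      residue[sub_at] <- vapply(ch[sub_at], function(x) {
        sample(setdiff(BASES, x), 1)
      }, character(1))
    }
    # deletions: event starts, geometric lengths, clipped at the end
    kept <- rep(TRUE, m)
    del_at <- which(runif(m) < del_rate)
    if (length(del_at) > 0) {
      lens <- rindel_len(length(del_at), indel_mean)
      for (q in seq_along(del_at)) {
        span <- del_at[q]:min(m, del_at[q] + lens[q] - 1L)
        kept[span] <- FALSE
      }
    }
    # insertions in the m + 1 inter-base slots
    ins <- rep("", m + 1L)
    ins_at <- which(runif(m + 1L) < ins_rate)
    if (length(ins_at) > 0) {
      lens <- rindel_len(length(ins_at), indel_mean)
      ins[ins_at] <- vapply(lens, random_dna, character(1))
    }
    pieces <- character(2L * m + 1L)
    pieces[seq(1L, 2L * m + 1L, by = 2L)] <- ins
    body <- ifelse(kept, residue, "")
    pieces[seq(2L, 2L * m, by = 2L)] <- body
    list(seq = paste(pieces, collapse = ""),
         kept = kept, residue = residue, ins = ins)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# project a set of edit traces (all vs the same base) into a single true
# multiple alignment; insertions falling in the same slot are left-aligned
# in a shared column block (ties resolved by sequence order)
project_traces <- function(base, traces, ids) {
  m <- nchar(base)
  bch <- strsplit(base, "")[[1]]
  ns <- length(traces)
  ins_len <- vapply(traces, function(tr) nchar(tr$ins), integer(m + 1L))
  if (m + 1L == 1L) ins_len <- matrix(ins_len, nrow = 1)
  slot_width <- apply(ins_len, 1, max)
  rows <- vector("list", ns + 1L)
  # base row
  parts <- character(2L * m + 1L)
  for (p in 0:m) {
    parts[2L * p + 1L] <- strrep("-", slot_width[p + 1L])
    if (p < m) parts[2L * p + 2L] <- bch[p + 1L]
  }
  rows[[1]] <- paste(parts, collapse = "")
  for (s in seq_len(ns)) {
    tr <- traces[[s]]
    parts <- character(2L * m + 1L)
    for (p in 0:m) {
      w <- slot_width[p + 1L]
      insert <- tr$ins[p + 1L]
      parts[2L * p + 1L] <-
        paste0(insert, strrep("-", w - nchar(insert)))
      if (p < m)
        parts[2L * p + 2L] <- if (tr$kept[p + 1L]) tr$residue[p + 1L] else "-"
    }
    rows[[s + 1L]] <- paste(parts, collapse = "")
  }
  out <- tibble(id = ids, aligned = unlist(rows))
  # drop columns that are gaps in every row (slots no sequence used)
  chm <- do.call(rbind, strsplit(out$aligned, ""))
  keep <- colSums(chm != "-") > 0
  out$aligned <- apply(chm[, keep, drop = FALSE], 1, paste, collapse = "")
  out
}

#' Generate a synthetic similar-sequence family with its true alignment
#'
#' Emulates the simulated-data protocol: the first sequence is the base (a
#' supplied sequence, e.g. a genome slice, or seeded uniform random DNA) and
#' each further sequence is an independently mutated copy whose identity to
#' the base hits the target. The mutation traces are projected into the true
#' multiple alignment, so generated families can be aligned and scored
#' without external gold data. Substitution rate is `(100 - target) / 100`;
#' insertion and deletion rates each default to 5% of the substitution rate
#' (10% combined), geometric lengths with mean `indel_mean`.
#'
#' @param m Base sequence length (ignored when `base` is supplied).
#' @param n_sequences Family size (>= 2), base included.
#' @param target_identity_pct Target percent identity of each derived
#'   sequence to the base.
#' @param seed Integer seed; the family is a deterministic function of the
#'   arguments.
#' @param base Optional base sequence (character string over `A,C,G,T`).
#' @param indel_frac Combined indel rate as a fraction of the substitution
#'   rate (default 0.1, split evenly between insertions and deletions).
#' @param indel_mean Mean indel length (default 3).
#' @return A `bandmsa_synth_family`: list with `sequences` (tibble `id`,
#'   `seq`), `truth` (tibble `id`, `aligned` -- the true MSA), `realized`
#'   (tibble of per-sequence percent identity to the base) and `config`.
#' @examples
#' fam <- generate_family(m = 300, n_sequences = 3,
#'                        target_identity_pct = 95, seed = 1)
#' fam$realized
#' @export
generate_family <- function(m = 1000, n_sequences = 2, target_identity_pct = 95,
                            seed = 1, base = NULL, indel_frac = 0.1,
                            indel_mean = 3) {
  stopifnot(n_sequences >= 2, target_identity_pct >= 0,
            target_identity_pct <= 100)
  sub_rate <- (100 - target_identity_pct) / 100
  ins_rate <- indel_frac / 2 * sub_rate
  del_rate <- indel_frac / 2 * sub_rate
  withr::with_seed(as.integer(seed), {
    if (is.null(base)) base <- random_dna(m) else m <- nchar(base)
    ids <- paste0("s", seq_len(n_sequences))
    traces <- lapply(seq_len(n_sequences - 1L), function(s) {
      mutate_seq(base, sub_rate, ins_rate, del_rate, indel_mean)
    })
    seqs <- tibble(
      id = ids,
      seq = c(base, vapply(traces, `[[`, character(1), "seq"))
    )
    truth <- project_traces(base, traces, ids)
    realized <- tibble(
      id = ids,
      identity_pct = c(100, vapply(traces, function(tr) {
        100 * sum(tr$kept & tr$residue == strsplit(base, "")[[1]]) /
          max(1, sum(tr$kept))
      }, numeric(1)))
    )
    structure(
      list(sequences = seqs, truth = truth, realized = realized,
           config = list(m = m, n_sequences = n_sequences,
                         target_identity_pct = target_identity_pct,
                         sub_rate = sub_rate, ins_rate = ins_rate,
                         del_rate = del_rate, indel_mean = indel_mean,
                         seed = seed)),
      class = "bandmsa_synth_family"
    )
  })
}

#' @export
print.bandmsa_synth_family <- function(x, ...) {
  cat("<synthetic family>", nrow(x$sequences), "sequences, base length",
      x$config$m, ", target identity", x$config$target_identity_pct, "%\n")
  invisible(x)
}

#' Build a knowledge base from synthetic training datasets
#'
#' For each training dataset a base/mutant pair is generated at a target
#' identity drawn from `identity_range`, both sequences are partitioned into
#' equal-size segments, the most distant positional segment pair (lowest
#' estimated identity, ties by length difference) supplies the feature key,
#' and [min_band_oracle()] on that segment pair supplies the minimal band,
#' stored as `diagonals_pct = 100 * max(d*, 1) / segment length` (at least
#' one diagonal, so the stored percentage is positive).
#'
#' @param n_datasets Number of training datasets (>= 1; 50 is typical).
#' @param identity_range Two-element range of target identities to sample.
#' @param m Training sequence length (default 1000).
#' @param segment_size Segment size used for training (default 500).
#' @param scoring A [scoring_params()] object.
#' @param seed Integer seed; the knowledge base is deterministic given it.
#' @param tolerance_pct Lookup tolerance of the returned knowledge base.
#' @param min_seed Seed length for the identity estimate (default 8).
#' @return A `bandmsa_kb`.
#' @export
build_training_kb <- function(n_datasets = 50, identity_range = c(50, 99),
                              m = 1000, segment_size = 500,
                              scoring = scoring_params(), seed = 1,
                              tolerance_pct = 3, min_seed = 8) {
  stopifnot(n_datasets >= 1)
  kb <- kb_new(tolerance_pct = tolerance_pct)
  targets <- withr::with_seed(as.integer(seed), {
    runif(n_datasets, identity_range[1], identity_range[2])
  })
  for (ds in seq_len(n_datasets)) {
    fam <- generate_family(m = m, n_sequences = 2,
                           target_identity_pct = targets[ds],
                           seed = as.integer(seed) + ds)
    a <- fam$sequences$seq[1]
    b <- fam$sequences$seq[2]
    segs <- partition_pair(a, b, segment_size)
    feats <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      pair_similarity(segs$seg_a[i], segs$seg_b[i], min_seed = min_seed)
    })
    worst <- order(feats$identity_pct, -feats$length_diff_pct)[1]
    dstar <- min_band_oracle(segs$seg_a[worst], segs$seg_b[worst], scoring)
    seglen <- max(nchar(segs$seg_a[worst]), nchar(segs$seg_b[worst]))
    kb <- kb_learn(kb,
                   length_diff_pct = round(feats$length_diff_pct[worst], 2),
                   identity_pct = round(feats$identity_pct[worst], 2),
                   diagonals_pct = 100 * max(dstar, 1L) / seglen)
  }
  kb
}
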