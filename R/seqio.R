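#' Read DNA/RNA sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a tibble with one row per
#' record. Residues are uppercased on ingest; whitespace inside sequence
#' lines is removed; the record id is the first whitespace-delimited token of
#' the header. Only the nucleotide alphabet `A, C, G, T, U, N` (and, when
#' `gapped = TRUE`, the gap character `-`) is accepted.
#'
#' @param path Path to a FASTA file.
#' @param rna_to_dna If `TRUE` (default), `U` is normalised to `T` so RNA and
#'   DNA inputs share one alphabet; set to `FALSE` to preserve `U`.
#' @param gapped If `TRUE`, `-` is allowed in the residues (used to read
#'   alignments written by [write_fasta()]).
#' @return A tibble with columns `id` (character) and `seq` (character),
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt", ">b", "GGTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, rna_to_dna = TRUE, gapped = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("not FASTA-parseable: ", path, " (",
                                     conditionMessage(e), ")"))
  )
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids)))
    abort("FASTA record with empty header")
  if (anyDuplicated(ids))
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(gsub("\\s+", "", as.character(set)))
  allowed <- "ACGTUN"
  if (gapped) allowed <- paste0(allowed, "-")
  bad <- stringr::str_remove_all(seqs, paste0("[", allowed, "]"))
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    abort(sprintf("illegal character '%s' in record '%s'",
                  substr(bad[i], 1, 1), ids[i]))
  }
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1]
    abort(sprintf("record '%s' has no residues", ids[i]))
  }
  if (rna_to_dna) seqs <- gsub("U", "T", seqs, fixed = TRUE)
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences or gapped alignment rows to FASTA
#'
#' @param x A tibble (or data frame) with columns `id` and `seq`; `seq` may
#'   contain `-` gap characters, so alignment rows round-trip unchanged.
#' @param path Output file path.
#' @param width Line-wrap width in characters (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (anyDuplicated(x$id)) abort("duplicate ids in FASTA output")
  if (nrow(x) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = max(1L, as.integer(width)))
  invisible(path)
}

#' Partition sequences into equal-size segments
#'
#' Each sequence is cut into consecutive segments of exactly `segment_size`
#' residues; only the final segment of a sequence may be shorter.
#' Concatenating a sequence's segments in index order reproduces it exactly.
#' Segment coordinates are 0-based.
#'
#' @param x A tibble with columns `id` and `seq` (as from [read_fasta()]), or
#'   a single character string.
#' @param segment_size Positive integer segment length.
#' @return A tibble with columns `seq_id`, `index` (0-based segment ordinal),
#'   `start` (0-based offset into the source sequence) and `seg`.
#' @examples
#' partition_segments(tibble::tibble(id = "s", seq = "ACGTACGTAC"), 4)
#' @export
partition_segments <- function(x, segment_size) {
  segment_size <- as.integer(segment_size)
  if (is.na(segment_size) || segment_size < 1)
    abort("segment_size must be a positive integer")
  if (is.character(x)) x <- tibble(id = "seq", seq = x)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]
    len <- nchar(s)
    starts <- seq.int(0L, len - 1L, by = segment_size)
    ends <- pmin(starts + segment_size, len)
    tibble(
      seq_id = x$id[i],
      index = seq_along(starts) - 1L,
      start = starts,
      seg = substring(s, starts + 1L, ends)
    )
  })
}
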