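#' Plot a multiple alignment as a residue tile map
#'
#' Intended for small alignments (a few dozen rows, a few thousand
#' columns); gaps are shown as blanks.
#'
#' @param object A `bandmsa_msa`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bandmsa_msa <- function(object, ...) {
  long <- tidy(object) |>
    mutate(chars = strsplit(.data$aligned, "")) |>
    tidyr::unnest_longer("chars", indices_to = "column") |>
    filter(.data$chars != "-")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$id,
                                     fill = .data$chars)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "base") +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot knowledge-base entries
#'
#' Diagonals percentage against identity, point size showing the length
#' difference: visualises the inverse relation between sequence similarity
#' and the band needed for an optimal alignment.
#'
#' @param kb A `bandmsa_kb`.
#' @return A ggplot object.
#' @export
plot_kb <- function(kb) {
  stopifnot(inherits(kb, "bandmsa_kb"))
  ggplot2::ggplot(kb$entries,
                  ggplot2::aes(x = .data$identity_pct,
                               y = .data$diagonals_pct,
                               size = .data$length_diff_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "identity (%)", y = "diagonals filled (%)",
                  size = "length\ndiff (%)") +
    ggplot2::theme_minimal()
}

#' Plot the compute-cost trend across runs
#'
#' Takes a tibble with one row per [run_msa()] call (e.g. built from
#' [glance()] plus a column identifying the condition) and plots total DP
#' cells filled against the condition -- the compute-cost analogue of a
#' runtime-vs-similarity curve.
#'
#' @param runs Tibble with columns `identity_pct` and `total_cells`.
#' @return A ggplot object.
#' @export
plot_cells_trend <- function(runs) {
  stopifnot(all(c("identity_pct", "total_cells") %in% names(runs)))
  ggplot2::ggplot(runs, ggplot2::aes(x = .data$identity_pct,
                                     y = .data$total_cells)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "family identity (%)", y = "DP cells filled") +
    ggplot2::theme_minimal()
}
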