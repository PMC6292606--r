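#' Published benchmark confusion counts
#'
#' Object-level confusion counts reported for a darkfield-microscopy CTC
#' benchmark of 263 images of healthy blood spiked with three tumor cell
#' lines (Hs 578T, MCF7, DLD-1; 632 fluorescence-validated CTCs in total,
#' about 1270 cells per image on average). Two evaluation campaigns are
#' included: `per_line` models trained and tested within each cell line
#' (plus the pooled row), and `generic` — a single combined model applied
#' to each line. Feeding these counts through [compute_metrics()]
#' reproduces the published sensitivity, FN-rate, estimated FP-rate and
#' estimated specificity figures under this package's rounding convention.
#'
#' @param campaign `"per_line"` or `"generic"`.
#' @return A confusion-counts tibble with a `dataset` column, ready for
#'   [compute_metrics()] row by row.
#' @export
ctc_benchmark_counts <- function(campaign = c("per_line", "generic")) {
  campaign <- match.arg(campaign)
  base <- switch(campaign,
    per_line = tibble::tibble(
      dataset = c("hs578t", "mcf7", "dld1", "combined"),
      n_images = c(83L, 60L, 120L, 263L),
      n_gt = c(235L, 200L, 197L, 632L),
      TP = c(230L, 185L, 168L, 587L),
      FP = c(1L, 14L, 36L, 51L)
    ),
    generic = tibble::tibble(
      dataset = c("hs578t", "mcf7", "dld1"),
      n_images = c(83L, 60L, 120L),
      n_gt = c(235L, 200L, 197L),
      TP = c(229L, 190L, 163L),
      FP = c(5L, 52L, 36L)
    )
  )
  dplyr::mutate(base, FN = .data$n_gt - .data$TP,
                avg_cells_per_image = 1270)[
    , c("dataset", "TP", "FN", "FP", "n_gt", "n_images",
        "avg_cells_per_image")]
}
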