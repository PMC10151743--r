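#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the family composition of a sample's DNJ-stems
#'
#' Summed family abundance per stem, split into the top member and the
#' remaining family members, colored by the evolution call - the picture
#' behind stem-based marker screening: evolving stems whose top member sits
#' below the conventional 5% threshold are exactly the markers that
#' single-clonotype screening misses.
#'
#' @param analysis A `stem_analysis`.
#' @param top_n Plot at most this many families (by total abundance).
#' @return A ggplot object.
#' @export
plot_family_composition <- function(analysis, top_n = 20) {
  f <- tidy(analysis)
  f <- utils::head(f[order(-f$total_percent), ], top_n)
  long <- dplyr::bind_rows(
    tibble::tibble(stem = f$stem, part = "top member",
                   percent = f$top_percent, call = f$call),
    tibble::tibble(stem = f$stem, part = "other members",
                   percent = f$total_percent - f$top_percent, call = f$call)
  )
  long$stem <- factor(long$stem, levels = rev(f$stem))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$percent, y = .data$stem, fill = .data$part,
    alpha = .data$call
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 5, linetype = "dashed") +
    ggplot2::scale_alpha_manual(values = c(evolving = 1, stable = 0.45)) +
    ggplot2::labs(x = "% of usable reads", y = "DNJ-stem",
                  fill = NULL, alpha = "call",
                  title = paste0("Stem families: ", analysis$sample$sample_id)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_family_composition
#' @param object A `stem_analysis`.
#' @param ... Passed to [plot_family_composition()].
#' @export
autoplot.stem_analysis <- function(object, ...) {
  plot_family_composition(object, ...)
}

#' Plot stem-level vs top-member MRD across timepoints
#'
#' One line per stem for the summed family abundance, one for the top
#' member alone; the vertical gap is the MRD underestimation that
#' single-clonotype tracking incurs.
#'
#' @param tracking A [track_longitudinal()] result.
#' @return A ggplot object.
#' @export
plot_mrd_tracking <- function(tracking) {
  series <- tidyr::unnest(tracking[, c("stem", "measurements")],
                          "measurements", names_sep = "_")
  long <- dplyr::bind_rows(
    tibble::tibble(stem = series$stem,
                   timepoint = series$measurements_timepoint_label,
                   what = "stem (family sum)",
                   percent = series$measurements_stem_percent_reads),
    tibble::tibble(stem = series$stem,
                   timepoint = series$measurements_timepoint_label,
                   what = "top member",
                   percent = series$measurements_top_member_percent_reads)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$timepoint, y = .data$percent, group = .data$what,
    color = .data$what
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stem, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% of usable reads", color = NULL,
                  title = "Stem-based vs top-member MRD") +
    ggplot2::theme_minimal()
}
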