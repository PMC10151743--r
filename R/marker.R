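#' Marker DNJ-stem policy
#'
#' A DNJ-stem qualifies as an MRD marker when the summed abundance of its
#' family reaches 5% of usable reads or 1% of cell equivalents, or when it
#' shows clonal evolution at any abundance.
#'
#' @param min_percent_reads Summed family abundance threshold in % usable
#'   reads (default 5).
#' @param min_percent_cells Summed family abundance threshold in % cell
#'   equivalents (default 1); only evaluated when spike-in normalization is
#'   available.
#' @param evolving_at_any_abundance Whether an evolving call alone makes a
#'   marker (default `TRUE`).
#' @return A list of class `marker_policy`.
#' @export
marker_policy <- function(min_percent_reads = 5, min_percent_cells = 1,
                          evolving_at_any_abundance = TRUE) {
  stopifnot(min_percent_reads > 0, min_percent_cells > 0)
  structure(list(min_percent_reads = min_percent_reads,
                 min_percent_cells = min_percent_cells,
                 evolving_at_any_abundance = evolving_at_any_abundance),
            class = "marker_policy")
}

#' Percent of sample cell equivalents for a read count
#'
#' Reads are converted to cell equivalents with the spike-in factor; the
#' denominator is the sample's total patient-cell equivalents, taken as
#' `usable_reads * cells_per_read`.
#'
#' @param read_count Read count(s).
#' @param sample An [airr_sample()].
#' @param qc A [normalization_factor()] result.
#' @return Percentage of cell equivalents, or `NA` when normalization is
#'   unavailable.
#' @export
percent_cells <- function(read_count, sample, qc = normalization_factor(sample)) {
  if (!qc$available) return(rep(NA_real_, length(read_count)))
  total_cells <- sample$usable_reads * qc$cells_per_read
  100 * read_count * qc$cells_per_read / total_cells
}

#' Call marker status for a stem family
#'
#' @param family One row of an evolution-called family tibble.
#' @param sample The [airr_sample()].
#' @param qc A [normalization_factor()] result for the sample.
#' @param policy A [marker_policy()].
#' @return A list with `is_marker`, `criteria_fired` (subset of
#'   `reads_threshold`, `cells_threshold`, `evolving`) and
#'   `would_conventional_miss` - `TRUE` when the stem is a marker but its
#'   single most abundant member stays below the conventional 5%-of-reads
#'   screening threshold and would have been ignored on its own.
#' @export
call_marker <- function(family, sample, qc = normalization_factor(sample),
                        policy = marker_policy()) {
  fam <- if (is.data.frame(family)) family else tibble::as_tibble(family)
  fired <- character(0)
  if (fam$total_percent[1] >= policy$min_percent_reads) {
    fired <- c(fired, "reads_threshold")
  }
  pc <- percent_cells(fam$total_reads[1], sample, qc)
  if (!is.na(pc) && pc >= policy$min_percent_cells) {
    fired <- c(fired, "cells_threshold")
  }
  if (policy$evolving_at_any_abundance && identical(fam$call[1], "evolving")) {
    fired <- c(fired, "evolving")
  }
  is_marker <- length(fired) > 0
  list(
    is_marker = is_marker,
    criteria_fired = fired,
    would_conventional_miss = is_marker && fam$top_percent[1] < 5
  )
}

#' Call marker status for every family of a sample
#'
#' @param families Evolution-called family tibble.
#' @param sample The [airr_sample()].
#' @param policy A [marker_policy()].
#' @return `families` with `is_marker`, `criteria_fired` (list-column) and
#'   `would_conventional_miss` columns.
#' @export
call_markers <- function(families, sample, policy = marker_policy()) {
  qc <- normalization_factor(sample)
  calls <- purrr::map(seq_len(nrow(families)),
                      ~ call_marker(families[.x, ], sample, qc, policy))
  families$is_marker <- purrr::map_lgl(calls, "is_marker")
  families$criteria_fired <- purrr::map(calls, "criteria_fired")
  families$would_conventional_miss <- purrr::map_lgl(calls, "would_conventional_miss")
  families
}
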