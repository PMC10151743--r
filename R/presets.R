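#' Depth-subsample a repertoire
#'
#' Binomial thinning of every clonotype's read count (and of the QC reads)
#' to a fraction of the original depth, dropping clonotypes that lose all
#' reads - the sampling process by which a peripheral-blood aliquot shows
#' fewer of a family's low-abundance members than marrow.
#'
#' @param sample An [airr_sample()].
#' @param fraction Retention probability per read.
#' @param sample_id,compartment New identifiers for the thinned sample.
#' @return A new [airr_sample()].
#' @export
subsample_repertoire <- function(sample, fraction,
                                 sample_id = paste0(sample$sample_id, "_sub"),
                                 compartment = "PB") {
  stopifnot(fraction > 0, fraction <= 1)
  cl <- sample$clonotypes
  cl$read_count <- stats::rbinom(nrow(cl), cl$read_count, fraction)
  cl <- cl[cl$read_count > 0, , drop = FALSE]
  airr_sample(cl, sample_id = sample_id, patient_id = sample$patient_id,
              compartment = compartment,
              timepoint_label = sample$timepoint_label,
              library = sample$library,
              qc_reads = stats::rbinom(1, sample$qc_reads, fraction),
              qc_cell_equivalents = sample$qc_cell_equivalents)
}

#' Simulate a follow-up sample for a patient
#'
#' Re-draws the within-family composition of the patient's leukemic stems
#' at a reduced leukemic fraction (therapy response), optionally removes
#' the diagnostic top member of every evolving stem (`kill_top_member`),
#' lets evolving burst stems emit one new member (ongoing recombination),
#' and refills depth with fresh polyclonal background.
#'
#' @param patient_sim A [simulate_patient()] result.
#' @param catalog,cfg See [simulate_patient()].
#' @param timepoint Follow-up timepoint label.
#' @param leukemic_fraction Leukemic read fraction at this timepoint.
#' @param kill_top_member Remove each evolving stem's diagnostic top member.
#' @param compartment Compartment label.
#' @return An IGH-VJ [airr_sample()].
#' @export
simulate_followup <- function(patient_sim, catalog, cfg = sim_config(),
                              timepoint = "day6",
                              leukemic_fraction = 0.05,
                              kill_top_member = FALSE,
                              compartment = "BM") {
  diag_vj <- patient_sim$vj$clonotypes
  truth <- patient_sim$truth
  fu_cfg <- cfg
  fu_cfg$leukemic_fraction <- leukemic_fraction

  stem_rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    s <- truth$stem[i]
    rows <- diag_vj[endsWith(diag_vj$junction, s), , drop = FALSE]
    rows <- rows[is.na(rows$parent_id) | rows$parent_id == "", , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    if (kill_top_member && isTRUE(truth$evolving[i]) && nrow(rows) > 1) {
      top <- which.max(rows$read_count)
      rows <- rows[-top, , drop = FALSE]
    }
    if (isTRUE(truth$evolving[i]) &&
        truth$mechanism[i] %in% c("DV_to_DJ", "mixed") &&
        !is.na(truth$mechanism[i])) {
      root <- list(d_call = rows$d_call[1], j_call = rows$j_call[1],
                   d_part = rows$d_part[1], n2 = rows$n2[1],
                   j_part = rows$j_part[1])
      new_member <- simulate_burst(root, 1, catalog, cfg)
      new_member$role <- "burst_new"
      rows <- dplyr::bind_rows(rows, new_member)
    }
    rows$read_count <- NULL
    rows
  })
  stem_rows <- stem_rows[!vapply(stem_rows, is.null, TRUE)]

  pid <- patient_sim$vj$patient_id
  stem_w <- stats::rgamma(length(stem_rows), 1)
  stem_w <- stem_w / sum(stem_w)
  leuk <- purrr::imap_dfr(stem_rows, function(rows, i) {
    w <- stats::rgamma(nrow(rows), 1)
    rows$weight <- stem_w[[i]] * w / sum(w)
    rows
  })
  bg <- simulate_rearrangements_vec(cfg$n_background, catalog, cfg, "IGH-VJ")
  bg_stem <- paste0(str_tail(bg$d_part, 3), bg$n2, bg$j_part)
  bg <- bg[!bg_stem %in% truth$stem, , drop = FALSE]
  bg$role <- "background"
  bg$weight <- stats::rgamma(nrow(bg), 1)
  bg$weight <- (1 - leukemic_fraction) * bg$weight / sum(bg$weight)
  leuk$weight <- leuk$weight * leukemic_fraction
  rows <- dplyr::bind_rows(leuk, bg)
  weights <- rows$weight / sum(rows$weight)
  rows$weight <- NULL
  finalize_library(rows, weights, fu_cfg, pid,
                   paste0(pid, "_", timepoint, "_", compartment, "_VJ"),
                   "IGH-VJ", compartment, timepoint)
}

#' Simulate and write a complete synthetic dataset
#'
#' Scenario presets:
#' * `diagnosis_only` - one BM diagnostic sample pair (IGH-VJ + IGH-DJ
#'   libraries) per patient;
#' * `bm_pb_pair` - adds a depth-thinned PB replicate of each diagnostic
#'   sample;
#' * `longitudinal` - adds follow-up IGH-VJ samples at the configured
#'   timepoints with reduced leukemic fractions (and optional top-member
#'   kill-off).
#'
#' Writes one AIRR Rearrangement TSV per sample/library, a sample-metadata
#' TSV and a ground-truth JSON under `out_dir`. Output is deterministic
#' per `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param preset One of `"diagnosis_only"`, `"bm_pb_pair"`,
#'   `"longitudinal"`.
#' @param catalog A [locus_catalog()].
#' @return Invisibly, a list with the simulated objects (`cohort`,
#'   `extra` samples per preset), the `metadata` tibble and the file
#'   `paths`.
#' @export
emit_cohort <- function(cfg = sim_config(), out_dir,
                        preset = c("diagnosis_only", "bm_pb_pair",
                                   "longitudinal"),
                        catalog = toy_locus()) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(cfg, catalog)

  samples <- list()
  for (pid in names(cohort$patients)) {
    samples[[length(samples) + 1]] <- cohort$patients[[pid]]$vj
    samples[[length(samples) + 1]] <- cohort$patients[[pid]]$dj
  }
  extra <- list()
  if (preset == "bm_pb_pair") {
    for (pid in names(cohort$patients)) {
      p <- cohort$patients[[pid]]
      pb_vj <- subsample_repertoire(p$vj, cfg$pb_depth_fraction,
                                    sample_id = sub("_BM_", "_PB_",
                                                    p$vj$sample_id),
                                    compartment = "PB")
      pb_dj <- subsample_repertoire(p$dj, cfg$pb_depth_fraction,
                                    sample_id = sub("_BM_", "_PB_",
                                                    p$dj$sample_id),
                                    compartment = "PB")
      extra <- c(extra, list(pb_vj, pb_dj))
    }
  } else if (preset == "longitudinal") {
    for (pid in names(cohort$patients)) {
      p <- cohort$patients[[pid]]
      for (tp in names(cfg$followup_leukemic)) {
        extra[[length(extra) + 1]] <- simulate_followup(
          p, catalog, cfg, timepoint = tp,
          leukemic_fraction = cfg$followup_leukemic[[tp]],
          kill_top_member = cfg$kill_top_member
        )
      }
    }
  }
  samples <- c(samples, extra)

  meta <- purrr::map_dfr(samples, function(s) {
    tibble::tibble(
      sample_id = s$sample_id, patient_id = s$patient_id,
      compartment = s$compartment, timepoint_label = s$timepoint_label,
      library = s$library,
      qc_cell_equivalents_input = s$qc_cell_equivalents,
      tsv = paste0(s$sample_id, ".tsv")
    )
  })
  paths <- character(0)
  for (s in samples) {
    p <- file.path(out_dir, paste0(s$sample_id, ".tsv"))
    write_airr_sample(s, p)
    paths <- c(paths, p)
  }
  meta_path <- file.path(out_dir, "metadata.tsv")
  readr::write_tsv(meta, meta_path, progress = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(seed = cfg$seed, preset = preset, stems = cohort$truth),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(list(cohort = cohort, extra = extra, metadata = meta,
                 paths = c(paths, meta_path, truth_path), dir = out_dir))
}
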