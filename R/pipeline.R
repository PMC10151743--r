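run_manifest <- function(out_dir, seed = NA, config = NULL, inputs = character(0)) {
  manifest <- list(
    package = "dnjstem",
    version = as.character(utils::packageVersion("dnjstem")),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config) else NA,
    input_hashes = if (length(inputs) > 0) {
      stats::setNames(as.list(vapply(inputs, function(p) {
        rlang::hash(readLines(p, warn = FALSE))
      }, "")), basename(inputs))
    } else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write per-sample stem-family reports and per-patient marker JSON
#'
#' Emits one `stem_families_<sample>.tsv` per analyzed sample (evidence and
#' mechanism columns included, percentages rendered with 2 decimals), a
#' `markers_<patient>.json` per patient, and a plain-text run log.
#'
#' @param analyses List of `stem_analysis` objects.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the run log/manifest.
#' @return Invisibly, the vector of written paths.
#' @export
write_reports <- function(analyses, out_dir, seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (a in analyses) {
    tab <- tidy(a)
    num <- vapply(tab, is.numeric, TRUE) & grepl("percent", names(tab))
    tab[num] <- lapply(tab[num], round, digits = 2)
    p <- file.path(out_dir, paste0("stem_families_", a$sample$sample_id, ".tsv"))
    readr::write_tsv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  by_patient <- split(analyses,
                      vapply(analyses, function(a) a$sample$patient_id, ""))
  for (pid in names(by_patient)) {
    markers <- dplyr::bind_rows(purrr::map(by_patient[[pid]], function(a) {
      f <- tidy(a)
      f[f$is_marker, intersect(c("stem", "library", "call", "total_percent",
                                 "criteria_fired", "would_conventional_miss",
                                 "mechanism_summary", "rooted"), names(f)),
        drop = FALSE]
    }))
    p <- file.path(out_dir, paste0("markers_", pid, ".json"))
    jsonlite::write_json(markers, p, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- c(paths, p)
  }
  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    paste0("dnjstem ", utils::packageVersion("dnjstem")),
    paste0("seed: ", seed),
    paste0("samples: ", length(analyses)),
    paste0("written: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), log_path)
  paths <- c(paths, log_path)
  invisible(paths)
}

#' Pipeline stage runners
#'
#' Orchestration wrappers mirroring the pipeline's stages, each validating
#' its inputs, writing outputs plus a JSON run manifest into `out_dir`, and
#' returning its result invisibly. `run_simulate()` wraps [emit_cohort()];
#' `run_call()` reads a simulated/collected dataset directory (AIRR TSVs +
#' `metadata.tsv`) and produces per-sample stem-family reports;
#' `run_mrd()` tracks a patient's diagnostic markers through follow-up
#' samples; `run_compare()` runs the BM/PB overlap; `run_cohort()`
#' aggregates patient summaries.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @param preset Scenario preset for [emit_cohort()].
#' @return See each stage's description.
#' @export
run_simulate <- function(cfg, out_dir, preset = "diagnosis_only") {
  res <- emit_cohort(cfg, out_dir, preset)
  run_manifest(out_dir, seed = cfg$seed, config = unclass(cfg))
  invisible(res)
}

#' @rdname run_simulate
#' @param dataset_dir Directory with AIRR TSVs and `metadata.tsv`.
#' @param catalog A [locus_catalog()].
#' @param ... Policies forwarded to [analyze_sample_pair()].
#' @export
run_call <- function(dataset_dir, out_dir, catalog = toy_locus(), ...) {
  meta_path <- file.path(dataset_dir, "metadata.tsv")
  if (!file.exists(meta_path)) {
    stop("no metadata.tsv in ", dataset_dir, call. = FALSE)
  }
  meta <- read_sample_metadata(meta_path)
  analyses <- list()
  key <- paste(meta$patient_id, meta$timepoint_label, meta$compartment)
  for (k in unique(key)) {
    rows <- meta[key == k, , drop = FALSE]
    read_one <- function(lib) {
      r <- rows[rows$library == lib, , drop = FALSE]
      if (nrow(r) == 0) return(NULL)
      read_airr_sample(file.path(dataset_dir, r$tsv[1]), r[1, ])
    }
    vj <- read_one("IGH-VJ")
    dj <- read_one("IGH-DJ")
    if (!is.null(vj) && !is.null(dj)) {
      pair <- analyze_sample_pair(vj, dj, catalog, ...)
      analyses <- c(analyses, list(pair$vj, pair$dj))
    } else if (!is.null(vj)) {
      analyses <- c(analyses, list(analyze_sample(vj, catalog, ...)))
    } else if (!is.null(dj)) {
      analyses <- c(analyses, list(analyze_sample(dj, catalog, ...)))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_reports(analyses, out_dir)
  run_manifest(out_dir, inputs = meta_path)
  invisible(analyses)
}

#' @rdname run_simulate
#' @param diagnostic A `stem_analysis` of the diagnostic sample.
#' @param followups List of follow-up [airr_sample()]s in time order.
#' @export
run_mrd <- function(diagnostic, followups, out_dir) {
  tracking <- track_longitudinal(diagnostic, followups)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- tidyr::unnest(
    tracking[, c("stem", "call", "measurements")], "measurements",
    names_sep = "_"
  )
  readr::write_tsv(series, file.path(out_dir, "mrd_timeseries.tsv"),
                   progress = FALSE)
  flags <- tracking[, c("stem", "call", "rooted", "stem_untraceable",
                        "top_member_vanished", "top_member_displaced",
                        "new_members_emerged")]
  readr::write_tsv(flags, file.path(out_dir, "mrd_flags.tsv"), progress = FALSE)
  run_manifest(out_dir)
  invisible(tracking)
}

#' @rdname run_simulate
#' @param bm,pb Analyzed BM and PB samples of one patient-timepoint.
#' @export
run_compare <- function(bm, pb, out_dir) {
  overlap <- compare_compartments(bm, pb)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(overlap$stems, file.path(out_dir, "compartment_stems.tsv"),
                   progress = FALSE)
  readr::write_tsv(overlap$member_overlap,
                   file.path(out_dir, "member_overlap.tsv"), progress = FALSE)
  run_manifest(out_dir)
  invisible(overlap)
}

#' @rdname run_simulate
#' @param patient_analyses List of per-patient lists of `stem_analysis`
#'   objects.
#' @export
run_cohort <- function(patient_analyses, out_dir) {
  patients <- dplyr::bind_rows(purrr::map(patient_analyses, patient_summary))
  summary <- summarize_cohort(patients)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(patients, file.path(out_dir, "patient_summaries.tsv"),
                   progress = FALSE)
  run_manifest(out_dir)
  invisible(list(patients = patients, summary = summary))
}
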