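draw_replaceable_v <- function(catalog, min_downstream = 4) {
  vs <- catalog[catalog$segment_type == "V", , drop = FALSE]
  eligible <- vs$name[vs$locus_rank <= max(vs$locus_rank) - min_downstream]
  sample(eligible, 1)
}

sim_stem <- function(mechanism, catalog, cfg) {
  # returns list(vj = member rows, dj = member rows, root_anatomy, truth row)
  vj <- NULL
  dj <- NULL
  root_emitted <- FALSE
  emit_p <- cfg$dj_root_emit_prob
  if (mechanism == "stable") {
    clone <- simulate_rearrangement(catalog, cfg, "IGH-VJ", min_d_keep = 5)
    clone$role <- "stable"
    vj <- clone
    origin <- clone
    if (stats::runif(1) < emit_p[["stable"]]) {
      root <- make_clonotype_row(d_call = clone$d_call, j_call = clone$j_call,
                                 d_part = clone$d_part, n2 = clone$n2,
                                 j_part = clone$j_part)
      root$role <- "dj_root"
      dj <- root
      root_emitted <- TRUE
    }
  } else if (mechanism == "DV_to_DJ") {
    root <- simulate_rearrangement(catalog, cfg, "IGH-DJ", min_d_keep = 7)
    size <- rburst_size(cfg)
    members <- simulate_burst(root, size, catalog, cfg)
    members$role <- "burst"
    vj <- members
    origin <- root
    if (stats::runif(1) < emit_p[["DV_to_DJ"]]) {
      root$role <- "dj_root"
      dj <- root
      root_emitted <- TRUE
    }
  } else if (mechanism == "VH_replacement") {
    mother <- simulate_rearrangement(catalog, cfg, "IGH-VJ", min_d_keep = 7)
    # a replacement mother must itself be replaceable: require several
    # downstream V genes (most-distal Vs cannot undergo VH replacement)
    mother$v_call <- draw_replaceable_v(catalog)
    mother$v_part <- str_tail(catalog_get(catalog, mother$v_call, "V")$sequence,
                              nchar(mother$v_part))
    mother$junction <- paste0(mother$v_part, mother$n1, mother$d_part,
                              mother$n2, mother$j_part)
    mother$role <- "mother"
    n_chains <- 1 + stats::rpois(1, cfg$replacement_chains_mean)
    members <- purrr::map_dfr(seq_len(n_chains), function(ch) {
      rounds <- sample(seq_len(cfg$replacement_rounds_max), 1)
      simulate_replacement_chain(mother, rounds, catalog, cfg)
    })
    members$role <- "replacement"
    vj <- dplyr::bind_rows(mother, members)
    origin <- mother
    if (stats::runif(1) < emit_p[["VH_replacement"]]) {
      root <- make_clonotype_row(d_call = mother$d_call, j_call = mother$j_call,
                                 d_part = mother$d_part, n2 = mother$n2,
                                 j_part = mother$j_part)
      root$role <- "dj_root"
      dj <- root
      root_emitted <- TRUE
    }
  } else if (mechanism == "D_to_DJ") {
    root <- simulate_rearrangement(catalog, cfg, "IGH-DJ", min_d_keep = 7)
    root$role <- "dj_root"
    n_tandem <- 2 + stats::rpois(1, cfg$tandem_count_mean)
    members <- purrr::map_dfr(seq_len(n_tandem),
                              function(i) simulate_d_dj_tandem(root, catalog, cfg))
    members$role <- "tandem"
    dj <- dplyr::bind_rows(root, members)
    origin <- root
    root_emitted <- TRUE
  } else if (mechanism == "mixed") {
    root <- simulate_rearrangement(catalog, cfg, "IGH-DJ", min_d_keep = 7)
    mother_v <- catalog_get(catalog, draw_replaceable_v(catalog), "V")
    mother <- make_clonotype_row(
      v_call = mother_v$name, d_call = root$d_call, j_call = root$j_call,
      v_part = str_tail(mother_v$sequence, 8),
      n1 = rand_nt(rgeom_capped(cfg$n_region_mean, cfg$n_region_max)),
      d_part = root$d_part, n2 = root$n2, j_part = root$j_part
    )
    mother$role <- "mother"
    burst <- simulate_burst(root, max(cfg$burst_size_min, rburst_size(cfg) %/% 2),
                            catalog, cfg)
    burst$role <- "burst"
    repl <- purrr::map_dfr(seq_len(1 + stats::rpois(1, 1)), function(ch) {
      simulate_replacement_chain(mother,
                                 sample(seq_len(cfg$replacement_rounds_max), 1),
                                 catalog, cfg)
    })
    repl$role <- "replacement"
    vj <- dplyr::bind_rows(mother, burst, repl)
    origin <- root
    if (stats::runif(1) < emit_p[["mixed"]]) {
      root$role <- "dj_root"
      dj <- root
      root_emitted <- TRUE
    }
  } else {
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  }
  stem <- extract_dnj_stem(origin)$stem
  fps <- if (!is.null(vj) && "planted_footprint" %in% names(vj)) {
    vj$planted_footprint[!is.na(vj$planted_footprint)]
  } else numeric(0)
  truth <- tibble::tibble(
    stem = stem,
    evolving = mechanism != "stable",
    mechanism = if (mechanism == "stable") NA_character_ else mechanism,
    dj_root_emitted = root_emitted,
    n_vj_members = if (is.null(vj)) 0L else nrow(vj),
    n_dj_members = if (is.null(dj)) 0L else nrow(dj),
    min_planted_footprint = if (length(fps) > 0) min(fps) else NA_real_
  )
  list(vj = vj, dj = dj, truth = truth)
}

finalize_library <- function(rows, weights, cfg, patient_id, sample_id, library,
                             compartment, timepoint) {
  stopifnot(nrow(rows) == length(weights))
  counts <- as.integer(stats::rmultinom(1, cfg$depth, weights))
  rows$read_count <- counts
  rows <- rows[rows$read_count > 0, , drop = FALSE]
  if (nrow(rows) == 0) stop("simulated library came out empty", call. = FALSE)
  # merge chance junction collisions (same junction = same clonotype)
  rows <- rows |>
    dplyr::group_by(.data$junction) |>
    dplyr::mutate(read_count = sum(.data$read_count)) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  rows$clonotype_id <- sprintf("%s_%s_%04d", sample_id,
                               sub("IGH-", "", library), seq_len(nrow(rows)))
  if (!"parent_id" %in% names(rows)) rows$parent_id <- NA_character_
  sats <- add_satellites(rows, cfg)
  rows <- dplyr::bind_rows(rows, sats)
  airr_sample(rows, sample_id = sample_id, patient_id = patient_id,
              compartment = compartment, timepoint_label = timepoint,
              library = library, qc_reads = cfg$qc_reads,
              qc_cell_equivalents = cfg$qc_cell_equivalents)
}

#' Simulate the two-library diagnostic repertoire of one patient
#'
#' Draws the patient's leukemic stems (stable clones plus evolving stems
#' with their mechanism), assigns Dirichlet-distributed read shares within
#' the leukemic fraction (mother clonotypes weighted heavily, burst members
#' lightly), fills the rest of the depth with polyclonal background, adds
#' error satellites, and packages both amplicon libraries.
#'
#' @param catalog A [locus_catalog()].
#' @param cfg A [sim_config()]; uses the current RNG stream.
#' @param patient_id Patient identifier.
#' @param compartment,timepoint Sample metadata labels.
#' @return A list with `vj` and `dj` [airr_sample()]s and a `truth` tibble
#'   (one row per leukemic stem).
#' @export
simulate_patient <- function(catalog, cfg = sim_config(),
                             patient_id = "P01", compartment = "BM",
                             timepoint = "day0") {
  n_evolving <- round(cfg$stems_per_patient * cfg$evolving_fraction)
  n_stable <- cfg$stems_per_patient - n_evolving
  mechs <- c(
    rep("stable", n_stable),
    if (n_evolving > 0) {
      sample(names(cfg$mechanism_mix), n_evolving, replace = TRUE,
             prob = cfg$mechanism_mix)
    }
  )
  stems <- purrr::map(mechs, sim_stem, catalog = catalog, cfg = cfg)
  truth <- dplyr::bind_rows(purrr::map(stems, "truth"))
  truth$patient_id <- patient_id

  assemble <- function(lib_rows_list, library) {
    leuk <- NULL
    if (length(lib_rows_list) > 0) {
      stem_w <- stats::rgamma(length(lib_rows_list), 1)
      stem_w <- stem_w / sum(stem_w)
      leuk <- purrr::imap_dfr(lib_rows_list, function(rows, i) {
        w <- stats::rgamma(nrow(rows), shape = 1)
        w[rows$role == "mother"] <- stats::rgamma(sum(rows$role == "mother"), 15)
        w[rows$role == "dj_root"] <- stats::rgamma(sum(rows$role == "dj_root"), 5)
        rows$weight <- stem_w[[i]] * w / sum(w)
        rows
      })
    }
    bg <- simulate_rearrangements_vec(cfg$n_background, catalog, cfg, library)
    # keep truth labels exact: a background clonotype whose stem collides
    # with a leukemic stem would be an unlabeled family member
    bg_stem <- paste0(str_tail(bg$d_part, 3), bg$n2, bg$j_part)
    bg <- bg[!bg_stem %in% truth$stem, , drop = FALSE]
    bg$role <- "background"
    bg$weight <- stats::rgamma(nrow(bg), 1)
    bg$weight <- (1 - cfg$leukemic_fraction) * bg$weight / sum(bg$weight)
    if (!is.null(leuk) && nrow(leuk) > 0) {
      leuk$weight <- leuk$weight * cfg$leukemic_fraction
      rows <- dplyr::bind_rows(leuk, bg)
    } else {
      rows <- bg
    }
    weights <- rows$weight / sum(rows$weight)
    rows$weight <- NULL
    list(rows = rows, weights = weights)
  }
  vj_list <- purrr::map(stems, "vj")
  dj_list <- purrr::map(stems, "dj")
  vj_asm <- assemble(vj_list[!vapply(vj_list, is.null, TRUE)], "IGH-VJ")
  dj_asm <- assemble(dj_list[!vapply(dj_list, is.null, TRUE)], "IGH-DJ")
  sample_base <- paste0(patient_id, "_", timepoint, "_", compartment)
  vj <- finalize_library(vj_asm$rows, vj_asm$weights, cfg, patient_id,
                         paste0(sample_base, "_VJ"), "IGH-VJ", compartment,
                         timepoint)
  dj <- finalize_library(dj_asm$rows, dj_asm$weights, cfg, patient_id,
                         paste0(sample_base, "_DJ"), "IGH-DJ", compartment,
                         timepoint)
  list(vj = vj, dj = dj, truth = truth, stems = stems)
}

#' Simulate a diagnostic cohort
#'
#' @param cfg A [sim_config()]; `cfg$seed` seeds the whole cohort.
#' @param catalog A [locus_catalog()] (the bundled [toy_locus()] by
#'   default).
#' @return A list with `patients` (per-patient [simulate_patient()]
#'   results, named by patient id) and `truth` (all stem truth rows).
#' @export
simulate_cohort <- function(cfg = sim_config(), catalog = toy_locus()) {
  set.seed(cfg$seed)
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  patients <- purrr::map(ids, function(pid) {
    simulate_patient(catalog, cfg, patient_id = pid)
  })
  names(patients) <- ids
  truth <- dplyr::bind_rows(purrr::map(patients, "truth"))
  list(patients = patients, truth = truth, config = cfg)
}
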