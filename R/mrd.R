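#' Quantify MRD for a diagnostic DNJ-stem in a follow-up sample
#'
#' Every follow-up clonotype whose junction ends with the diagnostic stem
#' string counts as a family member; members are searched at any abundance
#' (the 3-read/0.01% floor is an evolution-calling device, not a detection
#' threshold) to maximize sensitivity. Stem MRD is the summed abundance of
#' all detected members, which by construction is at least the
#' most-abundant-member MRD - following the stem avoids the
#' underestimation that single-clonotype tracking suffers when family
#' composition shifts.
#'
#' @param stem The diagnostic stem string.
#' @param sample The follow-up [airr_sample()].
#' @param qc A [normalization_factor()] result for the follow-up sample.
#' @return A one-row tibble: `stem`, `timepoint_label`, `n_members_detected`,
#'   `stem_percent_reads`, `stem_percent_cells` (NA without spike-in),
#'   `top_member_percent_reads`, `top_member_id`, `top_member_junction`,
#'   `traceable`.
#' @export
quantify_mrd <- function(stem, sample, qc = normalization_factor(sample)) {
  if (sample$usable_reads <= 0) {
    stop("follow-up sample has no usable reads; cannot quantify MRD",
         call. = FALSE)
  }
  cl <- sample$clonotypes
  hit <- cl[endsWith(cl$junction, stem), , drop = FALSE]
  hit <- hit[order(-hit$read_count, hit$junction), , drop = FALSE]
  n <- nrow(hit)
  stem_reads <- sum(hit$read_count)
  tibble::tibble(
    stem = stem,
    timepoint_label = sample$timepoint_label,
    n_members_detected = n,
    stem_percent_reads = abundance_percent(stem_reads, sample),
    stem_percent_cells = if (qc$available) {
      percent_cells(stem_reads, sample, qc)
    } else NA_real_,
    top_member_percent_reads = if (n > 0) {
      abundance_percent(hit$read_count[1], sample)
    } else 0,
    top_member_id = if (n > 0) hit$clonotype_id[1] else NA_character_,
    top_member_junction = if (n > 0) hit$junction[1] else NA_character_,
    traceable = n > 0
  )
}

#' Compare DNJ-stems and family members between BM and PB
#'
#' Categorizes each stem seen in either compartment of a matched
#' bone-marrow/peripheral-blood pair as `marker_both` (marker in both),
#' `detectable_both_marker_one`, or `one_compartment_only`, reports
#' evolution-call concordance, and for stems evolving in both compartments
#' computes the member-level junction overlap (shared / union, members
#' searched at any abundance).
#'
#' @param bm,pb Analyzed samples ([analyze_sample()] results) for the same
#'   patient and timepoint.
#' @return A list with `stems` (per-stem category tibble) and
#'   `member_overlap` (per-stem overlap for stems evolving in both).
#' @export
compare_compartments <- function(bm, pb) {
  if (!identical(bm$sample$patient_id, pb$sample$patient_id)) {
    stop("BM and PB analyses must come from the same patient", call. = FALSE)
  }
  fb <- bm$families
  fp <- pb$families
  stems <- union(fb$stem[fb$is_marker], fp$stem[fp$is_marker])
  categorize <- function(s) {
    in_b <- s %in% fb$stem
    in_p <- s %in% fp$stem
    mk_b <- s %in% fb$stem[fb$is_marker]
    mk_p <- s %in% fp$stem[fp$is_marker]
    if (mk_b && mk_p) "marker_both"
    else if (in_b && in_p) "detectable_both_marker_one"
    else "one_compartment_only"
  }
  call_of <- function(fam, s) {
    i <- match(s, fam$stem)
    if (is.na(i)) NA_character_ else fam$call[i]
  }
  per_stem <- tibble::tibble(
    stem = stems,
    category = vapply(stems, categorize, ""),
    call_bm = vapply(stems, call_of, "", fam = fb),
    call_pb = vapply(stems, call_of, "", fam = fp)
  )
  per_stem$evolution_concordant <- !is.na(per_stem$call_bm) &
    !is.na(per_stem$call_pb) & per_stem$call_bm == per_stem$call_pb

  both_evolving <- per_stem$stem[
    !is.na(per_stem$call_bm) & per_stem$call_bm == "evolving" &
    !is.na(per_stem$call_pb) & per_stem$call_pb == "evolving"]
  member_overlap <- purrr::map_dfr(both_evolving, function(s) {
    jb <- bm$sample$clonotypes$junction[endsWith(bm$sample$clonotypes$junction, s)]
    jp <- pb$sample$clonotypes$junction[endsWith(pb$sample$clonotypes$junction, s)]
    shared <- length(intersect(jb, jp))
    uni <- length(union(jb, jp))
    tibble::tibble(stem = s, n_bm = length(unique(jb)), n_pb = length(unique(jp)),
                   n_shared = shared, overlap = if (uni > 0) shared / uni else NA_real_)
  })
  list(stems = per_stem, member_overlap = member_overlap)
}

#' Track diagnostic marker stems across longitudinal follow-up samples
#'
#' For every marker stem of the diagnostic analysis, quantifies MRD at each
#' follow-up timepoint and raises flags: `stem_untraceable` (no member at
#' any follow-up), `top_member_vanished` (the diagnostic top member absent
#' at one or more follow-ups while other members persist),
#' `top_member_displaced` (the diagnostic top member detected but no longer
#' the most abundant member), `new_members_emerged` (follow-up members whose
#' junctions were not seen at diagnosis). Recommendation codes:
#' `report_sum` always (MRD as the family sum), `follow_stem_not_member`
#' for evolving stems, `follow_both_libraries` for rooted stems.
#'
#' @param diagnostic An [analyze_sample()] result at diagnosis.
#' @param followups List of follow-up [airr_sample()]s, ordered by time
#'   (ordering is taken from the caller, never inferred from labels).
#' @return A tibble, one row per marker stem, with a `measurements`
#'   list-column of per-timepoint [quantify_mrd()] rows, logical flag
#'   columns and a `recommendations` list-column.
#' @export
track_longitudinal <- function(diagnostic, followups) {
  stopifnot(length(followups) >= 1)
  fams <- diagnostic$families
  fams <- fams[fams$is_marker, , drop = FALSE]
  diag_cl <- diagnostic$sample$clonotypes
  purrr::map_dfr(seq_len(nrow(fams)), function(i) {
    fam <- fams[i, ]
    meas <- purrr::map_dfr(followups, function(s) quantify_mrd(fam$stem, s))
    diag_top_junction <- fam$top_junction
    top_present <- purrr::map_lgl(followups, function(s) {
      diag_top_junction %in% s$clonotypes$junction
    })
    others_present <- meas$traceable &
      !(top_present & meas$n_members_detected == 1)
    diag_junctions <- diag_cl$junction[endsWith(diag_cl$junction, fam$stem)]
    new_members <- any(purrr::map_lgl(followups, function(s) {
      j <- s$clonotypes$junction[endsWith(s$clonotypes$junction, fam$stem)]
      length(setdiff(j, diag_junctions)) > 0
    }))
    displaced <- any(top_present & meas$traceable &
                       !is.na(meas$top_member_junction) &
                       meas$top_member_junction != diag_top_junction)
    recs <- c("report_sum",
              if (identical(fam$call, "evolving")) "follow_stem_not_member",
              if (isTRUE(fam$rooted)) "follow_both_libraries")
    tibble::tibble(
      stem = fam$stem,
      call = fam$call,
      rooted = isTRUE(fam$rooted),
      measurements = list(meas),
      stem_untraceable = !any(meas$traceable),
      top_member_vanished = any(!top_present & others_present),
      top_member_displaced = displaced,
      new_members_emerged = new_members,
      recommendations = list(recs)
    )
  })
}

#' Screen marker stems shared between patients
#'
#' A DNJ-stem that appears as a marker in more than one patient of a cohort
#' is suspect as a patient-specific MRD target; this lists every such stem
#' with the patients carrying it. Stems link by exact (uppercase) string
#' identity.
#'
#' @param analyses List of analyzed samples (one or more per patient).
#' @return A tibble with `stem`, `n_patients`, `patient_ids` for each stem
#'   appearing as a marker in more than one patient; zero rows when all
#'   markers are patient-unique.
#' @export
cross_patient_specificity <- function(analyses) {
  stopifnot(length(analyses) >= 2)
  per <- purrr::map_dfr(analyses, function(a) {
    fams <- a$families
    tibble::tibble(stem = fams$stem[fams$is_marker],
                   patient_id = a$sample$patient_id)
  })
  per |>
    dplyr::distinct() |>
    dplyr::group_by(.data$stem) |>
    dplyr::summarise(n_patients = dplyr::n(),
                     patient_ids = paste(sort(.data$patient_id), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_patients > 1)
}
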