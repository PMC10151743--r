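#' Annotate clonotypes with junction anatomy and DNJ-stems
#'
#' Fills missing junction anatomy by [decompose_junction()] against the
#' catalog (records whose anatomy was pre-filled at load keep it), then
#' extracts every clonotype's DNJ-stem. Records whose junction yields no J
#' match are quarantined: removed from the clonotype table and counted in
#' the load report under `no_j_match`.
#'
#' @param sample An [airr_sample()].
#' @param catalog A [locus_catalog()]; may be `NULL` when all anatomy is
#'   pre-filled.
#' @param min_d_match Minimum exact D match length for region inference.
#' @return The sample with `stem`, `stem_d`, `stem_n2`, `stem_fallback`
#'   columns added to its clonotypes.
#' @export
annotate_stems <- function(sample, catalog = NULL, min_d_match = 5) {
  cl <- sample$clonotypes
  need <- is.na(cl$j_part) | cl$j_part == ""
  if (any(need)) {
    if (is.null(catalog)) {
      stop("anatomy missing and no catalog supplied for decomposition",
           call. = FALSE)
    }
    for (i in which(need)) {
      anat <- decompose_junction(cl$junction[i], cl$v_call[i], cl$j_call[i],
                                 catalog, min_d_match = min_d_match)
      if (is.null(anat)) next  # stays NA -> quarantined below
      cl$v_part[i] <- anat$v_part
      cl$n1[i] <- anat$n1
      cl$d2_part[i] <- anat$d2_part
      cl$n0[i] <- anat$n0
      cl$d_part[i] <- anat$d_part
      cl$n2[i] <- anat$n2
      cl$j_part[i] <- anat$j_part
      if (is.na(cl$d_call[i]) && !is.na(anat$d_call)) cl$d_call[i] <- anat$d_call
      if (is.na(cl$d2_call[i]) && !is.na(anat$d2_call)) cl$d2_call[i] <- anat$d2_call
    }
  }
  quarantine <- is.na(cl$j_part) | cl$j_part == ""
  if (any(quarantine)) {
    sample$load_report <- dplyr::bind_rows(
      sample$load_report,
      tibble::tibble(reason = "no_j_match", n = sum(quarantine))
    )
    cl <- cl[!quarantine, , drop = FALSE]
  }
  if (nrow(cl) > 0) {
    stems <- purrr::pmap(
      list(cl$n1, cl$d_part, cl$n2, cl$j_part),
      function(n1, d_part, n2, j_part) {
        extract_dnj_stem(list(n1 = n1, d_part = d_part, n2 = n2, j_part = j_part))
      }
    )
    cl$stem <- purrr::map_chr(stems, "stem")
    cl$stem_d <- purrr::map_chr(stems, "d_contribution")
    cl$stem_n2 <- purrr::map_chr(stems, "n2_contribution")
    cl$stem_fallback <- purrr::map_lgl(stems, "from_n_fallback")
  } else {
    cl$stem <- character(0)
    cl$stem_d <- character(0)
    cl$stem_n2 <- character(0)
    cl$stem_fallback <- logical(0)
  }
  sample$clonotypes <- cl
  sample
}

#' Group a sample's clonotypes into DNJ-stem families
#'
#' Partitions clonotypes by exact stem string equality. Families are sorted
#' by total reads (descending); members within a family by read count
#' descending with a lexicographic junction tie-break, so the top member is
#' reproducible.
#'
#' @param sample An [airr_sample()] whose clonotypes carry stems
#'   (see [annotate_stems()]).
#' @return A tibble with one row per stem family: `sample_id`, `library`,
#'   `stem`, `stem_n2`, `stem_fallback`, `n_members`, `total_reads`,
#'   `total_percent`, `top_id`, `top_junction`, `top_read_count`,
#'   `top_percent`, `rooted` (NA until [detect_root()]), and a `members`
#'   list-column of per-member tibbles.
#' @export
group_by_stem <- function(sample) {
  cl <- sample$clonotypes
  if (!"stem" %in% names(cl)) {
    stop("clonotypes carry no stems; run annotate_stems() first", call. = FALSE)
  }
  if (nrow(cl) == 0) {
    return(tibble::tibble(
      sample_id = character(0), library = character(0), stem = character(0),
      stem_n2 = character(0), stem_fallback = logical(0),
      n_members = integer(0), total_reads = integer(0),
      total_percent = numeric(0), top_id = character(0),
      top_junction = character(0), top_read_count = integer(0),
      top_percent = numeric(0), rooted = logical(0), members = list()
    ))
  }
  cl <- cl |>
    dplyr::arrange(dplyr::desc(.data$read_count), .data$junction,
                   .data$clonotype_id)
  fams <- tidyr::nest(cl, .by = "stem", .key = "members")
  fams <- fams |>
    dplyr::mutate(
      sample_id = sample$sample_id,
      library = sample$library,
      stem_n2 = purrr::map_chr(.data$members, ~ .x$stem_n2[1]),
      stem_fallback = purrr::map_lgl(.data$members, ~ .x$stem_fallback[1]),
      n_members = purrr::map_int(.data$members, nrow),
      total_reads = purrr::map_int(.data$members, ~ sum(.x$read_count)),
      total_percent = abundance_percent(.data$total_reads, sample),
      top_id = purrr::map_chr(.data$members, ~ .x$clonotype_id[1]),
      top_junction = purrr::map_chr(.data$members, ~ .x$junction[1]),
      top_read_count = purrr::map_int(.data$members, ~ .x$read_count[1]),
      top_percent = abundance_percent(.data$top_read_count, sample),
      rooted = NA
    ) |>
    dplyr::arrange(dplyr::desc(.data$total_reads), .data$stem) |>
    dplyr::select("sample_id", "library", "stem", "stem_n2", "stem_fallback",
                  "n_members", "total_reads", "total_percent", "top_id",
                  "top_junction", "top_read_count", "top_percent", "rooted",
                  "members")
  fams
}

#' Flag rooted DNJ-stems across the two amplicon libraries
#'
#' A stem is "rooted" when it is detected in both the IGH-VJ and the IGH-DJ
#' library of the same sample (or patient-timepoint): the incomplete DJ
#' rearrangement feeding ongoing recombination is then itself observable.
#' Matching is by exact stem string equality.
#'
#' @param vj_families,dj_families Family tibbles from [group_by_stem()] for
#'   the IGH-VJ and IGH-DJ libraries.
#' @return A list with elements `vj` and `dj`: the inputs with their
#'   `rooted` columns set.
#' @export
detect_root <- function(vj_families, dj_families) {
  vj_families$rooted <- vj_families$stem %in% dj_families$stem
  dj_families$rooted <- dj_families$stem %in% vj_families$stem
  list(vj = vj_families, dj = dj_families)
}
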