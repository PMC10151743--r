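#' @importFrom rlang .data
NULL

AIRR_REQUIRED <- c("sequence_id", "v_call", "d_call", "j_call", "junction",
                   "duplicate_count")
AIRR_OPTIONAL <- c("d2_call", "is_qc", "v_part", "np1", "d2_part", "np0",
                   "d_part", "np2", "j_part")

ANATOMY_COLS <- c("v_part", "n1", "d2_part", "n0", "d_part", "n2", "j_part")

#' Construct a sample repertoire
#'
#' The central container for one sample/library pair: a tibble of clonotypes
#' plus sample metadata, the cIT-QC spike-in tallies and the usable-read
#' denominator. Usable reads are the sum of clonotype read counts after
#' exclusion of QC reads; every percentage abundance downstream divides by
#' this number.
#'
#' @param clonotypes Tibble with at least `clonotype_id`, `v_call`, `d_call`,
#'   `d2_call`, `j_call`, `junction`, `read_count`. Anatomy columns
#'   (`v_part`, `n1`, `d2_part`, `n0`, `d_part`, `n2`, `j_part`) are carried
#'   when present.
#' @param sample_id,patient_id,compartment,timepoint_label,library Sample
#'   metadata; `compartment` is `"BM"` or `"PB"`, `library` is `"IGH-VJ"` or
#'   `"IGH-DJ"`.
#' @param qc_reads Total cIT-QC spike-in reads for this library.
#' @param qc_cell_equivalents Cell equivalents spiked in as cIT-QC.
#' @param load_report Optional tibble of dropped-row counts by reason.
#' @return An object of class `airr_sample`.
#' @export
airr_sample <- function(clonotypes, sample_id, patient_id = sample_id,
                        compartment = "BM", timepoint_label = "day0",
                        library = c("IGH-VJ", "IGH-DJ"),
                        qc_reads = 0, qc_cell_equivalents = 0,
                        load_report = NULL) {
  library <- match.arg(library)
  cl <- tibble::as_tibble(clonotypes)
  needed <- c("clonotype_id", "j_call", "junction", "read_count")
  missing <- setdiff(needed, names(cl))
  if (length(missing) > 0) {
    stop("clonotypes table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("v_call", "d_call", "d2_call")) {
    if (!col %in% names(cl)) cl[[col]] <- NA_character_
  }
  for (col in ANATOMY_COLS) {
    if (!col %in% names(cl)) cl[[col]] <- NA_character_
  }
  cl$junction <- toupper(cl$junction)
  cl$sample_id <- sample_id
  cl$library <- library
  if (nrow(cl) > 0) {
    if (any(cl$read_count < 1)) stop("read_count must be >= 1", call. = FALSE)
    if (any(nchar(cl$junction) < 6)) {
      stop("junctions must be at least 6 nt", call. = FALSE)
    }
    if (anyDuplicated(cl$clonotype_id)) {
      stop("clonotype_id must be unique within a sample/library", call. = FALSE)
    }
  }
  usable <- sum(cl$read_count)
  if (usable == 0) {
    stop("empty repertoire: no usable reads after QC exclusion", call. = FALSE)
  }
  structure(
    list(
      clonotypes = cl,
      sample_id = sample_id,
      patient_id = patient_id,
      compartment = compartment,
      timepoint_label = timepoint_label,
      library = library,
      qc_reads = qc_reads,
      qc_cell_equivalents = qc_cell_equivalents,
      usable_reads = usable,
      load_report = load_report %||%
        tibble::tibble(reason = character(0), n = integer(0))
    ),
    class = "airr_sample"
  )
}

#' @export
print.airr_sample <- function(x, ...) {
  cat(sprintf(
    "<airr_sample> %s [%s, %s, %s] %d clonotypes, %d usable reads, %d QC reads\n",
    x$sample_id, x$library, x$compartment, x$timepoint_label,
    nrow(x$clonotypes), x$usable_reads, x$qc_reads
  ))
  invisible(x)
}

#' Read one sample/library from an AIRR Rearrangement TSV
#'
#' Expects the AIRR columns `sequence_id`, `v_call`, `d_call`, `j_call`,
#' `junction`, `duplicate_count`, plus the optional columns `d2_call`,
#' `is_qc` (logical flag marking cIT-QC spike-in reads) and the junction
#' region columns `v_part`, `np1`, `d2_part`, `np0`, `d_part`, `np2`,
#' `j_part`. When the region columns are present and consistent with the
#' junction they pre-fill the junction anatomy; otherwise anatomy is left
#' for [annotate_stems()] to infer from the germline catalog.
#'
#' Rows flagged `is_qc` are tallied into `qc_reads` and excluded from the
#' clonotype table. Rows with an empty junction are dropped and counted in
#' the load report.
#'
#' @param tsv Path to the AIRR Rearrangement TSV.
#' @param meta A one-row data frame or named list with `sample_id`,
#'   `patient_id`, `compartment`, `timepoint_label`, `library` and
#'   `qc_cell_equivalents_input`.
#' @return An [airr_sample()].
#' @export
read_airr_sample <- function(tsv, meta) {
  if (!file.exists(tsv)) stop("file not found: ", tsv, call. = FALSE)
  meta <- as.list(meta)
  dat <- readr::read_tsv(tsv, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(AIRR_REQUIRED, names(dat))
  if (length(missing) > 0) {
    stop("AIRR TSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dc <- suppressWarnings(as.numeric(dat$duplicate_count))
  if (any(is.na(dc)) || any(dc != floor(dc))) {
    stop("duplicate_count must be integer-valued", call. = FALSE)
  }
  dat$duplicate_count <- as.integer(dc)

  is_qc <- if ("is_qc" %in% names(dat)) {
    tolower(dplyr::coalesce(dat$is_qc, "false")) %in% c("true", "t", "1")
  } else {
    rep(FALSE, nrow(dat))
  }
  qc_reads <- sum(dat$duplicate_count[is_qc])
  dat <- dat[!is_qc, , drop = FALSE]

  empty_junction <- is.na(dat$junction) | dat$junction == ""
  n_empty <- sum(empty_junction)
  dat <- dat[!empty_junction, , drop = FALSE]
  dat$junction <- toupper(dat$junction)
  bad_alpha <- !grepl("^[ACGT]+$", dat$junction)
  n_bad <- sum(bad_alpha)
  dat <- dat[!bad_alpha, , drop = FALSE]

  cl <- tibble::tibble(
    clonotype_id = dat$sequence_id,
    v_call = dplyr::na_if(dplyr::coalesce(dat$v_call, ""), ""),
    d_call = dplyr::na_if(dplyr::coalesce(dat$d_call, ""), ""),
    d2_call = if ("d2_call" %in% names(dat)) {
      dplyr::na_if(dplyr::coalesce(dat$d2_call, ""), "")
    } else NA_character_,
    j_call = dat$j_call,
    junction = dat$junction,
    read_count = dat$duplicate_count
  )

  region_in <- c("v_part", "np1", "d2_part", "np0", "d_part", "np2", "j_part")
  n_anatomy_mismatch <- 0L
  if (all(region_in %in% names(dat))) {
    parts <- lapply(dat[region_in], function(x) toupper(dplyr::coalesce(x, "")))
    rebuilt <- paste0(parts$v_part, parts$np1, parts$d2_part, parts$np0,
                      parts$d_part, parts$np2, parts$j_part)
    consistent <- rebuilt == cl$junction
    n_anatomy_mismatch <- sum(!consistent)
    cl$v_part <- ifelse(consistent, parts$v_part, NA_character_)
    cl$n1 <- ifelse(consistent, parts$np1, NA_character_)
    cl$d2_part <- ifelse(consistent, parts$d2_part, NA_character_)
    cl$n0 <- ifelse(consistent, parts$np0, NA_character_)
    cl$d_part <- ifelse(consistent, parts$d_part, NA_character_)
    cl$n2 <- ifelse(consistent, parts$np2, NA_character_)
    cl$j_part <- ifelse(consistent, parts$j_part, NA_character_)
  }

  report <- tibble::tibble(
    reason = c("empty_junction", "non_acgt_junction", "anatomy_mismatch"),
    n = c(n_empty, n_bad, n_anatomy_mismatch)
  )
  airr_sample(
    cl,
    sample_id = meta$sample_id,
    patient_id = meta$patient_id %||% meta$sample_id,
    compartment = meta$compartment %||% "BM",
    timepoint_label = meta$timepoint_label %||% "day0",
    library = meta$library,
    qc_reads = qc_reads,
    qc_cell_equivalents = as.numeric(meta$qc_cell_equivalents_input %||% 0),
    load_report = report
  )
}

#' Write a sample back to an AIRR Rearrangement TSV
#'
#' Emits the clonotype table with region columns, plus a single synthetic
#' `is_qc` row carrying the sample's pooled QC reads so that a read/write
#' round trip reproduces the repertoire exactly.
#'
#' @param sample An [airr_sample()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr_sample <- function(sample, path) {
  cl <- sample$clonotypes
  out <- tibble::tibble(
    sequence_id = cl$clonotype_id,
    v_call = dplyr::coalesce(cl$v_call, ""),
    d_call = dplyr::coalesce(cl$d_call, ""),
    d2_call = dplyr::coalesce(cl$d2_call, ""),
    j_call = cl$j_call,
    junction = cl$junction,
    duplicate_count = cl$read_count,
    is_qc = "FALSE",
    v_part = dplyr::coalesce(cl$v_part, ""),
    np1 = dplyr::coalesce(cl$n1, ""),
    d2_part = dplyr::coalesce(cl$d2_part, ""),
    np0 = dplyr::coalesce(cl$n0, ""),
    d_part = dplyr::coalesce(cl$d_part, ""),
    np2 = dplyr::coalesce(cl$n2, ""),
    j_part = dplyr::coalesce(cl$j_part, "")
  )
  if (sample$qc_reads > 0) {
    qc_row <- out[0, ]
    qc_row[1, ] <- list("cIT-QC", "", "", "", "IGHJ4", "TGTGCTGCTTTTGGA",
                        sample$qc_reads, "TRUE", "", "", "", "", "", "", "")
    out <- dplyr::bind_rows(out, qc_row)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Spike-in read-to-cell normalization factor
#'
#' The cIT-QC spike-in contributes a known number of cell equivalents; the
#' ratio of spiked cells to observed QC reads converts read counts to cell
#' equivalents. Normalization is unavailable (a value, not an error) when
#' the sample carries no QC reads or no spike-in metadata.
#'
#' @param sample An [airr_sample()].
#' @return A list with `cells_per_read` (NA when unavailable) and
#'   `available`.
#' @export
normalization_factor <- function(sample) {
  available <- sample$qc_reads > 0 && sample$qc_cell_equivalents > 0
  list(
    cells_per_read = if (available) sample$qc_cell_equivalents / sample$qc_reads else NA_real_,
    available = available
  )
}

#' Percentage abundance of a read count within a sample
#'
#' @param read_count Read count(s).
#' @param sample An [airr_sample()] supplying the usable-read denominator.
#' @return `100 * read_count / usable_reads`.
#' @export
abundance_percent <- function(read_count, sample) {
  if (sample$usable_reads <= 0) {
    stop("usable_reads must be positive", call. = FALSE)
  }
  100 * read_count / sample$usable_reads
}

#' Read a sample-metadata table
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `compartment`,
#'   `timepoint_label`, `library`, `qc_cell_equivalents_input` and
#'   optionally `tsv` (path to the sample's AIRR table, relative to the
#'   metadata file).
#' @return A tibble, one row per sample/library.
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    qc_cell_equivalents_input = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
}
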