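#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: with both table
#' margins fixed, sum the hypergeometric probabilities of every table whose
#' point probability does not exceed that of the observed table. This is
#' the "default" two-sided convention of the common statistical
#' implementations; two-sided Fisher definitions vary, so the rule is
#' stated here explicitly. Point probabilities are compared with a
#' relative tie tolerance of 1e-10, which is far below the smallest
#' possible relative gap between distinct hypergeometric weights at the
#' table sizes where ties matter, so floating-point noise never flips a
#' table in or out of the sum.
#'
#' A zero row or column margin leaves a degenerate table; by convention
#' p = 1 with a warning.
#'
#' @param table A 2x2 integer matrix, or vector `c(a, b, c, d)` read
#'   row-wise.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.integer(table)
  if (length(x) != 4 || any(is.na(x)) || any(x < 0)) {
    stop("table must be four non-negative integers", call. = FALSE)
  }
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  }
  n <- a + b + c_ + d
  if (n == 0) stop("table total must be positive", call. = FALSE)
  r1 <- a + b
  c1 <- a + c_
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(1)
  }
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  dens <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-10)])
  min(p, 1)
}

#' Summarize per-patient analyses into cohort counts
#'
#' A patient counts as evolving when at least one stem family is called
#' evolving in any library, as marker-positive when at least one marker
#' stem exists, and as stable when marker-positive without evolution.
#'
#' @param patients A tibble with one row per patient: `patient_id`,
#'   `n_marker_stems`, `n_evolving_stems`, and optionally mechanism count
#'   columns (`n_vh_replacement`, `n_dv_to_dj`, `n_mixed`). Build it with
#'   [patient_summary()] or by hand.
#' @return A list of cohort counts: `n_patients`, `n_with_marker`,
#'   `n_no_marker`, `n_evolving`, `n_stable`, `n_marker_stems`,
#'   `stems_per_patient_mean` (over marker-positive patients) and the
#'   summed mechanism breakdown.
#' @export
summarize_cohort <- function(patients) {
  if (nrow(patients) < 1) stop("empty cohort", call. = FALSE)
  with_marker <- patients$n_marker_stems > 0
  evolving <- patients$n_evolving_stems > 0
  mech <- function(col) {
    if (col %in% names(patients)) sum(patients[[col]], na.rm = TRUE) else NA_integer_
  }
  list(
    n_patients = nrow(patients),
    n_with_marker = sum(with_marker),
    n_no_marker = sum(!with_marker),
    n_evolving = sum(evolving),
    n_stable = sum(with_marker & !evolving),
    n_marker_stems = sum(patients$n_marker_stems),
    stems_per_patient_mean = if (any(with_marker)) {
      mean(patients$n_marker_stems[with_marker])
    } else NA_real_,
    n_vh_replacement = mech("n_vh_replacement"),
    n_dv_to_dj = mech("n_dv_to_dj"),
    n_mixed = mech("n_mixed")
  )
}

#' Collapse a patient's analyzed samples into one summary row
#'
#' @param analyses List of [analyze_sample()] results for one patient
#'   (e.g. both libraries of the diagnostic sample).
#' @return A one-row tibble with marker/evolving stem counts and the
#'   mechanism breakdown across all the patient's libraries.
#' @export
patient_summary <- function(analyses) {
  fams <- dplyr::bind_rows(purrr::map(analyses, function(a) {
    f <- a$families
    if (!"mechanism_summary" %in% names(f)) f$mechanism_summary <- NA_character_
    f[, c("stem", "library", "call", "is_marker", "mechanism_summary")]
  }))
  mech <- fams$mechanism_summary[fams$call == "evolving"]
  tibble::tibble(
    patient_id = analyses[[1]]$sample$patient_id,
    n_marker_stems = sum(fams$is_marker),
    n_evolving_stems = sum(fams$call == "evolving"),
    n_vh_replacement = sum(mech == "VH_replacement", na.rm = TRUE),
    n_dv_to_dj = sum(mech == "DV_to_DJ", na.rm = TRUE),
    n_mixed = sum(mech == "mixed", na.rm = TRUE)
  )
}

#' Test association between a patient attribute and a binary outcome
#'
#' Assembles the 2x2 table (group1 outcome+/outcome-, group2
#' outcome+/outcome-) and applies [fisher_exact_2x2()]. Patient-level by
#' design, matching how per-patient evolution rates are compared between
#' e.g. immunophenotype groups.
#'
#' @param data A data frame with one row per patient.
#' @param attribute Name of the categorical attribute column.
#' @param outcome Name of the logical outcome column.
#' @param groups Character vector of the two attribute levels to compare.
#' @return A list with `table` (2x2 matrix), `odds_ratio` (sample OR) and
#'   `p`.
#' @export
associate <- function(data, attribute, outcome, groups) {
  stopifnot(length(groups) == 2)
  a_col <- data[[attribute]]
  o_col <- data[[outcome]]
  if (any(is.na(a_col)) || any(is.na(o_col))) {
    stop("every patient needs a non-missing attribute and outcome", call. = FALSE)
  }
  g1 <- a_col == groups[1]
  g2 <- a_col == groups[2]
  if (sum(g1) == 0 || sum(g2) == 0) {
    stop("both groups must contain at least one patient", call. = FALSE)
  }
  tab <- matrix(c(sum(g1 & o_col), sum(g1 & !o_col),
                  sum(g2 & o_col), sum(g2 & !o_col)),
                nrow = 2, byrow = TRUE,
                dimnames = list(groups, c("outcome_yes", "outcome_no")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or, p = fisher_exact_2x2(tab))
}
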