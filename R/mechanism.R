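#' Mechanism-classification policy
#'
#' Parameters for discriminating VH replacement from ongoing D/V-to-DJ
#' recombination within an evolving DNJ-stem family.
#'
#' @param max_footprint Maximum length of a replaced-V remnant (5 bp; the
#'   biological upper bound for VH-replacement footprints).
#' @param min_footprint_evidence Minimum footprint length accepted as
#'   evidence (default 2; single-base matches are uninformative).
#' @param d5_stability_tolerance Nucleotides of 5' D (and N1-tail) loss
#'   tolerated while still calling the D region "stable" (default 1,
#'   absorbing sequencing error and minor exonuclease nibbling).
#' @param mother_abundance_factor A member is a mother candidate when its
#'   read count is at least this multiple of the family median (default 10);
#'   if none qualifies the single top member is the mother.
#' @param mixed_fraction A stem is summarized `mixed` when both mechanism
#'   classes exceed this fraction of classified members (default 0.2).
#' @return A list of class `mechanism_policy`.
#' @export
mechanism_policy <- function(max_footprint = 5, min_footprint_evidence = 2,
                             d5_stability_tolerance = 1,
                             mother_abundance_factor = 10,
                             mixed_fraction = 0.2) {
  stopifnot(min_footprint_evidence >= 1,
            min_footprint_evidence <= max_footprint)
  structure(list(max_footprint = max_footprint,
                 min_footprint_evidence = min_footprint_evidence,
                 d5_stability_tolerance = d5_stability_tolerance,
                 mother_abundance_factor = mother_abundance_factor,
                 mixed_fraction = mixed_fraction),
            class = "mechanism_policy")
}

#' Check stability of the D region's 5' site against a reference member
#'
#' VH replacement exchanges only the V segment: the D region's 5' end and
#' the 3' tail of the preceding N1 region survive (up to `tol` nucleotides
#' of loss). The member's D part must equal the reference D part with at
#' most `tol` nt eroded from its 5' end, and the 3'-most `min(4, len)` nt
#' of the reference N1 must still sit immediately 5' of the member's D part
#' (again allowing `tol` nt of loss).
#'
#' @param member,reference One-row member records (or lists) carrying
#'   `d_part` and `n1`.
#' @param tol Tolerated nucleotide loss (default 1).
#' @return `TRUE`/`FALSE`; `NA` when the reference lacks a D part
#'   (an undetermined signal, not an error).
#' @export
check_d5_stability <- function(member, reference, tol = 1) {
  ref_d <- reference$d_part %||% ""
  mem_d <- member$d_part %||% ""
  if (is.na(ref_d) || ref_d == "") return(NA)
  if (is.na(mem_d)) mem_d <- ""
  erosion <- nchar(ref_d) - nchar(mem_d)
  d_ok <- erosion >= 0 && erosion <= tol &&
    mem_d == substr(ref_d, erosion + 1, nchar(ref_d))
  if (!d_ok) return(FALSE)
  ref_n1 <- reference$n1 %||% ""
  if (is.na(ref_n1)) ref_n1 <- ""
  tail_len <- min(4, nchar(ref_n1))
  if (tail_len == 0) return(TRUE)
  need <- max(tail_len - tol, 0)
  if (need == 0) return(TRUE)
  mem_n1 <- member$n1 %||% ""
  if (is.na(mem_n1)) mem_n1 <- ""
  expected <- str_tail(ref_n1, tail_len)
  # allow up to tol nt lost from the 3' side of the preserved N1 tail,
  # in which case the same number must have been eroded off the D 5' end
  for (lost in 0:tol) {
    frag <- substr(expected, 1, tail_len - lost)
    if (nchar(frag) < need) break
    if (str_tail(mem_n1, nchar(frag)) == frag) return(TRUE)
  }
  FALSE
}

#' Search a member's N1 region for a replaced-V footprint
#'
#' Tests, for each candidate replaced (mother) V gene and for footprint
#' lengths from `max_footprint` down to `min_footprint_evidence`, whether
#' the germline 3' tail of that V occurs as a substring of the member's N1
#' region. The longest match wins; among equal lengths the mother with the
#' higher family abundance wins.
#'
#' @param member One-row member record with a non-empty `n1`.
#' @param candidates Tibble of mother candidates with columns `v_call` and
#'   `read_count` (used for the tie-break).
#' @param catalog A [locus_catalog()].
#' @param policy A [mechanism_policy()].
#' @return A list with `footprint` and `source_v`, or `NULL` when no tail
#'   matches.
#' @export
find_vh_footprint <- function(member, candidates, catalog,
                              policy = mechanism_policy()) {
  n1 <- member$n1 %||% ""
  if (is.na(n1) || n1 == "") return(NULL)
  cand <- candidates[!is.na(candidates$v_call), , drop = FALSE]
  cand <- cand[order(-cand$read_count), , drop = FALSE]
  cand <- cand[!duplicated(strip_allele(cand$v_call)), , drop = FALSE]
  for (k in seq(policy$max_footprint, policy$min_footprint_evidence)) {
    for (i in seq_len(nrow(cand))) {
      tail_k <- v_three_prime_tail(catalog, cand$v_call[i], k)
      if (grepl(tail_k, n1, fixed = TRUE)) {
        return(list(footprint = tail_k, source_v = strip_allele(cand$v_call[i])))
      }
    }
  }
  NULL
}

mother_candidates <- function(kept, policy) {
  med <- stats::median(kept$read_count)
  cand <- kept[kept$read_count >= policy$mother_abundance_factor * med, , drop = FALSE]
  if (nrow(cand) == 0) cand <- kept[1, , drop = FALSE]
  cand
}

d_compatible <- function(mem_d, ref_d) {
  if (is.na(mem_d)) mem_d <- ""
  if (is.na(ref_d)) ref_d <- ""
  if (mem_d == "" || ref_d == "") return(FALSE)
  endsWith(ref_d, mem_d) || endsWith(mem_d, ref_d)
}

#' Classify the mechanism behind each member of an evolving family
#'
#' For every kept member of an evolving stem family (mother candidates are
#' reported as `mother`), assigns one of:
#' * `VH_replacement` - the D 5' site and preceding N1 3' tail are stable
#'   relative to the mother and a footprint of the replaced V is found in
#'   the new N1;
#' * `D_to_DJ` - the member carries a second, upstream D (D-D tandem) or is
#'   an IGH-DJ-library record joining the root;
#' * `V_to_DJ` - a VJ-library member whose D part aligns with the
#'   reference D (possibly 5'-eroded) but whose N1 is fresh;
#' * `undetermined` - none of the above (including replacement members
#'   whose footprint was fully trimmed away).
#'
#' An incoming V that violates the downstream-locus requirement sets
#' `upstream_incoming_flag` but does not veto the replacement call (such
#' exceptions occur in real data and may be annotation errors).
#'
#' The reference anatomy for D-stability and erosion is the DJ root's top
#' member when supplied, otherwise the family's mother/top member.
#'
#' @param family One row of an evolution-called family tibble (with `kept`).
#' @param catalog A [locus_catalog()].
#' @param policy A [mechanism_policy()].
#' @param dj_root Optional one-row record of the DJ-library root member.
#' @return The kept member tibble with `mechanism`, `footprint`,
#'   `footprint_source_v`, `upstream_incoming_flag` columns.
#' @export
classify_members <- function(family, catalog, policy = mechanism_policy(),
                             dj_root = NULL) {
  kept <- if (is.data.frame(family)) family$kept[[1]] else family$kept
  stopifnot(nrow(kept) >= 1)
  mothers <- mother_candidates(kept, policy)
  mother <- mothers[1, ]
  reference <- if (!is.null(dj_root)) dj_root else mother
  is_mother <- kept$clonotype_id %in% mothers$clonotype_id

  out <- kept
  out$mechanism <- "undetermined"
  out$footprint <- NA_character_
  out$footprint_source_v <- NA_character_
  out$upstream_incoming_flag <- FALSE

  for (i in seq_len(nrow(kept))) {
    if (is_mother[i]) {
      out$mechanism[i] <- "mother"
      next
    }
    member <- kept[i, ]
    if (!is.na(member$d2_call) || (!is.na(member$d2_part) && member$d2_part != "")) {
      out$mechanism[i] <- "D_to_DJ"
      next
    }
    if (member$library == "IGH-DJ") {
      out$mechanism[i] <- "D_to_DJ"
      next
    }
    stable <- check_d5_stability(member, mother, tol = policy$d5_stability_tolerance)
    fp <- find_vh_footprint(member, mothers, catalog, policy)
    if (isTRUE(stable) && !is.null(fp)) {
      out$mechanism[i] <- "VH_replacement"
      out$footprint[i] <- fp$footprint
      out$footprint_source_v[i] <- fp$source_v
      if (!is.na(member$v_call) && !is.na(mother$v_call) &&
          strip_allele(member$v_call) != strip_allele(mother$v_call) &&
          !is_downstream(catalog, member$v_call, mother$v_call)) {
        out$upstream_incoming_flag[i] <- TRUE
      }
      next
    }
    if (!isTRUE(stable) &&
        d_compatible(member$d_part, reference$d_part)) {
      out$mechanism[i] <- "V_to_DJ"
      next
    }
  }
  out
}

#' Summarize member mechanisms into a stem-level call
#'
#' Majority vote among classified (non-mother, non-undetermined) members:
#' `VH_replacement` vs `DV_to_DJ` (the latter pooling V-to-DJ and D-to-DJ
#' recombination). When both classes each exceed `mixed_fraction` of
#' classified members the stem is `mixed` - a configuration the underlying
#' biology produces only rarely. With no classified member the summary is
#' `undetermined`.
#'
#' @param member_calls Output of [classify_members()].
#' @param rooted Whether the stem was detected in both libraries.
#' @param policy A [mechanism_policy()].
#' @param dj_root_id Clonotype id of the DJ root, if known.
#' @return A list with `summary`, `mother_id`, `dj_root_present`,
#'   `n_replacement`, `n_recombination`, `n_undetermined`.
#' @export
summarize_stem <- function(member_calls, rooted = FALSE,
                           policy = mechanism_policy(), dj_root_id = NA) {
  cls <- member_calls$mechanism
  n_rep <- sum(cls == "VH_replacement")
  n_rec <- sum(cls %in% c("V_to_DJ", "D_to_DJ"))
  n_und <- sum(cls == "undetermined")
  n_classified <- n_rep + n_rec
  mother_id <- member_calls$clonotype_id[match("mother", cls)]
  if (n_classified == 0) {
    summary <- "undetermined"
  } else if (n_rep > policy$mixed_fraction * n_classified &&
             n_rec > policy$mixed_fraction * n_classified) {
    summary <- "mixed"
  } else if (n_rep >= n_rec) {
    summary <- "VH_replacement"
  } else {
    summary <- "DV_to_DJ"
  }
  list(
    summary = summary,
    mother_id = if (summary == "VH_replacement") mother_id
                else if (isTRUE(rooted) && !is.na(dj_root_id)) dj_root_id
                else mother_id,
    dj_root_present = isTRUE(rooted),
    n_replacement = n_rep,
    n_recombination = n_rec,
    n_undetermined = n_und
  )
}

#' Classify mechanisms for all evolving families of a sample
#'
#' @param families Evolution-called family tibble
#'   (from [call_stem_evolution()], with `rooted` flags set).
#' @param catalog A [locus_catalog()].
#' @param policy A [mechanism_policy()].
#' @param dj_families Optional DJ-library family tibble of the same sample,
#'   used to look up the DJ root member for rooted stems.
#' @return `families` with `mechanism_summary`, `mother_id`,
#'   `n_replacement`, `n_recombination`, `n_undetermined` columns and a
#'   `member_mechanisms` list-column (non-evolving families get `NA`).
#' @export
classify_mechanisms <- function(families, catalog,
                                policy = mechanism_policy(),
                                dj_families = NULL) {
  n <- nrow(families)
  families$mechanism_summary <- NA_character_
  families$mother_id <- NA_character_
  families$n_replacement <- NA_integer_
  families$n_recombination <- NA_integer_
  families$n_undetermined <- NA_integer_
  families$member_mechanisms <- vector("list", n)
  for (i in seq_len(n)) {
    if (!identical(families$call[i], "evolving")) next
    dj_root <- NULL
    dj_root_id <- NA
    if (!is.null(dj_families) && isTRUE(families$rooted[i])) {
      hit <- which(dj_families$stem == families$stem[i])
      if (length(hit) > 0) {
        dj_root <- dj_families$members[[hit[1]]][1, ]
        dj_root_id <- dj_root$clonotype_id
      }
    }
    calls <- classify_members(families[i, ], catalog, policy, dj_root = dj_root)
    summ <- summarize_stem(calls, rooted = isTRUE(families$rooted[i]),
                           policy = policy, dj_root_id = dj_root_id)
    families$member_mechanisms[[i]] <- calls
    families$mechanism_summary[i] <- summ$summary
    families$mother_id[i] <- summ$mother_id
    families$n_replacement[i] <- summ$n_replacement
    families$n_recombination[i] <- summ$n_recombination
    families$n_undetermined[i] <- summ$n_undetermined
  }
  families
}
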