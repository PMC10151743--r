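#' Noise-filter policy
#'
#' Controls the removal of likely artifacts from a DNJ-stem family before
#' the evolution call: clonotypes highly similar to the most abundant
#' family member (PCR/sequencing-error satellites) and clonotypes below an
#' abundance floor of 3 reads or 0.01% of usable reads.
#'
#' @param min_reads Minimum read count to keep a member (default 3).
#' @param min_percent Minimum percentage of usable reads (default 0.01).
#' @param satellite_max_edit Maximum junction Levenshtein distance to the
#'   top member for satellite removal (default 2).
#' @param satellite_same_gene Require an identical 5' gene call for
#'   satellite removal (default `TRUE`); true VH-replacement members change
#'   the 5' gene and are thereby protected.
#' @return A list of class `noise_policy`.
#' @export
noise_policy <- function(min_reads = 3, min_percent = 0.01,
                         satellite_max_edit = 2, satellite_same_gene = TRUE) {
  stopifnot(min_reads >= 1, min_percent > 0, satellite_max_edit >= 0)
  structure(list(min_reads = min_reads, min_percent = min_percent,
                 satellite_max_edit = satellite_max_edit,
                 satellite_same_gene = satellite_same_gene),
            class = "noise_policy")
}

five_prime_gene <- function(members) {
  dplyr::if_else(
    members$library == "IGH-DJ",
    strip_allele(dplyr::coalesce(members$d2_call, members$d_call)),
    strip_allele(members$v_call)
  )
}

#' Apply the noise filter to a stem family
#'
#' The top (most abundant) member is never removed. A non-top member is
#' removed as a satellite when its junction is within
#' `satellite_max_edit` Levenshtein distance of the top member's junction
#' (and, by default, shares its 5' gene), or independently as low-abundance
#' when it has fewer than `min_reads` reads or less than `min_percent` of
#' usable reads.
#'
#' @param family One row of a [group_by_stem()] tibble (or a list with a
#'   `members` tibble).
#' @param policy A [noise_policy()].
#' @param sample The [airr_sample()] supplying the usable-read denominator.
#' @return A list with `kept` and `removed` member tibbles (`removed` gains
#'   a `removal_reason` column) and the removal counts.
#' @export
filter_noise <- function(family, policy, sample) {
  members <- if (is.data.frame(family)) family$members[[1]] else family$members
  stopifnot(nrow(members) >= 1)
  top <- members[1, ]
  percent <- abundance_percent(members$read_count, sample)
  gene5 <- five_prime_gene(members)
  same_gene <- !is.na(gene5) & !is.na(gene5[1]) & gene5 == gene5[1]
  if (!policy$satellite_same_gene) same_gene <- rep(TRUE, nrow(members))
  edit <- junction_distance(members$junction, rep(top$junction, nrow(members)))
  is_satellite <- same_gene & edit <= policy$satellite_max_edit
  is_low <- members$read_count < policy$min_reads | percent < policy$min_percent
  is_satellite[1] <- FALSE
  is_low[1] <- FALSE
  removed <- members[is_satellite | is_low, , drop = FALSE]
  if (nrow(removed) > 0) {
    removed$removal_reason <- dplyr::case_when(
      is_satellite[is_satellite | is_low] ~ "satellite",
      TRUE ~ "low_abundance"
    )
  } else {
    removed$removal_reason <- character(0)
  }
  kept <- members[!(is_satellite | is_low), , drop = FALSE]
  list(
    kept = kept,
    removed = removed,
    n_removed_satellites = sum(is_satellite),
    n_removed_low_abundance = sum(is_low & !is_satellite)
  )
}

#' Family metrics consulted by the evolution consensus
#'
#' Computes, for the filtered family: member counts (absolute and relative
#' to the sample's clonotype total), the number of distinct 5' genes
#' (gene-level V calls in the IGH-VJ library, D calls in IGH-DJ), the
#' number of distinct junction lengths, the noise ratio
#' removed/(removed+kept), the satellite ratio (top-member-similar
#' removals only, over the same denominator), and the complexity of the
#' stem's N-derived portion. N-region complexity is scored complex when the region is at
#' least 2 nt long with at least 2 distinct bases; a low-complexity stem
#' needs more corroborating members before it is trusted as specific.
#'
#' @param filtered Result of [filter_noise()].
#' @param sample The [airr_sample()].
#' @param family The family row (for the stem's N2 portion and fallback flag).
#' @return A one-row tibble of metrics.
#' @export
compute_metrics <- function(filtered, sample, family) {
  kept <- filtered$kept
  n_removed <- nrow(filtered$removed)
  n_kept <- nrow(kept)
  stem_n2 <- if (is.data.frame(family)) family$stem_n2[1] else family$stem_n2
  fallback <- if (is.data.frame(family)) family$stem_fallback[1] else family$stem_fallback
  n_region <- if (isTRUE(fallback)) {
    # stem built from the single N region: its contribution is the stem's
    # first <=3 nt plus any n2 (empty in the no-D decomposition)
    paste0(if (is.data.frame(family)) family$members[[1]]$stem_d[1] else "", stem_n2)
  } else {
    stem_n2
  }
  distinct_bases <- length(unique(strsplit(n_region, "")[[1]]))
  tibble::new_tibble(list(
    n_removed_satellites = filtered$n_removed_satellites,
    n_removed_low_abundance = filtered$n_removed_low_abundance,
    n_members_after_filter = n_kept,
    relative_members = n_kept / nrow(sample$clonotypes),
    n_distinct_5prime_genes = dplyr::n_distinct(stats::na.omit(five_prime_gene(kept))),
    n_distinct_junction_lengths = dplyr::n_distinct(nchar(kept$junction)),
    n_region_length = nchar(n_region),
    n_region_distinct_bases = distinct_bases,
    is_complex = nchar(n_region) >= 2 && distinct_bases >= 2,
    noise_ratio = if (n_kept + n_removed > 0) n_removed / (n_kept + n_removed) else 0,
    satellite_ratio = if (n_kept + n_removed > 0) {
      filtered$n_removed_satellites / (n_kept + n_removed)
    } else 0
  ), nrow = 1L)
}

#' Evolution consensus thresholds
#'
#' The rule-based consensus that turns family metrics into an
#' evolving/stable call. A family is called evolving only when it has
#' enough independent members with genuine junctional variability (several
#' distinct 5' genes and junction lengths), is not dominated by filtered
#' noise, and either has a complex (specific) stem N region or enough
#' members to compensate for a low-complexity stem.
#'
#' @param min_members Minimum members surviving the noise filter (default 3).
#' @param min_genes Minimum distinct 5' genes among kept members (default 2).
#' @param min_lengths Minimum distinct junction lengths (default 2).
#' @param max_noise_ratio Maximum fraction of the family removed as
#'   top-member-similar satellites (default 0.5). A family dominated by
#'   near-copies of its top member is an error cloud, not evolution;
#'   removals by the plain abundance floor, in contrast, are the expected
#'   satellite fringe of any abundant clone and do not count against the
#'   family.
#' @param relaxed_members Member count at which a low-complexity stem N
#'   region is tolerated. The default (3, i.e. the member floor itself)
#'   leaves complexity reported but not gating: an exact-match stem spans
#'   the D 3' end, N2 and the entire J region, so three independent
#'   members with gene and length diversity are already very unlikely by
#'   chance. Raise it for repertoires where short stems are a real
#'   specificity concern.
#' @return A list of class `evolution_policy` with a `policy_id` hash.
#' @export
evolution_policy <- function(min_members = 3, min_genes = 2, min_lengths = 2,
                             max_noise_ratio = 0.5, relaxed_members = 3) {
  pol <- list(min_members = min_members, min_genes = min_genes,
              min_lengths = min_lengths, max_noise_ratio = max_noise_ratio,
              relaxed_members = relaxed_members)
  pol$policy_id <- rlang::hash(pol)
  structure(pol, class = "evolution_policy")
}

#' Call a stem family evolving or stable
#'
#' @param metrics A one-row tibble from [compute_metrics()].
#' @param policy An [evolution_policy()].
#' @return A list with `call` (`"evolving"` or `"stable"`), `evidence`
#'   (each predicate with the metric value it consulted) and `policy_id`.
#' @export
call_evolution <- function(metrics, policy = evolution_policy()) {
  ev <- list(
    enough_members = metrics$n_members_after_filter >= policy$min_members,
    enough_genes = metrics$n_distinct_5prime_genes >= policy$min_genes,
    enough_lengths = metrics$n_distinct_junction_lengths >= policy$min_lengths,
    low_noise = metrics$satellite_ratio <= policy$max_noise_ratio,
    complex_or_large = metrics$is_complex ||
      metrics$n_members_after_filter >= policy$relaxed_members
  )
  list(
    call = if (all(unlist(ev))) "evolving" else "stable",
    evidence = c(ev, as.list(metrics)),
    policy_id = policy$policy_id
  )
}

#' Run noise filtering, metrics and the evolution call over all families
#'
#' @param families A [group_by_stem()] tibble.
#' @param sample The [airr_sample()] the families came from.
#' @param npolicy A [noise_policy()].
#' @param epolicy An [evolution_policy()].
#' @return `families` with added columns: `call`, `kept` and `removed`
#'   member list-columns, and all metric columns.
#' @export
call_stem_evolution <- function(families, sample,
                                npolicy = noise_policy(),
                                epolicy = evolution_policy()) {
  if (nrow(families) == 0) {
    families$call <- character(0)
    families$kept <- list()
    families$removed <- list()
    return(families)
  }
  res <- purrr::map(seq_len(nrow(families)), function(i) {
    fam <- families[i, ]
    filt <- filter_noise(fam, npolicy, sample)
    metrics <- compute_metrics(filt, sample, fam)
    call <- call_evolution(metrics, epolicy)
    list(filt = filt, metrics = metrics, call = call)
  })
  metrics <- dplyr::bind_rows(purrr::map(res, "metrics"))
  families$call <- purrr::map_chr(res, ~ .x$call$call)
  families$kept <- purrr::map(res, ~ .x$filt$kept)
  families$removed <- purrr::map(res, ~ .x$filt$removed)
  dplyr::bind_cols(families, metrics)
}
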