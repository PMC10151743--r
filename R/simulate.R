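#' Simulation configuration
#'
#' Defaults define the study conditions the synthetic cohorts emulate:
#' two-library amplicon repertoires containing stable leukemic clones,
#' V-to-DJ recombination bursts sharing a DJ root, multi-round
#' VH-replacement families with footprints of up to 5 bp, D-D tandem
#' fusions, PCR/sequencing-error satellites, polyclonal background and
#' cIT-QC spike-in reads. Sizes are desk-scale: 25 patients with 6 leukemic
#' stems each (2 evolving + 4 stable) at 50,000 usable reads per library.
#'
#' @param seed Integer seed; the same seed and config reproduce the cohort
#'   exactly.
#' @param n_patients Patients per cohort.
#' @param stems_per_patient Leukemic stems per patient.
#' @param evolving_fraction Fraction of stems that evolve.
#' @param mechanism_mix Named probabilities over `DV_to_DJ`,
#'   `VH_replacement`, `D_to_DJ`, `mixed` for evolving stems.
#' @param burst_size_mean,burst_size_min,burst_size_max Truncated-geometric
#'   burst size (mean 8 on support `[3, 400]`; a "burst" below 3 members is
#'   not an observable family).
#' @param replacement_chains_mean Replacement stems carry
#'   `1 + Poisson(replacement_chains_mean)` chains.
#' @param replacement_rounds_max Rounds per chain, uniform on
#'   `1:replacement_rounds_max`.
#' @param tandem_count_mean Tandem stems carry `2 + Poisson(tandem_count_mean)`
#'   incoming Ds.
#' @param trim_max Uniform 0..`trim_max` nt trimmed per segment end.
#' @param n_region_mean,n_region_max Geometric N-region lengths (mean 4,
#'   capped at 12).
#' @param v_usage_bias Weight multiplier for the rank-1 (most D-proximal) V
#'   gene when drawing burst Vs, echoing the strong real-locus bias.
#' @param d_usage_bias Weight multiplier for the designated tandem-incoming
#'   D segment (`tandem_biased_d`).
#' @param tandem_biased_d Name of the preferentially incoming D.
#' @param footprint_probs Probabilities of planted footprint lengths 0..5
#'   (0 = remnant fully trimmed away).
#' @param error_rate Per-base substitution probability used when deriving
#'   satellite junctions.
#' @param satellite_mean Poisson mean of satellites per abundant clonotype.
#' @param depth Usable reads per sample library.
#' @param leukemic_fraction Fraction of usable reads carried by leukemic
#'   stems at diagnosis.
#' @param n_background Polyclonal background clonotypes per library.
#' @param qc_reads,qc_cell_equivalents cIT-QC spike-in reads and cell
#'   equivalents per library.
#' @param dj_root_emit_prob Probability the DJ root is observable in the
#'   IGH-DJ library, by stem class (bursts mostly rooted, replacement
#'   stems mostly not).
#' @param pb_depth_fraction Depth thinning for the PB member of a BM/PB
#'   pair.
#' @param followup_leukemic Named leukemic fractions for the longitudinal
#'   follow-up timepoints.
#' @param kill_top_member In the longitudinal preset, remove the diagnostic
#'   top member of evolving stems from all follow-ups.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_patients = 25,
                       stems_per_patient = 6,
                       evolving_fraction = 1 / 3,
                       mechanism_mix = c(DV_to_DJ = 0.70, VH_replacement = 0.22,
                                         D_to_DJ = 0.06, mixed = 0.02),
                       burst_size_mean = 8, burst_size_min = 3,
                       burst_size_max = 400,
                       replacement_chains_mean = 2,
                       replacement_rounds_max = 4,
                       tandem_count_mean = 2,
                       trim_max = 4,
                       n_region_mean = 4, n_region_max = 12,
                       v_usage_bias = 5,
                       d_usage_bias = 9,
                       tandem_biased_d = "IGHD2-2",
                       footprint_probs = c(0.15, 0.10, 0.20, 0.25, 0.20, 0.10),
                       error_rate = 0.002,
                       satellite_mean = 2,
                       depth = 50000,
                       leukemic_fraction = 0.8,
                       n_background = 150,
                       qc_reads = 2500,
                       qc_cell_equivalents = 40,
                       dj_root_emit_prob = c(DV_to_DJ = 0.9, VH_replacement = 0.1,
                                             D_to_DJ = 1.0, mixed = 0.9,
                                             stable = 0.3),
                       pb_depth_fraction = 0.1,
                       followup_leukemic = c(day6 = 0.05, day22 = 0.002),
                       kill_top_member = FALSE) {
  stopifnot(abs(sum(mechanism_mix) - 1) < 1e-9,
            all(mechanism_mix >= 0), all(mechanism_mix <= 1),
            abs(sum(footprint_probs) - 1) < 1e-9,
            length(footprint_probs) == 6,
            burst_size_min >= 1, burst_size_max >= burst_size_min,
            evolving_fraction >= 0, evolving_fraction <= 1,
            depth > 0, leukemic_fraction > 0, leukemic_fraction <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

rand_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rgeom_capped <- function(mean, max) {
  min(stats::rgeom(1, 1 / (mean + 1)), max)
}

rburst_size <- function(cfg) {
  excess_mean <- cfg$burst_size_mean - cfg$burst_size_min
  min(cfg$burst_size_min + stats::rgeom(1, 1 / (excess_mean + 1)),
      cfg$burst_size_max)
}

draw_v <- function(catalog, cfg, biased = FALSE) {
  vs <- catalog[catalog$segment_type == "V", , drop = FALSE]
  w <- rep(1, nrow(vs))
  if (biased) w[vs$locus_rank == 1] <- cfg$v_usage_bias
  vs[sample.int(nrow(vs), 1, prob = w), , drop = FALSE]
}

draw_d <- function(catalog, cfg, biased = FALSE) {
  ds <- catalog[catalog$segment_type == "D", , drop = FALSE]
  w <- rep(1, nrow(ds))
  if (biased) w[ds$name == cfg$tandem_biased_d] <- cfg$d_usage_bias
  ds[sample.int(nrow(ds), 1, prob = w), , drop = FALSE]
}

draw_j <- function(catalog) {
  js <- catalog[catalog$segment_type == "J", , drop = FALSE]
  js[sample.int(nrow(js), 1), , drop = FALSE]
}

make_clonotype_row <- function(v_call = NA, d_call = NA, d2_call = NA, j_call,
                               v_part = "", n1 = "", d2_part = "", n0 = "",
                               d_part = "", n2 = "", j_part) {
  tibble::new_tibble(list(
    v_call = as.character(v_call), d_call = as.character(d_call),
    d2_call = as.character(d2_call), j_call = as.character(j_call),
    v_part = v_part, n1 = n1, d2_part = d2_part, n0 = n0,
    d_part = d_part, n2 = n2, j_part = j_part,
    junction = paste0(v_part, n1, d2_part, n0, d_part, n2, j_part)
  ), nrow = length(j_call))
}

rand_nt_vec <- function(lens) {
  total <- sum(lens)
  if (total == 0) return(rep("", length(lens)))
  pool <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  out <- character(length(lens))
  nonzero <- lens > 0
  out[nonzero] <- vapply(which(nonzero), function(i) {
    paste(pool[starts[i]:ends[i]], collapse = "")
  }, "")
  out
}

rgeom_capped_vec <- function(n, mean, max) {
  pmin(stats::rgeom(n, 1 / (mean + 1)), max)
}

# vectorized draw of n independent rearrangements (polyclonal background)
simulate_rearrangements_vec <- function(n, catalog, cfg, library,
                                        min_d_keep = 5) {
  ds <- catalog[catalog$segment_type == "D", , drop = FALSE]
  js <- catalog[catalog$segment_type == "J", , drop = FALSE]
  di <- sample.int(nrow(ds), n, replace = TRUE)
  ji <- sample.int(nrow(js), n, replace = TRUE)
  d_seq <- ds$sequence[di]
  d_len <- nchar(d_seq)
  max_tot <- pmax(d_len - min_d_keep, 0)
  t5 <- floor(stats::runif(n) * (pmin(cfg$trim_max, max_tot) + 1))
  t3 <- floor(stats::runif(n) * (pmin(cfg$trim_max, max_tot - t5) + 1))
  d_part <- substr(d_seq, 1 + t5, d_len - t3)
  j_seq <- js$sequence[ji]
  j_t5 <- floor(stats::runif(n) * (cfg$trim_max + 1))
  j_part <- substr(j_seq, 1 + j_t5, nchar(j_seq))
  n2 <- rand_nt_vec(rgeom_capped_vec(n, cfg$n_region_mean, cfg$n_region_max))
  if (library == "IGH-DJ") {
    v_call <- rep(NA_character_, n)
    v_part <- rep("", n)
    n1 <- rep("", n)
  } else {
    vs <- catalog[catalog$segment_type == "V", , drop = FALSE]
    vi <- sample.int(nrow(vs), n, replace = TRUE)
    v_call <- vs$name[vi]
    v_keep <- pmax(8 - floor(stats::runif(n) * (cfg$trim_max + 1)), 4)
    v_seq <- vs$sequence[vi]
    v_part <- substr(v_seq, nchar(v_seq) - v_keep + 1, nchar(v_seq))
    n1 <- rand_nt_vec(rgeom_capped_vec(n, cfg$n_region_mean, cfg$n_region_max))
  }
  make_clonotype_row(v_call = v_call, d_call = ds$name[di],
                     d2_call = rep(NA_character_, n),
                     j_call = js$name[ji], v_part = v_part, n1 = n1,
                     d2_part = rep("", n), n0 = rep("", n),
                     d_part = d_part, n2 = n2, j_part = j_part)
}

#' Simulate one random V(D)J (or DJ) rearrangement
#'
#' Picks germline segments, trims each involved end uniformly on
#' 0..`trim_max`, and joins them with non-templated N nucleotides of
#' geometric length. The generated anatomy is recorded as ground truth on
#' the returned row.
#'
#' @param catalog A [locus_catalog()].
#' @param cfg A [sim_config()]. Sampling uses R's global RNG stream: call
#'   `set.seed()` (or use the cohort-level wrappers) for reproducibility.
#' @param library `"IGH-VJ"` for a full VDJ junction, `"IGH-DJ"` for an
#'   incomplete DJ rearrangement.
#' @param min_d_keep Minimum D nucleotides retained after trimming.
#' @return A one-row tibble with gene calls, junction parts and the
#'   junction string.
#' @export
simulate_rearrangement <- function(catalog, cfg = sim_config(),
                                   library = c("IGH-VJ", "IGH-DJ"),
                                   min_d_keep = 5) {
  library <- match.arg(library)
  d <- draw_d(catalog, cfg)
  j <- draw_j(catalog)
  d_len <- nchar(d$sequence)
  max_trim_total <- max(d_len - min_d_keep, 0)
  t5 <- sample(0:min(cfg$trim_max, max_trim_total), 1)
  t3 <- sample(0:min(cfg$trim_max, max_trim_total - t5), 1)
  d_part <- substr(d$sequence, 1 + t5, d_len - t3)
  j_t5 <- sample(0:cfg$trim_max, 1)
  j_part <- substr(j$sequence, 1 + j_t5, nchar(j$sequence))
  n2 <- rand_nt(rgeom_capped(cfg$n_region_mean, cfg$n_region_max))
  if (library == "IGH-DJ") {
    return(make_clonotype_row(j_call = j$name, d_call = d$name,
                              d_part = d_part, n2 = n2, j_part = j_part))
  }
  v <- draw_v(catalog, cfg)
  v_keep <- 8 - sample(0:cfg$trim_max, 1)
  v_part <- str_tail(v$sequence, max(v_keep, 4))
  n1 <- rand_nt(rgeom_capped(cfg$n_region_mean, cfg$n_region_max))
  make_clonotype_row(v_call = v$name, d_call = d$name, j_call = j$name,
                     v_part = v_part, n1 = n1, d_part = d_part, n2 = n2,
                     j_part = j_part)
}

#' Simulate a V-to-DJ recombination burst on a DJ root
#'
#' Each member receives a freshly drawn V (biased toward the most
#' D-proximal gene), a fresh N1, and an independent 5' erosion of the
#' root's D part; the D 3' end, N2 and J parts are copied unchanged, so
#' every member shares the root's DNJ-stem by construction (erosion never
#' reaches the last 3 D nucleotides).
#'
#' @param dj_root A one-row DJ rearrangement (from
#'   [simulate_rearrangement()] with `library = "IGH-DJ"`).
#' @param size Number of burst members.
#' @param catalog,cfg See [simulate_rearrangement()].
#' @return A tibble of `size` member rows.
#' @export
simulate_burst <- function(dj_root, size, catalog, cfg = sim_config()) {
  purrr::map_dfr(seq_len(size), function(i) {
    v <- draw_v(catalog, cfg, biased = TRUE)
    v_keep <- 8 - sample(0:cfg$trim_max, 1)
    erosion <- sample(0:min(cfg$trim_max, nchar(dj_root$d_part) - 3), 1)
    make_clonotype_row(
      v_call = v$name, d_call = dj_root$d_call, j_call = dj_root$j_call,
      v_part = str_tail(v$sequence, max(v_keep, 4)),
      n1 = rand_nt(rgeom_capped(cfg$n_region_mean, cfg$n_region_max)),
      d_part = substr(dj_root$d_part, 1 + erosion, nchar(dj_root$d_part)),
      n2 = dj_root$n2, j_part = dj_root$j_part
    )
  })
}

#' Simulate a multi-round VH-replacement chain
#'
#' Each round replaces the current V with a strictly downstream
#' (D-distal) V. The new N1 is fresh N nucleotides, then a planted
#' footprint (the 3' tail of the replaced V, with length drawn from
#' `footprint_probs`; 0 means the remnant was trimmed away), then the
#' surviving 3' tail (up to 4 nt) of the previous N1. D, N2 and J are
#' untouched, so the mother's DNJ-stem is preserved exactly. If no
#' downstream V remains the chain is truncated.
#'
#' @param mother A one-row VDJ rearrangement with a `v_call`.
#' @param rounds Number of replacement rounds attempted.
#' @param catalog,cfg See [simulate_rearrangement()].
#' @return A tibble of member rows with a `planted_footprint` length column
#'   and a `replacement_round` column.
#' @export
simulate_replacement_chain <- function(mother, rounds, catalog,
                                       cfg = sim_config()) {
  vs <- catalog[catalog$segment_type == "V", , drop = FALSE]
  current <- mother
  out <- list()
  for (r in seq_len(rounds)) {
    cur_rank <- catalog_get(catalog, current$v_call, "V")$locus_rank
    downstream <- vs[vs$locus_rank > cur_rank, , drop = FALSE]
    if (nrow(downstream) == 0) break
    incoming <- downstream[sample.int(nrow(downstream), 1), , drop = FALSE]
    f <- sample(0:5, 1, prob = cfg$footprint_probs)
    footprint <- if (f > 0) {
      v_three_prime_tail(catalog, current$v_call, f)
    } else ""
    surviving <- str_tail(current$n1, min(4, nchar(current$n1)))
    fresh <- rand_nt(rgeom_capped(2, 6))
    v_keep <- 8 - sample(0:cfg$trim_max, 1)
    member <- make_clonotype_row(
      v_call = incoming$name, d_call = current$d_call,
      j_call = current$j_call,
      v_part = str_tail(incoming$sequence, max(v_keep, 4)),
      n1 = paste0(fresh, footprint, surviving),
      d_part = current$d_part, n2 = current$n2, j_part = current$j_part
    )
    member$planted_footprint <- f
    member$replacement_round <- r
    out[[r]] <- member
    current <- member
  }
  dplyr::bind_rows(out)
}

#' Simulate a D-D tandem fusion member on a DJ root
#'
#' An incoming D (biased toward the designated segment, echoing the strong
#' real-data preference) joins 5' of the possibly eroded root D with a
#' fresh N0; the root's D 3' end, N2 and J are kept, preserving the stem.
#'
#' @param dj_root A one-row DJ rearrangement.
#' @param catalog,cfg See [simulate_rearrangement()].
#' @return A one-row IGH-DJ member with `d2_call`/`d2_part` set.
#' @export
simulate_d_dj_tandem <- function(dj_root, catalog, cfg = sim_config()) {
  inc <- draw_d(catalog, cfg, biased = TRUE)
  d_len <- nchar(inc$sequence)
  t5 <- sample(0:min(cfg$trim_max, d_len - 5), 1)
  t3 <- sample(0:min(cfg$trim_max, d_len - 5 - t5), 1)
  erosion <- sample(0:min(cfg$trim_max, nchar(dj_root$d_part) - 3), 1)
  make_clonotype_row(
    d_call = dj_root$d_call, d2_call = inc$name, j_call = dj_root$j_call,
    d2_part = substr(inc$sequence, 1 + t5, d_len - t3),
    n0 = rand_nt(rgeom_capped(2, 6)),
    d_part = substr(dj_root$d_part, 1 + erosion, nchar(dj_root$d_part)),
    n2 = dj_root$n2, j_part = dj_root$j_part
  )
}

#' Add PCR/sequencing-error satellites to abundant clonotypes
#'
#' For every clonotype at or above `abundant_percent` of the read total,
#' draws `Poisson(satellite_mean)` satellites: copies of the junction with
#' 1-2 substitutions and a read count below the 3-read noise floor.
#' Substitution positions are uniform over the junction by default;
#' `avoid_stem` confines them 5' of the stem suffix so satellites stay in
#' their parent's family (useful for filter-fidelity fixtures).
#'
#' @param clonotypes Tibble of clonotype rows with `junction`, `read_count`
#'   and anatomy columns; stems must be extractable (`d_part`, `n2`,
#'   `j_part`).
#' @param cfg A [sim_config()].
#' @param abundant_percent Threshold (% of current read total) defining
#'   "abundant" parents.
#' @param avoid_stem Keep substitutions out of the stem suffix.
#' @return A tibble of satellite rows with `parent_id` set.
#' @export
add_satellites <- function(clonotypes, cfg = sim_config(),
                           abundant_percent = 1, avoid_stem = FALSE) {
  total <- sum(clonotypes$read_count)
  abundant <- which(100 * clonotypes$read_count / total >= abundant_percent)
  out <- list()
  for (i in abundant) {
    n_sat <- stats::rpois(1, cfg$satellite_mean)
    if (n_sat == 0) next
    parent <- clonotypes[i, ]
    stem_len <- nchar(extract_dnj_stem(parent)$stem)
    for (s in seq_len(n_sat)) {
      jn <- strsplit(parent$junction, "")[[1]]
      n_sub <- sample(1:2, 1)
      max_pos <- if (avoid_stem) length(jn) - stem_len else length(jn)
      if (max_pos < n_sub) next
      pos <- sample(max_pos, n_sub)
      for (p in pos) jn[p] <- sample(setdiff(c("A", "C", "G", "T"), jn[p]), 1)
      sat <- parent
      sat$junction <- paste(jn, collapse = "")
      # keep region columns consistent with the mutated junction
      lens <- cumsum(nchar(c(parent$v_part, parent$n1, parent$d2_part,
                             parent$n0, parent$d_part, parent$n2,
                             parent$j_part)))
      starts <- c(1, head(lens, -1) + 1)
      parts <- substring(sat$junction, starts, lens)
      sat$v_part <- parts[1]; sat$n1 <- parts[2]; sat$d2_part <- parts[3]
      sat$n0 <- parts[4]; sat$d_part <- parts[5]; sat$n2 <- parts[6]
      sat$j_part <- parts[7]
      sat$read_count <- sample(1:2, 1)
      sat$role <- "satellite"
      sat$parent_id <- parent$clonotype_id
      sat$clonotype_id <- paste0(parent$clonotype_id, "_sat", s)
      out[[length(out) + 1]] <- sat
    }
  }
  dplyr::bind_rows(out)
}
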