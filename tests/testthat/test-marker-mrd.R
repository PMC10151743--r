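mk_analysis <- function(cl, library = "IGH-VJ", qc_reads = 0, qc_cells = 0,
                        patient_id = "PT1", sample_id = "S1") {
  s <- airr_sample(cl, sample_id = sample_id, patient_id = patient_id,
                   library = library, qc_reads = qc_reads,
                   qc_cell_equivalents = qc_cells)
  analyze_sample(s)
}

test_that("marker calls fire on summed reads, cells, or evolution", {
  # stable family at 6.2% summed reads -> marker via reads threshold
  fam <- dplyr::bind_rows(
    anat_row("big", read_count = 620),
    anat_row("rest", n1 = "TTTTTTTT", n2 = "CGCG", v_call = "IGHV1-2",
             read_count = 9380)
  )
  a <- mk_analysis(fam)
  f <- a$families
  big <- f[f$top_id == "big", ]
  mc <- call_marker(big, a$sample)
  expect_true(mc$is_marker)
  expect_equal(mc$criteria_fired, "reads_threshold")

  # stable family at 4.9%, QC unavailable -> not a marker
  fam2 <- dplyr::bind_rows(
    anat_row("small", read_count = 49),
    anat_row("rest", n1 = "TTTTTTTT", n2 = "CGCG", v_call = "IGHV1-2",
             read_count = 951)
  )
  a2 <- mk_analysis(fam2)
  mc2 <- call_marker(a2$families[a2$families$top_id == "small", ], a2$sample)
  expect_false(mc2$is_marker)

  # evolving family at ~0.3% summed reads -> marker via evolving alone
  set.seed(90)
  cfg <- sim_config(seed = 90)
  root <- simulate_rearrangement(toy, cfg, "IGH-DJ", min_d_keep = 7)
  members <- simulate_burst(root, 6, toy, cfg)
  members$clonotype_id <- sprintf("b%d", 1:6)
  members$read_count <- rep(5L, 6)
  filler <- anat_row("fill", n1 = "GGGGGGGGGG", read_count = 9970)
  a3 <- mk_analysis(dplyr::bind_rows(members, filler))
  evf <- a3$families[a3$families$call == "evolving", ]
  expect_equal(nrow(evf), 1)
  expect_lt(evf$total_percent, 1)
  mc3 <- call_marker(evf, a3$sample)
  expect_true(mc3$is_marker)
  expect_true("evolving" %in% mc3$criteria_fired)
  expect_true(mc3$would_conventional_miss)
})

test_that("marker status is monotone in summed abundance", {
  mk <- function(reads) {
    fam <- dplyr::bind_rows(
      anat_row("x", read_count = reads),
      anat_row("rest", n1 = "TTTTTTTT", n2 = "CGCG", v_call = "IGHV1-2",
               read_count = 10000 - reads)
    )
    a <- mk_analysis(fam)
    call_marker(a$families[a$families$top_id == "x", ], a$sample)$is_marker
  }
  grid <- c(100, 400, 499, 501, 900, 5000)
  res <- vapply(grid, mk, TRUE)
  expect_false(any(diff(res) < 0))  # once marker, stays marker as % grows
})

test_that("MRD follows members at any abundance and sums them", {
  stem <- "ATCGATGTATAAGTAAACATTTCGCTTGAAGTGTGGGAGC"
  fu <- dplyr::bind_rows(
    anat_row("m1", n1 = "AAAA", read_count = 200),
    anat_row("m2", n1 = "CC", v_call = "IGHV1-2", read_count = 50),
    anat_row("m3", n1 = "G", v_call = "IGHV1-3", read_count = 10),
    anat_row("bg", n1 = "T", n2 = "CGCG", read_count = 9740)
  )
  s <- make_sample(fu)
  m <- quantify_mrd(stem, s)
  expect_equal(m$n_members_detected, 3)
  expect_equal(m$stem_percent_reads, 2.6)
  expect_equal(m$top_member_percent_reads, 2.0)
  expect_true(m$traceable)
  # members below any evolution-filter floor still count
  expect_gte(m$stem_percent_reads, m$top_member_percent_reads)

  none <- quantify_mrd("TTTTTTTTTTTTTTTTTTTT", s)
  expect_false(none$traceable)
  expect_equal(none$stem_percent_reads, 0)
})

test_that("stem MRD dominates top-member MRD on simulated follow-ups", {
  set.seed(91)
  cfg <- sim_config(seed = 91, n_patients = 1, depth = 20000,
                    n_background = 60)
  p <- simulate_patient(toy, cfg, "P01")
  fu <- simulate_followup(p, toy, cfg, leukemic_fraction = 0.02)
  for (stem in p$truth$stem) {
    m <- quantify_mrd(stem, fu)
    expect_gte(m$stem_percent_reads, m$top_member_percent_reads)
  }
})

test_that("a zero-depth follow-up is rejected, not reported negative", {
  s <- make_sample(anat_row("c1"))
  s$usable_reads <- 0L
  expect_error(quantify_mrd("AAAA", s), "usable reads")
})

test_that("compartment comparison categorizes stems and overlaps members", {
  set.seed(92)
  cfg <- sim_config(seed = 92, n_patients = 1, depth = 20000,
                    n_background = 60)
  p <- simulate_patient(toy, cfg, "P01")
  bm <- analyze_sample_pair(p$vj, p$dj, toy)
  # identical samples -> complete overlap, all concordant
  same <- compare_compartments(bm$vj, bm$vj)
  expect_true(all(same$stems$category == "marker_both"))
  expect_true(all(same$stems$evolution_concordant))
  if (nrow(same$member_overlap) > 0) {
    expect_true(all(same$member_overlap$overlap == 1))
  }
  # subsampled PB keeps high-abundance stems, loses members
  pb_vj <- subsample_repertoire(p$vj, 0.1, sample_id = "PB_VJ")
  pb_dj <- subsample_repertoire(p$dj, 0.1, sample_id = "PB_DJ")
  pb <- analyze_sample_pair(pb_vj, pb_dj, toy)
  ov <- compare_compartments(bm$vj, pb$vj)
  expect_true(all(ov$stems$category %in%
    c("marker_both", "detectable_both_marker_one", "one_compartment_only")))
  big_bm <- bm$vj$families$stem[bm$vj$families$total_percent > 10]
  expect_true(all(big_bm %in% ov$stems$stem[ov$stems$category != "one_compartment_only"]))
  if (nrow(ov$member_overlap) > 0) {
    expect_true(all(ov$member_overlap$overlap <= 1))
  }
  # different patients are refused
  pb$vj$sample$patient_id <- "OTHER"
  expect_error(compare_compartments(bm$vj, pb$vj), "same patient")
})

test_that("longitudinal tracking raises the right flags", {
  diag_cl <- dplyr::bind_rows(
    anat_row("top", n1 = "AAAA", n2 = "GATC", read_count = 5000),
    anat_row("m2", n1 = "CCG", v_call = "IGHV1-2", n2 = "GATC", read_count = 3000),
    anat_row("m3", n1 = "T", v_call = "IGHV1-3", n2 = "GATC", read_count = 2000)
  )
  diag <- mk_analysis(diag_cl)
  stem <- diag$families$stem[1]

  # top persists and stays top -> no flags
  fu_same <- make_sample(diag_cl, sample_id = "FU1")
  fu_same$timepoint_label <- "day6"
  tr1 <- track_longitudinal(diag, list(fu_same))
  expect_false(any(tr1$stem_untraceable))
  expect_false(any(tr1$top_member_vanished))
  expect_false(any(tr1$top_member_displaced))

  # stem absent everywhere -> untraceable
  off <- make_sample(anat_row("other", n2 = "CCCC"), sample_id = "FU2")
  tr2 <- track_longitudinal(diag, list(off))
  expect_true(all(tr2$stem_untraceable))

  # ranking inversion -> displaced
  inv <- diag_cl
  inv$read_count <- c(100L, 6000L, 2000L)
  fu_inv <- make_sample(inv, sample_id = "FU3")
  tr3 <- track_longitudinal(diag, list(fu_inv))
  expect_true(tr3$top_member_displaced[tr3$stem == stem])
  expect_false(tr3$top_member_vanished[tr3$stem == stem])

  # top eradicated while siblings persist -> vanished
  gone <- diag_cl[-1, ]
  fu_gone <- make_sample(gone, sample_id = "FU4")
  tr4 <- track_longitudinal(diag, list(fu_gone))
  expect_true(tr4$top_member_vanished[tr4$stem == stem])
  expect_false(tr4$stem_untraceable[tr4$stem == stem])

  # recommendations: sum always; stem-not-member for evolving
  expect_true(all(vapply(tr1$recommendations,
                         function(r) "report_sum" %in% r, TRUE)))
  ev <- tr1$call == "evolving"
  if (any(ev)) {
    expect_true(all(vapply(tr1$recommendations[ev],
                           function(r) "follow_stem_not_member" %in% r, TRUE)))
  }
})

test_that("cross-patient screening lists only shared marker stems", {
  set.seed(93)
  cfg <- sim_config(seed = 93, n_patients = 1, depth = 20000,
                    n_background = 60)
  p1 <- simulate_patient(toy, cfg, "P01")
  p2 <- simulate_patient(toy, cfg, "P02")
  a1 <- analyze_sample_pair(p1$vj, p1$dj, toy)
  a2 <- analyze_sample_pair(p2$vj, p2$dj, toy)
  none <- cross_patient_specificity(list(a1$vj, a2$vj))
  expect_equal(nrow(none), 0)

  # plant a shared abundant clone in both patients
  shared <- anat_row("shared", n2 = "TTAG", read_count = 8000)
  s1 <- a1$vj$sample; s2 <- a2$vj$sample
  s1$clonotypes <- dplyr::bind_rows(s1$clonotypes, shared)
  s2$clonotypes <- dplyr::bind_rows(s2$clonotypes, shared)
  b1 <- analyze_sample(s1)
  b2 <- analyze_sample(s2)
  b1$sample$patient_id <- "P01"; b2$sample$patient_id <- "P02"
  rep <- cross_patient_specificity(list(b1, b2))
  expect_equal(nrow(rep), 1)
  expect_equal(rep$n_patients, 2)
  expect_match(rep$patient_ids, "P01,P02")
})

test_that("percent cells uses the spike-in factor", {
  cl <- dplyr::bind_rows(anat_row("c1", read_count = 100),
                         anat_row("c2", n1 = "A", read_count = 900))
  s <- make_sample(cl, qc_reads = 2000, qc_cells = 100)
  qc <- normalization_factor(s)
  expect_equal(percent_cells(100, s, qc), 10)
  s0 <- make_sample(cl)
  expect_true(is.na(percent_cells(100, s0)))
})
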