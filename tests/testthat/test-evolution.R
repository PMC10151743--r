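# helper: one annotated sample + its single interesting family
family_of <- function(cl, library = "IGH-VJ") {
  s <- annotate_stems(make_sample(cl, library = library))
  fams <- group_by_stem(s)
  list(sample = s, fam = fams[which.max(fams$n_members), ])
}

test_that("noise filter removes satellites and sub-floor members, never the top", {
  top <- anat_row("top", n1 = "AAAA", read_count = 10000)
  sat <- top
  sat$clonotype_id <- "sat"
  # one substitution outside the stem
  substr(sat$n1, 1, 1) <- "C"
  sat$junction <- paste0(sat$v_part, sat$n1, sat$d_part, sat$n2, sat$j_part)
  sat$read_count <- 500L
  low <- anat_row("low", n1 = "GGCC", v_call = "IGHV1-2", read_count = 2)
  far <- anat_row("far", n1 = "TTTTTTTTT", v_call = "IGHV1-3",
                  read_count = 100)
  fx <- family_of(dplyr::bind_rows(top, sat, low, far))
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  expect_setequal(filt$kept$clonotype_id, c("top", "far"))
  expect_equal(filt$n_removed_satellites, 1)
  expect_equal(filt$n_removed_low_abundance, 1)
  expect_equal(filt$removed$removal_reason[filt$removed$clonotype_id == "sat"],
               "satellite")
  # reads conserved across the filter
  expect_equal(sum(filt$kept$read_count) + sum(filt$removed$read_count),
               fx$fam$total_reads)
})

test_that("a member below 3 reads is removed whatever its similarity", {
  top <- anat_row("top", n1 = "AAAA", read_count = 1000)
  two <- anat_row("two", n1 = "GGGG", v_call = "IGHV1-2", read_count = 2)
  fx <- family_of(dplyr::bind_rows(top, two))
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  expect_equal(filt$removed$clonotype_id, "two")
  expect_equal(filt$removed$removal_reason, "low_abundance")
})

test_that("a dissimilar abundant member with a different V is kept", {
  top <- anat_row("top", n1 = "AAAA", read_count = 10000)
  other <- anat_row("oth", n1 = "CGCGTTT", v_call = "IGHV1-2",
                    read_count = 100)  # 0.5s% of reads, edit distance > 2
  fx <- family_of(dplyr::bind_rows(top, other,
                                   anat_row("pad", n1 = "T", v_call = "IGHV2-5",
                                            read_count = 9900)))
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  expect_true("oth" %in% filt$kept$clonotype_id)
})

test_that("satellite rule respects the same-gene requirement", {
  top <- anat_row("top", n1 = "AAAA", read_count = 10000)
  twin <- top
  twin$clonotype_id <- "twin"
  twin$v_call <- "IGHV1-2"   # different gene, near-identical junction
  substr(twin$n1, 1, 1) <- "C"
  twin$junction <- paste0(twin$v_part, twin$n1, twin$d_part, twin$n2,
                          twin$j_part)
  twin$read_count <- 400L
  fx <- family_of(dplyr::bind_rows(top, twin))
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  expect_true("twin" %in% filt$kept$clonotype_id)
  filt2 <- filter_noise(fx$fam, noise_policy(satellite_same_gene = FALSE),
                        fx$sample)
  expect_false("twin" %in% filt2$kept$clonotype_id)
})

test_that("family metrics count genes, lengths and complexity as defined", {
  cl <- dplyr::bind_rows(
    anat_row("m1", v_call = "IGHV6-1", n1 = "ACGTACGTA", read_count = 500),
    anat_row("m2", v_call = "IGHV1-2", n1 = "ACGTAC", read_count = 400),
    anat_row("m3", v_call = "IGHV1-2*02", n1 = "CGT", read_count = 300)
  )
  fx <- family_of(cl)
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  m <- compute_metrics(filt, fx$sample, fx$fam)
  expect_equal(m$n_distinct_5prime_genes, 2)   # alleles collapse to genes
  expect_equal(m$n_distinct_junction_lengths, 3)
  expect_equal(m$n_members_after_filter, 3)
  expect_equal(m$noise_ratio, 0)
})

test_that("junction lengths deduplicate", {
  # N1 paddings 0/3/6/0 give junction lengths {46, 49, 52, 46} -> 3 distinct
  pads <- c(0, 3, 6, 0)
  cl <- dplyr::bind_rows(lapply(seq_along(pads), function(i) {
    anat_row(paste0("m", i), v_call = c("IGHV6-1", "IGHV1-2", "IGHV1-3",
                                        "IGHV2-5")[i],
             n1 = strrep("A", pads[i]), read_count = 100)
  }))
  fx <- family_of(cl)
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  m <- compute_metrics(filt, fx$sample, fx$fam)
  expect_equal(m$n_distinct_junction_lengths, 3)
})

test_that("stem N-region complexity needs length >= 2 and >= 2 bases", {
  single_base <- family_of(anat_row("c1", n2 = "GG"))
  filt <- filter_noise(single_base$fam, noise_policy(), single_base$sample)
  m <- compute_metrics(filt, single_base$sample, single_base$fam)
  expect_equal(m$n_region_length, 2)
  expect_false(m$is_complex)

  mixed_bases <- family_of(anat_row("c1", n2 = "GA"))
  filt2 <- filter_noise(mixed_bases$fam, noise_policy(), mixed_bases$sample)
  expect_true(compute_metrics(filt2, mixed_bases$sample,
                              mixed_bases$fam)$is_complex)
})

test_that("the consensus call is a conjunction of its predicates", {
  # singleton family can never evolve
  fx <- family_of(anat_row("solo"))
  f1 <- filter_noise(fx$fam, noise_policy(), fx$sample)
  m1 <- compute_metrics(f1, fx$sample, fx$fam)
  call1 <- call_evolution(m1)
  expect_equal(call1$call, "stable")
  expect_false(call1$evidence$enough_members)

  # a family whose non-top members are all top-satellites is an error cloud
  top <- anat_row("top", n1 = "AAAAA", n2 = "CA", read_count = 10000)
  sats <- dplyr::bind_rows(lapply(1:9, function(i) {
    s <- top
    s$clonotype_id <- paste0("s", i)
    substr(s$n1, (i %% 4) + 1, (i %% 4) + 1) <- "T"
    s$junction <- paste0(s$v_part, s$n1, s$d_part, s$n2, s$j_part)
    s$read_count <- 50L + i
    s
  }))
  fx2 <- family_of(dplyr::bind_rows(top, sats))
  f2 <- filter_noise(fx2$fam, noise_policy(), fx2$sample)
  m2 <- compute_metrics(f2, fx2$sample, fx2$fam)
  expect_equal(m2$noise_ratio, 0.9)
  expect_gt(m2$satellite_ratio, 0.5)
  expect_equal(call_evolution(m2)$call, "stable")
})

test_that("a simulated burst family is called evolving", {
  set.seed(404)
  cfg <- sim_config(seed = 404)
  root <- simulate_rearrangement(toy, cfg, "IGH-DJ", min_d_keep = 7)
  # force a complex N2 so the example is self-contained
  root$n2 <- "GATC"
  root$junction <- paste0(root$d_part, root$n2, root$j_part)
  members <- simulate_burst(root, 12, toy, cfg)
  members$clonotype_id <- sprintf("b%02d", 1:12)
  members$read_count <- c(2000L, rep(300L, 11))
  fx <- family_of(members)
  filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
  m <- compute_metrics(filt, fx$sample, fx$fam)
  expect_gte(m$n_distinct_5prime_genes, 2)
  expect_gte(m$n_distinct_junction_lengths, 2)
  expect_equal(call_evolution(m)$call, "evolving")
})

test_that("adding a diverse member never flips evolving to stable", {
  set.seed(405)
  cfg <- sim_config(seed = 405)
  root <- simulate_rearrangement(toy, cfg, "IGH-DJ", min_d_keep = 7)
  members <- simulate_burst(root, 6, toy, cfg)
  members$clonotype_id <- sprintf("b%02d", 1:6)
  members$read_count <- rep(500L, 6)
  base_call <- function(cl) {
    fx <- family_of(cl)
    filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
    call_evolution(compute_metrics(filt, fx$sample, fx$fam))$call
  }
  if (base_call(members) == "evolving") {
    extra <- simulate_burst(root, 1, toy, cfg)
    extra$v_call <- "IGHV3-74"   # guaranteed new gene
    extra$n1 <- strrep("ACGT", 4)  # new junction length
    extra$v_part <- substr(extra$v_part, 1, 5)
    extra$junction <- paste0(extra$v_part, extra$n1, extra$d_part,
                             extra$n2, extra$j_part)
    extra$clonotype_id <- "extra"
    extra$read_count <- 500L
    expect_equal(base_call(dplyr::bind_rows(members, extra)), "evolving")
  }
})

test_that("evolution calls are deterministic for identical input", {
  set.seed(406)
  cfg <- sim_config(seed = 406)
  root <- simulate_rearrangement(toy, cfg, "IGH-DJ", min_d_keep = 7)
  members <- simulate_burst(root, 8, toy, cfg)
  members$clonotype_id <- sprintf("b%02d", 1:8)
  members$read_count <- rep(100L, 8)
  fx <- family_of(members)
  run <- function() {
    filt <- filter_noise(fx$fam, noise_policy(), fx$sample)
    call_evolution(compute_metrics(filt, fx$sample, fx$fam))
  }
  expect_identical(run(), run())
})
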