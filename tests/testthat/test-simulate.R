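test_that("trio genotypes follow Hardy-Weinberg and Mendelian transmission", {
  cfg <- sim_config(n_trios = 400, n_snps = 25, maf = 0.5, seed = 61)
  trios <- simulate_trios(cfg)
  # child heterozygosity at maf 0.5 is 2pq = 0.5
  expect_equal(mean(trios$child_call == "AB"), 0.5, tolerance = 0.02)
  # transmitted alleles are consistent with the recorded parental calls
  pair <- list(AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B"))
  ok_m <- mapply(function(al, call) al %in% pair[[call]],
                 trios$maternal_allele, trios$mother_call)
  ok_f <- mapply(function(al, call) al %in% pair[[call]],
                 trios$paternal_allele, trios$father_call)
  expect_true(all(ok_m) && all(ok_f))
  # monomorphic limit: tiny maf gives essentially all homozygotes
  mono <- simulate_trios(sim_config(n_trios = 200, n_snps = 5,
                                    maf = 1e-6, seed = 62))
  expect_true(all(mono$child_call %in% c("AA", "BB")))
  expect_true(all(mono$mother_call == mono$child_call))
})

test_that("generator output is reproducible from the seed alone", {
  cfg <- sim_config(n_snps = 15, seed = 63)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$beads, s2$beads)
  expect_identical(s1$genotypes, s2$genotypes)
  s3 <- simulate_study(sim_config(n_snps = 15, seed = 64))
  expect_false(identical(s1$beads, s3$beads))
  m1 <- simulate_mixture_series(config = cfg)
  m2 <- simulate_mixture_series(config = cfg)
  expect_identical(m1$beads, m2$beads)
})

test_that("expression fractions implement each mode rule", {
  trios <- tibble::tibble(
    snp_id = "s1", family_id = sprintf("F%d", 1:4), maf = 0.5,
    mother_call = "AA", father_call = "BB",
    maternal_allele = c("A", "A", "B", "B"),
    paternal_allele = c("B", "B", "A", "A"),
    child_call = "AB"
  )
  for (case in list(
    list(mode = "biallelic", want = c(0.5, 0.5, 0.5, 0.5)),
    list(mode = "imprinting_maternal", want = c(0.97, 0.97, 0.03, 0.03)),
    list(mode = "imprinting_paternal", want = c(0.03, 0.03, 0.97, 0.97)),
    list(mode = "partial_imprinting", want = c(0.72, 0.72, 0.28, 0.28))
  )) {
    cfg <- sim_config(n_snps = 1, mode = case$mode, seed = 65)
    expr <- simulate_expression(trios, cfg)
    expect_equal(expr$frac_a, case$want, info = case$mode)
  }
  # homozygous children express their only allele
  hom <- dplyr::mutate(trios, child_call = "AA",
                       maternal_allele = "A", paternal_allele = "A")
  expr_hom <- simulate_expression(hom, sim_config(n_snps = 1,
                                                  mode = "imprinting_maternal",
                                                  seed = 65))
  expect_equal(expr_hom$frac_a, rep(1, 4))
  expect_error(
    simulate_expression(trios, sim_config(n_snps = 1, mode = "nonsense")),
    "mode"
  )
})

test_that("bead intensities follow the two-channel noise model", {
  frac <- tibble::tibble(snp_id = "s1", sample_id = "p1", array_id = "r1",
                         frac_a = 0.5, base_intensity = 12)
  quiet <- sim_config(bead_noise_sd = 0, dye_bias = 0, beads_per_snp = 20,
                      seed = 66)
  b <- simulate_beads(frac, quiet)
  expect_equal(log2(b$intensity_a / b$intensity_b), rep(0, 20))
  b2 <- simulate_beads(dplyr::mutate(frac, frac_a = 0.8), quiet)
  expect_equal(log2(b2$intensity_a / b2$intensity_b),
               rep(log2(1.61 / 0.41), 20))
  # per-bead log-ratio noise is sqrt(2) times the channel noise
  noisy <- sim_config(bead_noise_sd = 0.3, dye_bias = 0,
                      beads_per_snp = 8000, seed = 67)
  b3 <- simulate_beads(frac, noisy)
  expect_equal(sd(log2(b3$intensity_a / b3$intensity_b)), sqrt(2) * 0.3,
               tolerance = 0.02)
  # dye bias shifts the log-ratio additively
  biased <- sim_config(bead_noise_sd = 0, dye_bias = 0.4, beads_per_snp = 5,
                       seed = 68)
  b4 <- simulate_beads(frac, biased)
  expect_equal(log2(b4$intensity_a / b4$intensity_b), rep(0.4, 5))
})

test_that("mixture fractions follow the dosage-blend formula", {
  cfg <- sim_config(n_snps = 120, bead_noise_sd = 0, dye_bias = 0,
                    beads_per_snp = 1, seed = 69)
  sim <- simulate_mixture_series(config = cfg)
  # a 50:50 blend of AA and BB is perfectly balanced
  aa_bb <- sim$genotypes_1$snp_id[sim$genotypes_1$call == "AA" &
                                    sim$genotypes_2$call == "BB"]
  if (length(aa_bb) > 0) {
    ref <- dplyr::filter(sim$design_map, p1 == 50)$sample_id[1]
    b <- dplyr::filter(sim$beads, snp_id %in% aa_bb, sample_id == ref)
    expect_equal(log2(b$intensity_a / b$intensity_b),
                 rep(0, nrow(b)), tolerance = 1e-9)
  }
  # pure 100:0 arrays reproduce individual 1
  pure <- dplyr::filter(sim$design_map, p1 == 100)$sample_id[1]
  bp <- dplyr::filter(sim$beads, sample_id == pure, array_id == "r1")
  dosage <- c(AA = 2, AB = 1, BB = 0)
  f1 <- dosage[sim$genotypes_1$call] / 2
  names(f1) <- sim$genotypes_1$snp_id
  want <- log2((2 * f1[bp$snp_id] + 0.01) / (2 * (1 - f1[bp$snp_id]) + 0.01))
  expect_equal(log2(bp$intensity_a / bp$intensity_b), unname(want),
               tolerance = 1e-9)
  # true negatives keep a constant fraction across every mixture
  tn <- dplyr::filter(sim$truth, label == "true_negative")$snp_id[1]
  if (!is.na(tn)) {
    btn <- dplyr::filter(sim$beads, snp_id == tn)
    expect_equal(length(unique(round(log2(btn$intensity_a /
                                            btn$intensity_b), 9))), 1)
  }
})

test_that("summary-level generator matches the bead-model noise scale", {
  cfg <- sim_config(n_snps = 60, mode = "biallelic", seed = 70,
                    intensity_range = c(13, 14))
  sim <- simulate_summaries(cfg)
  # heterozygous placentas only: homozygotes sit at the saturated log-ratio
  hets <- dplyr::filter(sim$sample_truth, child_call == "AB") %>%
    dplyr::mutate(sample_id = paste0(family_id, "_PC"))
  cdna <- dplyr::semi_join(sim$summaries, hets,
                           by = c("snp_id", "sample_id"))
  expect_equal(sd(cdna$m), sqrt(2) * 0.3 / sqrt(30), tolerance = 0.06)
  expect_true(all(c("summaries", "pedigree", "genotypes", "snp_truth") %in%
                    names(sim)))
})
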