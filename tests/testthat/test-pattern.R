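test_that("parent-of-origin inference follows the homozygous-parent rule", {
  # mother homozygous for the expressed allele -> maternal
  r1 <- infer_origin("AB", "AA", "BB", 3)
  expect_equal(r1$expressed_allele, "A")
  expect_equal(r1$origin, "maternal")
  # both parents heterozygous -> uninformative
  r2 <- infer_origin("AB", "AB", "AB", 3)
  expect_equal(r2$origin, "uninformative")
  # reversed parental genotypes -> paternal
  r3 <- infer_origin("AB", "BB", "AA", 3)
  expect_equal(r3$origin, "paternal")
  # absent father, homozygous mother: untransmitted maternal allele implies
  # the paternal one
  r4 <- infer_origin("AB", "BB", "NN", 3)
  expect_equal(r4$origin, "paternal")
  # father homozygous, mother het: transmitted paternal allele known
  r5 <- infer_origin("AB", "AB", "AA", -3)
  expect_equal(r5$expressed_allele, "B")
  expect_equal(r5$origin, "maternal")
  # impossible configuration flags a Mendelian error
  r6 <- infer_origin("AB", "AA", "AA", 3)
  expect_true(r6$mendelian_error)
  expect_error(infer_origin("AA", "AA", "AA", 3), "AB")
})

test_that("allele intensity reconstruction inverts the (M, A) transform", {
  ai <- allele_intensities(m = 2, a = 10)
  expect_equal(log2(ai$allele_a / ai$allele_b), 2)
  expect_equal(0.5 * log2(ai$allele_a * ai$allele_b), 10)
})

test_that("fold difference matches the analytic ratio", {
  expect_equal(fold_difference(c(4, 4), c(4, 4)), 1.0)
  # every sample at M = +2 and equal A: ratio is exactly 2^M = 4
  ai <- allele_intensities(rep(2, 5), rep(12, 5))
  expect_equal(fold_difference(ai$allele_a, ai$allele_b), 4.0)
  # monotone in the expressed intensities
  expect_gt(fold_difference(c(10, 10), c(2, 2)),
            fold_difference(c(8, 8), c(2, 2)))
  expect_error(fold_difference(numeric(0), 1), "empty")
})

test_that("classifier recovers each synthetic expression mode", {
  modes <- rep(c("biallelic", "imprinting_maternal", "imprinting_paternal",
                 "partial_imprinting", "preferential",
                 "random_monoallelic", "random_ase"), each = 40)
  sim <- simulate_summaries(sim_config(n_snps = length(modes), mode = modes,
                                       intensity_range = c(14, 16),
                                       seed = 31))
  ase <- suppressWarnings(ase_test(sim$summaries, sim$genotypes,
                                   sim$pedigree))
  pat <- classify_patterns(ase, sim$genotypes, sim$pedigree, sim$summaries)
  res <- dplyr::inner_join(pat, sim$snp_truth, by = "snp_id") %>%
    dplyr::mutate(truth = ifelse(grepl("^imprinting", mode.y),
                                 "imprinting", mode.y))
  acc <- sapply(split(res, res$truth),
                function(d) mean(d$mode.x == d$truth))
  expect_gte(acc[["imprinting"]], 0.90)
  expect_gte(acc[["biallelic"]], 0.90)
  expect_gte(acc[["partial_imprinting"]], 0.75)
  expect_gte(acc[["preferential"]], 0.75)
  expect_gte(acc[["random_monoallelic"]], 0.75)
  expect_gte(acc[["random_ase"]], 0.75)
  # imprinting orientation is recovered
  imp <- dplyr::filter(res, mode.x == "imprinting")
  expect_true(all(
    imp$oriented_parent[imp$mode.y == "imprinting_maternal"] == "maternal"))
  expect_true(all(
    imp$oriented_parent[imp$mode.y == "imprinting_paternal"] == "paternal"))
})

test_that("swapping parents flips every imprinting orientation and nothing else", {
  modes <- c(rep("imprinting_maternal", 10), rep("biallelic", 20))
  sim <- simulate_summaries(sim_config(n_snps = 30, mode = modes,
                                       intensity_range = c(14, 16),
                                       seed = 32))
  ase <- suppressWarnings(ase_test(sim$summaries, sim$genotypes,
                                   sim$pedigree))
  pat1 <- classify_patterns(ase, sim$genotypes, sim$pedigree, sim$summaries)
  swapped <- dplyr::rename(sim$pedigree, mother_gdna = father_gdna,
                           father_gdna = mother_gdna)
  pat2 <- classify_patterns(ase, sim$genotypes, swapped, sim$summaries)
  expect_equal(pat2$mode, pat1$mode)
  flip <- c(maternal = "paternal", paternal = "maternal", none = "none")
  expect_equal(pat2$oriented_parent, unname(flip[pat1$oriented_parent]))
  expect_equal(pat2$fold_difference, pat1$fold_difference)
})

test_that("partial imprinting is separated from complete imprinting by the reference", {
  modes <- c(rep("partial_imprinting", 15), rep("imprinting_maternal", 15),
             rep("biallelic", 30))
  sim <- simulate_summaries(sim_config(n_snps = 60, mode = modes,
                                       intensity_range = c(14, 16),
                                       seed = 33))
  ase <- suppressWarnings(ase_test(sim$summaries, sim$genotypes,
                                   sim$pedigree))
  pat <- classify_patterns(ase, sim$genotypes, sim$pedigree, sim$summaries)
  res <- dplyr::inner_join(pat, sim$snp_truth, by = "snp_id")
  partial <- dplyr::filter(res, mode.y == "partial_imprinting")
  full <- dplyr::filter(res, mode.y == "imprinting_maternal")
  expect_gte(mean(partial$mode.x == "partial_imprinting"), 0.75)
  expect_gte(mean(full$mode.x == "imprinting"), 0.90)
  # partially imprinted genes show a smaller allelic fold difference
  expect_lt(median(partial$fold_difference),
            median(full$fold_difference))
})
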