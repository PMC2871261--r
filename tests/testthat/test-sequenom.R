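test_that("success rate is the fraction of conservative calls", {
  expect_equal(success_rate(rep("conservative", 23)), 1.0)
  expect_equal(success_rate(c(rep("conservative", 15), rep("other", 5))),
               0.75)
  expect_equal(success_rate(rep("failed", 10)), 0.0)
  expect_error(success_rate(character(0)), "no genotyping attempts")
})

test_that("success-rate ratio filter is inclusive at the boundary", {
  expect_true(sr_filter(0.9, 1.0))
  expect_false(sr_filter(0.5, 1.0))
  expect_true(sr_filter(0.75, 1.0)) # boundary passes
  expect_error(sr_filter(0.5, 0), "positive")
})

test_that("paired skew test has the expected nulls, tails and power", {
  # identical cDNA and gDNA: t = 0, p = 0.5
  x <- c(0.4, 0.5, 0.6, 0.55)
  r0 <- paired_allele_ttest(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  # fully monoallelic cDNA against balanced gDNA with n = 9
  cdna <- rep(1.0, 9)
  gdna <- rep(0.5, 9) + c(-0.02, 0.01, 0, 0.02, -0.01, 0.015, -0.005,
                          0.01, -0.02)
  r1 <- paired_allele_ttest(cdna, gdna)
  d <- abs(cdna - 0.5) - abs(gdna - 0.5)
  t_manual <- mean(d) / (sd(d) / sqrt(9))
  expect_equal(r1$t, t_manual)
  expect_equal(r1$p, pt(t_manual, df = 8, lower.tail = FALSE))
  expect_lt(r1$p, 1e-6)
  # cDNA less skewed than gDNA lands in the far tail
  r2 <- paired_allele_ttest(rep(0.5, 6),
                            c(0.8, 0.9, 0.85, 0.75, 0.95, 0.7))
  expect_gt(r2$p, 0.5)
  # a single pair is not testable
  expect_false(paired_allele_ttest(0.9, 0.5)$testable)
})

test_that("paired skew test is invariant to allele relabelling", {
  withr::with_seed(41, {
    for (i in 1:50) {
      n <- sample(3:12, 1)
      c1 <- runif(n)
      g1 <- runif(n, 0.3, 0.7)
      a <- paired_allele_ttest(c1, g1)
      b <- paired_allele_ttest(1 - c1, 1 - g1)
      expect_equal(a$t, b$t)
      expect_equal(a$p, b$p)
    }
  })
})

test_that("paired skew test holds its size under the null", {
  withr::with_seed(42, {
    p <- replicate(10000, {
      c1 <- 0.5 + rnorm(6, 0, 0.05)
      g1 <- 0.5 + rnorm(6, 0, 0.05)
      paired_allele_ttest(pmin(pmax(c1, 0), 1),
                          pmin(pmax(g1, 0), 1))$p
    })
  })
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("skew difference converts fractions to percentage points", {
  expect_equal(skew_difference(rep(0.5, 4)), 0.0)
  expect_equal(skew_difference(rep(1.0, 3)), 100.0)
  expect_equal(skew_difference(c(0.99, 0.97)), 96.0)
  expect_error(skew_difference(numeric(0)), "no heterozygote")
})

make_quants <- function(frac_cdna, pedigree, snp = "rs1",
                        frac_gdna = 0.5, rating = "conservative") {
  n <- nrow(pedigree)
  dplyr::bind_rows(
    tibble::tibble(snp_id = snp, sample_id = pedigree$placenta_gdna,
                   sample_type = "gDNA", frac_a = frac_gdna,
                   rating = rating),
    tibble::tibble(snp_id = snp, sample_id = pedigree$placenta_cdna,
                   sample_type = "cDNA", frac_a = frac_cdna,
                   rating = rating)
  )
}

test_that("the table-level analysis filters on SR ratio and adjusts across SNPs", {
  ped <- tibble::tibble(
    family_id = sprintf("F%d", 1:9),
    placenta_gdna = sprintf("F%d_PG", 1:9),
    placenta_cdna = sprintf("F%d_PC", 1:9),
    mother_gdna = sprintf("F%d_M", 1:9),
    father_gdna = sprintf("F%d_F", 1:9)
  )
  withr::with_seed(43, {
    # gDNA fractions carry comparable measurement noise; a noiseless gDNA
    # reference would make any cDNA noise look like extra skew
    imprint <- make_quants(sample(c(0.02, 0.98), 9, TRUE), ped, "rs_imp",
                           frac_gdna = 0.5 + rnorm(9, 0, 0.02))
    nullsnp <- make_quants(0.5 + rnorm(9, 0, 0.02), ped, "rs_null",
                           frac_gdna = 0.5 + rnorm(9, 0, 0.02))
    lowexpr <- make_quants(rep(0.95, 9), ped, "rs_low",
                           frac_gdna = 0.5 + rnorm(9, 0, 0.02))
  })
  # the lowly expressed SNP fails genotyping in half its cDNA attempts
  lowexpr$rating[lowexpr$sample_type == "cDNA"][1:5] <- "failed"
  quants <- dplyr::bind_rows(imprint, nullsnp, lowexpr)
  res <- sequenom_test(quants, ped)
  expect_equal(nrow(res), 3)
  low <- dplyr::filter(res, snp_id == "rs_low")
  expect_false(low$sr_pass)
  expect_false(low$testable)
  imp <- dplyr::filter(res, snp_id == "rs_imp")
  expect_true(imp$sr_pass)
  expect_lt(imp$p_adj, 0.05)
  expect_gt(imp$difference, 90)
  nul <- dplyr::filter(res, snp_id == "rs_null")
  expect_gt(nul$p_adj, 0.05)
  expect_lt(nul$difference, 10)
})

test_that("imprinted simulation reaches adjusted significance with 9 hets", {
  ped <- tibble::tibble(
    family_id = sprintf("F%d", 1:9),
    placenta_gdna = sprintf("F%d_PG", 1:9),
    placenta_cdna = sprintf("F%d_PC", 1:9),
    mother_gdna = sprintf("F%d_M", 1:9),
    father_gdna = sprintf("F%d_F", 1:9)
  )
  hits <- sapply(1:50, function(s) {
    withr::with_seed(s, {
      cdna_frac <- sample(c(0.02, 0.98), 9, TRUE) + rnorm(9, 0, 0.01)
      gdna_frac <- 0.5 + rnorm(9, 0, 0.02)
    })
    quants <- dplyr::bind_rows(
      make_quants(pmin(pmax(cdna_frac, 0), 1), ped, "rs_imp",
                  frac_gdna = pmin(pmax(gdna_frac, 0), 1)),
      make_quants(0.5, ped, "rs_null")
    )
    res <- sequenom_test(quants, ped)
    dplyr::filter(res, snp_id == "rs_imp")$p_adj < 0.05
  })
  expect_gte(mean(hits), 0.99)
})
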