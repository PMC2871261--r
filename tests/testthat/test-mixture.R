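test_that("truth sets follow the genotype-pair classes", {
  g1 <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                       call = c("AA", "AB", "AA", "AB", "AA"))
  g2 <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                       call = c("BB", "AB", "AA", "BB", "NN"))
  truth <- build_truth_sets(g1, g2)
  lk <- stats::setNames(truth$label, truth$snp_id)
  expect_equal(lk[["s1"]], "true_positive")   # AA:BB
  expect_equal(lk[["s2"]], "true_negative")   # AB:AB
  expect_equal(lk[["s3"]], "true_negative")   # AA:AA
  expect_equal(lk[["s4"]], "true_positive")   # AB:BB
  expect_equal(lk[["s5"]], "excluded")        # NN
})

test_that("the default titration design carries 17 entries around a 50:50 anchor", {
  des <- mixture_design()
  expect_equal(nrow(des), 17)
  expect_true(any(des$p1 == 50 & des$p2 == 50))
  expect_true(all(des$p1 + des$p2 == 100))
  # the duplicated 5:95 entry is kept as distinct mixtures
  expect_equal(sum(des$p1 == 5 & des$p2 == 95), 2)
  expect_error(mixture_design(proportions = cbind(40, 60)), "50:50")
})

test_that("contrast estimates equal the analytic dosage-blend log-ratios", {
  # summaries constructed directly from the blend formula (vanishing
  # replicate noise keeps the variance prior estimable): this isolates the
  # contrast arithmetic from bead-level preprocessing
  blend_m <- function(d1, d2, p1, p2, eps = 0.01) {
    f <- (p1 * d1 + p2 * d2) / (2 * (p1 + p2))
    log2((2 * f + eps) / (2 * (1 - f) + eps))
  }
  withr::with_seed(51, {
    n <- 40
    d1 <- sample(0:2, n, replace = TRUE)
    d2 <- sample(0:2, n, replace = TRUE)
    design_map <- tidyr::expand_grid(mixture_design(),
                                     array_id = c("r1", "r2")) %>%
      dplyr::mutate(sample_id = mixture_id) %>%
      dplyr::select(sample_id, array_id, mixture_id, p1, p2)
    summ <- tidyr::expand_grid(
      snp_id = sprintf("s%02d", 1:n),
      dplyr::distinct(design_map, sample_id, array_id, p1, p2)
    ) %>%
      dplyr::mutate(
        m = blend_m(d1[as.integer(substr(snp_id, 2, 3))],
                    d2[as.integer(substr(snp_id, 2, 3))], p1, p2) +
          rnorm(dplyr::n(), 0, 1e-5),
        a = 13
      ) %>%
      dplyr::select(snp_id, sample_id, array_id, m, a)
  })
  fit <- mixture_contrasts(summ, design_map)
  ctr <- fit$contrasts
  i <- as.integer(substr(ctr$snp_id, 2, 3))
  expected <- blend_m(d1[i], d2[i], ctr$p1, ctr$p2) -
    blend_m(d1[i], d2[i], 50, 50)
  expect_equal(ctr$coef, expected, tolerance = 1e-3)
  # identical genotypes give zero contrast at every mixture
  tn_idx <- which(d1 == d2)
  tn <- dplyr::filter(ctr, as.integer(substr(snp_id, 2, 3)) %in% tn_idx)
  expect_lt(max(abs(tn$coef)), 1e-3)
})

test_that("contrast machinery demands replicated 50:50 arrays", {
  cfg <- sim_config(n_snps = 15, beads_per_snp = 5, seed = 52)
  sim <- simulate_mixture_series(config = cfg)
  summ <- preprocess_beads(sim$beads)
  no_ref <- dplyr::filter(sim$design_map, p1 != 50)
  expect_error(mixture_contrasts(dplyr::semi_join(summ, no_ref,
                                                  by = "sample_id"),
                                 no_ref),
               "50:50")
})

test_that("AUC matches brute-force pair counting with ties", {
  expect_equal(roc_auc(c(3, 2, 1), c("true_positive", "true_positive",
                                     "true_negative"))$auc, 1.0)
  expect_equal(roc_auc(rep(1, 6), rep(c("true_positive", "true_negative"),
                                      3))$auc, 0.5)
  s <- c(5, 4, 4, 2, 1)
  l <- c("true_positive", "true_positive", "true_negative",
         "true_positive", "true_negative")
  expect_equal(roc_auc(s, l)$auc, auc_brute(s, l))
  expect_error(roc_auc(1:3, rep("true_positive", 3)), "true negative")
  withr::with_seed(53, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      scores <- sample(1:5, n, replace = TRUE)
      labels <- sample(c("true_positive", "true_negative"), n,
                       replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels))
    }
  })
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  withr::with_seed(54, {
    scores <- rnorm(60)
    labels <- sample(c("true_positive", "true_negative"), 60, TRUE,
                     prob = c(0.6, 0.4))
  })
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(scores * 100 - 7, labels)$auc, a0)
  expect_equal(roc_auc(rank(scores), labels)$auc, a0)
})

test_that("label permutation centres the AUC at one half", {
  withr::with_seed(55, {
    scores <- rnorm(80)
    labels <- rep(c("true_positive", "true_negative"), each = 40)
    aucs <- replicate(1000, roc_auc(scores, sample(labels))$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("detection degrades towards the 50:50 mixture", {
  cfg <- sim_config(n_snps = 250, seed = 56)
  sim <- simulate_mixture_series(config = cfg)
  run <- suppressWarnings(run_mixture(sim$beads, sim$design_map,
                                      sim$genotypes_1, sim$genotypes_2))
  a <- dplyr::mutate(run$auc, dist = abs(p1 - 50))
  far <- mean(a$auc[a$dist >= 30])
  near <- mean(a$auc[a$dist <= 10])
  expect_gte(far, near)
  # shuffled labels give chance-level AUC
  withr::with_seed(57, {
    shuffled <- dplyr::mutate(
      run$fit$contrasts,
      label = sample(rep(c("true_positive", "true_negative"),
                         length.out = dplyr::n()))
    )
  })
  one_mix <- dplyr::filter(shuffled, mixture_id == "mix05")
  expect_lt(abs(roc_auc(one_mix$log_odds, one_mix$label)$auc - 0.5), 0.1)
})
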