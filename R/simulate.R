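#' Simulation configuration for synthetic trio studies
#'
#' Defines the study conditions the generator emulates: 23 family trios,
#' about 30 beads per SNP, duplicate hybridisations of the placental
#' samples, lognormal per-bead channel noise, an additive dye bias on the
#' log-ratio removed later by median centring, and a per-SNP allelic
#' expression mode. Complete silencing defaults to an expressed-allele
#' fraction of 0.97, reflecting the observation that repression of the
#' silenced allele is rarely total.
#'
#' @param n_trios Number of family trios (default 23).
#' @param n_snps Number of SNPs.
#' @param maf Minor-allele (allele B) frequency per SNP, recycled.
#' @param mode Allelic expression mode per SNP, recycled: one of
#'   `"biallelic"`, `"imprinting_maternal"`, `"imprinting_paternal"`,
#'   `"partial_imprinting"`, `"preferential"`, `"random_monoallelic"`,
#'   `"random_ase"`.
#' @param base_intensity Per-SNP baseline log2 intensity; `NULL` draws
#'   uniformly from `intensity_range`.
#' @param intensity_range Range for random baseline intensities.
#' @param bead_noise_sd Per-bead, per-channel log2-scale noise SD.
#' @param beads_per_snp Beads per SNP per array.
#' @param replicates Replicate arrays for placental gDNA and cDNA
#'   (parental gDNA is hybridised once).
#' @param dye_bias Additive log-ratio offset applied to every array.
#' @param silencing Expressed-allele fraction under complete silencing
#'   (imprinting and random monoallelic modes).
#' @param partial_bias Expressed-allele fraction under partial imprinting.
#' @param preferential_bias Preferred-allele fraction under preferential
#'   ASE.
#' @param random_ase_bias Expressed-allele fraction under random ASE.
#' @param eps Allelic-fraction floor in the intensity model (keeps the
#'   silenced channel above zero).
#' @param seed Integer seed; every generator output is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trios = 23, n_snps = 200, maf = 0.3,
                       mode = "biallelic", base_intensity = NULL,
                       intensity_range = c(9, 15), bead_noise_sd = 0.3,
                       beads_per_snp = 30, replicates = 2, dye_bias = 0.1,
                       silencing = 0.97, partial_bias = 0.72,
                       preferential_bias = 0.8, random_ase_bias = 0.72,
                       eps = 0.01, seed = 1L) {
  valid_modes <- c("biallelic", "imprinting_maternal", "imprinting_paternal",
                   "partial_imprinting", "preferential",
                   "random_monoallelic", "random_ase")
  stopifnot(
    n_trios >= 1, n_snps >= 1, all(maf > 0), all(maf <= 0.5),
    all(mode %in% valid_modes), bead_noise_sd >= 0, beads_per_snp >= 1,
    replicates >= 1, silencing > 0.5, silencing <= 1,
    partial_bias > 0.5, partial_bias <= 1,
    preferential_bias > 0.5, preferential_bias <= 1,
    random_ase_bias > 0.5, random_ase_bias <= 1, eps > 0
  )
  structure(
    list(
      n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
      maf = maf, mode = mode, base_intensity = base_intensity,
      intensity_range = intensity_range, bead_noise_sd = bead_noise_sd,
      beads_per_snp = as.integer(beads_per_snp),
      replicates = as.integer(replicates), dye_bias = dye_bias,
      silencing = silencing, partial_bias = partial_bias,
      preferential_bias = preferential_bias,
      random_ase_bias = random_ase_bias, eps = eps,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

.count_to_call <- function(n_a) c("BB", "AB", "AA")[n_a + 1]

#' Simulate trio genotypes under Hardy-Weinberg and Mendelian transmission
#'
#' Parental alleles are drawn independently from Hardy-Weinberg proportions
#' at each SNP's minor-allele frequency; the child receives one uniformly
#' chosen allele from each parent. The transmitted alleles are retained as
#' ground truth for parent-of-origin checks.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per SNP x family: genotype calls for mother,
#'   father and child plus the transmitted `maternal_allele` and
#'   `paternal_allele`.
#' @export
simulate_trios <- function(config = sim_config()) {
  withr::local_seed(config$seed)
  n_cell <- config$n_snps * config$n_trios
  maf <- rep_len(config$maf, config$n_snps)
  # The channel an allele is measured in is arbitrary on the platform, so
  # the minor allele is assigned to channel A or B with equal probability;
  # this keeps the two channel distributions of an array exchangeable, the
  # premise of between-channel quantile normalisation.
  minor_is_b <- runif(config$n_snps) < 0.5
  p_a_snp <- ifelse(minor_is_b, 1 - maf, maf)
  grid <- tidyr::expand_grid(
    snp_id = sprintf("snp%04d", seq_len(config$n_snps)),
    family_id = sprintf("F%02d", seq_len(config$n_trios))
  ) %>%
    mutate(maf = rep(maf, each = config$n_trios))
  p_a <- rep(p_a_snp, each = config$n_trios)
  m1 <- rbinom(n_cell, 1, p_a); m2 <- rbinom(n_cell, 1, p_a)
  f1 <- rbinom(n_cell, 1, p_a); f2 <- rbinom(n_cell, 1, p_a)
  pick_m <- rbinom(n_cell, 1, 0.5)
  pick_f <- rbinom(n_cell, 1, 0.5)
  mat <- ifelse(pick_m == 1, m1, m2)
  pat <- ifelse(pick_f == 1, f1, f2)
  grid %>%
    mutate(
      mother_call = .count_to_call(m1 + m2),
      father_call = .count_to_call(f1 + f2),
      maternal_allele = ifelse(mat == 1, "A", "B"),
      paternal_allele = ifelse(pat == 1, "A", "B"),
      child_call = .count_to_call(mat + pat)
    )
}

#' True cDNA allelic fractions under an expression mode
#'
#' For each heterozygous child the expressed-allele fraction follows the
#' SNP's mode: biallelic gives 0.5; maternal/paternal imprinting silences
#' the other parent's allele down to `1 - silencing`; partial imprinting
#' biases towards the maternal allele; preferential ASE biases towards a
#' fixed allele identity regardless of parent; random monoallelic and
#' random ASE bias towards a fair-coin allele per individual. Homozygous
#' children express their only allele by construction.
#'
#' @param trios Output of [simulate_trios()].
#' @param config A [sim_config()]; `mode` is recycled across SNPs. For
#'   `"preferential"` SNPs the preferred allele is drawn once per SNP and
#'   recorded.
#' @return `trios` with added columns `mode`, `frac_a` (true cDNA allele-A
#'   fraction) and `pref_allele` (preferential SNPs only, else `NA`).
#' @export
simulate_expression <- function(trios, config = sim_config()) {
  withr::local_seed(config$seed + 1L)
  snps <- distinct(trios, .data$snp_id) %>%
    mutate(
      mode = rep_len(config$mode, dplyr::n()),
      pref_allele = ifelse(.data$mode == "preferential",
                           ifelse(runif(dplyr::n()) < 0.5, "A", "B"),
                           NA_character_)
    )
  dat <- trios %>%
    inner_join(snps, by = "snp_id") %>%
    mutate(coin_allele = ifelse(runif(dplyr::n()) < 0.5, "A", "B"))
  toward <- function(target_allele, frac) {
    ifelse(target_allele == "A", frac, 1 - frac)
  }
  het <- dat$child_call == "AB"
  frac <- dplyr::case_when(
    dat$child_call == "AA" ~ 1,
    dat$child_call == "BB" ~ 0,
    dat$mode == "biallelic" ~ 0.5,
    dat$mode == "imprinting_maternal" ~
      toward(dat$maternal_allele, config$silencing),
    dat$mode == "imprinting_paternal" ~
      toward(dat$paternal_allele, config$silencing),
    dat$mode == "partial_imprinting" ~
      toward(dat$maternal_allele, config$partial_bias),
    dat$mode == "preferential" ~
      toward(dat$pref_allele, config$preferential_bias),
    dat$mode == "random_monoallelic" ~
      toward(dat$coin_allele, config$silencing),
    dat$mode == "random_ase" ~
      toward(dat$coin_allele, config$random_ase_bias)
  )
  dat %>%
    mutate(frac_a = frac) %>%
    select(-"coin_allele")
}

#' Simulate bead-level two-channel intensities
#'
#' For every row of `frac_tbl` (one SNP in one sample on one array),
#' generates `beads_per_snp` beads with channel intensities
#' `2^(base + log2(2*frac + eps) + N(0, sd) + dye/2)` for channel A and the
#' complementary fraction with `-dye/2` for channel B. The lognormal noise
#' is independent per channel so the per-bead log-ratio has SD
#' `sqrt(2) * bead_noise_sd`; the dye bias is a constant log-ratio offset
#' that per-array median centring must remove.
#'
#' @param frac_tbl Tibble with columns `snp_id`, `sample_id`, `array_id`,
#'   `frac_a` (in `[0, 1]`), `base_intensity`.
#' @param config A [sim_config()].
#' @param seed Integer seed for the bead noise (defaults to `config$seed`).
#' @return Bead tibble: `snp_id`, `sample_id`, `array_id`, `intensity_a`,
#'   `intensity_b`.
#' @export
simulate_beads <- function(frac_tbl, config = sim_config(),
                           seed = config$seed) {
  stopifnot(all(c("snp_id", "sample_id", "array_id", "frac_a",
                  "base_intensity") %in% names(frac_tbl)),
            all(frac_tbl$frac_a >= 0), all(frac_tbl$frac_a <= 1))
  withr::local_seed(seed)
  nb <- config$beads_per_snp
  idx <- rep(seq_len(nrow(frac_tbl)), each = nb)
  n <- length(idx)
  frac <- frac_tbl$frac_a[idx]
  base <- frac_tbl$base_intensity[idx]
  la <- base + log2(2 * frac + config$eps) +
    rnorm(n, 0, config$bead_noise_sd) + config$dye_bias / 2
  lb <- base + log2(2 * (1 - frac) + config$eps) +
    rnorm(n, 0, config$bead_noise_sd) - config$dye_bias / 2
  tibble(
    snp_id = frac_tbl$snp_id[idx],
    sample_id = frac_tbl$sample_id[idx],
    array_id = frac_tbl$array_id[idx],
    intensity_a = 2^la,
    intensity_b = 2^lb
  )
}

# Dosage of allele A implied by a genotype call (AA = 2, AB = 1, BB = 0).
.dosage <- function(call) {
  c(AA = 2, AB = 1, BB = 0)[call]
}

# Standard sample naming: <family>_PG / _PC / _M / _F.
.trio_pedigree <- function(n_trios) {
  tibble(
    family_id = sprintf("F%02d", seq_len(n_trios)),
    placenta_gdna = sprintf("F%02d_PG", seq_len(n_trios)),
    placenta_cdna = sprintf("F%02d_PC", seq_len(n_trios)),
    mother_gdna = sprintf("F%02d_M", seq_len(n_trios)),
    father_gdna = sprintf("F%02d_F", seq_len(n_trios))
  )
}

# Placental samples are hybridised `replicates` times, parents once.
.role_arrays <- function(replicates) {
  reps <- sprintf("r%d", seq_len(replicates))
  bind_rows(
    tidyr::expand_grid(role = "PG", array_id = reps),
    tidyr::expand_grid(role = "PC", array_id = reps),
    tibble(role = "M", array_id = "r1"),
    tibble(role = "F", array_id = "r1")
  )
}

# One row per SNP x sample x array with the true allelic fraction: gDNA
# samples carry the genotype dosage, placental cDNA the expression fraction.
.fraction_table <- function(expr, snp_base, replicates) {
  expr %>%
    mutate(
      frac_PG = .dosage(.data$child_call) / 2,
      frac_PC = .data$frac_a,
      frac_M = .dosage(.data$mother_call) / 2,
      frac_F = .dosage(.data$father_call) / 2
    ) %>%
    select("snp_id", "family_id", dplyr::starts_with("frac_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("frac_"), names_to = "role",
                        values_to = "frac_a", names_prefix = "frac_") %>%
    inner_join(.role_arrays(replicates), by = "role",
               relationship = "many-to-many") %>%
    mutate(sample_id = paste0(.data$family_id, "_", .data$role)) %>%
    inner_join(snp_base, by = "snp_id") %>%
    select("snp_id", "sample_id", "array_id", "frac_a", "base_intensity")
}

# Long genotype table over placenta gDNA and both parents.
.genotype_table <- function(expr) {
  expr %>%
    select("snp_id", "family_id", "child_call", "mother_call",
           "father_call") %>%
    tidyr::pivot_longer(dplyr::ends_with("_call"), names_to = "role",
                        values_to = "call") %>%
    mutate(
      role = dplyr::recode(.data$role, child_call = "PG",
                           mother_call = "M", father_call = "F"),
      sample_id = paste0(.data$family_id, "_", .data$role)
    ) %>%
    select("snp_id", "sample_id", "call")
}

# Per-SNP baseline intensities, drawn when not fixed in the config.
.snp_baselines <- function(expr, config) {
  withr::local_seed(config$seed + 2L)
  n_snps <- dplyr::n_distinct(expr$snp_id)
  base <- config$base_intensity
  if (is.null(base)) {
    base <- runif(n_snps, config$intensity_range[1],
                  config$intensity_range[2])
  }
  distinct(expr, .data$snp_id) %>%
    mutate(base_intensity = rep_len(base, n_snps))
}

# Assemble the full study output list from an expression table.
.assemble_study <- function(expr, config, snp_base = NULL) {
  if (is.null(snp_base)) snp_base <- .snp_baselines(expr, config)
  per_fam <- .fraction_table(expr, snp_base, config$replicates)
  beads <- simulate_beads(per_fam, config, seed = config$seed + 3L)
  snp_truth <- distinct(expr, .data$snp_id, .data$mode,
                        .data$pref_allele) %>%
    inner_join(snp_base, by = "snp_id")
  sample_truth <- expr %>%
    select("snp_id", "family_id", "child_call", "maternal_allele",
           "paternal_allele", "frac_a")
  list(beads = beads, pedigree = .trio_pedigree(config$n_trios),
       genotypes = .genotype_table(expr), snp_truth = snp_truth,
       sample_truth = sample_truth, config = config)
}

#' Simulate a complete trio ASE study
#'
#' Produces every input the analysis pipeline consumes: a bead-level
#' intensity table covering placental gDNA (replicated), placental cDNA
#' (replicated), maternal and paternal gDNA (single arrays), a pedigree,
#' true genotype calls, and ground-truth tables (per-SNP mode and per-family
#' true allelic fractions with transmitted parental alleles).
#'
#' @param config A [sim_config()].
#' @return List with elements `beads`, `pedigree`, `genotypes`, `snp_truth`,
#'   `sample_truth` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  trios <- simulate_trios(config)
  expr <- simulate_expression(trios, config)
  .assemble_study(expr, config)
}

#' Simulate a study with one benchmark SNP of fixed configuration
#'
#' Builds a study containing a single target SNP with an exact number of
#' heterozygous placentas (mother `AA`, father `BB`, so every het is
#' origin-informative) at a fixed baseline intensity and expression mode,
#' on top of a background of biallelic SNPs with random genotypes. This
#' reproduces the situation of a known control gene - e.g. a completely
#' imprinted, highly expressed gene with 12 informative heterozygotes, or a
#' biallelic control with 13 - inside an otherwise unremarkable experiment.
#'
#' @param n_hets Number of heterozygous placentas for the target SNP
#'   (remaining trios are homozygous `AA`).
#' @param mode Expression mode of the target SNP.
#' @param base_intensity Baseline log2 intensity of the target SNP.
#' @param n_background Number of background biallelic SNPs.
#' @param config A [sim_config()]; `n_snps` is overridden.
#' @return As [simulate_study()]; the target SNP is named `"target"`.
#' @export
simulate_benchmark_snp <- function(n_hets, mode = "imprinting_maternal",
                                   base_intensity = 14,
                                   n_background = 39,
                                   config = sim_config()) {
  stopifnot(n_hets >= 0, n_hets <= config$n_trios)
  cfg_bg <- config
  cfg_bg$n_snps <- as.integer(n_background)
  cfg_bg$mode <- "biallelic"
  study <- simulate_study(cfg_bg)

  fams <- study$pedigree$family_id
  het_fam <- fams[seq_len(n_hets)]
  target <- tibble(
    snp_id = "target",
    family_id = fams,
    maf = NA_real_,
    mother_call = "AA",
    father_call = ifelse(fams %in% het_fam, "BB", "AA"),
    maternal_allele = "A",
    paternal_allele = ifelse(fams %in% het_fam, "B", "A"),
    child_call = ifelse(fams %in% het_fam, "AB", "AA")
  )
  cfg_t <- config
  cfg_t$mode <- mode
  cfg_t$n_snps <- 1L
  expr <- simulate_expression(target, cfg_t)

  snp_base <- tibble(snp_id = "target", base_intensity = base_intensity)
  per_fam <- .fraction_table(expr, snp_base, config$replicates)
  target_beads <- simulate_beads(per_fam, config, seed = config$seed + 4L)

  study$beads <- bind_rows(study$beads, target_beads)
  study$genotypes <- bind_rows(study$genotypes, .genotype_table(expr))
  study$snp_truth <- bind_rows(
    study$snp_truth,
    tibble(snp_id = "target", mode = mode, pref_allele = NA_character_,
           base_intensity = base_intensity)
  )
  study$sample_truth <- bind_rows(
    study$sample_truth,
    select(expr, "snp_id", "family_id", "child_call", "maternal_allele",
           "paternal_allele", "frac_a")
  )
  study
}

#' Simulate preprocessed summaries directly from true allelic fractions
#'
#' Generates per-SNP/sample/array summary tables at the granularity the ASE
#' test consumes, bypassing the bead level: the summarised log-ratio is the
#' analytic value `log2((2 f + eps) / (2 (1 - f) + eps))` plus replicate
#' noise with standard deviation `sqrt(2) * bead_noise_sd /
#' sqrt(beads_per_snp)` (the sampling error of a bead-type mean under the
#' bead model), and the average log-intensity is the corresponding analytic
#' value around the SNP baseline. Output is on the post-normalisation scale
#' (no dye bias, no centring step left to do). This isolates downstream
#' modules - the moderated test and the pattern classifier - from
#' preprocessing, which is exercised separately on bead-level data.
#'
#' @param config A [sim_config()].
#' @return As [simulate_study()] but with `summaries` instead of `beads`.
#' @export
simulate_summaries <- function(config = sim_config()) {
  trios <- simulate_trios(config)
  expr <- simulate_expression(trios, config)
  snp_base <- .snp_baselines(expr, config)
  per_fam <- .fraction_table(expr, snp_base, config$replicates)
  withr::local_seed(config$seed + 5L)
  sigma <- sqrt(2) * config$bead_noise_sd / sqrt(config$beads_per_snp)
  eps <- config$eps
  f <- per_fam$frac_a
  summaries <- per_fam %>%
    mutate(
      m = log2((2 * f + eps) / (2 * (1 - f) + eps)) +
        rnorm(dplyr::n(), 0, sigma),
      a = .data$base_intensity +
        0.5 * (log2(2 * f + eps) + log2(2 * (1 - f) + eps)) +
        rnorm(dplyr::n(), 0, sigma),
      n_beads_used = config$beads_per_snp,
      n_beads_removed = 0L
    ) %>%
    select("snp_id", "sample_id", "array_id", "m", "a",
           "n_beads_used", "n_beads_removed")
  out <- .assemble_study(expr, config, snp_base = snp_base)
  out$beads <- NULL
  out$summaries <- summaries
  out
}

#' Simulate an all-heterozygous biallelic null study
#'
#' Every trio is constructed as mother `AA`, father `BB`, child `AB`, and
#' every SNP is biallelically expressed, so the true cDNA log-ratio is zero
#' for every single test. This is the cleanest null for checking the type-I
#' error of the ASE test itself: with every bead at allelic fraction 0.5
#' the two channels of each array are exchangeable, so preprocessing adds
#' no composition artifact on top of the measurement noise.
#'
#' @param config A [sim_config()]; `maf` and `mode` are ignored.
#' @return As [simulate_study()].
#' @export
simulate_null_study <- function(config = sim_config()) {
  n_snps <- config$n_snps
  n_trios <- config$n_trios
  trios <- tidyr::expand_grid(
    snp_id = sprintf("snp%04d", seq_len(n_snps)),
    family_id = sprintf("F%02d", seq_len(n_trios))
  ) %>%
    mutate(
      maf = 0.5, mother_call = "AA", father_call = "BB",
      maternal_allele = "A", paternal_allele = "B", child_call = "AB"
    )
  cfg <- config
  cfg$mode <- "biallelic"
  expr <- simulate_expression(trios, cfg)
  .assemble_study(expr, cfg)
}

#' Simulate the two-individual gDNA mixture titration series
#'
#' Draws Hardy-Weinberg genotypes for two individuals, blends their allele
#' dosages according to each design proportion
#' (`frac_a = (p1 d1 + p2 d2) / (2 (p1 + p2))`), and generates replicated
#' bead-level arrays for every mixture. Truth labels follow from the
#' genotype pair via [build_truth_sets()].
#'
#' @param design A [mixture_design()].
#' @param config A [sim_config()]; `n_snps`, `maf`, noise and bead settings
#'   apply.
#' @return List with `beads`, `design_map` (sample to mixture mapping),
#'   `genotypes_1`, `genotypes_2`, `truth`, `config`.
#' @export
simulate_mixture_series <- function(design = mixture_design(),
                                    config = sim_config()) {
  withr::local_seed(config$seed + 10L)
  n <- config$n_snps
  maf <- rep_len(config$maf, n)
  snp_id <- sprintf("snp%04d", seq_len(n))
  # minor allele lands in either channel with equal probability (see
  # simulate_trios)
  p_a <- ifelse(runif(n) < 0.5, 1 - maf, maf)
  d1 <- rbinom(n, 2, p_a)
  d2 <- rbinom(n, 2, p_a)
  genotypes_1 <- tibble(snp_id = snp_id, call = .count_to_call(d1))
  genotypes_2 <- tibble(snp_id = snp_id, call = .count_to_call(d2))
  base <- config$base_intensity
  if (is.null(base)) {
    base <- runif(n, config$intensity_range[1], config$intensity_range[2])
  }
  snp_tbl <- tibble(snp_id = snp_id, d1 = d1, d2 = d2,
                    base_intensity = rep_len(base, n))

  reps <- sprintf("r%d", seq_len(design$replicates[1]))
  design_map <- design %>%
    tidyr::expand_grid(array_id = reps) %>%
    mutate(sample_id = .data$mixture_id) %>%
    select("sample_id", "array_id", "mixture_id", "p1", "p2")

  frac_tbl <- tidyr::expand_grid(
    snp_tbl,
    distinct(design_map, .data$sample_id, .data$array_id, .data$p1,
             .data$p2)
  ) %>%
    mutate(frac_a = (.data$p1 * .data$d1 + .data$p2 * .data$d2) /
             (2 * (.data$p1 + .data$p2))) %>%
    select("snp_id", "sample_id", "array_id", "frac_a", "base_intensity")
  beads <- simulate_beads(frac_tbl, config, seed = config$seed + 11L)
  truth <- build_truth_sets(genotypes_1, genotypes_2)
  list(beads = beads, design_map = design_map, genotypes_1 = genotypes_1,
       genotypes_2 = genotypes_2, truth = truth, config = config)
}
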