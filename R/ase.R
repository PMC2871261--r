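#' Apply the three-criterion ASE call rule per SNP
#'
#' A SNP is called allele-specifically expressed when all three criteria
#' hold: (1) average cDNA intensity across all placenta samples exceeds the
#' intensity threshold; (2) at least `min_sig_hets` heterozygous placentas
#' are individually significant (adjusted p below `alpha_adj` and absolute
#' fitted log-ratio above `lfc_threshold`); and (3) at least
#' `homozygote_pass_fraction` of homozygous placentas show the expected
#' single-allele signal by the same significance rule (probe quality
#' control: in a homozygote only one allele is present, so a good probe must
#' report strong imbalance). SNPs with zero informative homozygotes cannot
#' be quality-controlled; their homozygote criterion and `ase_flag` are `NA`
#' and they are excluded from calls. Samples with `NN` genotype are excluded
#' from both counts.
#'
#' @param tests Per-SNP/sample test tibble with columns `snp_id`,
#'   `sample_id`, `coef`, `p_adj` and `call` (placental gDNA genotype of the
#'   sample's family).
#' @param intensities Tibble `snp_id`, `avg_intensity` (mean A over all
#'   placenta cDNA summaries).
#' @param config An [ase_config()].
#' @return Tibble with one row per SNP: counts, criterion flags
#'   (`crit_intensity`, `crit_hets`, `crit_homs`) and `ase_flag`.
#' @export
call_ase <- function(tests, intensities, config = ase_config()) {
  stopifnot(all(c("snp_id", "sample_id", "coef", "p_adj", "call") %in%
                  names(tests)))
  per_snp <- tests %>%
    mutate(
      sig = .data$p_adj < config$alpha_adj &
        abs(.data$coef) > config$lfc_threshold,
      het = .data$call == "AB",
      hom = .data$call %in% c("AA", "BB")
    ) %>%
    group_by(.data$snp_id) %>%
    summarise(
      n_hets = sum(.data$het),
      n_hets_sig = sum(.data$het & .data$sig, na.rm = TRUE),
      n_homs = sum(.data$hom),
      n_homs_sig = sum(.data$hom & .data$sig, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(hom_pass_fraction = ifelse(.data$n_homs > 0,
                                      .data$n_homs_sig / .data$n_homs,
                                      NA_real_))
  per_snp %>%
    left_join(intensities, by = "snp_id") %>%
    mutate(
      crit_intensity = .data$avg_intensity > config$intensity_threshold,
      crit_hets = .data$n_hets_sig >= config$min_sig_hets,
      crit_homs = ifelse(.data$n_homs > 0,
                         .data$hom_pass_fraction >=
                           config$homozygote_pass_fraction,
                         NA),
      ase_flag = .data$crit_intensity & .data$crit_hets & .data$crit_homs
    )
}

#' Moderated-t test for allele-specific expression
#'
#' The core statistical test. For every SNP in every placenta cDNA sample,
#' the replicate centred log-ratios are summarised by an intercept-only
#' linear model ([fit_snp_sample_model()]); variances are moderated by
#' empirical-Bayes shrinkage across all fits ([ebayes_moderate()]); raw
#' two-sided p-values are adjusted globally by Benjamini-Hochberg
#' ([bh_adjust()]); and the three-criterion rule ([call_ase()]) produces the
#' per-SNP ASE calls.
#'
#' @param summaries Preprocessed summaries from [preprocess_beads()]
#'   (placenta cDNA arrays must be present; other samples are ignored here).
#' @param genotypes Genotype calls (`snp_id`, `sample_id`, `call`) for the
#'   placental gDNA samples, e.g. from [call_genotypes()].
#' @param pedigree Trio pedigree tibble ([read_pedigree()]).
#' @param config An [ase_config()].
#' @return An object of class `ase_fit`: a list with `tests` (per-SNP/sample
#'   moderated statistics), `snps` (per-SNP calls), `prior` (variance prior)
#'   and `config`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
ase_test <- function(summaries, genotypes, pedigree, config = ase_config()) {
  stopifnot(all(c("snp_id", "sample_id", "array_id", "m", "a") %in%
                  names(summaries)))
  if (nrow(pedigree) == 0) abort("empty pedigree")
  cdna <- filter(summaries, .data$sample_id %in% pedigree$placenta_cdna)
  if (nrow(cdna) == 0) abort("no placenta cDNA summaries found")

  fits <- cdna %>%
    group_by(.data$snp_id, .data$sample_id) %>%
    summarise(
      coef = mean(.data$m),
      resid_var = ifelse(dplyr::n() > 1, var(.data$m), NA_real_),
      df_resid = dplyr::n() - 1L,
      unscaled_sd = 1 / sqrt(dplyr::n()),
      .groups = "drop"
    )
  eb <- ebayes_moderate(fits, proportion = config$prior_proportion)
  eb$p_adj <- bh_adjust(eb$p_raw)

  fam <- pedigree %>%
    select(child_gdna = "placenta_gdna", sample_id = "placenta_cdna")
  child_calls <- genotypes %>%
    select("snp_id", child_gdna = "sample_id", "call") %>%
    inner_join(fam, by = "child_gdna") %>%
    select("snp_id", "sample_id", "call")
  tests <- eb %>%
    left_join(child_calls, by = c("snp_id", "sample_id")) %>%
    mutate(call = ifelse(is.na(.data$call), "NN", .data$call))

  intensities <- cdna %>%
    group_by(.data$snp_id) %>%
    summarise(avg_intensity = mean(.data$a), .groups = "drop")

  snps <- call_ase(tests, intensities, config)
  structure(
    list(
      tests = tests,
      snps = snps,
      prior = list(df_prior = tests$df_prior[1],
                   var_prior = tests$var_prior[1]),
      config = config
    ),
    class = "ase_fit"
  )
}

#' @export
print.ase_fit <- function(x, ...) {
  cat("<ase_fit>\n")
  cat(sprintf("  %d SNPs x %d samples (%d tests)\n",
              dplyr::n_distinct(x$tests$snp_id),
              dplyr::n_distinct(x$tests$sample_id), nrow(x$tests)))
  cat(sprintf("  variance prior: d0 = %.3g, s0^2 = %.3g\n",
              x$prior$df_prior, x$prior$var_prior))
  cat(sprintf("  ASE-positive SNPs: %d\n",
              sum(x$snps$ase_flag, na.rm = TRUE)))
  invisible(x)
}

#' Tidy an ASE fit into per-SNP calls
#'
#' @param x An `ase_fit` from [ase_test()].
#' @param ... Unused.
#' @return The per-SNP call tibble (counts, criterion flags, `ase_flag`).
#' @export
tidy.ase_fit <- function(x, ...) {
  x$snps
}

#' One-row summary of an ASE analysis (the filter-chain ledger)
#'
#' Reports the successive filter counts of the call rule: SNPs tested, SNPs
#' above the intensity threshold, SNPs with at least two heterozygous
#' placentas, SNPs whose probe passes the homozygote quality criterion, and
#' ASE-significant SNPs.
#'
#' @param x An `ase_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.ase_fit <- function(x, ...) {
  s <- x$snps
  tibble(
    n_snps = nrow(s),
    n_above_intensity = sum(s$crit_intensity, na.rm = TRUE),
    n_min_hets = sum(s$crit_intensity & s$n_hets >= 2, na.rm = TRUE),
    n_hom_quality = sum(s$crit_intensity & s$n_hets >= 2 & s$crit_homs,
                        na.rm = TRUE),
    n_ase = sum(s$ase_flag, na.rm = TRUE),
    df_prior = x$prior$df_prior,
    var_prior = x$prior$var_prior
  )
}
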