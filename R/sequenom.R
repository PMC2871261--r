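#' Genotyping success rate
#'
#' Fraction of genotyping attempts for one SNP on one template type (gDNA or
#' cDNA) that returned a high-confidence ("conservative") call. The
#' cDNA/gDNA success-rate ratio proxies expression level: lowly expressed
#' transcripts genotype poorly in cDNA.
#'
#' @param ratings Character vector of per-attempt ratings; `"conservative"`
#'   counts as success.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(ratings) {
  if (length(ratings) == 0) abort("no genotyping attempts")
  mean(ratings == "conservative")
}

#' Success-rate ratio filter
#'
#' @param sr_cdna,sr_gdna Success rates for cDNA and gDNA.
#' @param min_ratio Minimum cDNA/gDNA ratio (inclusive, default 0.75).
#' @return Logical pass flag.
#' @export
sr_filter <- function(sr_cdna, sr_gdna, min_ratio = 0.75) {
  if (any(sr_gdna <= 0)) abort("gDNA success rate must be positive")
  sr_cdna / sr_gdna >= min_ratio
}

#' One-tailed paired t-test on allelic skew
#'
#' Tests, over heterozygous trios, whether the allelic quantification in
#' placental cDNA is more skewed away from 50:50 than in the paired
#' placental gDNA. The statistic is formed on the absolute skew,
#' `d_i = |frac_cdna_i - 0.5| - |frac_gdna_i - 0.5|`, because under
#' imprinting the over-expressed allele differs between trios and raw
#' fractions would cancel; the test is one-tailed in the direction of
#' increased skew (upper tail of t with `n - 1` df).
#'
#' @param frac_a_cdna,frac_a_gdna Paired numeric vectors of allele-A signal
#'   fractions in `[0, 1]` over heterozygous trios, length >= 2.
#' @return A list with `t`, `df`, `p` (one-tailed) and `n`.
#' @export
paired_allele_ttest <- function(frac_a_cdna, frac_a_gdna) {
  stopifnot(length(frac_a_cdna) == length(frac_a_gdna))
  n <- length(frac_a_cdna)
  if (n < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, n = n,
                testable = FALSE))
  }
  stopifnot(all(frac_a_cdna >= 0 & frac_a_cdna <= 1),
            all(frac_a_gdna >= 0 & frac_a_gdna <= 1))
  d <- abs(frac_a_cdna - 0.5) - abs(frac_a_gdna - 0.5)
  s <- sd(d)
  if (s == 0) {
    # degenerate but well-defined limits
    p <- if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = p, n = n, testable = TRUE))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1,
       p = pt(tstat, df = n - 1, lower.tail = FALSE),
       n = n, testable = TRUE)
}

#' Mean allelic skew in percentage points
#'
#' Average over heterozygotes of the absolute difference between the two
#' allele fractions, `mean(|frac_a - frac_b|) * 100 =
#' mean(|2 frac_a - 1|) * 100`. 0 means balanced expression, 100 means
#' fully monoallelic.
#'
#' @param frac_a_cdna Numeric vector of cDNA allele-A fractions over
#'   informative heterozygotes.
#' @return Percentage points in `[0, 100]`.
#' @export
skew_difference <- function(frac_a_cdna) {
  if (length(frac_a_cdna) == 0) abort("no heterozygote fractions")
  stopifnot(all(frac_a_cdna >= 0 & frac_a_cdna <= 1))
  mean(abs(2 * frac_a_cdna - 1)) * 100
}

#' Paired allelic-ratio ASE test for allelotyping data
#'
#' Full medium-throughput analysis arm. Per SNP: success rates on gDNA and
#' cDNA are computed from the call ratings ([success_rate()]), SNPs with a
#' cDNA/gDNA success-rate ratio below `min_sr_ratio` are dropped
#' ([sr_filter()]), heterozygous trios are selected on the placental gDNA,
#' the one-tailed paired skew test ([paired_allele_ttest()]) is run over
#' them, p-values are BH-adjusted across SNPs, and the mean cDNA skew is
#' reported in percentage points ([skew_difference()]).
#'
#' Heterozygosity is taken from `genotypes` when supplied; otherwise a trio
#' counts as heterozygous when its placental gDNA allele fraction lies
#' within `het_band` of 0.5.
#'
#' @param quants Tibble of allele quantifications with columns `snp_id`,
#'   `sample_id`, `sample_type` (`"gDNA"`/`"cDNA"`), `frac_a`, `rating`.
#' @param pedigree Trio pedigree tibble; `placenta_gdna`/`placenta_cdna`
#'   identify the paired samples.
#' @param genotypes Optional genotype calls for the placental gDNA samples.
#' @param min_sr_ratio Success-rate ratio cut-off (inclusive).
#' @param het_band Half-width of the gDNA fraction window used to call
#'   heterozygotes when `genotypes` is absent.
#' @return Tibble with one row per SNP: `snp_id`, `sr_gdna`, `sr_cdna`,
#'   `sr_ratio`, `sr_pass`, `n_hets`, `t`, `p_raw`, `p_adj`, `difference`,
#'   `testable`.
#' @export
sequenom_test <- function(quants, pedigree, genotypes = NULL,
                          min_sr_ratio = 0.75, het_band = 0.2) {
  stopifnot(all(c("snp_id", "sample_id", "sample_type", "frac_a",
                  "rating") %in% names(quants)))
  if (any(!quants$sample_type %in% c("gDNA", "cDNA"))) {
    abort("sample_type must be gDNA or cDNA")
  }
  sr <- quants %>%
    group_by(.data$snp_id, .data$sample_type) %>%
    summarise(sr = success_rate(.data$rating), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample_type", values_from = "sr",
                       names_prefix = "sr_") %>%
    rename(sr_gdna = "sr_gDNA", sr_cdna = "sr_cDNA")

  conserved <- filter(quants, .data$rating == "conservative")
  gdna <- conserved %>%
    filter(.data$sample_type == "gDNA") %>%
    inner_join(select(pedigree, "family_id", sample_id = "placenta_gdna"),
               by = "sample_id") %>%
    select("snp_id", "family_id", frac_gdna = "frac_a")
  cdna <- conserved %>%
    filter(.data$sample_type == "cDNA") %>%
    inner_join(select(pedigree, "family_id", sample_id = "placenta_cdna"),
               by = "sample_id") %>%
    select("snp_id", "family_id", frac_cdna = "frac_a")
  paired <- inner_join(gdna, cdna, by = c("snp_id", "family_id"))

  if (!is.null(genotypes)) {
    hets <- genotypes %>%
      filter(.data$call == "AB") %>%
      inner_join(select(pedigree, "family_id",
                        sample_id = "placenta_gdna"),
                 by = "sample_id") %>%
      select("snp_id", "family_id")
    paired <- semi_join(paired, hets, by = c("snp_id", "family_id"))
  } else {
    paired <- filter(paired, abs(.data$frac_gdna - 0.5) <= het_band)
  }

  test_one <- function(df) {
    tt <- paired_allele_ttest(df$frac_cdna, df$frac_gdna)
    tibble(n_hets = nrow(df), t = tt$t, p_raw = tt$p,
           difference = skew_difference(df$frac_cdna),
           testable = tt$testable)
  }
  tested <- paired %>%
    group_by(.data$snp_id) %>%
    dplyr::group_modify(~ test_one(.x)) %>%
    ungroup()

  out <- sr %>%
    left_join(tested, by = "snp_id") %>%
    mutate(
      sr_ratio = ifelse(.data$sr_gdna > 0,
                        .data$sr_cdna / .data$sr_gdna, NA_real_),
      sr_pass = !is.na(.data$sr_ratio) & .data$sr_ratio >= min_sr_ratio,
      n_hets = tidyr::replace_na(.data$n_hets, 0L),
      testable = tidyr::replace_na(.data$testable, FALSE) & .data$sr_pass
    )
  out$p_adj <- NA_real_
  idx <- out$testable & !is.na(out$p_raw)
  out$p_adj[idx] <- bh_adjust(out$p_raw[idx])
  out %>%
    select("snp_id", "sr_gdna", "sr_cdna", "sr_ratio", "sr_pass",
           "n_hets", "t", "p_raw", "p_adj", "difference", "testable") %>%
    arrange(.data$p_adj)
}
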