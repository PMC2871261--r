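#' Log2 fold-change equivalent of an allelic ratio
#'
#' Converts an allelic ratio such as 60:40 into the corresponding absolute
#' log2 fold change between the two alleles. The default ASE effect-size
#' cut-off used throughout the package is `lfc_from_ratio(60, 40)` = 0.585:
#' mixture-titration experiments show that allelic imbalances at or below a
#' 60:40 ratio are hard to detect reliably on this platform, so only larger
#' log-ratios are accepted as evidence of ASE.
#'
#' @param p,q The two sides of the ratio (e.g. 60 and 40). Units are
#'   arbitrary; only `p/q` matters.
#' @return A single numeric, `log2(p/q)`.
#' @examples
#' lfc_from_ratio(60, 40) # 0.585 to 3 d.p.
#' @export
lfc_from_ratio <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), p > 0, q > 0)
  log2(p / q)
}

#' Analysis configuration for the ASE pipeline
#'
#' Bundles every tunable threshold of the ASE analysis. Defaults are the
#' study values: intensity cut-off 11.25 log2 fluorescence units (below it
#' allelic quantification is unreliable), effect-size cut-off
#' `log2(60/40)` = 0.585, adjusted-p cut-off 0.01, at least 2 significant
#' heterozygotes, at least 80% of homozygotes behaving monoallelically,
#' MAD outlier multiplier 3, and a symmetric 1.5 log2-unit margin for
#' threshold genotype calling from gDNA log-ratios.
#'
#' @param intensity_threshold Minimum average cDNA log2 intensity (A) across
#'   samples for a SNP to be considered expressed enough to test.
#' @param lfc_threshold Minimum absolute fitted log-ratio (log2 fold change
#'   between alleles) for a sample to count as allelically imbalanced.
#' @param alpha_adj Adjusted p-value (BH) cut-off.
#' @param min_sig_hets Minimum number of heterozygous placentas that must be
#'   individually significant.
#' @param homozygote_pass_fraction Minimum fraction of homozygous placentas
#'   that must show the expected single-allele signal in cDNA (probe quality
#'   control).
#' @param mad_k Outlier multiplier for bead-level MAD filtering.
#' @param genotype_call_margin Symmetric log2 margin for the threshold
#'   genotype caller: gDNA M at or beyond +/- margin is called homozygous.
#' @param completeness_factor Fraction of the homozygous-gDNA reference
#'   log-ratio that a cDNA log-ratio must reach to count as complete
#'   silencing of one allele (see `classify_patterns()`).
#' @param parent_consistency Fraction of origin-informative significant
#'   heterozygotes that must share one parental origin for a
#'   (partial-)imprinting call.
#' @param allele_consistency Fraction of significant heterozygotes that must
#'   over-express the same allele (by identity) for a preferential call.
#' @param prior_proportion Prior proportion of truly imbalanced SNPs used in
#'   the posterior log-odds (B-statistic); the B-statistic is used only for
#'   ranking, never for calling.
#' @return An object of class `ase_config` (a named list).
#' @examples
#' cfg <- ase_config()
#' cfg$lfc_threshold
#' @export
ase_config <- function(intensity_threshold = 11.25,
                       lfc_threshold = lfc_from_ratio(60, 40),
                       alpha_adj = 0.01,
                       min_sig_hets = 2,
                       homozygote_pass_fraction = 0.80,
                       mad_k = 3,
                       genotype_call_margin = 1.5,
                       completeness_factor = 0.6,
                       parent_consistency = 0.80,
                       allele_consistency = 0.90,
                       prior_proportion = 0.01) {
  stopifnot(
    intensity_threshold > 0, lfc_threshold > 0, alpha_adj > 0, alpha_adj <= 1,
    min_sig_hets >= 1, homozygote_pass_fraction > 0,
    homozygote_pass_fraction <= 1, mad_k > 0, genotype_call_margin > 0,
    completeness_factor > 0, completeness_factor <= 1,
    parent_consistency > 0, parent_consistency <= 1,
    allele_consistency > 0, allele_consistency <= 1,
    prior_proportion > 0, prior_proportion < 1
  )
  structure(
    list(
      intensity_threshold = intensity_threshold,
      lfc_threshold = lfc_threshold,
      alpha_adj = alpha_adj,
      min_sig_hets = min_sig_hets,
      homozygote_pass_fraction = homozygote_pass_fraction,
      mad_k = mad_k,
      genotype_call_margin = genotype_call_margin,
      completeness_factor = completeness_factor,
      parent_consistency = parent_consistency,
      allele_consistency = allele_consistency,
      prior_proportion = prior_proportion
    ),
    class = "ase_config"
  )
}

#' @export
print.ase_config <- function(x, ...) {
  cat("<ase_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]], digits = 4)))
  }
  invisible(x)
}
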