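#' Parent-of-origin of the expressed allele in one trio
#'
#' For a heterozygous placenta, the sign of the cDNA log-ratio identifies
#' the over-expressed allele (positive = allele A). When at least one parent
#' is homozygous the parental origin of that allele can be deduced: a mother
#' homozygous for an allele must have transmitted it, and with a homozygous
#' father the transmitted paternal allele is known so the maternal one is
#' the child's other allele. An absent father (call `NN`) still allows
#' origin inference when the mother is homozygous. When both parents are
#' heterozygous (or the needed parent is missing) the trio is
#' origin-uninformative. Both parents homozygous for the same allele with a
#' heterozygous child is a Mendelian error. Vectorised over trios.
#'
#' @param child,mother,father Genotype calls; `child` must be `"AB"`.
#' @param cdna_m Placenta cDNA log-ratio(s) (non-zero).
#' @return Tibble with `expressed_allele` (`A`/`B`), `origin`
#'   (`maternal`/`paternal`/`uninformative`) and `mendelian_error`.
#' @examples
#' infer_origin("AB", "AA", "BB", 3) # maternal A expressed
#' @export
infer_origin <- function(child, mother, father, cdna_m) {
  n <- length(cdna_m)
  child <- rep_len(child, n); mother <- rep_len(mother, n)
  father <- rep_len(father, n)
  if (any(child != "AB")) abort("origin inference requires AB placenta gDNA")
  stopifnot(all(is.finite(cdna_m)), all(cdna_m != 0))
  expressed <- ifelse(cdna_m > 0, "A", "B")
  other <- ifelse(expressed == "A", "B", "A")
  mother_hom <- substr(mother, 1, 1)
  mother_hom[!mother %in% c("AA", "BB")] <- NA
  father_hom <- substr(father, 1, 1)
  father_hom[!father %in% c("AA", "BB")] <- NA

  mendel <- !is.na(mother_hom) & !is.na(father_hom) &
    mother_hom == father_hom
  # maternal allele of the child, where deducible
  maternal <- ifelse(!is.na(mother_hom), mother_hom,
                     ifelse(!is.na(father_hom),
                            # father transmitted his allele; mother gave the
                            # child's other allele
                            NA, NA))
  idx <- is.na(maternal) & !is.na(father_hom)
  # child is AB: if father transmitted X, mother transmitted the complement
  maternal[idx] <- ifelse(father_hom[idx] == "A", "B", "A")
  origin <- rep("uninformative", n)
  known <- !is.na(maternal) & !mendel
  origin[known] <- ifelse(expressed[known] == maternal[known],
                          "maternal", "paternal")
  tibble(
    expressed_allele = expressed,
    origin = ifelse(mendel, "uninformative", origin),
    mendelian_error = mendel
  )
}

#' Origin calls for every significant heterozygous placenta
#'
#' Builds the long per-trio origin table behind trio bar plots: one row per
#' (SNP, family) where the placenta gDNA is heterozygous, with the expressed
#' allele, its parental origin where deducible, and whether the silencing is
#' complete relative to the homozygous gDNA reference of the same SNP.
#'
#' @param ase An `ase_fit` from [ase_test()].
#' @param genotypes Genotype calls covering placenta and parental gDNA
#'   samples.
#' @param pedigree Trio pedigree tibble.
#' @param summaries Preprocessed summaries (used for the homozygous-gDNA
#'   reference log-ratio).
#' @param config An [ase_config()].
#' @return Tibble with one row per informative het:
#'   `snp_id`, `family_id`, `cdna_m`, `significant`, `expressed_allele`,
#'   `origin`, `origin_informative`, `complete`, `mendelian_error`.
#' @export
infer_origins <- function(ase, genotypes, pedigree, summaries,
                          config = ase_config()) {
  stopifnot(inherits(ase, "ase_fit"))
  href <- homozygote_reference(summaries, genotypes, pedigree)

  sample_roles <- pedigree %>%
    tidyr::pivot_longer(c("placenta_gdna", "mother_gdna", "father_gdna"),
                        names_to = "role", values_to = "sample_id") %>%
    filter(!is.na(.data$sample_id))
  calls_by_role <- genotypes %>%
    inner_join(sample_roles, by = "sample_id") %>%
    select("snp_id", "family_id", "role", "call") %>%
    tidyr::pivot_wider(names_from = "role", values_from = "call",
                       values_fill = "NN")
  if (!"father_gdna" %in% names(calls_by_role)) {
    calls_by_role$father_gdna <- "NN"
  }

  cdna_a <- summaries %>%
    filter(.data$sample_id %in% pedigree$placenta_cdna) %>%
    group_by(.data$snp_id, .data$sample_id) %>%
    summarise(cdna_a = mean(.data$a), .groups = "drop")
  tests <- ase$tests %>%
    inner_join(select(pedigree, "family_id", sample_id = "placenta_cdna"),
               by = "sample_id") %>%
    left_join(cdna_a, by = c("snp_id", "sample_id"))
  out <- tests %>%
    inner_join(calls_by_role, by = c("snp_id", "family_id")) %>%
    filter(.data$placenta_gdna == "AB", .data$coef != 0) %>%
    mutate(significant = .data$p_adj < config$alpha_adj &
             abs(.data$coef) > config$lfc_threshold)
  if (nrow(out) == 0) {
    return(tibble(snp_id = character(), family_id = character(),
                  cdna_m = numeric(), cdna_a = numeric(),
                  significant = logical(),
                  expressed_allele = character(), origin = character(),
                  origin_informative = logical(), complete = logical(),
                  mendelian_error = logical()))
  }
  oc <- infer_origin(out$placenta_gdna, out$mother_gdna, out$father_gdna,
                     out$coef)
  out %>%
    mutate(
      cdna_m = .data$coef,
      expressed_allele = oc$expressed_allele,
      origin = oc$origin,
      origin_informative = oc$origin != "uninformative",
      mendelian_error = oc$mendelian_error
    ) %>%
    left_join(href, by = "snp_id") %>%
    mutate(complete = !is.na(.data$hom_ref_m) &
             abs(.data$cdna_m) >=
             config$completeness_factor * .data$hom_ref_m) %>%
    select("snp_id", "family_id", "cdna_m", "cdna_a", "significant",
           "expressed_allele", "origin", "origin_informative", "complete",
           "mendelian_error")
}

#' Homozygous-gDNA reference log-ratio per SNP
#'
#' The median absolute summarised log-ratio of homozygous gDNA samples of
#' the same SNP. This is the array's effective dynamic range for the probe:
#' a completely silenced allele in cDNA can at most reach this log-ratio, so
#' it anchors the complete-vs-partial silencing comparison.
#'
#' @param summaries Preprocessed summaries.
#' @param genotypes Genotype calls.
#' @param pedigree Trio pedigree (identifies the gDNA samples).
#' @return Tibble `snp_id`, `hom_ref_m` (`NA` when a SNP has no homozygous
#'   gDNA sample).
#' @export
homozygote_reference <- function(summaries, genotypes, pedigree) {
  gdna_samples <- unique(stats::na.omit(c(pedigree$placenta_gdna,
                                          pedigree$mother_gdna,
                                          pedigree$father_gdna)))
  hom <- genotypes %>%
    filter(.data$sample_id %in% gdna_samples,
           .data$call %in% c("AA", "BB"))
  summaries %>%
    semi_join(hom, by = c("snp_id", "sample_id")) %>%
    group_by(.data$snp_id) %>%
    summarise(hom_ref_m = median(abs(.data$m)), .groups = "drop")
}

#' Fold difference between expressed and silenced allele
#'
#' @param raw_expressed,raw_silenced Positive numeric vectors of raw
#'   per-sample allele intensities (reconstructed with
#'   [allele_intensities()]).
#' @return `mean(raw_expressed) / mean(raw_silenced)`.
#' @export
fold_difference <- function(raw_expressed, raw_silenced) {
  if (length(raw_expressed) == 0 || length(raw_silenced) == 0) {
    abort("empty intensity vectors")
  }
  stopifnot(all(raw_expressed > 0), all(raw_silenced > 0))
  mean(raw_expressed) / mean(raw_silenced)
}

#' Reconstruct per-allele raw intensities from (M, A)
#'
#' Inverts the log-ratio / average-log-intensity transform:
#' `allele_a = 2^(A + M/2)` and `allele_b = 2^(A - M/2)`.
#'
#' @param m,a Numeric vectors of log-ratios and average log-intensities.
#' @return Tibble with columns `allele_a`, `allele_b`.
#' @export
allele_intensities <- function(m, a) {
  stopifnot(length(m) == length(a))
  tibble(allele_a = 2^(a + m / 2), allele_b = 2^(a - m / 2))
}

#' Classify ASE-positive SNPs into allelic-expression modes
#'
#' Codifies the visual categorisation of trio bar plots into a decision
#' ladder over the significant heterozygotes of each ASE-positive SNP
#' (first match wins):
#'
#' 1. `imprinting` - at least `parent_consistency` of origin-informative
#'    significant hets share one parental origin AND at least
#'    `parent_consistency` of significant hets show complete silencing;
#' 2. `partial_imprinting` - parental origin is consistent but silencing is
#'    incomplete;
#' 3. `preferential` - origins mixed or uninformative, but the same allele
#'    (by identity) is over-expressed in at least `allele_consistency` of
#'    significant hets;
#' 4. `random_monoallelic` - silencing mostly complete, alleles and origins
#'    inconsistent;
#' 5. `random_ase` - remaining significant SNPs;
#' 6. `unclassified` - fewer than 2 origin-informative hets and no
#'    allele-consistency signal.
#'
#' SNPs whose `ase_flag` is not `TRUE` are reported as `biallelic`.
#' Completeness compares the cDNA log-ratio against
#' `completeness_factor * hom_ref_m` (see [homozygote_reference()]).
#' The fold difference between expressed and silenced allele is computed
#' over the significant hets from the reconstructed raw allele intensities.
#'
#' @param ase An `ase_fit` from [ase_test()].
#' @param genotypes Genotype calls covering placental and parental gDNA.
#' @param pedigree Trio pedigree tibble.
#' @param summaries Preprocessed summaries.
#' @param config An [ase_config()].
#' @return Tibble with one row per SNP: `snp_id`, `mode`, `oriented_parent`,
#'   `preferred_allele`, `fold_difference`, `n_informative`,
#'   `n_significant`; the per-trio origin table is attached as attribute
#'   `"origins"`.
#' @export
classify_patterns <- function(ase, genotypes, pedigree, summaries,
                              config = ase_config()) {
  stopifnot(inherits(ase, "ase_fit"))
  origins <- infer_origins(ase, genotypes, pedigree, summaries, config)
  avg_a <- ase$tests %>%
    distinct(.data$snp_id) %>% pull("snp_id")

  classify_one <- function(snp, flag) {
    oc <- filter(origins, .data$snp_id == snp, .data$significant,
                 !.data$mendelian_error)
    n_sig <- nrow(oc)
    n_inf <- sum(oc$origin_informative)
    base <- tibble(
      snp_id = snp, mode = "unclassified",
      oriented_parent = "none", preferred_allele = "none",
      fold_difference = NA_real_,
      n_informative = n_inf, n_significant = n_sig
    )
    if (!isTRUE(flag)) {
      base$mode <- "biallelic"
      return(base)
    }
    if (n_sig == 0) return(base)
    ai <- allele_intensities(oc$cdna_m,
                             ifelse(is.na(oc$cdna_a), 0, oc$cdna_a))
    expressed <- ifelse(oc$cdna_m > 0, ai$allele_a, ai$allele_b)
    silenced <- ifelse(oc$cdna_m > 0, ai$allele_b, ai$allele_a)
    base$fold_difference <- fold_difference(expressed, silenced)
    complete_frac <- mean(oc$complete)
    allele_tab <- table(factor(oc$expressed_allele, c("A", "B")))
    allele_share <- max(allele_tab) / n_sig
    top_allele <- names(allele_tab)[which.max(allele_tab)]
    if (n_inf >= 2) {
      orig_tab <- table(factor(oc$origin[oc$origin_informative],
                               c("maternal", "paternal")))
      parent_share <- max(orig_tab) / n_inf
      top_parent <- names(orig_tab)[which.max(orig_tab)]
      if (parent_share >= config$parent_consistency) {
        if (complete_frac >= config$parent_consistency) {
          base$mode <- "imprinting"
        } else {
          base$mode <- "partial_imprinting"
        }
        base$oriented_parent <- top_parent
        return(base)
      }
    }
    if (allele_share >= config$allele_consistency) {
      base$mode <- "preferential"
      base$preferred_allele <- top_allele
      return(base)
    }
    if (complete_frac >= config$parent_consistency) {
      base$mode <- "random_monoallelic"
      return(base)
    }
    if (n_inf >= 2) base$mode <- "random_ase"
    base
  }

  flags <- setNames(ase$snps$ase_flag, ase$snps$snp_id)
  out <- purrr::map(avg_a, ~ classify_one(.x, flags[[.x]])) %>% bind_rows()
  attr(out, "origins") <- origins
  out
}
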