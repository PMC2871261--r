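#' End-to-end trio ASE analysis
#'
#' Runs the complete analysis path on a bead-level intensity table:
#' preprocessing ([preprocess_beads()]), threshold genotype calling from the
#' gDNA arrays ([call_genotypes()]) with Mendelian checks, the moderated-t
#' ASE test ([ase_test()]) and pattern classification
#' ([classify_patterns()]).
#'
#' @param beads Bead tibble ([read_bead_table()] or [simulate_study()]).
#' @param pedigree Trio pedigree tibble.
#' @param config An [ase_config()].
#' @param genotypes Optional pre-called genotypes (`snp_id`, `sample_id`,
#'   `call`); when `NULL` they are called from the gDNA log-ratios.
#' @return An object of class `illumina_run`: list with `summaries`,
#'   `genotypes`, `mendel` (per-trio consistency), `ase` (an `ase_fit`),
#'   `patterns`, `origins`, `filter_chain` and `manifest` (config and call
#'   snapshot).
#' @export
run_illumina <- function(beads, pedigree, config = ase_config(),
                         genotypes = NULL) {
  if (nrow(pedigree) == 0) abort("empty pedigree")
  if (anyDuplicated(pedigree$family_id)) {
    abort("duplicated family_id in pedigree")
  }
  summaries <- preprocess_beads(beads, config)
  if (is.null(genotypes)) {
    gdna_samples <- unique(stats::na.omit(c(pedigree$placenta_gdna,
                                            pedigree$mother_gdna,
                                            pedigree$father_gdna)))
    genotypes <- call_genotypes(summaries, samples = gdna_samples,
                                margin = config$genotype_call_margin) %>%
      select("snp_id", "sample_id", "call")
  }

  lookup <- genotypes %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "call")
  get_call <- function(ids, snp_tbl) {
    out <- rep("NN", length(ids))
    ok <- !is.na(ids) & ids %in% names(snp_tbl)
    out[ok] <- unlist(snp_tbl[ids[ok]])
    out
  }
  mendel <- tidyr::expand_grid(
    snp_id = unique(genotypes$snp_id),
    pedigree %>% select("family_id", "placenta_gdna", "mother_gdna",
                        "father_gdna")
  ) %>%
    left_join(genotypes %>% rename(child = "call"),
              by = c(snp_id = "snp_id", placenta_gdna = "sample_id")) %>%
    left_join(genotypes %>% rename(mother = "call"),
              by = c(snp_id = "snp_id", mother_gdna = "sample_id")) %>%
    left_join(genotypes %>% rename(father = "call"),
              by = c(snp_id = "snp_id", father_gdna = "sample_id")) %>%
    mutate(
      dplyr::across(c("child", "mother", "father"),
                    ~ tidyr::replace_na(.x, "NN")),
      consistency = check_mendelian(.data$child, .data$mother, .data$father)
    ) %>%
    select("snp_id", "family_id", "child", "mother", "father",
           "consistency")

  ase <- ase_test(summaries, genotypes, pedigree, config)
  patterns <- classify_patterns(ase, genotypes, pedigree, summaries, config)

  g <- glance(ase)
  filter_chain <- tibble(
    step = c("tested", "above_intensity", "min_two_hets", "hom_quality",
             "ase_significant"),
    n_snps = c(g$n_snps, g$n_above_intensity, g$n_min_hets,
               g$n_hom_quality, g$n_ase)
  )
  structure(
    list(
      summaries = summaries, genotypes = genotypes, mendel = mendel,
      ase = ase, patterns = patterns,
      origins = attr(patterns, "origins"),
      filter_chain = filter_chain,
      manifest = list(config = config, n_trios = nrow(pedigree),
                      timestamp = format(Sys.time(), tz = "UTC"))
    ),
    class = "illumina_run"
  )
}

#' @export
print.illumina_run <- function(x, ...) {
  cat("<illumina_run>\n")
  print(x$filter_chain)
  invisible(x)
}

#' End-to-end mixture calibration analysis
#'
#' Preprocesses the titration-series arrays, forms per-SNP contrasts of
#' every mixture against the 50:50 anchor ([mixture_contrasts()]), derives
#' genotype-based truth labels ([build_truth_sets()]) and computes an ROC
#' curve and AUC per mixture by ranking SNPs on the posterior log-odds
#' ([roc_auc()]).
#'
#' @param beads Bead tibble of the mixture arrays.
#' @param design_map Tibble `sample_id`, `mixture_id`, `p1`, `p2`.
#' @param genotypes_1,genotypes_2 Genotype calls of the two mixed
#'   individuals (`snp_id`, `call`).
#' @param config An [ase_config()].
#' @return An object of class `mixture_run`: list with `summaries`, `fit`
#'   (a `mixture_fit`), `truth`, `auc` (per-mixture tibble) and `curves`.
#' @export
run_mixture <- function(beads, design_map, genotypes_1, genotypes_2,
                        config = ase_config()) {
  summaries <- preprocess_beads(beads, config)
  fit <- mixture_contrasts(summaries, design_map, config)
  truth <- build_truth_sets(genotypes_1, genotypes_2)
  usable <- filter(truth, .data$label != "excluded")
  scored <- fit$contrasts %>%
    inner_join(usable, by = "snp_id")
  per_mix <- scored %>%
    group_by(.data$mixture_id, .data$p1, .data$p2) %>%
    dplyr::group_map(function(df, key) {
      roc <- roc_auc(df$log_odds, df$label)
      list(
        auc = tibble(mixture_id = key$mixture_id, p1 = key$p1,
                     p2 = key$p2, auc = roc$auc,
                     n_tp = sum(df$label == "true_positive"),
                     n_tn = sum(df$label == "true_negative")),
        curve = mutate(roc$curve, mixture_id = key$mixture_id,
                       p1 = key$p1, p2 = key$p2)
      )
    })
  auc <- bind_rows(purrr::map(per_mix, "auc"))
  curves <- bind_rows(purrr::map(per_mix, "curve"))
  structure(
    list(summaries = summaries, fit = fit, truth = truth, auc = auc,
         curves = curves,
         manifest = list(config = config,
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "mixture_run"
  )
}

#' @export
print.mixture_run <- function(x, ...) {
  cat("<mixture_run>\n")
  print(x$auc)
  invisible(x)
}
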