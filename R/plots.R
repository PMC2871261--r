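#' Trio bar plot of allelic log-ratios for one SNP
#'
#' The classic way to read imprinting by eye: for each informative family,
#' the summarised log-ratios of placental gDNA, placental cDNA, maternal
#' and paternal gDNA are drawn side by side. An imprinted SNP shows cDNA
#' bars oscillating in sign across families, always matching the sign of
#' the homozygous parent whose allele is expressed.
#'
#' @param summaries Preprocessed summaries.
#' @param pedigree Trio pedigree tibble.
#' @param snp SNP id to plot.
#' @return A ggplot object.
#' @export
plot_trio_logratios <- function(summaries, pedigree, snp) {
  roles <- pedigree %>%
    tidyr::pivot_longer(c("placenta_gdna", "placenta_cdna", "mother_gdna",
                          "father_gdna"),
                        names_to = "role", values_to = "sample_id") %>%
    filter(!is.na(.data$sample_id)) %>%
    mutate(role = dplyr::recode(.data$role,
                                placenta_gdna = "placenta gDNA",
                                placenta_cdna = "placenta cDNA",
                                mother_gdna = "maternal gDNA",
                                father_gdna = "paternal gDNA"))
  dat <- summaries %>%
    filter(.data$snp_id == snp) %>%
    inner_join(roles, by = "sample_id") %>%
    group_by(.data$family_id, .data$role) %>%
    summarise(m = mean(.data$m), .groups = "drop") %>%
    mutate(role = factor(.data$role,
                         c("placenta gDNA", "placenta cDNA",
                           "maternal gDNA", "paternal gDNA")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$family_id, y = .data$m,
                                    fill = .data$role)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "family", y = "allelic log-ratio (log2 A/B)",
                  fill = NULL, title = snp) +
    ggplot2::theme_minimal()
}

#' Volcano-style overview of an ASE fit
#'
#' Plots every per-SNP/sample test: fitted log-ratio against -log10
#' adjusted p, coloured by the placental genotype, with the effect-size and
#' significance cut-offs drawn.
#'
#' @param object An `ase_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ase_fit <- function(object, ...) {
  cfg <- object$config
  dat <- mutate(object$tests,
                mlp = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$coef, y = .data$mlp,
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * cfg$lfc_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha_adj),
                        linetype = "dashed") +
    ggplot2::labs(x = "fitted log-ratio (log2)",
                  y = "-log10 adjusted p", colour = "gDNA call") +
    ggplot2::theme_minimal()
}

#' ROC curves of a mixture calibration run
#'
#' One curve per mixture, sensitivity against 1 - specificity, with the
#' mixture AUC in the legend.
#'
#' @param object A `mixture_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_run <- function(object, ...) {
  lab <- object$auc %>%
    mutate(label = sprintf("%d:%d (AUC %.2f)", .data$p1, .data$p2,
                           .data$auc)) %>%
    select("mixture_id", "label")
  dat <- object$curves %>% inner_join(lab, by = "mixture_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity,
                                    colour = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = "mixture") +
    ggplot2::theme_minimal()
}
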