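#' The two-individual gDNA titration design
#'
#' The default design mixes genomic DNA of two individuals in 17 proportions
#' (including both pure samples, a 50:50 anchor, and a duplicated 5:95
#' entry), each hybridised in duplicate. Contrasts of every mixture against
#' the 50:50 anchor cancel dye biases and systematic shifts.
#'
#' @param proportions Optional two-column matrix/data frame of (p1, p2)
#'   pairs summing to 100; defaults to the 17-entry titration series.
#' @param replicates Arrays per mixture (default 2).
#' @return Tibble with `mixture_id`, `p1`, `p2`, `replicates`.
#' @export
mixture_design <- function(proportions = NULL, replicates = 2) {
  if (is.null(proportions)) {
    proportions <- rbind(
      c(0, 100), c(5, 95), c(91, 9), c(83, 17), c(67, 33), c(64, 36),
      c(60, 40), c(56, 44), c(50, 50), c(44, 56), c(40, 60), c(36, 64),
      c(33, 67), c(17, 83), c(9, 91), c(5, 95), c(100, 0)
    )
  }
  proportions <- as.matrix(proportions)
  stopifnot(ncol(proportions) == 2, all(rowSums(proportions) == 100),
            replicates >= 1)
  if (!any(proportions[, 1] == 50 & proportions[, 2] == 50)) {
    abort("the design must include the 50:50 mixture")
  }
  tibble(
    mixture_id = sprintf("mix%02d", seq_len(nrow(proportions))),
    p1 = proportions[, 1],
    p2 = proportions[, 2],
    replicates = as.integer(replicates)
  )
}

#' Genotype-derived truth labels for the mixture experiment
#'
#' SNPs where the two individuals' genotypes imply a change of allelic
#' ratio with mixing (homozygous-different `AA:BB`/`BB:AA`, or heterozygous
#' vs homozygous) are true positives; SNPs with identical genotypes are true
#' negatives (mixing identical sources cannot change the ratio); SNPs with
#' missing (`NN`) calls in either individual are excluded.
#'
#' @param genotypes_1,genotypes_2 Tibbles `snp_id`, `call` for the two
#'   individuals.
#' @return Tibble `snp_id`, `label`
#'   (`true_positive`/`true_negative`/`excluded`), `reason` (the genotype
#'   pair).
#' @export
build_truth_sets <- function(genotypes_1, genotypes_2) {
  stopifnot(all(c("snp_id", "call") %in% names(genotypes_1)),
            all(c("snp_id", "call") %in% names(genotypes_2)))
  joined <- inner_join(
    select(genotypes_1, "snp_id", call_1 = "call"),
    select(genotypes_2, "snp_id", call_2 = "call"),
    by = "snp_id"
  )
  joined %>%
    mutate(
      reason = paste0(.data$call_1, ":", .data$call_2),
      label = dplyr::case_when(
        .data$call_1 == "NN" | .data$call_2 == "NN" ~ "excluded",
        .data$call_1 == .data$call_2 ~ "true_negative",
        TRUE ~ "true_positive"
      )
    ) %>%
    select("snp_id", "label", "reason")
}

#' Per-SNP contrasts of each mixture against the 50:50 anchor
#'
#' Fits a mixture-indexed linear model to the summarised log-ratios of each
#' SNP (cell means per mixture, pooled residual variance) and forms the
#' contrast of every mixture against the 50:50 mixture. Variances are then
#' moderated across SNPs ([ebayes_moderate()]) and each contrast gets a
#' moderated t, a two-sided p and a posterior log-odds for ranking.
#'
#' @param summaries Preprocessed summaries of all mixture arrays.
#' @param design_map Tibble mapping `sample_id` to `mixture_id`, `p1`, `p2`
#'   (one row per mixture sample).
#' @param config An [ase_config()] (for the log-odds prior proportion).
#' @return An object of class `mixture_fit`: list with `contrasts` (tibble
#'   `snp_id`, `mixture_id`, `p1`, `p2`, `coef`, `mod_t`, `p_raw`, `p_adj`,
#'   `log_odds`, ...) and `prior`.
#' @export
mixture_contrasts <- function(summaries, design_map, config = ase_config()) {
  stopifnot(all(c("sample_id", "mixture_id", "p1", "p2") %in%
                  names(design_map)))
  ref_ids <- design_map$sample_id[design_map$p1 == 50 & design_map$p2 == 50]
  if (length(ref_ids) == 0) abort("design has no 50:50 mixture")
  dat <- summaries %>%
    inner_join(distinct(design_map, .data$sample_id, .data$mixture_id,
                        .data$p1, .data$p2),
               by = "sample_id")
  n_ref <- dat %>%
    filter(.data$sample_id %in% ref_ids) %>%
    count(.data$snp_id) %>% pull(.data$n)
  if (length(n_ref) == 0 || min(n_ref) < 2) {
    abort("need at least 2 replicate arrays of the 50:50 mixture")
  }

  cell <- dat %>%
    group_by(.data$snp_id, .data$mixture_id, .data$p1, .data$p2) %>%
    summarise(mean_m = mean(.data$m), n_arrays = dplyr::n(),
              rss = sum((.data$m - mean(.data$m))^2), .groups = "drop")
  pooled <- cell %>%
    group_by(.data$snp_id) %>%
    summarise(
      resid_var = sum(.data$rss) / (sum(.data$n_arrays) - dplyr::n()),
      df_resid = sum(.data$n_arrays) - dplyr::n(),
      .groups = "drop"
    )
  ref <- cell %>%
    filter(.data$p1 == 50, .data$p2 == 50) %>%
    select("snp_id", ref_m = "mean_m", ref_n = "n_arrays")

  fits <- cell %>%
    filter(!(.data$p1 == 50 & .data$p2 == 50)) %>%
    inner_join(ref, by = "snp_id") %>%
    inner_join(pooled, by = "snp_id") %>%
    mutate(
      coef = .data$mean_m - .data$ref_m,
      unscaled_sd = sqrt(1 / .data$n_arrays + 1 / .data$ref_n)
    )
  # The variance prior is fitted on one pooled variance per SNP, then the
  # squeezed variance is shared by all contrasts of that SNP.
  prior <- fit_variance_prior(pooled$resid_var, pooled$df_resid)
  df_pooled_sum <- sum(pooled$df_resid)
  eb <- fits %>%
    select("snp_id", "mixture_id", "p1", "p2", "coef", "resid_var",
           "df_resid", "unscaled_sd") %>%
    mutate(
      df_prior = prior$df_prior,
      var_prior = prior$var_prior,
      mod_var = .squeeze_var(.data$resid_var, .data$df_resid,
                             prior$df_prior, prior$var_prior),
      df_total = pmin(.data$df_resid + prior$df_prior, df_pooled_sum),
      mod_t = .data$coef / (.data$unscaled_sd * sqrt(.data$mod_var)),
      p_raw = 2 * pt(-abs(.data$mod_t), df = .data$df_total)
    )
  eb$log_odds <- .log_odds(eb$mod_t, eb$unscaled_sd, eb$df_total,
                           prior$df_prior, prior$var_prior,
                           config$prior_proportion)
  eb$p_adj <- bh_adjust(eb$p_raw)
  structure(
    list(
      contrasts = eb,
      prior = prior
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>\n")
  cat(sprintf("  %d SNPs x %d mixture contrasts\n",
              dplyr::n_distinct(x$contrasts$snp_id),
              dplyr::n_distinct(x$contrasts$mixture_id)))
  cat(sprintf("  variance prior: d0 = %.3g, s0^2 = %.3g\n",
              x$prior$df_prior, x$prior$var_prior))
  invisible(x)
}

#' Tidy mixture contrasts
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return The per-SNP/mixture contrast tibble.
#' @export
tidy.mixture_fit <- function(x, ...) x$contrasts

#' Area under the ROC curve from ranking scores and truth labels
#'
#' Computes the AUC as the tie-corrected Mann-Whitney statistic (ties count
#' one half), together with the sensitivity/specificity curve at every
#' score threshold. Excluded SNPs must be removed before calling.
#'
#' @param scores Numeric ranking statistic (higher = more likely a true
#'   positive), e.g. the posterior log-odds.
#' @param labels Character labels, `"true_positive"`/`"true_negative"`.
#' @return List with `auc` and `curve` (tibble `threshold`, `sensitivity`,
#'   `specificity`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("true_positive", "true_negative")))
  is_tp <- labels == "true_positive"
  n_tp <- sum(is_tp)
  n_tn <- sum(!is_tp)
  if (n_tp == 0 || n_tn == 0) {
    abort("need at least one true positive and one true negative")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_tp]) - n_tp * (n_tp + 1) / 2) / (n_tp * n_tn)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[is_tp] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[!is_tp] < t),
                         numeric(1))
  )
  list(auc = auc, curve = curve)
}
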