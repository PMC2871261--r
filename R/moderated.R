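#' Intercept-only fit to replicate log-ratios
#'
#' Summarises the replicate cDNA log-ratios of one SNP in one sample with an
#' intercept-only linear model: the coefficient is the mean log-ratio, the
#' residual variance is the sample variance on `n - 1` degrees of freedom.
#' With a single replicate the variance is undefined; the fit then carries
#' zero residual degrees of freedom and its variance is later shrunk fully
#' to the empirical-Bayes prior.
#'
#' @param replicate_m Numeric vector of centred log-ratios (one per
#'   replicate array); at least one value.
#' @return A list with `coef`, `resid_var` (`NA` when `df_resid` is 0) and
#'   `df_resid`.
#' @examples
#' fit_snp_sample_model(c(1.0, 1.2))
#' @export
fit_snp_sample_model <- function(replicate_m) {
  if (length(replicate_m) == 0) abort("no replicate observations")
  stopifnot(all(is.finite(replicate_m)))
  n <- length(replicate_m)
  list(
    coef = mean(replicate_m),
    resid_var = if (n > 1) var(replicate_m) else NA_real_,
    df_resid = n - 1L
  )
}

# Newton inversion of the trigamma function (vectorised).
trigamma_inverse <- function(x) {
  stopifnot(all(is.finite(x)))
  out <- numeric(length(x))
  hi <- x > 1e7
  lo <- x < 1e-6
  out[hi] <- 1 / sqrt(x[hi])
  out[lo] <- 1 / x[lo]
  mid <- !hi & !lo
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Estimate the variance prior by moments of log sample variances
#'
#' Fits the scaled-F model underlying variance moderation: sample variances
#' `s_g^2` are assumed to follow `s0^2 * F(d_g, d0)`. Matching the mean and
#' variance of `log(s_g^2)` to the theoretical log-chi-square moments gives
#' closed-form estimates of the prior degrees of freedom `d0` and prior
#' variance `s0^2`. An infinite `d0` (all variances equal up to sampling
#' noise) is a valid outcome.
#'
#' @param resid_var Numeric vector of sample variances.
#' @param df_resid Residual degrees of freedom of each variance (>= 1; fits
#'   with 0 df are ignored here).
#' @return A list with `df_prior` (`d0`, possibly `Inf`) and `var_prior`
#'   (`s0^2`).
#' @export
fit_variance_prior <- function(resid_var, df_resid) {
  ok <- is.finite(resid_var) & df_resid >= 1
  s2 <- resid_var[ok]
  df <- df_resid[ok]
  if (length(s2) == 0) abort("no variances with positive degrees of freedom")
  if (all(s2 == 0)) {
    abort("all residual variances are zero; add jitter or use ordinary t")
  }
  if (any(s2 == 0)) {
    # exact zeros arise e.g. when one SNP sits at the array median on every
    # replicate; they carry no scale information and are left out
    if (mean(s2 == 0) > 0.01) {
      warn("more than 1% of sample variances are exactly zero; they are ignored when fitting the variance prior")
    }
    df <- df[s2 > 0]
    s2 <- s2[s2 > 0]
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

# Posterior (squeezed) variances given a fitted prior.
.squeeze_var <- function(resid_var, df_resid, df_prior, var_prior) {
  if (!is.finite(df_prior)) return(rep(var_prior, length(resid_var)))
  s2 <- ifelse(df_resid > 0, resid_var, 0)
  (df_prior * var_prior + df_resid * s2) / (df_prior + df_resid)
}

# Prior variance of the coefficient (v0) estimated from the top of the
# moderated-t distribution, for the posterior log-odds. Mirrors the standard
# target-quantile method: the largest `proportion/2 * n` |t| values are
# matched against the quantiles they would have under the two-component
# mixture model.
.tmixture_vector <- function(tstat, stdev_unscaled, df, proportion,
                             v0_lim = NULL) {
  ok <- is.finite(tstat)
  tstat <- tstat[ok]
  stdev_unscaled <- stdev_unscaled[ok]
  df <- df[ok]
  ngenes <- length(tstat)
  ntarget <- ceiling(proportion / 2 * ngenes)
  if (ntarget < 1) return(NA_real_)
  p <- max(ntarget / ngenes, proportion)
  tstat <- abs(tstat)
  max_df <- max(df)
  i <- df < max_df
  if (any(i)) {
    tail_p <- pt(tstat[i], df = df[i], lower.tail = FALSE, log.p = TRUE)
    tstat[i] <- qt(tail_p, df = max_df, lower.tail = FALSE, log.p = TRUE)
    df[i] <- max_df
  }
  o <- order(tstat, decreasing = TRUE)[seq_len(ntarget)]
  tstat <- tstat[o]
  v1 <- stdev_unscaled[o]^2
  r <- seq_len(ntarget)
  p0 <- 2 * pt(-tstat, df = max_df)
  ptarget <- ((r - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- rep(0, ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- qt(ptarget[pos] / 2, df = max_df, lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((tstat[pos] / qtarget)^2 - 1)
  }
  if (!is.null(v0_lim)) v0 <- pmin(pmax(v0, v0_lim[1]), v0_lim[2])
  mean(v0)
}

# Posterior log-odds of differential allelic expression (B-statistic).
# v0 (the coefficient prior variance) is estimated on the unscaled scale,
# i.e. relative to the residual variance, so it combines directly with
# stdev_unscaled^2.
.log_odds <- function(tstat, stdev_unscaled, df_total, df_prior, var_prior,
                      proportion) {
  v0 <- .tmixture_vector(tstat, stdev_unscaled, df_total, proportion,
                         v0_lim = c(0.1, 4)^2 / var_prior)
  if (!is.finite(v0) || v0 < 0) v0 <- 0
  r <- (stdev_unscaled^2 + v0) / stdev_unscaled^2
  t2 <- tstat^2
  if (is.finite(df_prior)) {
    kernel <- (1 + df_total) / 2 *
      log((t2 + df_total) / (t2 / r + df_total))
  } else {
    kernel <- t2 * (1 - 1 / r) / 2
  }
  log(proportion / (1 - proportion)) - log(r) / 2 + kernel
}

#' Empirical-Bayes moderation of replicate fits
#'
#' Takes the per-SNP/sample intercept-only fits of one analysis and computes
#' moderated t-statistics: the variance prior `(d0, s0^2)` is estimated from
#' all sample variances by [fit_variance_prior()], each variance is squeezed
#' towards the prior, and the t-statistic uses the posterior variance on
#' `d0 + d_g` degrees of freedom. Two-sided p-values are returned along with
#' the posterior log-odds of differential allelic expression (B-statistic,
#' prior proportion `proportion`), which is used only for ranking.
#'
#' When fewer than 10 fits carry positive residual degrees of freedom the
#' prior cannot be estimated reliably; the function falls back to ordinary
#' t-statistics with a warning.
#'
#' @param fits Tibble with columns `coef`, `resid_var`, `df_resid` and
#'   `unscaled_sd` (standard-error multiplier of the coefficient; `1/sqrt(n)`
#'   for an intercept-only fit with `n` replicates).
#' @param proportion Prior proportion of truly imbalanced tests for the
#'   B-statistic.
#' @return The input tibble with added columns `df_prior`, `var_prior`,
#'   `mod_var`, `mod_t`, `df_total`, `p_raw`, `log_odds`.
#' @export
ebayes_moderate <- function(fits, proportion = 0.01) {
  stopifnot(all(c("coef", "resid_var", "df_resid", "unscaled_sd") %in%
                  names(fits)))
  n_inform <- sum(fits$df_resid >= 1 & is.finite(fits$resid_var))
  if (n_inform < 10) {
    warn("fewer than 10 informative variances; using ordinary t-statistics")
    out <- fits %>%
      mutate(
        df_prior = 0,
        var_prior = NA_real_,
        mod_var = .data$resid_var,
        df_total = as.numeric(.data$df_resid),
        mod_t = ifelse(.data$df_resid > 0,
                       .data$coef / (.data$unscaled_sd *
                                       sqrt(.data$resid_var)),
                       NA_real_),
        p_raw = 2 * pt(-abs(.data$mod_t), df = .data$df_total),
        log_odds = NA_real_
      )
    return(out)
  }
  prior <- fit_variance_prior(fits$resid_var, fits$df_resid)
  mod_var <- .squeeze_var(fits$resid_var, fits$df_resid,
                          prior$df_prior, prior$var_prior)
  df_total <- pmin(fits$df_resid + prior$df_prior,
                   sum(fits$df_resid, na.rm = TRUE))
  mod_t <- fits$coef / (fits$unscaled_sd * sqrt(mod_var))
  p_raw <- 2 * pt(-abs(mod_t), df = df_total)
  log_odds <- .log_odds(mod_t, fits$unscaled_sd, df_total,
                        prior$df_prior, prior$var_prior, proportion)
  fits %>%
    mutate(
      df_prior = prior$df_prior,
      var_prior = prior$var_prior,
      mod_var = mod_var,
      df_total = df_total,
      mod_t = mod_t,
      p_raw = p_raw,
      log_odds = log_odds
    )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false-discovery-rate adjustment: p-values are sorted
#' ascending, each is multiplied by `n/rank`, monotonicity is enforced by a
#' cumulative minimum from the largest rank down, and results are capped at
#' 1 and returned in the original order. Adjustment is global across all
#' tests of one analysis.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    abort("p-values must lie in [0, 1]")
  }
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE, na.last = FALSE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p_values[o]))[ro]
  adj[is.na(p_values)] <- NA_real_
  adj
}

#' Pearson correlation of paired log-ratios across platforms
#'
#' Standard Pearson correlation used to compare allelic quantification of
#' the same samples on two platforms. For count-like allelotyping data the
#' log-ratios should first be formed with [pseudo_log_ratio()].
#'
#' @param log_ratios_x,log_ratios_y Paired finite numeric vectors, length
#'   at least 3.
#' @return Pearson r.
#' @export
platform_correlation <- function(log_ratios_x, log_ratios_y) {
  stopifnot(length(log_ratios_x) == length(log_ratios_y))
  if (length(log_ratios_x) < 3) abort("need at least 3 pairs")
  stopifnot(all(is.finite(log_ratios_x)), all(is.finite(log_ratios_y)))
  if (sd(log_ratios_x) == 0 || sd(log_ratios_y) == 0) {
    abort("correlation undefined: zero variance in one vector")
  }
  cor(log_ratios_x, log_ratios_y)
}

#' Pseudo-count log-ratio for allelotyping signal pairs
#'
#' `log2((x + 1) / (y + 1))`: the +1 pseudo-count keeps ratios finite when
#' one allele signal is zero.
#'
#' @param x,y Non-negative numeric vectors of the two allele signals.
#' @return Numeric vector of log2 ratios.
#' @export
pseudo_log_ratio <- function(x, y) {
  stopifnot(all(x >= 0), all(y >= 0))
  log2((x + 1) / (y + 1))
}
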