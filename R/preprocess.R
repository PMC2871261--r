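#' Quantile-normalise the two channels of one array
#'
#' Forces the empirical distributions of the two fluorescence channels of a
#' single array to be identical: both channels are mapped onto the mean of
#' the two sorted intensity vectors, preserving within-channel rank order.
#' Ties receive the mean of their target quantiles. This removes global
#' channel (dye) differences before log-ratios are formed.
#'
#' @param a_values,b_values Equal-length numeric vectors of positive raw
#'   intensities: all beads of one array, channel A and channel B.
#' @return A list with components `a` and `b`, the normalised vectors in the
#'   original order.
#' @examples
#' quantile_normalize_channels(c(1, 2, 3), c(2, 4, 6))
#' @export
quantile_normalize_channels <- function(a_values, b_values) {
  if (length(a_values) != length(b_values)) {
    abort("channel vectors must have equal length")
  }
  stopifnot(length(a_values) >= 1, all(is.finite(a_values)),
            all(is.finite(b_values)))
  target <- (sort(a_values) + sort(b_values)) / 2
  map_to <- function(x) {
    r <- rank(x, ties.method = "average")
    if (length(target) == 1) return(rep(target, length(x)))
    approx(seq_along(target), target, xout = r)$y
  }
  list(a = map_to(a_values), b = map_to(b_values))
}

#' Per-bead log-ratio and average log-intensity
#'
#' Computes the two standard coordinates of a two-channel measurement:
#' `m = log2(intensity_a / intensity_b)` (allelic log-ratio) and
#' `a = 0.5 * log2(intensity_a * intensity_b)` (average log-intensity).
#'
#' @param intensity_a,intensity_b Positive numeric vectors.
#' @return A list with numeric components `m` and `a`.
#' @examples
#' bead_m_a(8, 2) # m = 2, a = 2
#' @export
bead_m_a <- function(intensity_a, intensity_b) {
  if (any(intensity_a <= 0) || any(intensity_b <= 0)) {
    abort("intensities must be positive; clip non-positive values first")
  }
  list(
    m = log2(intensity_a / intensity_b),
    a = 0.5 * log2(intensity_a * intensity_b)
  )
}

#' Summarise one bead type with MAD outlier removal
#'
#' Removes values further than `mad_k` median-absolute-deviations from the
#' median of the bead type and averages the survivors. The MAD here is the
#' unscaled median absolute deviation about the median (no 1.4826
#' consistency factor), matching the plain meaning of "MAD". When the MAD is
#' zero (constant beads) nothing is removed, so a bead set is never deleted
#' wholesale.
#'
#' @param values Numeric vector of per-bead values (M or A) for one bead
#'   type on one array; at least one value.
#' @param mad_k Positive multiplier (default 3).
#' @return A list with `mean` (mean of retained values) and `n_removed`.
#' @examples
#' summarize_bead_type(c(rep(0, 29), 10))
#' @export
summarize_bead_type <- function(values, mad_k = 3) {
  if (length(values) == 0) abort("empty bead set")
  stopifnot(all(is.finite(values)), mad_k > 0)
  med <- median(values)
  mad0 <- median(abs(values - med))
  keep <- if (mad0 > 0) abs(values - med) <= mad_k * mad0
          else rep(TRUE, length(values))
  list(mean = mean(values[keep]), n_removed = sum(!keep))
}

#' Median-centre the log-ratios of one array
#'
#' @param m_values Numeric vector of summarised log-ratios on one array.
#' @return The input minus its median (output median is zero).
#' @export
median_center <- function(m_values) {
  stopifnot(length(m_values) >= 1, all(is.finite(m_values)))
  m_values - median(m_values)
}

# Internal: vectorised MAD-filtered mean + removal count per group.
# values are already ordered by group; idx is the group factor.
.mad_summarise <- function(values, mad_k) {
  med <- median(values)
  mad0 <- median(abs(values - med))
  keep <- if (mad0 > 0) abs(values - med) <= mad_k * mad0
          else rep(TRUE, length(values))
  c(mean(values[keep]), sum(!keep))
}

#' Preprocess the beads of one array
#'
#' Runs the fixed preprocessing pipeline for a single array (one sample
#' hybridisation): between-channel quantile normalisation over all beads of
#' the array jointly, per-bead (M, A) computation, per-SNP MAD outlier
#' removal and averaging (M and A filtered independently), and finally
#' median-centring of the summarised M values across the SNPs of the array
#' (A is summarised but not centred).
#'
#' @param beads Tibble of bead measurements for one `sample_id`/`array_id`
#'   combination, with columns `snp_id`, `sample_id`, `array_id`,
#'   `intensity_a`, `intensity_b`.
#' @param config An [ase_config()]; only `mad_k` is used here.
#' @return Tibble with one row per SNP: `snp_id`, `sample_id`, `array_id`,
#'   `m`, `a`, `n_beads_used`, `n_beads_removed`.
#' @export
preprocess_array <- function(beads, config = ase_config()) {
  stopifnot(all(c("snp_id", "sample_id", "array_id",
                  "intensity_a", "intensity_b") %in% names(beads)))
  if (nrow(beads) == 0) abort("no beads supplied")
  if (dplyr::n_distinct(beads$sample_id) != 1 ||
      dplyr::n_distinct(beads$array_id) != 1) {
    abort("preprocess_array() expects the beads of exactly one array")
  }
  qn <- quantile_normalize_channels(beads$intensity_a, beads$intensity_b)
  ma <- bead_m_a(qn$a, qn$b)
  k <- config$mad_k
  out <- tibble(
    snp_id = beads$snp_id,
    m_bead = ma$m,
    a_bead = ma$a
  ) %>%
    group_by(.data$snp_id) %>%
    summarise(
      m = .mad_summarise(.data$m_bead, k)[1],
      n_beads_removed = .mad_summarise(.data$m_bead, k)[2],
      a = .mad_summarise(.data$a_bead, k)[1],
      n_beads_used = dplyr::n() - .data$n_beads_removed,
      .groups = "drop"
    ) %>%
    mutate(
      sample_id = beads$sample_id[1],
      array_id = beads$array_id[1],
      m = median_center(.data$m)
    ) %>%
    select("snp_id", "sample_id", "array_id", "m", "a",
           "n_beads_used", "n_beads_removed")
  out
}

#' Preprocess a full bead table
#'
#' Applies [preprocess_array()] to every array (every `sample_id` x
#' `array_id` combination) of a bead table and binds the results.
#'
#' @param beads Bead tibble as returned by [read_bead_table()] or
#'   [simulate_study()].
#' @param config An [ase_config()].
#' @return Tibble of per-SNP/sample/array summaries (columns as in
#'   [preprocess_array()]).
#' @export
preprocess_beads <- function(beads, config = ase_config()) {
  stopifnot(all(c("snp_id", "sample_id", "array_id",
                  "intensity_a", "intensity_b") %in% names(beads)))
  beads %>%
    dplyr::group_split(.data$sample_id, .data$array_id) %>%
    purrr::map(preprocess_array, config = config) %>%
    bind_rows()
}
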