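#' Threshold genotype calling from gDNA log-ratios
#'
#' Calls genotypes from genomic-DNA allelic log-ratios with a fixed symmetric
#' margin: `m >= +margin` is `AA`, `m <= -margin` is `BB`, values strictly
#' inside the margin are `AB`, and non-finite input is `NN`. Boundary values
#' are assigned to the homozygote side. This deterministic rule replaces
#' cluster-based callers and is adequate when the three genotype clusters are
#' well separated on the log-ratio axis, as they are for genomic DNA.
#'
#' @param m Numeric vector of gDNA log-ratios (log2 units, allele A over
#'   allele B).
#' @param margin Positive log2 margin (default 1.5).
#' @return Character vector of calls in `AA`, `AB`, `BB`, `NN`.
#' @examples
#' call_genotype(c(2.4, 0, -1.5, NA))
#' @export
call_genotype <- function(m, margin = 1.5) {
  stopifnot(is.numeric(m), margin > 0)
  out <- rep("NN", length(m))
  fin <- is.finite(m)
  out[fin & m >= margin] <- "AA"
  out[fin & m <= -margin] <- "BB"
  out[fin & abs(m) < margin] <- "AB"
  out
}

#' Call genotypes for every SNP x sample from summarised gDNA data
#'
#' Averages the summarised log-ratio over replicate arrays of each gDNA
#' sample, then applies [call_genotype()].
#'
#' @param summaries Tibble of per-SNP/sample/array summaries with columns
#'   `snp_id`, `sample_id`, `m` (e.g. from [preprocess_beads()]).
#' @param samples Optional character vector restricting to these sample ids
#'   (typically the gDNA samples of the pedigree).
#' @param margin Log2 margin passed to [call_genotype()].
#' @return Tibble with `snp_id`, `sample_id`, `m_gdna`, `call`.
#' @export
call_genotypes <- function(summaries, samples = NULL, margin = 1.5) {
  stopifnot(all(c("snp_id", "sample_id", "m") %in% names(summaries)))
  tbl <- summaries
  if (!is.null(samples)) tbl <- filter(tbl, .data$sample_id %in% samples)
  tbl %>%
    group_by(.data$snp_id, .data$sample_id) %>%
    summarise(m_gdna = mean(.data$m), .groups = "drop") %>%
    mutate(call = call_genotype(.data$m_gdna, margin = margin))
}

.allele_pairs <- list(
  AA = c("A", "A"), AB = c("A", "B"), BB = c("B", "B")
)

#' Mendelian consistency check for a trio
#'
#' A child genotype is consistent when it can be formed by taking one allele
#' from the mother and one from the father. Any `NN` among the three calls
#' makes the trio indeterminate (missing data is never flagged as an error).
#' Vectorised over trios.
#'
#' @param child,mother,father Character vectors of genotype calls
#'   (`AA`/`AB`/`BB`/`NN`). Use `NN` for an absent parent.
#' @return Character vector: `"consistent"`, `"inconsistent"` or
#'   `"indeterminate"`.
#' @examples
#' check_mendelian("AB", "AA", "BB")
#' check_mendelian("AA", "BB", "BB")
#' @export
check_mendelian <- function(child, mother, father) {
  n <- length(child)
  stopifnot(length(mother) == n, length(father) == n)
  valid <- c("AA", "AB", "BB", "NN")
  stopifnot(all(child %in% valid), all(mother %in% valid),
            all(father %in% valid))
  out <- character(n)
  for (i in seq_len(n)) {
    if (child[i] == "NN" || mother[i] == "NN" || father[i] == "NN") {
      out[i] <- "indeterminate"
      next
    }
    ca <- .allele_pairs[[child[i]]]
    ma <- .allele_pairs[[mother[i]]]
    fa <- .allele_pairs[[father[i]]]
    ok <- FALSE
    for (x in ma) {
      for (y in fa) {
        if (identical(sort(c(x, y)), sort(ca))) ok <- TRUE
      }
    }
    out[i] <- if (ok) "consistent" else "inconsistent"
  }
  out
}

#' Identify informative heterozygous trios for a SNP
#'
#' A trio is informative for allelic readout when the placental gDNA is
#' heterozygous (`AB`). It is additionally origin-informative when at least
#' one parent is homozygous, since then the parental origin of the expressed
#' allele can be deduced; with an absent father, a homozygous mother is
#' sufficient (the untransmitted maternal allele implies the paternal one).
#'
#' @param snp A single SNP id.
#' @param trios Pedigree tibble as returned by [read_pedigree()].
#' @param genotypes Genotype tibble with `snp_id`, `sample_id`, `call`.
#' @return The subset of `trios` with heterozygous placental gDNA, with
#'   added columns `child_call`, `mother_call`, `father_call`,
#'   `origin_informative`.
#' @export
informative_hets <- function(snp, trios, genotypes) {
  stopifnot(length(snp) == 1)
  gt <- filter(genotypes, .data$snp_id == snp)
  lookup <- setNames(gt$call, gt$sample_id)
  get_call <- function(ids) {
    out <- unname(lookup[ids])
    out[is.na(out)] <- "NN"
    out
  }
  res <- trios %>%
    mutate(
      child_call = get_call(.data$placenta_gdna),
      mother_call = get_call(.data$mother_gdna),
      father_call = ifelse(is.na(.data$father_gdna), "NN",
                           get_call(.data$father_gdna))
    ) %>%
    filter(.data$child_call == "AB") %>%
    mutate(origin_informative = .data$mother_call %in% c("AA", "BB") |
             .data$father_call %in% c("AA", "BB"))
  res
}
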