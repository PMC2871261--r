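#' Read a bead-level intensity table
#'
#' Reads a TSV of raw per-bead two-channel fluorescence measurements, one row
#' per bead. Required columns: `snp_id`, `sample_id`, `array_id`,
#' `intensity_a`, `intensity_b`. Beads with non-positive intensities are
#' floor-clipped to `floor` so that downstream log-ratios stay finite; the
#' number of clipped values is attached as attribute `n_clipped` and a
#' warning is raised when any clipping happened.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param floor Positive value substituted for non-positive intensities.
#' @return A tibble of bead measurements.
#' @export
read_bead_table <- function(path, floor = 1.0) {
  stopifnot(file.exists(path), floor > 0)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("snp_id", "sample_id", "array_id", "intensity_a", "intensity_b")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("bead table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) abort("bead table contains no data rows")
  tbl <- tbl %>%
    mutate(
      snp_id = as.character(.data$snp_id),
      sample_id = as.character(.data$sample_id),
      array_id = as.character(.data$array_id)
    )
  if (any(!nzchar(tbl$snp_id)) || any(!nzchar(tbl$sample_id)) ||
      any(!nzchar(tbl$array_id))) {
    abort("bead table identifiers must be non-empty")
  }
  n_clipped <- sum(tbl$intensity_a <= 0) + sum(tbl$intensity_b <= 0)
  if (n_clipped > 0) {
    tbl$intensity_a[tbl$intensity_a <= 0] <- floor
    tbl$intensity_b[tbl$intensity_b <= 0] <- floor
    warn(sprintf("%d non-positive intensities floor-clipped to %g",
                 n_clipped, floor))
  }
  attr(tbl, "n_clipped") <- n_clipped
  tbl
}

#' Read a trio pedigree file
#'
#' Reads a PED-like TSV linking the samples of each family trio: placental
#' genomic DNA, placental cDNA, maternal gDNA and paternal gDNA. A `-` in the
#' father column marks an absent father (such trios remain usable: when the
#' mother is homozygous the untransmitted maternal allele implies the
#' paternal one).
#'
#' @param path Path to a tab-separated file with header columns `family_id`,
#'   `placenta_gdna`, `placenta_cdna`, `mother_gdna`, `father_gdna`.
#' @return A tibble with one row per trio; absent fathers are `NA`.
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("family_id", "placenta_gdna", "placenta_cdna",
                "mother_gdna", "father_gdna")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("pedigree is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl %>% mutate(dplyr::across(dplyr::all_of(required),
                                      ~ dplyr::na_if(.x, "-")))
  if (anyDuplicated(tbl$family_id)) {
    abort("duplicated family_id in pedigree")
  }
  if (any(is.na(tbl$placenta_gdna)) || any(is.na(tbl$placenta_cdna))) {
    abort("placenta gDNA and cDNA samples are required for every trio")
  }
  tbl
}

#' Read a genotype call table
#'
#' @param path TSV with columns `snp_id`, `sample_id`, `call`; calls must be
#'   one of `AA`, `AB`, `BB`, `NN` (`NN` = missing/uncallable).
#' @return A tibble of genotype calls.
#' @export
read_genotype_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("snp_id", "sample_id", "call")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("genotype table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$call), c("AA", "AB", "BB", "NN"))
  if (length(bad) > 0) {
    abort(paste0("invalid genotype call(s): ", paste(bad, collapse = ", ")))
  }
  tbl
}
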