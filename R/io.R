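paired_cohort_cols <- function() {
  c("pair_id",
    "patient_id", "patient_population", paste0("patient_", genotype_cols()),
    "donor_id", "donor_population", paste0("donor_", genotype_cols()))
}

#' Write a paired patient-donor cohort to CSV
#'
#' The bulk paired patient-donor format: one row per transplant pair with
#' `pair_id`, per-party `id` and `population`, and the ten per-party
#' genotype columns (`patient_A_1`, ..., `donor_DQB1_2`).
#'
#' @param pairs Pair tibble (see [pair_cohorts()]).
#' @param path Output CSV path.
#' @return `pairs`, invisibly.
#' @export
write_paired_cohort <- function(pairs, path) {
  cols <- intersect(paired_cohort_cols(), names(pairs))
  missing_cols <- setdiff(paired_cohort_cols(), cols)
  if (length(missing_cols)) {
    abort(paste0("Missing paired-cohort column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(pairs[, cols], path)
  invisible(pairs)
}

#' Read a paired patient-donor cohort CSV
#'
#' @param path CSV path in the format written by [write_paired_cohort()].
#' @return A pair tibble with validated, canonically ordered genotypes.
#' @export
read_paired_cohort <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(paired_cohort_cols(), names(out))
  if (length(missing_cols)) {
    abort(paste0("Missing paired-cohort column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (party in c("patient", "donor")) {
    cols <- paste0(party, "_", genotype_cols())
    g <- out[, cols]
    names(g) <- genotype_cols()
    parse_allele(unlist(g, use.names = FALSE))  # validation
    g <- reduce_check_sort(g)
    names(g) <- cols
    out[, cols] <- g
  }
  out
}

# canonical within-locus sorting without resolution change
reduce_check_sort <- function(g) {
  for (locus in hla_loci()) {
    c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
    bad <- !startsWith(g[[c1]], paste0(locus, "*")) |
      !startsWith(g[[c2]], paste0(locus, "*"))
    if (any(bad)) {
      abort(paste0("Allele in the wrong locus column at row(s): ",
                   paste(which(bad), collapse = ", ")))
    }
    a <- g[[c1]]; b <- g[[c2]]
    swap <- a > b
    g[[c1]] <- ifelse(swap, b, a)
    g[[c2]] <- ifelse(swap, a, b)
  }
  g
}
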