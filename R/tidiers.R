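#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an imputation result
#'
#' @param x An `hla_imputation`.
#' @param ... Unused.
#' @return The candidate tibble with `population` and `failed` columns
#'   prepended (zero rows for failed results).
#' @method tidy hla_imputation
#' @export
tidy.hla_imputation <- function(x, ...) {
  if (x$failed) {
    return(tibble(population = x$population, failed = TRUE,
                  rank = integer(0), h1 = character(0), h2 = character(0),
                  weight = numeric(0), fallback_level = integer(0))[0, ])
  }
  mutate(x$candidates, population = x$population, failed = FALSE, .before = 1L)
}

#' Glance at an imputation result
#'
#' @param x An `hla_imputation`.
#' @param ... Unused.
#' @return One-row tibble: `population`, `mode`, `strict`, `failed`,
#'   `n_candidates`, `top_weight`, `fallback_level`.
#' @method glance hla_imputation
#' @export
glance.hla_imputation <- function(x, ...) {
  tibble(population = x$population, mode = x$mode, strict = x$strict,
         failed = x$failed,
         n_candidates = if (x$failed) 0L else nrow(x$candidates),
         top_weight = if (x$failed) NA_real_ else x$candidates$weight[1L],
         fallback_level = if (x$failed) NA_integer_ else x$candidates$fallback_level[1L])
}

#' Tidy a study object
#'
#' @param x An `hla_study`.
#' @param ... Unused.
#' @return The per-pair deviation records tibble.
#' @method tidy hla_study
#' @export
tidy.hla_study <- function(x, ...) x$records

#' Glance at a study object
#'
#' @param x An `hla_study`.
#' @param ... Unused.
#' @return One-row tibble of headline study quantities: pair and assumption
#'   counts, failure rates and mean allele mismatch by assumption class,
#'   and noticeable-deviation proportions (multiple imputation) by class.
#' @method glance hla_study
#' @export
glance.hla_study <- function(x, ...) {
  m <- x$summary$marginals
  pick <- function(metric, class) {
    v <- m$value[m$metric == metric & m$assumption_class == class]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  tibble(
    n_pairs = nrow(x$pairs),
    n_assumptions = nrow(x$assumptions),
    failure_rate_matched = pick("failure_rate", "matched"),
    failure_rate_mismatched = pick("failure_rate", "mismatched"),
    mean_allele_mismatch_matched = pick("mean_allele_mismatch", "matched"),
    mean_allele_mismatch_mismatched = pick("mean_allele_mismatch", "mismatched"),
    noticeable_matched = pick("noticeable_proportion", "matched"),
    noticeable_mismatched = pick("noticeable_proportion", "mismatched")
  )
}
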