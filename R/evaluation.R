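#' Count allele-level mismatches between two genotypes
#'
#' Per locus, the mismatch count is `2 - |multiset intersection|` of the
#' two unordered allele pairs; the total over the five loci lies in
#' `[0, 10]`.
#'
#' @param truth,imputed High-resolution genotypes (see [as_genotype()]), or
#'   data frames of genotype columns compared row-wise.
#' @return Integer vector of mismatch counts.
#' @export
#' @examples
#' g <- genotype_from_haplotypes(
#'   "A*01:01~C*01:01~B*01:01~DRB1*01:01~DQB1*01:01",
#'   "A*02:01~C*02:01~B*02:01~DRB1*02:01~DQB1*02:01")
#' count_allele_mismatches(g, g)
count_allele_mismatches <- function(truth, imputed) {
  if (!is.data.frame(truth)) truth <- as_tibble(as.list(as_genotype(truth)))
  if (!is.data.frame(imputed)) imputed <- as_tibble(as.list(as_genotype(imputed)))
  if (nrow(truth) != nrow(imputed)) abort("Row counts differ.")
  th <- is_high_resolution(unlist(truth[, genotype_cols()]))
  ih <- is_high_resolution(unlist(imputed[, genotype_cols()]))
  if (any(th != ih)) abort("Resolution mismatch between `truth` and `imputed`.")
  total <- integer(nrow(truth))
  for (locus in hla_loci()) {
    t1 <- truth[[paste0(locus, "_1")]]; t2 <- truth[[paste0(locus, "_2")]]
    i1 <- imputed[[paste0(locus, "_1")]]; i2 <- imputed[[paste0(locus, "_2")]]
    # multiset intersection of two sorted pairs
    inter <- pmax((t1 == i1) + (t2 == i2), (t1 == i2) + (t2 == i1))
    total <- total + (2L - inter)
  }
  total
}

#' Log-delta between a ground-truth and an imputed mismatch score
#'
#' `log(truth + offset) - log(imputed + offset)`. The +1 offset keeps the
#' delta finite when a score is 0 (e.g. a true score of 5 imputed as 0
#' gives `log(6) ~ 1.79`: drastic but finite), and is the package's default
#' smoothing; a smaller `offset` approaches the raw log-ratio.
#'
#' @param truth_score,imputed_score Non-negative numeric vectors.
#' @param offset Positive smoothing constant added before the log
#'   (default 1).
#' @return Numeric vector of log-deltas.
#' @export
#' @examples
#' log_delta(5, 0)
log_delta <- function(truth_score, imputed_score, offset = 1) {
  if (any(truth_score < 0, na.rm = TRUE) || any(imputed_score < 0, na.rm = TRUE)) {
    abort("Mismatch scores must be non-negative.")
  }
  if (offset <= 0) abort("`offset` must be > 0.")
  log(truth_score + offset) - log(imputed_score + offset)
}

#' Proportion of noticeable deviations per group
#'
#' A deviation record is "noticeable" when `|log_delta|` exceeds the
#' threshold (default 0.1). Groups with no records are absent from the
#' output rather than reported as 0.
#'
#' @param records Tibble with a `log_delta` column.
#' @param by Character vector of grouping columns (default none: one
#'   overall row).
#' @param threshold Noticeable-deviation threshold on `|log_delta|`
#'   (default 0.1).
#' @return A tibble of the grouping columns plus `n` and
#'   `noticeable_proportion`.
#' @export
noticeable_proportion <- function(records, by = NULL, threshold = 0.1) {
  if (!"log_delta" %in% names(records)) abort("`records` needs a `log_delta` column.")
  records |>
    filter(!is.na(.data$log_delta)) |>
    group_by(across(all_of(by %||% character(0)))) |>
    summarise(n = n(),
              noticeable_proportion = mean(abs(.data$log_delta) > threshold),
              .groups = "drop")
}

#' Allele-call evaluation table for one imputation result
#'
#' Builds the per-(locus, allele) binary-classification view of one
#' individual's imputation: the candidate universe at a locus is every
#' allele appearing in the truth pair or in any candidate genotype; the
#' predicted probability of an allele is the sum of normalized candidate
#' weights whose genotype carries it (capped at 1); the label is membership
#' in the truth pair; `called` is membership in the single-imputation
#' (top-candidate) pair.
#'
#' @param truth High-resolution truth genotype.
#' @param result An `hla_imputation` (multiple mode recommended; the top
#'   candidate provides the single-imputation call).
#' @return Tibble with columns `locus`, `allele`, `label`, `probability`,
#'   `called`; zero rows for failed results.
#' @export
allele_call_evaluation <- function(truth, result) {
  stopifnot(inherits(result, "hla_imputation"))
  if (result$failed) {
    return(tibble(locus = character(0), allele = character(0),
                  label = logical(0), probability = numeric(0), called = logical(0)))
  }
  truth <- as_genotype(truth)
  cand_g <- haplotypes_to_genotype_tbl(result$candidates$h1, result$candidates$h2)
  w <- result$candidates$weight
  out <- vector("list", 5L)
  for (li in seq_along(hla_loci())) {
    locus <- hla_loci()[li]
    c1 <- cand_g[[paste0(locus, "_1")]]; c2 <- cand_g[[paste0(locus, "_2")]]
    t_pair <- unname(truth[paste0(locus, c("_1", "_2"))])
    universe <- unique(c(t_pair, c1, c2))
    prob <- vapply(universe, function(a) {
      min(1, sum(w[c1 == a | c2 == a]))
    }, numeric(1))
    out[[li]] <- tibble(locus = locus, allele = universe,
                        label = universe %in% t_pair,
                        probability = unname(prob),
                        called = universe %in% c(c1[1L], c2[1L]))
  }
  list_rbind(out)
}

binary_f1 <- function(label, called, positive) {
  tp <- sum(label == positive & called == positive)
  fp <- sum(label != positive & called == positive)
  fn <- sum(label == positive & called != positive)
  if (tp + fp == 0 || tp + fn == 0) return(if (tp + fn == 0) NA_real_ else 0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Classification metrics over allele-call evaluations
#'
#' Computes the four imputation-performance metrics on a pooled
#' allele-call table (see [allele_call_evaluation()]): rank-based AUC of
#' the predicted allele probabilities against the labels, Brier score
#' (mean squared probability error), label-weighted F1 and balanced
#' accuracy of the single-imputation calls. A degenerate single-class
#' label set yields `NA` for AUC and balanced accuracy.
#'
#' @param evals Tibble with columns `label`, `probability`, `called`.
#' @return One-row tibble: `n`, `auc`, `brier`, `weighted_f1`,
#'   `balanced_accuracy`.
#' @export
classification_metrics <- function(evals) {
  need <- c("label", "probability", "called")
  if (!all(need %in% names(evals))) {
    abort(paste0("`evals` needs columns ", paste(need, collapse = ", "), "."))
  }
  lab <- as.logical(evals$label)
  prob <- evals$probability
  called <- as.logical(evals$called)
  auc <- if (length(unique(lab)) < 2L) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(response = lab, predictor = prob,
                                   quiet = TRUE, direction = "<",
                                   levels = c(FALSE, TRUE))))
  }
  brier <- mean((prob - as.numeric(lab))^2)
  f1_pos <- binary_f1(lab, called, TRUE)
  f1_neg <- binary_f1(lab, called, FALSE)
  support <- c(sum(lab), sum(!lab))
  f1s <- c(f1_pos, f1_neg)
  ok <- !is.na(f1s) & support > 0
  weighted_f1 <- if (any(ok)) sum(f1s[ok] * support[ok]) / sum(support[ok]) else NA_real_
  sens <- if (sum(lab) > 0) sum(called & lab) / sum(lab) else NA_real_
  spec <- if (sum(!lab) > 0) sum(!called & !lab) / sum(!lab) else NA_real_
  tibble(n = length(lab), auc = auc, brier = brier,
         weighted_f1 = weighted_f1, balanced_accuracy = (sens + spec) / 2)
}

#' Reliability percentile curve of absolute log-deltas
#'
#' Sorts `|log_delta|` ascending and reports, for each cumulative
#' percentile `p`, the value at rank `ceiling(p * n)` (clamped to
#' `[1, n]`): the maximum deviation observed within the best `p` fraction
#' of cases. The curve is non-decreasing and its right endpoint is the
#' maximum absolute deviation.
#'
#' @param log_deltas Numeric vector of log-deltas (or a records tibble with
#'   a `log_delta` column).
#' @param percentiles Increasing percentiles in `(0, 1]`.
#' @return Tibble with columns `percentile`, `max_abs_log_delta`.
#' @export
reliability_curve <- function(log_deltas,
                              percentiles = c(0.5, 0.75, 0.9, 0.95, 0.99, 1)) {
  if (is.data.frame(log_deltas)) log_deltas <- log_deltas$log_delta
  log_deltas <- log_deltas[!is.na(log_deltas)]
  if (length(log_deltas) == 0) abort("No log-deltas to summarize.")
  if (any(percentiles <= 0 | percentiles > 1) || is.unsorted(percentiles, strictly = TRUE)) {
    abort("`percentiles` must be strictly increasing within (0, 1].")
  }
  v <- sort(abs(log_deltas))
  n <- length(v)
  rank <- pmin(pmax(ceiling(percentiles * n), 1L), n)
  tibble(percentile = percentiles, max_abs_log_delta = v[rank])
}
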