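gt <- function(...) {
  g <- c(...)
  names(g) <- genotype_cols()
  as_genotype(g)
}

full_het <- gt("A*01:01", "A*02:01", "C*01:01", "C*02:01", "B*01:01", "B*02:01",
               "DRB1*01:01", "DRB1*02:01", "DQB1*01:01", "DQB1*02:01")

test_that("allele mismatches use per-locus multiset intersections", {
  expect_equal(count_allele_mismatches(full_het, full_het), 0L)
  # truth A*01:01/A*02:01 vs called A*01:01/A*01:01 -> one mismatch
  called <- full_het
  called[c("A_1", "A_2")] <- c("A*01:01", "A*01:01")
  expect_equal(count_allele_mismatches(full_het, called), 1L)
  # overlapping but unequal pairs: {01, 02} vs {02, 03} share one allele
  called2 <- full_het
  called2[c("A_1", "A_2")] <- c("A*02:01", "A*03:01")
  expect_equal(count_allele_mismatches(full_het, called2), 1L)
  # fully discordant at all five loci
  other <- gt("A*03:01", "A*04:01", "C*03:01", "C*04:01", "B*03:01", "B*04:01",
              "DRB1*03:01", "DRB1*04:01", "DQB1*03:01", "DQB1*04:01")
  expect_equal(count_allele_mismatches(full_het, other), 10L)
  # resolution mismatch is an error
  expect_error(count_allele_mismatches(full_het, reduce_to_first_field(full_het)),
               "Resolution")
})

test_that("log-deltas are smoothed, antisymmetric, and reject negatives", {
  expect_equal(log_delta(3, 3), 0)
  expect_equal(log_delta(5, 0), log(6))
  expect_equal(log_delta(0, 5), -log(6))
  expect_equal(log_delta(5, 0), -log_delta(0, 5))
  expect_error(log_delta(-1, 0), "non-negative")
  # smaller offset approaches the raw log ratio
  expect_equal(log_delta(10, 5, offset = 1e-9), log(10 / 5), tolerance = 1e-6)
})

test_that("noticeable proportions are grouped and threshold-driven", {
  rec <- tibble::tibble(group = c("a", "a", "a", "a", "b"),
                        log_delta = c(0.05, 0.15, 0.2, 0.0, -0.5))
  out <- noticeable_proportion(rec, by = "group")
  expect_equal(out$noticeable_proportion[out$group == "a"], 0.5)
  expect_equal(out$noticeable_proportion[out$group == "b"], 1)
  # huge threshold -> nothing noticeable
  out2 <- noticeable_proportion(rec, by = "group", threshold = Inf)
  expect_true(all(out2$noticeable_proportion == 0))
  # groups with no records are absent, not zero
  expect_false("c" %in% out$group)
  # sign does not matter
  expect_equal(noticeable_proportion(tibble::tibble(log_delta = c(-0.2, 0.2)))$
                 noticeable_proportion, 1)
})

test_that("classification metrics reproduce their closed forms", {
  # perfect degenerate predictions
  perfect <- tibble::tibble(label = c(TRUE, FALSE, TRUE, FALSE),
                            probability = c(1, 0, 1, 0),
                            called = c(TRUE, FALSE, TRUE, FALSE))
  m <- classification_metrics(perfect)
  expect_equal(m$brier, 0)
  expect_equal(m$weighted_f1, 1)
  expect_equal(m$balanced_accuracy, 1)
  expect_equal(m$auc, 1)

  # probability one-half on balanced labels
  half <- tibble::tibble(label = rep(c(TRUE, FALSE), 10),
                         probability = 0.5, called = rep(c(TRUE, FALSE), 10))
  expect_equal(classification_metrics(half)$brier, 0.25)

  # separable 4-point toy set has AUC exactly 1
  toy <- tibble::tibble(label = c(TRUE, TRUE, FALSE, FALSE),
                        probability = c(0.9, 0.8, 0.3, 0.1),
                        called = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(classification_metrics(toy)$auc, 1)

  # degenerate single-class labels give NA AUC
  one_class <- tibble::tibble(label = c(TRUE, TRUE), probability = c(0.2, 0.9),
                              called = c(TRUE, FALSE))
  expect_true(is.na(classification_metrics(one_class)$auc))
})

test_that("all metrics stay within [0, 1] under fuzzing", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    ev <- tibble::tibble(label = sample(c(TRUE, FALSE), n, replace = TRUE),
                         probability = runif(n),
                         called = sample(c(TRUE, FALSE), n, replace = TRUE))
    m <- classification_metrics(ev)
    vals <- unlist(m[, c("auc", "brier", "weighted_f1", "balanced_accuracy")])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("reliability curves follow the rank rule and are monotone", {
  expect_equal(reliability_curve(rep(0.3, 10))$max_abs_log_delta, rep(0.3, 6))
  # n-1 zeros and a single large value: median is still zero
  d <- c(rep(0, 99), 5)
  expect_equal(reliability_curve(d, percentiles = 0.5)$max_abs_log_delta, 0)
  # ranks: values 1..100, p = 0.99 -> 99
  expect_equal(reliability_curve(1:100, percentiles = c(0.5, 0.99, 1))$
                 max_abs_log_delta, c(50, 99, 100))
  set.seed(42)
  x <- rnorm(173)
  curve <- reliability_curve(x)
  expect_false(is.unsorted(curve$max_abs_log_delta))
  expect_equal(curve$max_abs_log_delta[6], max(abs(x)))
  expect_error(reliability_curve(numeric(0)), "No log-deltas")
  expect_error(reliability_curve(1:5, percentiles = c(0.9, 0.5)), "increasing")
})

test_that("allele-call evaluations carry capped candidate-weight probabilities", {
  ha <- paste(sprintf("%s*01:01", loci5), collapse = "~")
  hb <- paste(sprintf("%s*01:02", loci5), collapse = "~")
  res <- imputation_result(tibble::tibble(
    h1 = c(ha, ha, hb), h2 = c(ha, hb, hb), weight = c(0.5, 0.3, 0.2)))
  truth <- genotype_from_haplotypes(ha, hb)
  ev <- allele_call_evaluation(truth, res)
  a <- ev[ev$locus == "A", ]
  expect_setequal(a$allele, c("A*01:01", "A*01:02"))
  # A*01:01 occurs in candidates 1 and 2 -> probability 0.8
  expect_equal(a$probability[a$allele == "A*01:01"], 0.8)
  expect_equal(a$probability[a$allele == "A*01:02"], 0.5)
  expect_true(all(a$label))
  # called = top candidate (homozygous h1/h1)
  expect_equal(a$called, c(TRUE, FALSE))
  # failed results yield an empty table
  failed <- imputation_result(tibble::tibble(h1 = character(0), h2 = character(0),
                                             weight = numeric(0)), failed = TRUE)
  expect_equal(nrow(allele_call_evaluation(truth, failed)), 0L)
})
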