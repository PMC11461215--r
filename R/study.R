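low_res_keys <- function(cohort) {
  gmat <- as.matrix(reduce_to_first_field(cohort[, genotype_cols(), drop = FALSE]))
  apply(gmat, 1L, paste, collapse = "|")
}

truth_keys <- function(cohort) {
  apply(as.matrix(cohort[, genotype_cols(), drop = FALSE]), 1L, paste, collapse = "|")
}

#' Classify an imputation assumption against a true population
#'
#' An assumption is `"matched"` when it is the individual's own detailed
#' population or (with a scheme) the broad category containing it,
#' `"super"` when it is the pooled super-population, and `"mismatched"`
#' otherwise.
#'
#' @param true_population,assumption Character vectors (recycled
#'   element-wise).
#' @param scheme Optional detailed-to-broad mapping (columns
#'   `detailed_id`, `broad_id`).
#' @param super_id Id of the pooled super-population table.
#' @return Character vector of classes.
#' @export
classify_assumption <- function(true_population, assumption, scheme = NULL,
                                super_id = "SUPER") {
  broad_of <- if (!is.null(scheme)) {
    setNames(scheme$broad_id, scheme$detailed_id)
  } else {
    setNames(character(0), character(0))
  }
  out <- rep("mismatched", length(true_population))
  out[assumption == super_id] <- "super"
  matched <- assumption == true_population |
    (!is.na(broad_of[true_population]) & broad_of[true_population] == assumption)
  out[matched] <- "matched"
  out
}

# Candidate info for one imputation result: genotype keys, weights, the
# single-imputation call, and whether the candidates are natural (level-0)
# haplotype pairs (the strict-imputation view).
candidate_info <- function(res) {
  if (res$failed) {
    return(list(failed = TRUE, natural = FALSE))
  }
  g <- haplotypes_to_genotype_tbl(res$candidates$h1, res$candidates$h2)
  keys <- apply(as.matrix(g), 1L, paste, collapse = "|")
  list(failed = FALSE,
       keys = keys, weights = res$candidates$weight,
       natural = res$candidates$fallback_level[1L] == 0L,
       single_key = keys[1L])
}

#' Run a complete simulated imputation-deviation study
#'
#' End-to-end orchestration of the study design: simulate patient and donor
#' cohorts from (synthetic or supplied) population haplotype-frequency
#' tables, pair them, reduce to first-field resolution, impute every
#' individual under every ancestry assumption (each detailed population,
#' optional broad categories, and the pooled SUPER table), score T-cell
#' (`pirche`) and B-cell (`snow`) molecular mismatch for ground-truth and
#' imputed genotypes (one party imputed at a time, the other kept at its
#' true high-resolution genotype), and summarize deviations, allele
#' mismatches, imputation failures, classification metrics and reliability
#' curves grouped by true and assumed ancestry.
#'
#' @param freqs Frequency tibble of detailed populations; `NULL` generates
#'   synthetic tables via [generate_frequency_tables()].
#' @param scheme Optional detailed-to-broad mapping (see
#'   [build_scheme_tables()]).
#' @param n_populations,n_haplotypes,alleles_per_locus,sharing,concentration
#'   Synthetic-table parameters, used when `freqs` is `NULL`.
#' @param n_per_population Individuals per population per party.
#' @param pair_mode Pairing mode, see [pair_cohorts()].
#' @param cumulative_mass,fallback_penalty Imputation parameters, see
#'   [imputation_config()].
#' @param max_candidates Cap on retained candidates per imputation
#'   (default 64, a computational bound on the candidate cross-products).
#' @param db Optional `hla_seqdb`; `NULL` generates one covering every
#'   allele of the assumption tables.
#' @param alignment_length,n_exposed,polymorphic_fraction Synthetic
#'   sequence-database parameters, used when `db` is `NULL`.
#' @param noticeable_threshold Threshold on `|log_delta|` defining a
#'   noticeable deviation (default 0.1).
#' @param percentiles Reliability-curve percentiles.
#' @param seed Integer master seed; every stochastic step derives its own
#'   sub-seed from it.
#' @param super_id Id of the pooled super-population table.
#' @return An object of class `hla_study`: a list with the simulated
#'   inputs (`freqs`, `pairs`, table of `assumptions`), the raw per-pair
#'   deviation `records` and per-individual allele `calls`, the pooled
#'   allele-probability table `allele_probs`, and the grouped `summary`
#'   (see [summarize_study()]). Supports [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot].
#' @export
run_study <- function(freqs = NULL, scheme = NULL,
                      n_populations = 3L, n_haplotypes = 150L,
                      alleles_per_locus = 24L, sharing = 0.3,
                      concentration = 0.2,
                      n_per_population = 300L, pair_mode = "within",
                      cumulative_mass = 0.99, fallback_penalty = 1e-4,
                      max_candidates = 64L,
                      db = NULL, alignment_length = 30L, n_exposed = 10L,
                      polymorphic_fraction = 0.1,
                      noticeable_threshold = 0.1,
                      percentiles = c(0.5, 0.75, 0.9, 0.95, 0.99, 1),
                      seed = 1L, super_id = "SUPER") {
  seed <- as.integer(seed)
  if (is.null(freqs)) {
    freqs <- generate_frequency_tables(n_populations, n_haplotypes,
                                       alleles_per_locus, sharing = sharing,
                                       concentration = concentration, seed = seed)
  }
  tabs <- build_scheme_tables(freqs, scheme, super_id = super_id)
  assumptions <- attr(tabs, "assumptions")$assumption
  patients <- simulate_cohorts(freqs, n_per_population, seed = seed + 101L, id_prefix = "PT_")
  donors <- simulate_cohorts(freqs, n_per_population, seed = seed + 202L, id_prefix = "DN_")
  pairs <- pair_cohorts(patients, donors, mode = pair_mode, seed = seed + 303L)
  if (is.null(db)) {
    all_alleles <- unique(unlist(strsplit(tabs$haplotype, "~", fixed = TRUE)))
    db <- generate_sequence_db(all_alleles, alignment_length, n_exposed,
                               polymorphic_fraction, seed = seed + 404L)
  }
  predictor <- make_anchor_predictor(db)
  config <- imputation_config(mode = "multiple", cumulative_mass = cumulative_mass,
                              fallback_penalty = fallback_penalty,
                              max_candidates = max_candidates)

  individuals <- bind_rows(mutate(patients, party = "patient"),
                           mutate(donors, party = "donor"))
  individuals$low_key <- low_res_keys(individuals)
  individuals$truth_key <- truth_keys(individuals)

  # impute each distinct low-resolution genotype once per assumption
  uniq_keys <- unique(individuals$low_key)
  cand_by_assumption <- lapply(setNames(nm = assumptions), function(a) {
    idx <- prepare_frequency_table(tabs, population = a)
    res <- lapply(uniq_keys, function(k) candidate_info(impute(genotype_from_key(k), idx, config)))
    names(res) <- uniq_keys
    res
  })

  # pairwise score cache shared across the whole study
  score_cache <- new.env(parent = emptyenv())
  scorer_fns <- list(pirche = function(p, d) pirche_score_impl(p, d, db, predictor),
                     snow = function(p, d) snow_score_impl(p, d, db))
  get_score <- function(pkey, dkey, scorer) {
    key <- paste0(pkey, "||", dkey, "||", scorer)
    s <- score_cache[[key]]
    if (is.null(s)) {
      s <- scorer_fns[[scorer]](genotype_from_key(pkey), genotype_from_key(dkey))
      assign(key, s, envir = score_cache)
    }
    s
  }

  # ground-truth scores per pair
  p_truth <- truth_keys(rename_with(pairs, ~ sub("^patient_", "", .x),
                                    starts_with("patient_")))
  d_truth <- truth_keys(rename_with(pairs, ~ sub("^donor_", "", .x),
                                    starts_with("donor_")))
  p_low <- individuals$low_key[match(pairs$patient_id, individuals$id)]
  d_low <- individuals$low_key[match(pairs$donor_id, individuals$id)]
  n_pairs <- nrow(pairs)
  truth_scores <- lapply(setNames(nm = names(scorer_fns)), function(sc) {
    vapply(seq_len(n_pairs), function(i) get_score(p_truth[i], d_truth[i], sc), numeric(1))
  })

  # per-pair deviation records: one imputed party at a time
  records <- list(); r <- 0L
  for (a in assumptions) {
    cand <- cand_by_assumption[[a]]
    for (party in c("patient", "donor")) {
      imp_low <- if (party == "patient") p_low else d_low
      fixed_truth <- if (party == "patient") d_truth else p_truth
      party_truth <- if (party == "patient") p_truth else d_truth
      true_pop <- if (party == "patient") pairs$patient_population else pairs$donor_population
      for (sc in names(scorer_fns)) {
        v_mult <- rep(NA_real_, n_pairs); v_single <- rep(NA_real_, n_pairs)
        natural <- logical(n_pairs); failed <- logical(n_pairs)
        for (i in seq_len(n_pairs)) {
          ci <- cand[[imp_low[i]]]
          if (ci$failed) { failed[i] <- TRUE; next }
          natural[i] <- ci$natural
          s <- vapply(ci$keys, function(k) {
            if (party == "patient") get_score(k, fixed_truth[i], sc)
            else get_score(fixed_truth[i], k, sc)
          }, numeric(1))
          v_mult[i] <- sum(ci$weights * s)
          v_single[i] <- s[[1L]]
        }
        tr <- truth_scores[[sc]]
        for (strategy in c("multiple", "single")) {
          v <- if (strategy == "multiple") v_mult else v_single
          r <- r + 1L
          records[[r]] <- new_tibble(list(
            pair_id = pairs$pair_id, party = rep.int(party, n_pairs),
            scorer = rep.int(sc, n_pairs), strategy = rep.int(strategy, n_pairs),
            assumption = rep.int(a, n_pairs), true_population = true_pop,
            truth_score = tr, imputed_score = v,
            log_delta = log_delta(tr, v),
            failed = failed, natural = natural
          ), nrow = n_pairs)
        }
      }
    }
  }
  records <- list_rbind(records)
  records$noticeable <- !is.na(records$log_delta) &
    abs(records$log_delta) > noticeable_threshold
  records$assumption_class <- classify_assumption(records$true_population,
                                                  records$assumption, scheme, super_id)

  # per-individual allele-level evaluation of single-imputation calls
  key_split <- function(keys) {
    out <- as_tibble(as.data.frame(do.call(rbind, strsplit(keys, "|", fixed = TRUE)),
                                   stringsAsFactors = FALSE))
    names(out) <- genotype_cols()
    out
  }
  truth_tbl <- key_split(individuals$truth_key)
  calls <- list()
  for (a in assumptions) {
    cand <- cand_by_assumption[[a]]
    per_ind <- cand[individuals$low_key]
    failed <- vapply(per_ind, `[[`, logical(1), "failed")
    natural <- !failed & vapply(per_ind, `[[`, logical(1), "natural")
    mism <- rep(NA_integer_, nrow(individuals))
    if (any(!failed)) {
      singles <- vapply(per_ind[!failed], `[[`, character(1), "single_key")
      mism[!failed] <- count_allele_mismatches(truth_tbl[!failed, ], key_split(singles))
    }
    calls[[a]] <- new_tibble(list(
      id = individuals$id, party = individuals$party,
      true_population = individuals$population,
      assumption = rep.int(a, nrow(individuals)),
      failed = failed, natural = natural, allele_mismatch = mism
    ), nrow = nrow(individuals))
  }
  calls <- list_rbind(unname(calls))
  calls$strict_failed <- calls$failed | !calls$natural
  calls$assumption_class <- classify_assumption(calls$true_population,
                                                calls$assumption, scheme, super_id)

  # pooled allele-probability table (for AUC / Brier / F1 / balanced acc.)
  allele_probs <- build_allele_probs(individuals, cand_by_assumption, scheme, super_id)

  summary <- summarize_study(records, calls, allele_probs = allele_probs,
                             threshold = noticeable_threshold,
                             percentiles = percentiles)
  structure(list(freqs = freqs, assumptions = attr(tabs, "assumptions"),
                 scheme = scheme, pairs = pairs, db = db,
                 records = records, calls = calls, allele_probs = allele_probs,
                 summary = summary, seed = seed,
                 noticeable_threshold = noticeable_threshold,
                 n_per_population = n_per_population),
            class = "hla_study")
}

build_allele_probs <- function(individuals, cand_by_assumption, scheme, super_id) {
  loci <- hla_loci()
  acc_id <- list(); acc_pop <- list(); acc_assum <- list(); acc_locus <- list()
  acc_allele <- list(); acc_label <- list(); acc_prob <- list(); acc_called <- list()
  k <- 0L
  for (a in names(cand_by_assumption)) {
    cand <- cand_by_assumption[[a]]
    # per-locus candidate allele probabilities are shared by every
    # individual with the same low-resolution genotype
    locus_info <- lapply(cand, function(ci) {
      if (ci$failed) return(NULL)
      cmat <- do.call(rbind, strsplit(ci$keys, "|", fixed = TRUE))
      single <- strsplit(ci$single_key, "|", fixed = TRUE)[[1L]]
      lapply(seq_along(loci), function(li) {
        c1 <- cmat[, 2L * li - 1L]; c2 <- cmat[, 2L * li]
        alleles <- unique(c(c1, c2))
        prob <- vapply(alleles, function(al) {
          min(1, sum(ci$weights[c1 == al | c2 == al]))
        }, numeric(1))
        list(alleles = alleles, prob = unname(prob),
             called = single[c(2L * li - 1L, 2L * li)])
      })
    })
    for (i in seq_len(nrow(individuals))) {
      info <- locus_info[[individuals$low_key[i]]]
      if (is.null(info)) next
      truth <- strsplit(individuals$truth_key[i], "|", fixed = TRUE)[[1L]]
      for (li in seq_along(loci)) {
        t_pair <- truth[c(2L * li - 1L, 2L * li)]
        extra <- setdiff(t_pair, info[[li]]$alleles)
        universe <- c(info[[li]]$alleles, extra)
        n_u <- length(universe)
        k <- k + 1L
        acc_id[[k]] <- rep.int(individuals$id[i], n_u)
        acc_pop[[k]] <- rep.int(individuals$population[i], n_u)
        acc_assum[[k]] <- rep.int(a, n_u)
        acc_locus[[k]] <- rep.int(loci[li], n_u)
        acc_allele[[k]] <- universe
        acc_label[[k]] <- universe %in% t_pair
        acc_prob[[k]] <- c(info[[li]]$prob, rep.int(0, length(extra)))
        acc_called[[k]] <- universe %in% info[[li]]$called
      }
    }
  }
  out <- new_tibble(list(
    id = unlist(acc_id), true_population = unlist(acc_pop),
    assumption = unlist(acc_assum), locus = unlist(acc_locus),
    allele = unlist(acc_allele), label = unlist(acc_label),
    probability = unlist(acc_prob), called = unlist(acc_called)
  ), nrow = length(unlist(acc_label)))
  out$assumption_class <- classify_assumption(out$true_population, out$assumption,
                                              scheme, super_id)
  out
}

#' Summarize deviation records and allele calls into grouped tables
#'
#' Produces the grouped evaluation matrices of an imputation-deviation
#' study: imputation failure rates and mean allele mismatches per (true
#' population x assumption) cell, noticeable-deviation proportions per
#' scorer and imputed party, matched / mismatched / SUPER marginals
#' (unweighted means over the corresponding cells), classification metrics
#' per assumption class, and reliability percentile curves.
#'
#' @param records Per-pair deviation records (see [run_study()]); must
#'   carry `scorer`, `party`, `strategy`, `assumption`, `true_population`,
#'   `assumption_class`, `log_delta`, `failed`, `natural`.
#' @param calls Per-individual allele-call table with `failed`,
#'   `strict_failed`, `natural`, `allele_mismatch`, `assumption`,
#'   `true_population`, `assumption_class`.
#' @param allele_probs Optional pooled allele-probability table (columns
#'   `label`, `probability`, `called`, `assumption_class`) for the
#'   classification metrics.
#' @param threshold Noticeable-deviation threshold (default 0.1).
#' @param percentiles Reliability-curve percentiles.
#' @return A list of class `hla_study_summary` with tibbles
#'   `failure_rate`, `allele_mismatch`, `noticeable`, `marginals`,
#'   `metrics` (when `allele_probs` given) and `reliability`.
#' @export
summarize_study <- function(records, calls, allele_probs = NULL,
                            threshold = 0.1,
                            percentiles = c(0.5, 0.75, 0.9, 0.95, 0.99, 1)) {
  failure_rate <- calls |>
    group_by(.data$true_population, .data$assumption, .data$assumption_class) |>
    summarise(n = n(), failure_rate = mean(.data$failed),
              strict_failure_rate = mean(.data$strict_failed), .groups = "drop")

  allele_mismatch <- calls |>
    group_by(.data$true_population, .data$assumption, .data$assumption_class) |>
    summarise(
      mean_allele_mismatch = mean(.data$allele_mismatch[!.data$failed]),
      strict_mean_allele_mismatch = if (any(.data$natural))
        mean(.data$allele_mismatch[.data$natural]) else NA_real_,
      .groups = "drop")

  noticeable <- records |>
    filter(.data$strategy == "multiple", !.data$failed) |>
    group_by(.data$scorer, .data$party, .data$true_population,
             .data$assumption, .data$assumption_class) |>
    summarise(n = n(),
              noticeable_proportion = mean(abs(.data$log_delta) > threshold),
              .groups = "drop")

  marginals <- bind_rows(
    failure_rate |>
      group_by(.data$assumption_class) |>
      summarise(metric = "failure_rate", value = mean(.data$failure_rate),
                .groups = "drop"),
    failure_rate |>
      group_by(.data$assumption_class) |>
      summarise(metric = "strict_failure_rate",
                value = mean(.data$strict_failure_rate), .groups = "drop"),
    allele_mismatch |>
      group_by(.data$assumption_class) |>
      summarise(metric = "mean_allele_mismatch",
                value = mean(.data$mean_allele_mismatch, na.rm = TRUE),
                .groups = "drop"),
    allele_mismatch |>
      group_by(.data$assumption_class) |>
      summarise(metric = "strict_mean_allele_mismatch",
                value = mean(.data$strict_mean_allele_mismatch, na.rm = TRUE),
                .groups = "drop"),
    noticeable |>
      group_by(.data$assumption_class, .data$scorer, .data$party) |>
      summarise(metric = "noticeable_proportion",
                value = mean(.data$noticeable_proportion), .groups = "drop")
  ) |>
    relocate("metric", .before = 1L)

  metrics <- if (!is.null(allele_probs)) {
    allele_probs |>
      group_by(.data$assumption_class) |>
      group_modify(~ classification_metrics(.x)) |>
      ungroup()
  } else NULL

  reliability <- records |>
    filter(!.data$failed) |>
    group_by(.data$scorer, .data$party, .data$strategy, .data$assumption_class) |>
    group_modify(~ reliability_curve(.x$log_delta, percentiles)) |>
    ungroup()

  structure(list(failure_rate = failure_rate, allele_mismatch = allele_mismatch,
                 noticeable = noticeable, marginals = marginals,
                 metrics = metrics, reliability = reliability,
                 threshold = threshold),
            class = "hla_study_summary")
}

#' @export
print.hla_study_summary <- function(x, ...) {
  cat("<hla_study_summary>\n")
  cat("Marginals over (true population x assumption) cells:\n")
  print(x$marginals, n = 30)
  invisible(x)
}

#' @export
print.hla_study <- function(x, ...) {
  cat("<hla_study> ", nrow(x$pairs), " transplant pairs, ",
      length(unique(x$calls$assumption)), " ancestry assumptions, seed ",
      x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
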