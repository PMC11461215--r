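#' Deterministic anchor-residue presentation predictor
#'
#' A pluggable, deterministic stand-in for peptide–MHC class II binding
#' prediction: a 9-mer core is "presented" by a DRB1 molecule iff the core
#' residues at three fixed anchor offsets (1, 4 and 6, 0-based) all occur in
#' the presenter's exposure-masked residue set. It is a pure function of the
#' presenter sequence and the core, and sensitive to DRB1 identity — which
#' is what drives the patient-vs-donor asymmetry of T-cell epitope scores.
#'
#' @param db An `hla_seqdb` (supplies the DRB1 exposure mask).
#' @param anchors Integer anchor offsets within the 9-mer, 0-based.
#' @return A function `f(presenter_sequence, cores)` returning a logical
#'   vector along `cores`.
#' @export
make_anchor_predictor <- function(db, anchors = c(1L, 4L, 6L)) {
  stopifnot(inherits(db, "hla_seqdb"), all(anchors >= 0L), all(anchors <= 8L))
  force(anchors)
  function(presenter, cores) {
    if (length(cores) == 0) return(logical(0))
    res_set <- db_presenter_residues(db, presenter)
    ok <- rep(TRUE, length(cores))
    for (a in anchors) {
      ok <- ok & substring(cores, a + 1L, a + 1L) %in% res_set
    }
    ok
  }
}

check_scoring_genotype <- function(g, db, who) {
  g <- as_genotype(g)
  if (!all(is_high_resolution(g))) {
    abort(paste0("The ", who, " genotype must be high-resolution (two-field) for scoring."))
  }
  missing_alleles <- setdiff(unique(unname(g)), db$sequences$allele)
  if (length(missing_alleles)) {
    abort(paste0("Allele(s) missing from the sequence database: ",
                 paste(missing_alleles, collapse = ", ")))
  }
  g
}

#' T-cell epitope mismatch score (PIRCHE-II style)
#'
#' Counts distinct (core peptide, presenter) tuples where a 9-mer core from
#' any donor HLA protein (all five loci) is absent from the patient's
#' self-peptidome (the 9-mers of all patient HLA proteins across the five
#' loci) and is predicted to be presented by a patient DRB1 molecule.
#' Distinct patient DRB1 *protein sequences* act as presenters, so a
#' DRB1-homozygous patient (or one whose two DRB1 alleles encode the same
#' protein) contributes a single presenter — identical homozygous
#' presenters are not counted separately.
#'
#' @param patient,donor High-resolution genotypes (see [as_genotype()]).
#' @param db An `hla_seqdb` covering every allele of both genotypes.
#' @param predictor Presentation predictor `f(presenter_sequence, cores)`;
#'   default [make_anchor_predictor()] on `db`.
#' @return Non-negative integer score.
#' @export
pirche_score <- function(patient, donor, db, predictor = NULL) {
  patient <- check_scoring_genotype(patient, db, "patient")
  donor <- check_scoring_genotype(donor, db, "donor")
  pirche_score_impl(patient, donor, db, predictor %||% make_anchor_predictor(db))
}

pirche_score_impl <- function(patient, donor, db, predictor) {
  donor_cores <- unique(unlist(lapply(unique(unname(donor)), db_windows, db = db),
                               use.names = FALSE))
  self_pep <- unique(unlist(lapply(unique(unname(patient)), db_windows, db = db),
                            use.names = FALSE))
  nonself <- setdiff(donor_cores, self_pep)
  if (length(nonself) == 0) return(0L)
  presenters <- unique(unname(db_sequence(db, unique(patient[c("DRB1_1", "DRB1_2")]))))
  total <- 0L
  for (p in presenters) {
    total <- total + sum(predictor(p, nonself))
  }
  as.integer(total)
}

#' B-cell epitope mismatch score (surface-exposed mismatches, Snow style)
#'
#' Counts distinct (locus, position, residue) tuples where, at a
#' surface-exposed alignment position of a locus, some donor allele carries
#' a residue that no patient allele at the same locus carries at that
#' position. Comparison is within-locus; exposure comes from the database's
#' per-locus exposure mask.
#'
#' @inheritParams pirche_score
#' @return Non-negative integer score.
#' @export
snow_score <- function(patient, donor, db) {
  patient <- check_scoring_genotype(patient, db, "patient")
  donor <- check_scoring_genotype(donor, db, "donor")
  snow_score_impl(patient, donor, db)
}

snow_score_impl <- function(patient, donor, db) {
  donor_t <- unique(unlist(lapply(unique(unname(donor)), db_exposed_tuples, db = db),
                           use.names = FALSE))
  patient_t <- unique(unlist(lapply(unique(unname(patient)), db_exposed_tuples, db = db),
                             use.names = FALSE))
  length(setdiff(donor_t, patient_t))
}

resolve_scorer <- function(scorer, db, predictor = NULL) {
  if (is.function(scorer)) {
    return(list(name = "custom", fn = function(p, d) scorer(p, d, db)))
  }
  scorer <- match.arg(scorer, c("pirche", "snow"))
  if (scorer == "pirche") {
    predictor <- predictor %||% make_anchor_predictor(db)
    list(name = "pirche", fn = function(p, d) pirche_score_impl(p, d, db, predictor))
  } else {
    list(name = "snow", fn = function(p, d) snow_score_impl(p, d, db))
  }
}

# Candidate genotypes + weights from an imputation result or a fixed
# genotype. Returns NULL for failed imputations.
score_candidates <- function(x) {
  if (inherits(x, "hla_imputation")) {
    if (x$failed) return(NULL)
    g <- haplotypes_to_genotype_tbl(x$candidates$h1, x$candidates$h2)
    keys <- apply(as.matrix(g), 1L, paste, collapse = "|")
    list(keys = keys, weights = x$candidates$weight)
  } else {
    list(keys = genotype_key(as_genotype(x)), weights = 1)
  }
}

#' Frequency-weighted aggregated mismatch score over imputed genotype sets
#'
#' The molecular mismatch load of an imputed transplant pair is the
#' weighted average of the pairwise scores over the cross-product of
#' patient and donor candidate genotypes, with weights given by the
#' normalized imputed genotype frequencies (a fixed genotype is a single
#' candidate of weight 1). If either side's imputation failed, the
#' aggregated score is failed too.
#'
#' @param patient,donor Each an `hla_imputation` result or a fixed
#'   high-resolution genotype.
#' @param scorer `"pirche"`, `"snow"`, or a function
#'   `f(patient_genotype, donor_genotype, db)`.
#' @param db An `hla_seqdb`.
#' @param predictor Optional presentation predictor (pirche only).
#' @param cache Optional environment caching pairwise scores across calls
#'   (keys `patient_key||donor_key||scorer`).
#' @return A one-row tibble: `scorer`, `value`,
#'   `n_candidate_combinations`, `failed`.
#' @export
aggregate_score <- function(patient, donor, scorer, db, predictor = NULL,
                            cache = NULL) {
  sc <- resolve_scorer(scorer, db, predictor)
  p <- score_candidates(patient)
  d <- score_candidates(donor)
  if (is.null(p) || is.null(d)) {
    return(tibble(scorer = sc$name, value = NA_real_,
                  n_candidate_combinations = 0L, failed = TRUE))
  }
  total <- 0; wsum <- 0
  for (i in seq_along(p$keys)) {
    gi <- genotype_from_key(p$keys[i])
    for (j in seq_along(d$keys)) {
      w <- p$weights[i] * d$weights[j]
      key <- paste0(p$keys[i], "||", d$keys[j], "||", sc$name)
      s <- if (!is.null(cache)) cache[[key]] else NULL
      if (is.null(s)) {
        s <- sc$fn(gi, genotype_from_key(d$keys[j]))
        if (!is.null(cache)) assign(key, s, envir = cache)
      }
      total <- total + w * s
      wsum <- wsum + w
    }
  }
  tibble(scorer = sc$name, value = total / wsum,
         n_candidate_combinations = length(p$keys) * length(d$keys),
         failed = FALSE)
}
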