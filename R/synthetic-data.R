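run_seeded <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(as.integer(seed), fn())
}

# Synthetic allele name pools: per locus, `alleles_per_locus` two-field
# names organised into first-field groups of `alleles_per_group` variants
# (A*01:01, A*01:02, ..., A*02:01, ...). Group structure is what makes
# first-field data informative and imputation ambiguous, as in real HLA.
synthetic_allele_pools <- function(alleles_per_locus, alleles_per_group = 3L) {
  stopifnot(alleles_per_locus >= 1, alleles_per_group >= 1)
  lapply(setNames(nm = hla_loci()), function(locus) {
    g <- rep(seq_len(ceiling(alleles_per_locus / alleles_per_group)),
             each = alleles_per_group)[seq_len(alleles_per_locus)]
    v <- stats::ave(g, g, FUN = seq_along)
    sprintf("%s*%02d:%02d", locus, g, v)
  })
}

draw_distinct_haplotypes <- function(n, pools, exclude = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 100L) abort("Could not draw enough distinct haplotypes; allele pool too small.")
    k <- (n - length(out)) * 2L
    cand <- do.call(paste, c(lapply(pools, sample, size = k, replace = TRUE), sep = "~"))
    cand <- setdiff(unique(cand), c(exclude, out))
    out <- c(out, head(cand, n - length(out)))
  }
  out
}

#' Generate synthetic population haplotype-frequency tables
#'
#' Emulates the structure of published multi-population haplotype-frequency
#' tables: several populations whose supports partially overlap (a `sharing`
#' fraction of each population's haplotypes is drawn from a common pool, the
#' rest is population-private) and whose frequency spectra are heavy-tailed
#' (symmetric Dirichlet with small `concentration`, giving the
#' few-common-many-rare shape that drives imputation ambiguity).
#'
#' @param n_populations Number of detailed populations.
#' @param n_haplotypes Haplotypes per population.
#' @param alleles_per_locus Size of the two-field allele pool at each locus.
#' @param alleles_per_group Two-field variants per first-field group
#'   (default 3).
#' @param sharing Fraction in `[0, 1]` of each population's haplotypes drawn
#'   from the common pool; 0 gives pairwise-disjoint supports, 1 identical
#'   supports with population-specific frequencies.
#' @param concentration Symmetric Dirichlet concentration (> 0) of the
#'   frequency spectrum; smaller is more skewed. Default 0.2.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @param population_ids Ids of the populations (default `POP01`, ...).
#' @return A normalized frequency tibble (see [read_frequency_table()]).
#' @export
#' @examples
#' generate_frequency_tables(2, n_haplotypes = 10, seed = 1)
generate_frequency_tables <- function(n_populations, n_haplotypes,
                                      alleles_per_locus = 24L,
                                      alleles_per_group = 3L,
                                      sharing = 0.3, concentration = 0.2,
                                      seed = NULL,
                                      population_ids = sprintf("POP%02d", seq_len(n_populations))) {
  stopifnot(n_populations >= 1, n_haplotypes >= 1,
            sharing >= 0, sharing <= 1, concentration > 0,
            length(population_ids) == n_populations)
  pools <- synthetic_allele_pools(alleles_per_locus, alleles_per_group)
  n_shared <- round(sharing * n_haplotypes)
  capacity <- prod(vapply(pools, length, 1L))
  needed <- n_haplotypes + n_populations * (n_haplotypes - n_shared)
  if (needed > capacity) {
    abort(paste0("Requested ", needed, " distinct haplotypes but only ",
                 capacity, " allele combinations exist; increase alleles_per_locus."))
  }
  run_seeded(seed, function() {
    pool <- draw_distinct_haplotypes(n_haplotypes, pools)
    used <- pool
    out <- vector("list", n_populations)
    for (p in seq_len(n_populations)) {
      shared <- if (n_shared > 0) sample(pool, n_shared) else character(0)
      private <- if (n_haplotypes > n_shared) {
        draw_distinct_haplotypes(n_haplotypes - n_shared, pools, exclude = used)
      } else character(0)
      used <- c(used, private)
      support <- c(shared, private)
      g <- rgamma(length(support), shape = concentration)
      g <- pmax(g, 1e-300)
      out[[p]] <- tibble(population = population_ids[p],
                         haplotype = support,
                         frequency = g / sum(g))
    }
    arrange(list_rbind(out), .data$population, desc(.data$frequency), .data$haplotype)
  })
}

#' Simulate a cohort of individuals from one frequency table
#'
#' Each individual is built by two independent weighted draws of a haplotype
#' (probability proportional to its table frequency; drawing the same
#' haplotype twice is allowed and yields a haplotype-homozygous individual).
#' The expected population frequency of the individual is the product of
#' the two drawn haplotypes' frequencies.
#'
#' @param freqs Frequency tibble of a single population.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param id_prefix Prefix for individual ids (default the population id).
#' @return A tibble with columns `id`, `population`, `h1`, `h2` (sorted
#'   haplotype pair), the ten [genotype_cols()], and `expected_frequency`.
#' @export
simulate_cohort <- function(freqs, n, seed = NULL, id_prefix = NULL) {
  check_frequency_table(freqs)
  pops <- unique(freqs$population)
  if (length(pops) != 1L) {
    abort("simulate_cohort() works on a single population; filter first or use simulate_cohorts().")
  }
  if (n < 1) abort("`n` must be >= 1.")
  f <- freqs$frequency / sum(freqs$frequency)
  run_seeded(seed, function() {
    i1 <- sample.int(nrow(freqs), n, replace = TRUE, prob = f)
    i2 <- sample.int(nrow(freqs), n, replace = TRUE, prob = f)
    a <- freqs$haplotype[i1]; b <- freqs$haplotype[i2]
    swap <- a > b
    h1 <- ifelse(swap, b, a); h2 <- ifelse(swap, a, b)
    prefix <- id_prefix %||% pops
    bind_cols(
      tibble(id = sprintf("%s_%05d", prefix, seq_len(n)),
             population = pops, h1 = h1, h2 = h2),
      haplotypes_to_genotype_tbl(h1, h2),
      tibble(expected_frequency = f[i1] * f[i2])
    )
  })
}

#' Simulate one cohort per population
#'
#' @param freqs Frequency tibble of one or more populations.
#' @param n_per_population Individuals per population.
#' @param seed Integer seed; each population uses a sub-seed derived from it.
#' @param id_prefix Prefix prepended to per-population ids.
#' @return A tibble of all individuals (see [simulate_cohort()]).
#' @export
simulate_cohorts <- function(freqs, n_per_population, seed = NULL, id_prefix = "") {
  pops <- unique(freqs$population)
  out <- vector("list", length(pops))
  for (i in seq_along(pops)) {
    out[[i]] <- simulate_cohort(freqs[freqs$population == pops[i], ],
                                n_per_population,
                                seed = if (is.null(seed)) NULL else seed + i,
                                id_prefix = paste0(id_prefix, pops[i]))
  }
  list_rbind(out)
}

prefix_party_cols <- function(cohort, prefix) {
  keep <- intersect(c("id", "population", "h1", "h2", genotype_cols(),
                      "expected_frequency"), names(cohort))
  out <- cohort[, keep, drop = FALSE]
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Pair patient and donor cohorts into transplant pairs
#'
#' Stratified pairing of simulated (or real) cohorts: `"within"` pairs
#' patients and donors of the same population after a seeded shuffle (sizes
#' must match per population); `"across"` shuffles both sides globally and
#' pairs index-wise, approximating uniform pairing over the population
#' cross-product; `"both"` concatenates the two. No individual is reused
#' within a mode.
#'
#' @param patients,donors Cohort tibbles (see [simulate_cohort()]) with at
#'   least `id`, `population` and the genotype columns.
#' @param mode `"within"`, `"across"` or `"both"`.
#' @param seed Integer seed for the shuffles.
#' @return A tibble with `pair_id`, `pair_mode`, and all cohort columns
#'   prefixed `patient_` / `donor_`.
#' @export
pair_cohorts <- function(patients, donors, mode = c("within", "across", "both"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(patients) == 0 || nrow(donors) == 0) abort("Cohorts must be non-empty.")
  run_seeded(seed, function() {
    pair_within <- function() {
      pops <- unique(patients$population)
      if (!setequal(pops, unique(donors$population))) {
        abort("Within-mode pairing needs the same populations on both sides.")
      }
      out <- vector("list", length(pops))
      for (i in seq_along(pops)) {
        p <- patients[patients$population == pops[i], , drop = FALSE]
        d <- donors[donors$population == pops[i], , drop = FALSE]
        if (nrow(p) != nrow(d)) {
          abort(paste0("Within-mode size mismatch for population ", pops[i],
                       ": ", nrow(p), " patients vs ", nrow(d), " donors."))
        }
        out[[i]] <- bind_cols(prefix_party_cols(p[sample.int(nrow(p)), ], "patient"),
                              prefix_party_cols(d[sample.int(nrow(d)), ], "donor"))
      }
      list_rbind(out)
    }
    pair_across <- function() {
      n <- min(nrow(patients), nrow(donors))
      bind_cols(
        prefix_party_cols(patients[sample.int(nrow(patients), n), ], "patient"),
        prefix_party_cols(donors[sample.int(nrow(donors), n), ], "donor")
      )
    }
    out <- switch(mode,
      within = mutate(pair_within(), pair_mode = "within"),
      across = mutate(pair_across(), pair_mode = "across"),
      both = bind_rows(mutate(pair_within(), pair_mode = "within"),
                       mutate(pair_across(), pair_mode = "across"))
    )
    out |>
      mutate(pair_id = sprintf("PAIR_%05d", seq_len(n())), .before = 1L) |>
      relocate("pair_mode", .after = "pair_id")
  })
}
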