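#' Default stepwise linkage-relaxation ladder
#'
#' When no full five-locus haplotype pair in the frequency table is
#' consistent with the observed genotype, linkage assumptions between loci
#' are removed stepwise: first the A locus is detached from the
#' C~B~DRB1~DQB1 block, then the C~B and DRB1~DQB1 blocks are separated,
#' and finally all five loci are treated independently (pure allele-group
#' frequencies). The ladder respects the strong known linkage of C~B and
#' DRB1~DQB1 and is fully configurable.
#'
#' @return A list of ladder levels; each level is a list of character
#'   vectors partitioning the five loci into blocks.
#' @export
default_fallback_ladder <- function() {
  list(
    list("A", c("C", "B", "DRB1", "DQB1")),
    list("A", c("C", "B"), c("DRB1", "DQB1")),
    as.list(hla_loci())
  )
}

#' Imputation configuration
#'
#' @param mode `"multiple"` keeps the weighted candidate set; `"single"`
#'   keeps only the most frequent genotype (weight 1).
#' @param strict Forbid the linkage-relaxation fallback: when no natural
#'   haplotype pair matches, imputation fails instead (default `FALSE`).
#' @param cumulative_mass After normalization, only the minimal prefix of
#'   candidates (sorted by descending weight) whose cumulative weight
#'   reaches this mass is retained, then renormalized (default 0.99).
#' @param fallback_penalty Multiplicative weight penalty per removed
#'   linkage, in (0, 1); its default 1e-4 guarantees that natural-haplotype
#'   candidates outrank fallback candidates at realistic frequency
#'   magnitudes (default 1e-4).
#' @param fallback_ladder Ladder of locus-block partitions, see
#'   [default_fallback_ladder()].
#' @param hardy_weinberg Multiply heterozygous pair weights by 2
#'   (Hardy-Weinberg convention). Off by default: the plain product of the
#'   two haplotype frequencies is used, with unordered pairs counted once.
#' @param max_candidates Cap on retained candidates after the cumulative
#'   mass truncation (default `Inf`); a computational safeguard for very
#'   flat weight spectra.
#' @param max_chromosome_options Cap on per-chromosome block assemblies
#'   explored at each fallback level, keeping the highest-weight ones
#'   (default 100; the weight spectra are heavy-tailed, so the discarded
#'   tail carries negligible mass).
#' @return A list of class `hla_imputation_config`.
#' @export
imputation_config <- function(mode = c("multiple", "single"), strict = FALSE,
                              cumulative_mass = 0.99, fallback_penalty = 1e-4,
                              fallback_ladder = default_fallback_ladder(),
                              hardy_weinberg = FALSE,
                              max_candidates = Inf,
                              max_chromosome_options = 100L) {
  mode <- match.arg(mode)
  if (!(cumulative_mass > 0 && cumulative_mass <= 1)) {
    abort("`cumulative_mass` must be in (0, 1].")
  }
  if (!(fallback_penalty > 0 && fallback_penalty < 1)) {
    abort("`fallback_penalty` must be in (0, 1).")
  }
  for (level in fallback_ladder) {
    if (!setequal(unlist(level), hla_loci()) || anyDuplicated(unlist(level))) {
      abort("Every fallback ladder level must partition the five loci.")
    }
  }
  structure(list(mode = mode, strict = strict, cumulative_mass = cumulative_mass,
                 fallback_penalty = fallback_penalty, fallback_ladder = fallback_ladder,
                 hardy_weinberg = hardy_weinberg, max_candidates = max_candidates,
                 max_chromosome_options = as.integer(max_chromosome_options)),
            class = "hla_imputation_config")
}

#' Enumerate phase decompositions of a genotype
#'
#' Splits the two alleles of every locus across two chromosomes in all
#' possible ways, yielding every unordered pair of haplotype patterns
#' consistent with the genotype: `2^(h-1)` patterns for `h` heterozygous
#' loci (one pattern when fully homozygous).
#'
#' @param g A genotype (see [as_genotype()]), any resolution.
#' @return A tibble with columns `h1`, `h2` (pattern strings, pair sorted).
#' @export
enumerate_phase_decompositions <- function(g) {
  g <- as_genotype(g)
  enumerate_decompositions_impl(g)
}

enumerate_decompositions_impl <- function(g) {
  a1 <- g[seq(1L, 9L, 2L)]
  a2 <- g[seq(2L, 10L, 2L)]
  het <- which(a1 != a2)
  if (length(het) == 0L) {
    h <- paste(a1, collapse = "~")
    return(tibble(h1 = h, h2 = h))
  }
  free <- het[-1L]  # first heterozygous locus fixed to chromosome 1
  n <- 2L^length(free)
  h1 <- character(n); h2 <- character(n)
  for (k in seq_len(n)) {
    bits <- as.integer(intToBits(k - 1L))[seq_along(free)]
    c1 <- a1; c2 <- a2
    flip <- free[bits == 1L]
    c1[flip] <- a2[flip]; c2[flip] <- a1[flip]
    s1 <- paste(c1, collapse = "~"); s2 <- paste(c2, collapse = "~")
    if (s1 <= s2) { h1[k] <- s1; h2[k] <- s2 } else { h1[k] <- s2; h2[k] <- s1 }
  }
  tibble(h1 = h1, h2 = h2)
}

#' Prepare a frequency table for repeated imputation
#'
#' Precomputes the first-field reduction of every table haplotype and a
#' pattern index so that many genotypes can be imputed against the same
#' table cheaply. All imputation functions accept either a frequency tibble
#' or a prepared index.
#'
#' @param freqs Frequency tibble of a single population.
#' @param population Optional population id to select from a multi-population
#'   tibble.
#' @return An object of class `hla_freq_index`.
#' @export
prepare_frequency_table <- function(freqs, population = NULL) {
  if (inherits(freqs, "hla_freq_index")) return(freqs)
  check_frequency_table(freqs)
  if (!is.null(population)) freqs <- freqs[freqs$population == population, , drop = FALSE]
  pops <- unique(freqs$population)
  if (length(pops) != 1L) abort("Imputation needs a single population table; use `population`.")
  f <- freqs$frequency / sum(freqs$frequency)
  ff <- ff_truncate(freqs$haplotype)
  structure(
    list(population = pops, haplotype = freqs$haplotype, frequency = f,
         ff = ff, pattern_index = split(seq_along(ff), ff),
         cache = new.env(parent = emptyenv())),
    class = "hla_freq_index"
  )
}

# Descending-weight ordering with deterministic lexicographic tie-break.
# Tie-break keys are computed lazily, only for runs of exactly equal
# weights (keeps large candidate lists cheap to sort).
order_weight_key <- function(w, key_fn) {
  ord <- order(-w, method = "radix")
  ws <- w[ord]
  n <- length(ws)
  if (n > 1L) {
    run_id <- cumsum(c(TRUE, ws[-1L] != ws[-n]))
    need <- run_id %in% run_id[duplicated(run_id)]
    if (any(need)) {
      key <- key_fn(ord[need])
      ord[need] <- ord[need][order(run_id[need], key, method = "radix")]
    }
  }
  ord
}

# Candidate accumulator: plain lists for speed, tibble at the surface.
candidate_tbl <- function(h1, h2, raw_weight, fallback_level) {
  new_tibble(list(h1 = h1, h2 = h2, raw_weight = raw_weight,
                  fallback_level = rep.int(fallback_level, length(h1))),
             nrow = length(h1))
}

#' Natural-haplotype candidate genotypes for a low-resolution genotype
#'
#' A pair of table haplotypes is a candidate iff the first-field reduction
#' of its implied genotype equals the input genotype. The raw weight of a
#' candidate is the product of the two haplotype frequencies, unordered
#' pairs counted once (see `hardy_weinberg` in [imputation_config()] for
#' the 2pq convention).
#'
#' @param g_low First-field genotype (see [reduce_to_first_field()]).
#' @param freqs Frequency tibble or prepared index of one population.
#' @param config An [imputation_config()].
#' @return Tibble of candidates `h1`, `h2`, `raw_weight`,
#'   `fallback_level = 0`; zero rows when no pair matches.
#' @export
match_candidates <- function(g_low, freqs, config = imputation_config()) {
  idx <- prepare_frequency_table(freqs)
  g_low <- as_genotype(g_low)
  if (any(is_high_resolution(g_low))) {
    abort("`g_low` must be at first-field resolution; see reduce_to_first_field().")
  }
  match_candidates_impl(g_low, idx, config)
}

match_candidates_impl <- function(g_low, idx, config) {
  pat <- enumerate_decompositions_impl(g_low)
  out_h1 <- list(); out_h2 <- list(); out_w <- list(); n_out <- 0L
  for (k in seq_len(nrow(pat))) {
    i1 <- idx$pattern_index[[pat$h1[k]]]
    i2 <- idx$pattern_index[[pat$h2[k]]]
    if (is.null(i1) || is.null(i2)) next
    if (pat$h1[k] == pat$h2[k]) {
      grid <- expand.grid(i = i1, j = i2, KEEP.OUT.ATTRS = FALSE)
      grid <- grid[grid$i <= grid$j, , drop = FALSE]
    } else {
      grid <- expand.grid(i = i1, j = i2, KEEP.OUT.ATTRS = FALSE)
    }
    if (nrow(grid) == 0L) next
    a <- idx$haplotype[grid$i]; b <- idx$haplotype[grid$j]
    w <- idx$frequency[grid$i] * idx$frequency[grid$j]
    if (config$hardy_weinberg) w <- w * (1 + (a != b))
    swap <- a > b
    h1 <- a; h1[swap] <- b[swap]
    h2 <- b; h2[swap] <- a[swap]
    n_out <- n_out + 1L
    out_h1[[n_out]] <- h1
    out_h2[[n_out]] <- h2
    out_w[[n_out]] <- w
  }
  if (n_out == 0L) return(candidate_tbl(character(0), character(0), numeric(0), 0L))
  candidate_tbl(unlist(out_h1), unlist(out_h2), unlist(out_w), 0L)
}

# Block-marginal frequency index for a set of loci: marginal frequencies of
# the block haplotypes (summing the table over the other loci) plus a
# first-field pattern index over block keys.
block_marginals <- function(idx, block) {
  key <- paste0("blk|", paste(block, collapse = "+"))
  cached <- idx$cache[[key]]
  if (!is.null(cached)) return(cached)
  rows <- match(block, hla_loci())
  mat <- haplotype_matrix(idx$haplotype)
  bk <- if (length(rows) == 1L) mat[rows, ] else apply(mat[rows, , drop = FALSE], 2, paste, collapse = "~")
  marg <- rowsum(idx$frequency, bk)
  bh <- rownames(marg)
  val <- list(haplotype = bh, frequency = as.numeric(marg),
              pattern_index = split(seq_along(bh), ff_truncate(bh)))
  assign(key, val, envir = idx$cache)
  val
}

# All block assemblies for one chromosome pattern at one ladder level.
# Returns list(haplotype = <full 5-locus pseudo-haplotype>, weight) or NULL
# when some block has no match. Assemblies are pruned to the top
# `max_options` by weight (deterministic tie-break on the haplotype string).
assemble_chromosomes <- function(idx, pattern, blocks, max_options) {
  pat_alleles <- strsplit(pattern, "~", fixed = TRUE)[[1]]
  acc_key <- character(1); acc_w <- numeric(1)
  # accumulate per block, carrying partial (locus -> allele) assignments
  parts <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    block <- blocks[[b]]
    rows <- match(block, hla_loci())
    want <- paste(pat_alleles[rows], collapse = "~")
    bm <- block_marginals(idx, block)
    hit <- bm$pattern_index[[want]]
    if (is.null(hit)) return(NULL)
    parts[[b]] <- list(key = bm$haplotype[hit], w = bm$frequency[hit], rows = rows)
  }
  # iterative cross product with pruning
  cur <- list(alleles = matrix(NA_character_, nrow = 5L, ncol = 1L), w = 1)
  for (b in seq_along(parts)) {
    p <- parts[[b]]
    n_cur <- length(cur$w); n_new <- length(p$w)
    w <- as.numeric(outer(cur$w, p$w))
    rep_cur <- rep(seq_len(n_cur), times = n_new)
    rep_new <- rep(seq_len(n_new), each = n_cur)
    alleles <- cur$alleles[, rep_cur, drop = FALSE]
    block_alleles <- do.call(cbind, strsplit(p$key, "~", fixed = TRUE))
    alleles[p$rows, ] <- block_alleles[, rep_new, drop = FALSE]
    if (length(w) > max_options) {
      keep <- order_weight_key(w, function(i) {
        apply(alleles[, i, drop = FALSE], 2, paste, collapse = "~")
      })[seq_len(max_options)]
      w <- w[keep]; alleles <- alleles[, keep, drop = FALSE]
    }
    cur <- list(alleles = alleles, w = w)
  }
  list(haplotype = apply(cur$alleles, 2, paste, collapse = "~"), weight = cur$w)
}

#' Fallback candidates under stepwise linkage relaxation
#'
#' Walks the configured ladder of locus-block partitions. At each level,
#' block-level marginal frequencies are derived from the table by summing
#' over the other loci; candidate pseudo-haplotypes assemble one block
#' haplotype per block and the candidate weight is the product of block
#' frequencies for both chromosomes times `fallback_penalty` per removed
#' linkage. The first ladder level producing at least one candidate wins;
#' later levels are never mixed in.
#'
#' @inheritParams match_candidates
#' @return Tibble of candidates with `fallback_level >= 1`; zero rows when
#'   every level fails.
#' @export
fallback_candidates <- function(g_low, freqs, config = imputation_config()) {
  idx <- prepare_frequency_table(freqs)
  g_low <- as_genotype(g_low)
  fallback_candidates_impl(g_low, idx, config)
}

fallback_candidates_impl <- function(g_low, idx, config) {
  pat <- enumerate_decompositions_impl(g_low)
  for (level in seq_along(config$fallback_ladder)) {
    blocks <- config$fallback_ladder[[level]]
    removed <- length(blocks) - 1L
    penalty <- config$fallback_penalty^removed
    out_h1 <- list(); out_h2 <- list(); out_w <- list(); n_out <- 0L
    side_cache <- new.env(parent = emptyenv())
    side <- function(pattern) {
      got <- side_cache[[pattern]]
      if (!is.null(got)) return(if (identical(got, FALSE)) NULL else got)
      val <- assemble_chromosomes(idx, pattern, blocks, config$max_chromosome_options)
      assign(pattern, if (is.null(val)) FALSE else val, envir = side_cache)
      val
    }
    for (k in seq_len(nrow(pat))) {
      s1 <- side(pat$h1[k]); if (is.null(s1)) next
      s2 <- side(pat$h2[k]); if (is.null(s2)) next
      same <- pat$h1[k] == pat$h2[k]
      grid <- expand.grid(i = seq_along(s1$weight), j = seq_along(s2$weight),
                          KEEP.OUT.ATTRS = FALSE)
      if (same) grid <- grid[grid$i <= grid$j, , drop = FALSE]
      if (nrow(grid) == 0L) next
      a <- s1$haplotype[grid$i]; b <- s2$haplotype[grid$j]
      w <- s1$weight[grid$i] * s2$weight[grid$j] * penalty
      if (config$hardy_weinberg) w <- w * (1 + (a != b))
      swap <- a > b
      h1 <- a; h1[swap] <- b[swap]
      h2 <- b; h2[swap] <- a[swap]
      n_out <- n_out + 1L
      out_h1[[n_out]] <- h1
      out_h2[[n_out]] <- h2
      out_w[[n_out]] <- w
    }
    if (n_out > 0L) {
      return(candidate_tbl(unlist(out_h1), unlist(out_h2), unlist(out_w), level))
    }
  }
  candidate_tbl(character(0), character(0), numeric(0), 0L)
}

#' Impute high-resolution genotypes from a first-field genotype
#'
#' Core imputation: candidate haplotype pairs are looked up in the
#' population table ([match_candidates()]); when none exist and `strict` is
#' off, the linkage-relaxation fallback is tried ([fallback_candidates()]).
#' Candidate weights are normalized, sorted descending (ties broken
#' lexicographically on the haplotype pair, making single imputation
#' deterministic), truncated to the minimal prefix reaching
#' `cumulative_mass`, and renormalized. In `"single"` mode only the top
#' candidate is kept with weight 1. An empty candidate set yields a failed
#' result, not an error.
#'
#' @inheritParams match_candidates
#' @return An object of class `hla_imputation`: a list with elements
#'   `input` (the low-resolution genotype), `population`, `candidates`
#'   (tibble `rank`, `h1`, `h2`, `weight`, `raw_weight`, `fallback_level`)
#'   and `failed`. Supports [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
#' @examples
#' freqs <- generate_frequency_tables(1, n_haplotypes = 8, seed = 1)
#' g <- reduce_to_first_field(genotype_from_haplotypes(
#'   freqs$haplotype[1], freqs$haplotype[2]))
#' impute(g, freqs)
impute <- function(g_low, freqs, config = imputation_config()) {
  idx <- prepare_frequency_table(freqs)
  g_low <- as_genotype(g_low)
  cand <- match_candidates_impl(g_low, idx, config)
  if (nrow(cand) == 0L && !config$strict) {
    cand <- fallback_candidates_impl(g_low, idx, config)
  }
  if (nrow(cand) == 0L) {
    return(new_hla_imputation(candidate_tbl(character(0), character(0), numeric(0), 0L),
                              input = g_low, population = idx$population, failed = TRUE,
                              config = config))
  }
  w <- cand$raw_weight / sum(cand$raw_weight)
  sub <- seq_along(w)
  if (length(w) > 2048L) {
    # preselect the highest-weight slice (ties at the threshold included)
    # when it already carries the required cumulative mass; the discarded
    # tail can then never enter the minimal qualifying prefix
    thr <- -sort(-w, partial = 1024L)[1024L]
    cand_sub <- which(w >= thr)
    if (sum(w[cand_sub]) >= config$cumulative_mass - 1e-12) sub <- cand_sub
  }
  ord <- sub[order_weight_key(w[sub], function(i) {
    paste(cand$h1[sub[i]], cand$h2[sub[i]], sep = "+")
  })]
  w <- w[ord]
  keep <- which(cumsum(w) >= config$cumulative_mass - 1e-12)[1L]
  if (is.na(keep)) keep <- length(w)
  keep <- min(keep, config$max_candidates)
  if (config$mode == "single") keep <- 1L
  sel <- ord[seq_len(keep)]
  w <- w[seq_len(keep)]
  out <- new_tibble(list(rank = seq_len(keep),
                         h1 = cand$h1[sel], h2 = cand$h2[sel],
                         weight = w / sum(w),
                         raw_weight = cand$raw_weight[sel],
                         fallback_level = cand$fallback_level[sel]),
                    nrow = keep)
  new_hla_imputation(out, input = g_low, population = idx$population,
                     failed = FALSE, config = config)
}

#' Construct an imputation result object
#'
#' Mostly for programmatic use (e.g. feeding externally computed candidate
#' sets to [aggregate_score()]); [impute()] is the normal constructor.
#'
#' @param candidates Tibble with columns `h1`, `h2`, `weight` (normalized),
#'   and optionally `raw_weight`, `fallback_level`, `rank`.
#' @param input Optional low-resolution input genotype.
#' @param population Optional population id.
#' @param failed Logical failure flag; a failed result has no candidates.
#' @param config Optional [imputation_config()].
#' @return An object of class `hla_imputation`.
#' @export
imputation_result <- function(candidates, input = NULL, population = NA_character_,
                              failed = FALSE, config = imputation_config()) {
  candidates <- as_tibble(candidates)
  if (!failed) {
    if (!all(c("h1", "h2", "weight") %in% names(candidates)) || nrow(candidates) == 0) {
      abort("Non-failed results need candidates with columns h1, h2, weight.")
    }
    if (abs(sum(candidates$weight) - 1) > 1e-6) {
      abort("Candidate weights must sum to 1.")
    }
    if (!"raw_weight" %in% names(candidates)) candidates$raw_weight <- candidates$weight
    if (!"fallback_level" %in% names(candidates)) candidates$fallback_level <- 0L
    if (!"rank" %in% names(candidates)) candidates$rank <- seq_len(nrow(candidates))
  }
  new_hla_imputation(candidates, input = input, population = population,
                     failed = failed, config = config)
}

new_hla_imputation <- function(candidates, input, population, failed, config) {
  structure(list(input = input, population = population,
                 candidates = candidates, failed = failed,
                 mode = config$mode, strict = config$strict,
                 cumulative_mass = config$cumulative_mass),
            class = "hla_imputation")
}

#' @export
print.hla_imputation <- function(x, ...) {
  cat("<hla_imputation> population ", x$population,
      if (x$failed) " [FAILED]" else paste0(": ", nrow(x$candidates), " candidate(s)"),
      "\n", sep = "")
  if (!x$failed) print(x$candidates, n = 5)
  invisible(x)
}

#' Impute every individual of a cohort under one ancestry assumption
#'
#' Genotypes are reduced to first-field resolution, deduplicated, imputed
#' against the given population table, and the candidate sets mapped back
#' to individuals. Failed imputations appear with `failed = TRUE` and no
#' candidate rows.
#'
#' @param cohort Cohort tibble with `id` and the [genotype_cols()] columns
#'   (any resolution; reduced internally).
#' @param freqs Frequency tibble or prepared index.
#' @param population Optional population id selecting the assumption table
#'   from a multi-population tibble.
#' @param config An [imputation_config()].
#' @return A tibble with one row per (individual, candidate):
#'   `id`, `assumption`, `failed`, `rank`, `h1`, `h2`, `weight`,
#'   `fallback_level` (failed individuals contribute one row with `NA`
#'   candidate fields).
#' @export
impute_cohort <- function(cohort, freqs, population = NULL,
                          config = imputation_config()) {
  idx <- prepare_frequency_table(freqs, population)
  if (!"id" %in% names(cohort)) abort("`cohort` needs an `id` column.")
  gmat <- as.matrix(reduce_to_first_field(cohort[, genotype_cols(), drop = FALSE]))
  keys <- apply(gmat, 1L, paste, collapse = "|")
  uniq <- !duplicated(keys)
  results <- lapply(which(uniq), function(i) {
    impute(setNames(gmat[i, ], genotype_cols()), idx, config)
  })
  names(results) <- keys[uniq]
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    res <- results[[keys[i]]]
    if (res$failed) {
      tibble(id = cohort$id[i], assumption = idx$population, failed = TRUE,
             rank = NA_integer_, h1 = NA_character_, h2 = NA_character_,
             weight = NA_real_, fallback_level = NA_integer_)
    } else {
      n <- nrow(res$candidates)
      new_tibble(list(id = rep.int(cohort$id[i], n),
                      assumption = rep.int(idx$population, n),
                      failed = rep.int(FALSE, n),
                      rank = res$candidates$rank,
                      h1 = res$candidates$h1, h2 = res$candidates$h2,
                      weight = res$candidates$weight,
                      fallback_level = res$candidates$fallback_level), nrow = n)
    }
  })
  list_rbind(rows)
}
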