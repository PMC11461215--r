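# two haplotypes sharing every first field (variant :01 vs :02), plus an
# unrelated third
hap_v <- function(variant, group = 1) {
  paste(sprintf("%s*%02d:%02d", loci5, group, variant), collapse = "~")
}

test_that("phase decomposition yields 2^(h-1) unordered patterns", {
  make_g <- function(h_het) {
    a1 <- sprintf("%s*01", loci5)
    a2 <- a1
    if (h_het > 0) a2[seq_len(h_het)] <- sprintf("%s*02", loci5[seq_len(h_het)])
    g <- as.vector(rbind(a1, a2))
    names(g) <- genotype_cols()
    as_genotype(g)
  }
  for (h_het in 0:5) {
    d <- enumerate_phase_decompositions(make_g(h_het))
    expect_equal(nrow(d), max(1L, 2L^(h_het - 1L)), info = paste("h =", h_het))
    expect_false(anyDuplicated(paste(d$h1, d$h2)) > 0)
    # every pattern recombines to the input genotype
    for (k in seq_len(nrow(d))) {
      expect_identical(genotype_from_haplotypes(d$h1[k], d$h2[k]), make_g(h_het))
    }
  }
})

test_that("natural candidates carry product weights, unordered pairs once", {
  freqs <- tibble::tibble(population = "P",
                          haplotype = c(hap_v(1), hap_v(2)),
                          frequency = c(0.6, 0.4))
  g_low <- reduce_to_first_field(genotype_from_haplotypes(hap_v(1), hap_v(2)))
  cand <- match_candidates(g_low, freqs)
  got <- setNames(cand$raw_weight, paste(cand$h1, cand$h2))
  expect_equal(got[[paste(hap_v(1), hap_v(1))]], 0.36)
  expect_equal(got[[paste(hap_v(1), hap_v(2))]], 0.24)
  expect_equal(got[[paste(hap_v(2), hap_v(2))]], 0.16)
  expect_equal(nrow(cand), 3L)
  expect_true(all(cand$fallback_level == 0L))

  # a group absent from every table haplotype -> no candidates
  g_none <- reduce_to_first_field(genotype_from_haplotypes(hap_v(1, group = 7),
                                                           hap_v(1, group = 7)))
  expect_equal(nrow(match_candidates(g_none, freqs)), 0L)

  # single matching haplotype -> the homozygous pair with weight f^2
  freqs1 <- freqs[1, ]
  g1 <- reduce_to_first_field(genotype_from_haplotypes(hap_v(1), hap_v(1)))
  cand1 <- match_candidates(g1, normalize_frequencies(freqs1))
  expect_equal(nrow(cand1), 1L)
  expect_equal(cand1$raw_weight, 1)

  expect_error(match_candidates(genotype_from_haplotypes(hap_v(1), hap_v(2)), freqs),
               "first-field")
})

test_that("truncation keeps the minimal qualifying prefix and single mode the argmax", {
  freqs <- tibble::tibble(population = "P",
                          haplotype = c(hap_v(1), hap_v(2)),
                          frequency = c(0.6, 0.4))
  g_low <- reduce_to_first_field(genotype_from_haplotypes(hap_v(1), hap_v(2)))
  res <- impute(g_low, freqs)
  # normalized weights 0.36/0.76, 0.24/0.76, 0.16/0.76; all retained at 0.99
  expect_equal(res$candidates$weight, c(0.36, 0.24, 0.16) / 0.76, tolerance = 1e-12)
  expect_equal(res$candidates$h1[1], hap_v(1))
  expect_equal(res$candidates$h2[1], hap_v(1))

  single <- impute(g_low, freqs, imputation_config(mode = "single"))
  expect_equal(nrow(single$candidates), 1L)
  expect_equal(single$candidates$weight, 1)
  expect_identical(single$candidates$h1, res$candidates$h1[1])
  expect_identical(single$candidates$h2, res$candidates$h2[1])

  # 0.995 / 0.005: only the dominant candidate survives mass 0.99
  freqs2 <- tibble::tibble(population = "P",
                           haplotype = c(hap_v(1), hap_v(2)),
                           frequency = c(sqrt(0.995), NA))
  freqs2$frequency[2] <- sqrt(0.995) * 0.005 / 0.995  # f1*f2/f1^2 = 0.005/0.995
  g_hom <- reduce_to_first_field(genotype_from_haplotypes(hap_v(1), hap_v(1)))
  res2 <- impute(g_hom, normalize_frequencies(freqs2),
                 imputation_config(cumulative_mass = 0.99))
  # candidates: (h1,h1), (h1,h2), (h2,h2); top two already exceed 0.99
  full <- impute(g_hom, normalize_frequencies(freqs2),
                 imputation_config(cumulative_mass = 1))
  cum <- cumsum(full$candidates$weight)
  expect_equal(nrow(res2$candidates), which(cum >= 0.99 - 1e-12)[1])
  expect_equal(sum(res2$candidates$weight), 1, tolerance = 1e-12)
})

test_that("truncation is monotone in the cumulative mass", {
  set.seed(42)
  for (rep in 1:25) {
    freqs <- random_small_table(12)
    g_low <- reduce_to_first_field(random_table_genotype(freqs))
    masses <- sort(runif(3, 0.3, 1))
    kept <- lapply(masses, function(m) {
      r <- impute(g_low, freqs, imputation_config(cumulative_mass = m))
      paste(r$candidates$h1, r$candidates$h2)
    })
    expect_true(all(kept[[1]] %in% kept[[2]]))
    expect_true(all(kept[[2]] %in% kept[[3]]))
  }
})

test_that("linkage fallback assembles penalized block candidates", {
  # the requested A group and the requested C~B~DRB1~DQB1 block both exist,
  # but never on one haplotype
  hA <- "A*02:01~C*01:01~B*01:01~DRB1*01:01~DQB1*01:01"
  hB <- "A*01:01~C*02:01~B*02:01~DRB1*02:01~DQB1*02:01"
  freqs <- tibble::tibble(population = "P", haplotype = c(hA, hB),
                          frequency = c(0.5, 0.5))
  want <- "A*01:01~C*01:01~B*01:01~DRB1*01:01~DQB1*01:01"
  g_low <- reduce_to_first_field(genotype_from_haplotypes(want, want))
  expect_equal(nrow(match_candidates(g_low, freqs)), 0L)

  cfg <- imputation_config()
  cand <- fallback_candidates(g_low, freqs, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$fallback_level, 1L)
  expect_identical(cand$h1, want)
  expect_identical(cand$h2, want)
  # one chromosome = f(A*01 marginal) * f(C~B~DRB1~DQB1 block marginal),
  # pair weight = product over both chromosomes, one removed linkage
  chrom_w <- 0.5 * 0.5
  expect_equal(cand$raw_weight, chrom_w * chrom_w * cfg$fallback_penalty,
               tolerance = 1e-15)

  # a group absent from the whole table still fails at every level
  g_absent <- reduce_to_first_field(genotype_from_haplotypes(
    "A*09:01~C*01:01~B*01:01~DRB1*01:01~DQB1*01:01",
    "A*09:01~C*01:01~B*01:01~DRB1*01:01~DQB1*01:01"))
  expect_equal(nrow(fallback_candidates(g_absent, freqs, cfg)), 0L)
  res <- impute(g_absent, freqs)
  expect_true(res$failed)
  expect_equal(nrow(res$candidates), 0L)

  # strict mode fails instead of falling back
  strict <- impute(g_low, freqs, imputation_config(strict = TRUE))
  expect_true(strict$failed)
  nonstrict <- impute(g_low, freqs)
  expect_false(nonstrict$failed)
  expect_true(all(nonstrict$candidates$fallback_level == 1L))
})

test_that("fallback weights match direct marginalization at every ladder level", {
  set.seed(7)
  for (rep in 1:10) {
    freqs <- random_small_table(8, n_groups = 3, n_variants = 1)
    idx <- prepare_frequency_table(freqs)
    cfg <- imputation_config()
    g_low <- reduce_to_first_field(random_table_genotype(freqs))
    # force fallback by asking for a cross-haplotype combination
    i <- sample.int(nrow(freqs), 2)
    mixed <- strsplit(freqs$haplotype[i], "~")
    forced <- paste(c(mixed[[1]][1], mixed[[2]][2:5]), collapse = "~")
    g_forced <- reduce_to_first_field(genotype_from_haplotypes(forced, forced))
    if (nrow(match_candidates(g_forced, idx)) > 0) next
    cand <- fallback_candidates(g_forced, idx, cfg)
    if (nrow(cand) == 0) next
    lvl <- cand$fallback_level[1]
    blocks <- cfg$fallback_ladder[[lvl]]
    # oracle: marginal of a block haplotype = sum of table frequencies
    # agreeing with it on the block loci
    marginal <- function(hap, block) {
      rows <- match(block, loci5)
      keys <- vapply(strsplit(freqs$haplotype, "~"), function(x) {
        paste(x[rows], collapse = "~")
      }, character(1))
      want <- paste(strsplit(hap, "~")[[1]][rows], collapse = "~")
      sum(idx$frequency[keys == want])
    }
    for (r in seq_len(nrow(cand))) {
      w1 <- prod(vapply(blocks, function(b) marginal(cand$h1[r], b), numeric(1)))
      w2 <- prod(vapply(blocks, function(b) marginal(cand$h2[r], b), numeric(1)))
      expect_equal(cand$raw_weight[r],
                   w1 * w2 * cfg$fallback_penalty^(length(blocks) - 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("exactly identifiable genotypes are recovered with weight one", {
  set.seed(13)
  freqs <- unique_group_table(20)
  for (rep in 1:20) {
    i <- sample.int(20, 2, replace = TRUE)
    pair <- sort(freqs$haplotype[i])
    g_low <- reduce_to_first_field(genotype_from_haplotypes(pair[1], pair[2]))
    res <- impute(g_low, freqs)
    expect_false(res$failed)
    expect_equal(nrow(res$candidates), 1L)
    expect_equal(res$candidates$weight, 1)
    expect_identical(c(res$candidates$h1, res$candidates$h2), pair)
  }
})

test_that("cohort imputation maps candidate sets back to individuals", {
  freqs <- generate_frequency_tables(1, n_haplotypes = 15, seed = 21)
  co <- simulate_cohort(freqs, 10, seed = 22)
  imp <- impute_cohort(co, freqs)
  expect_setequal(unique(imp$id), co$id)
  expect_true(all(imp$assumption == "POP01"))
  ok <- imp[!imp$failed, ]
  sums <- tapply(ok$weight, ok$id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # every candidate reduces to the individual's low-resolution genotype
  i <- which(co$id == ok$id[1])
  g_low_key <- paste(reduce_to_first_field(as_genotype(co[i, genotype_cols()])),
                     collapse = "|")
  for (r in which(ok$id == ok$id[1])) {
    g <- reduce_to_first_field(genotype_from_haplotypes(ok$h1[r], ok$h2[r]))
    expect_identical(paste(g, collapse = "|"), g_low_key)
  }
})

test_that("imputation results expose tidy and glance views", {
  freqs <- tibble::tibble(population = "P",
                          haplotype = c(hap_v(1), hap_v(2)),
                          frequency = c(0.6, 0.4))
  g_low <- reduce_to_first_field(genotype_from_haplotypes(hap_v(1), hap_v(2)))
  res <- impute(g_low, freqs)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  gl <- generics::glance(res)
  expect_equal(gl$n_candidates, 3L)
  expect_false(gl$failed)
})
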