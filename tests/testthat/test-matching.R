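test_that("self-vs-self and protein-identical genotypes score zero", {
  set.seed(31)
  db <- random_toy_db()
  g <- random_toy_genotype(db)
  expect_equal(pirche_score(g, g, db), 0L)
  expect_equal(snow_score(g, g, db), 0L)

  # donor differing only by alleles with identical sequences scores 0
  seqs <- db$sequences
  extra <- seqs[seqs$allele == "A*01:01", ]
  extra$allele <- "A*09:01"
  db2 <- sequence_db(dplyr::bind_rows(seqs, extra), db$exposure)
  gp <- g; gp[c("A_1", "A_2")] <- c("A*01:01", "A*01:01")
  gd <- gp; gd[c("A_1", "A_2")] <- c("A*09:01", "A*09:01")
  expect_equal(pirche_score(gp, gd, db2), 0L)
  expect_equal(snow_score(gp, gd, db2), 0L)
})

test_that("scorers match exhaustive tuple enumeration on toy databases", {
  set.seed(32)
  for (rep in 1:20) {
    db <- random_toy_db(alleles_per_locus = 4, len = sample(9:12, 1),
                        n_exposed = sample(2:4, 1))
    predictor <- make_anchor_predictor(db)
    scalar_pred <- function(p, core) predictor(p, core)
    for (j in 1:3) {
      gp <- random_toy_genotype(db)
      gd <- random_toy_genotype(db)
      expect_equal(pirche_score(gp, gd, db, predictor),
                   oracle_pirche(gp, gd, db, scalar_pred))
      expect_equal(snow_score(gp, gd, db), oracle_snow(gp, gd, db))
      # invariance under within-locus allele swap
      gp2 <- gp[c(2, 1, 3:10)]; names(gp2) <- names(gp)
      expect_equal(pirche_score(gp2, gd, db, predictor),
                   pirche_score(gp, gd, db, predictor))
      expect_equal(snow_score(gp2, gd, db), snow_score(gp, gd, db))
    }
  }
})

test_that("a custom first-residue predictor reproduces hand enumeration", {
  # presenter presents a core iff their first residues agree
  pred <- function(presenter, cores) {
    substring(cores, 1, 1) == substring(presenter, 1, 1)
  }
  set.seed(33)
  db <- random_toy_db(alleles_per_locus = 3, len = 11)
  for (rep in 1:10) {
    gp <- random_toy_genotype(db)
    gd <- random_toy_genotype(db)
    expect_equal(pirche_score(gp, gd, db, pred),
                 oracle_pirche(gp, gd, db, function(p, core) pred(p, core)))
  }
})

test_that("an always-false predictor scores zero everywhere", {
  set.seed(34)
  db <- random_toy_db()
  never <- function(presenter, cores) rep(FALSE, length(cores))
  for (rep in 1:5) {
    expect_equal(pirche_score(random_toy_genotype(db), random_toy_genotype(db),
                              db, never), 0L)
  }
})

test_that("identical homozygous presenters are not counted separately", {
  set.seed(35)
  db <- random_toy_db(alleles_per_locus = 3, len = 12)
  seqs <- db$sequences
  # DRB1*03:01 gets the same protein as DRB1*01:01
  seqs$sequence[seqs$allele == "DRB1*03:01"] <-
    seqs$sequence[seqs$allele == "DRB1*01:01"]
  db2 <- sequence_db(seqs, db$exposure)
  gd <- random_toy_genotype(db2)
  hom <- random_toy_genotype(db2)
  hom[c("DRB1_1", "DRB1_2")] <- c("DRB1*01:01", "DRB1*01:01")
  twin <- hom
  twin[c("DRB1_1", "DRB1_2")] <- c("DRB1*01:01", "DRB1*03:01")
  expect_equal(pirche_score(twin, gd, db2), pirche_score(hom, gd, db2))
})

test_that("a single exposed substitution gives a snow score of one", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- vapply(loci5, function(l) paste(rep("A", 10), collapse = ""), character(1))
  seqs <- dplyr::bind_rows(lapply(loci5, function(l) {
    tibble::tibble(locus = l,
                   allele = sprintf("%s*0%d:01", l, 1:2),
                   sequence = paste(rep("A", 10), collapse = ""))
  }))
  # donor B*02:01 differs from both patient B alleles at exposed position 4
  seqs$sequence[seqs$allele == "B*02:01"] <- "AAAWAAAAAA"
  expo <- tibble::tibble(locus = loci5, position = 4L)
  db <- sequence_db(seqs, expo)
  gp <- as_genotype(sprintf("%s*01:01", rep(loci5, each = 2)), validate = FALSE)
  names(gp) <- genotype_cols()
  gd <- gp; gd[c("B_1", "B_2")] <- c("B*01:01", "B*02:01")
  expect_equal(snow_score(gp, gd, db), 1L)
  # removing the exposed position removes the mismatch
  db_empty <- sequence_db(seqs, expo[expo$locus != "B", ])
  expect_equal(snow_score(gp, gd, db_empty), 0L)
})

test_that("snow score never increases when the exposure mask shrinks", {
  set.seed(36)
  for (rep in 1:10) {
    db <- random_toy_db(alleles_per_locus = 3, len = 12, n_exposed = 4)
    gp <- random_toy_genotype(db); gd <- random_toy_genotype(db)
    full <- snow_score(gp, gd, db)
    shrunk <- db$exposure |> dplyr::group_by(locus) |> dplyr::slice_head(n = 2) |>
      dplyr::ungroup()
    expect_lte(snow_score(gp, gd, sequence_db(db$sequences, shrunk)), full)
  }
})

test_that("aggregation is the weighted mean over candidate cross-products", {
  set.seed(37)
  db <- random_toy_db()
  gp <- random_toy_genotype(db)
  gd <- random_toy_genotype(db)
  # fixed genotypes on both sides reduce to the plain score
  agg <- aggregate_score(gp, gd, "pirche", db)
  expect_equal(agg$value, pirche_score(gp, gd, db))
  expect_equal(agg$n_candidate_combinations, 1L)

  # hand-computed weighted sum: donor candidates 0.75 / 0.25, scores 4 and 8
  h_a <- paste(sprintf("%s*01:01", loci5), collapse = "~")
  h_b <- paste(sprintf("%s*02:01", loci5), collapse = "~")
  donor_res <- imputation_result(tibble::tibble(
    h1 = c(h_a, h_b), h2 = c(h_a, h_b), weight = c(0.75, 0.25)))
  stub <- local({
    lookup <- c(4, 8)
    function(p, d, db) lookup[[if (d[["A_1"]] == "A*01:01") 1L else 2L]]
  })
  agg2 <- aggregate_score(gp, donor_res, stub, db)
  expect_equal(agg2$value, 0.75 * 4 + 0.25 * 8)
  expect_equal(agg2$n_candidate_combinations, 2L)

  # identical scores everywhere are invariant to the weights
  const <- function(p, d, db) 7
  agg3 <- aggregate_score(donor_res, donor_res, const, db)
  expect_equal(agg3$value, 7)

  # failed side propagates
  failed <- imputation_result(tibble::tibble(h1 = character(0), h2 = character(0),
                                             weight = numeric(0)), failed = TRUE)
  agg4 <- aggregate_score(gp, failed, "snow", db)
  expect_true(agg4$failed)
  expect_true(is.na(agg4$value))
})

test_that("aggregated scores stay within the pairwise score range", {
  set.seed(38)
  db <- random_toy_db(alleles_per_locus = 4)
  for (rep in 1:20) {
    mk <- function(n) {
      haps <- vapply(seq_len(n), function(i) {
        paste(vapply(loci5, function(l) {
          sample(db$sequences$allele[db$sequences$locus == l], 1)
        }, character(1)), collapse = "~")
      }, character(1))
      w <- rgamma(n, 1); w <- w / sum(w)
      imputation_result(tibble::tibble(h1 = haps, h2 = rev(haps), weight = w))
    }
    pr <- mk(sample(1:4, 1)); dr <- mk(sample(1:4, 1))
    for (sc in c("pirche", "snow")) {
      agg <- aggregate_score(pr, dr, sc, db)
      pw <- outer(seq_len(nrow(pr$candidates)), seq_len(nrow(dr$candidates)),
                  Vectorize(function(i, j) {
        g1 <- genotype_from_haplotypes(pr$candidates$h1[i], pr$candidates$h2[i])
        g2 <- genotype_from_haplotypes(dr$candidates$h1[j], dr$candidates$h2[j])
        if (sc == "pirche") pirche_score(g1, g2, db) else snow_score(g1, g2, db)
      }))
      expect_gte(agg$value, min(pw) - 1e-9)
      expect_lte(agg$value, max(pw) + 1e-9)
      # exact double-sum oracle
      w <- outer(pr$candidates$weight, dr$candidates$weight)
      expect_equal(agg$value, sum(w * pw) / sum(w), tolerance = 1e-12)
    }
  }
})
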