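# Independent brute-force oracles and fixture builders shared by the
# unit and acceptance tests. Everything here is deliberately written in
# the most naive way possible and never reuses package internals beyond
# the public parsing/formatting helpers.

loci5 <- c("A", "C", "B", "DRB1", "DQB1")

# Brute-force imputation oracle: scan all unordered haplotype pairs of
# the table, keep those whose implied genotype reduces to `g_low`,
# weight = product of the two frequencies, normalize.
oracle_impute <- function(g_low, freqs) {
  f <- freqs$frequency / sum(freqs$frequency)
  h <- freqs$haplotype
  # first-field allele matrix of every table haplotype (plain string ops,
  # no package parsing involved)
  ff <- matrix(unlist(strsplit(gsub(":[0-9]+", "", h), "~", fixed = TRUE)),
               nrow = 5L)
  key_low <- paste(g_low[genotype_cols()], collapse = "|")
  out <- list(); k <- 0L
  for (i in seq_along(h)) {
    for (j in i:length(h)) {
      key <- character(10L)
      for (l in 1:5) {
        a <- ff[l, i]; b <- ff[l, j]
        key[2L * l - 1L] <- if (a <= b) a else b
        key[2L * l] <- if (a <= b) b else a
      }
      if (paste(key, collapse = "|") == key_low) {
        k <- k + 1L
        pair <- sort(c(h[i], h[j]))
        out[[k]] <- data.frame(h1 = pair[1], h2 = pair[2], w = f[i] * f[j])
      }
    }
  }
  if (k == 0L) return(NULL)
  res <- do.call(rbind, out)
  res$w <- res$w / sum(res$w)
  res[order(-res$w, paste(res$h1, res$h2)), ]
}

# Exhaustive (core, presenter) tuple enumeration for the T-cell scorer.
oracle_pirche <- function(patient, donor, db, predictor) {
  windows_of <- function(allele) {
    s <- db$sequences$sequence[db$sequences$allele == allele]
    L <- nchar(s)
    if (L < 9) character(0) else substring(s, 1:(L - 8), 9:L)
  }
  donor_cores <- unique(unlist(lapply(unique(unname(donor)), windows_of)))
  self_pep <- unique(unlist(lapply(unique(unname(patient)), windows_of)))
  presenters <- unique(vapply(unique(unname(patient[c("DRB1_1", "DRB1_2")])),
                              function(a) db$sequences$sequence[db$sequences$allele == a],
                              character(1)))
  n <- 0L
  for (core in donor_cores) {
    if (core %in% self_pep) next
    for (p in presenters) {
      if (predictor(p, core)) n <- n + 1L
    }
  }
  n
}

# Exhaustive (locus, position, residue) scan for the B-cell scorer.
oracle_snow <- function(patient, donor, db) {
  n <- 0L
  for (locus in loci5) {
    pos <- db$exposure$position[db$exposure$locus == locus]
    d_alleles <- unique(unname(donor[paste0(locus, c("_1", "_2"))]))
    p_alleles <- unique(unname(patient[paste0(locus, c("_1", "_2"))]))
    seq_of <- function(a) db$sequences$sequence[db$sequences$allele == a]
    for (p in pos) {
      d_res <- unique(vapply(d_alleles, function(a) substr(seq_of(a), p, p), character(1)))
      p_res <- unique(vapply(p_alleles, function(a) substr(seq_of(a), p, p), character(1)))
      n <- n + sum(!d_res %in% p_res)
    }
  }
  n
}

# Random small frequency table over a deliberately collision-rich allele
# pool (few groups, few variants) so that first-field patterns recur.
random_small_table <- function(n_haplotypes, n_groups = 2, n_variants = 2,
                               population = "TST") {
  pool <- lapply(loci5, function(locus) {
    as.vector(outer(seq_len(n_groups), seq_len(n_variants), function(g, v) {
      sprintf("%s*%02d:%02d", locus, g, v)
    }))
  })
  h <- unique(vapply(seq_len(n_haplotypes * 3), function(i) {
    paste(vapply(pool, sample, character(1), size = 1), collapse = "~")
  }, character(1)))
  h <- h[seq_len(min(length(h), n_haplotypes))]
  w <- stats::rgamma(length(h), shape = 0.5) + 1e-9
  tibble::tibble(population = population, haplotype = h, frequency = w / sum(w))
}

# Table in which every haplotype carries its own private first-field
# group at every locus, so each reduced genotype has a unique consistent
# haplotype pair.
unique_group_table <- function(n_haplotypes, population = "UNIQ") {
  h <- vapply(seq_len(n_haplotypes), function(k) {
    paste(sprintf("%s*%02d:01", loci5, k), collapse = "~")
  }, character(1))
  w <- stats::rgamma(n_haplotypes, shape = 0.3) + 1e-9
  tibble::tibble(population = population, haplotype = h, frequency = w / sum(w))
}

# Tiny hand-rollable sequence database: random sequences per allele,
# shared alignment length per locus, random exposure mask.
random_toy_db <- function(alleles_per_locus = 3, len = 12, n_exposed = 3) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- list(); expo <- list()
  for (locus in loci5) {
    alle <- sprintf("%s*%02d:01", locus, seq_len(alleles_per_locus))
    seqs[[locus]] <- tibble::tibble(
      locus = locus, allele = alle,
      sequence = vapply(alle, function(a) {
        paste(sample(aa, len, replace = TRUE), collapse = "")
      }, character(1)))
    expo[[locus]] <- tibble::tibble(locus = locus,
                                    position = sort(sample.int(len, n_exposed)))
  }
  sequence_db(dplyr::bind_rows(seqs), dplyr::bind_rows(expo))
}

# Genotype drawing both alleles per locus from a toy db's allele set.
random_toy_genotype <- function(db) {
  g <- unlist(lapply(loci5, function(locus) {
    alle <- db$sequences$allele[db$sequences$locus == locus]
    sort(sample(alle, 2, replace = TRUE))
  }))
  names(g) <- genotype_cols()
  g
}

# Random genotype whose reduction is guaranteed imputable from `freqs`:
# the union of two random table haplotypes.
random_table_genotype <- function(freqs) {
  i <- sample.int(nrow(freqs), 2, replace = TRUE)
  genotype_from_haplotypes(freqs$haplotype[i[1]], freqs$haplotype[i[2]])
}
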