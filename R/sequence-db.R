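amino_acids <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an aligned HLA protein sequence database
#'
#' The molecular-mismatch scorers work on per-locus protein alignments plus
#' a per-locus surface-exposure mask (the alignment positions treated as
#' antibody-accessible). This constructor accepts user data; for synthetic
#' studies use [generate_sequence_db()].
#'
#' @param sequences Tibble/data frame with columns `locus`, `allele`,
#'   `sequence`; all sequences at a locus must share one alignment length.
#' @param exposure Tibble with columns `locus`, `position` (1-based
#'   alignment positions of surface-exposed residues).
#' @return An object of class `hla_seqdb`.
#' @export
sequence_db <- function(sequences, exposure) {
  if (!all(c("locus", "allele", "sequence") %in% names(sequences))) {
    abort("`sequences` needs columns locus, allele, sequence.")
  }
  if (!all(c("locus", "position") %in% names(exposure))) {
    abort("`exposure` needs columns locus, position.")
  }
  sequences <- as_tibble(sequences)
  exposure <- as_tibble(exposure) |> mutate(position = as.integer(.data$position))
  if (anyDuplicated(sequences$allele)) abort("Duplicate allele in `sequences`.")
  len <- tapply(nchar(sequences$sequence), sequences$locus, unique, simplify = FALSE)
  if (any(lengths(len) != 1L)) {
    abort(paste0("Unequal sequence lengths within locus: ",
                 paste(names(len)[lengths(len) != 1L], collapse = ", ")))
  }
  alignment_length <- vapply(len, `[[`, 1L, 1L)
  for (locus in unique(exposure$locus)) {
    pos <- exposure$position[exposure$locus == locus]
    if (any(pos < 1L) || (locus %in% names(alignment_length) &&
                          any(pos > alignment_length[[locus]]))) {
      abort(paste0("Exposure positions outside the ", locus, " alignment."))
    }
  }
  structure(
    list(sequences = sequences, exposure = exposure,
         alignment_length = alignment_length, cache = new.env(parent = emptyenv())),
    class = "hla_seqdb"
  )
}

#' @export
print.hla_seqdb <- function(x, ...) {
  cat("<hla_seqdb> ", nrow(x$sequences), " alleles over ",
      length(unique(x$sequences$locus)), " loci\n", sep = "")
  for (locus in unique(x$sequences$locus)) {
    cat("  ", locus, ": ", sum(x$sequences$locus == locus), " alleles, length ",
        x$alignment_length[[locus]], ", ",
        sum(x$exposure$locus == locus), " exposed positions\n", sep = "")
  }
  invisible(x)
}

#' Generate a synthetic aligned sequence database
#'
#' Stand-in for curated HLA protein alignments and structural exposure
#' annotation. Sequences are built hierarchically — a per-locus consensus,
#' a per-first-field-group consensus carrying twice the per-allele number
#' of substitutions, and per-allele substitutions on top — so that alleles
#' sharing a first field are genuinely more similar than alleles across
#' groups, mirroring the shared protein motifs of real HLA allele groups.
#' The exposure mask is drawn once per locus.
#'
#' @param alleles Character vector of two-field allele names (the loci are
#'   taken from the names); identical names always receive identical
#'   sequences.
#' @param alignment_length Alignment length per locus (default 30).
#' @param n_exposed Number of exposed positions per locus (default 10).
#' @param polymorphic_fraction Fraction of positions substituted per allele
#'   relative to its group consensus (default 0.1); 0 makes all alleles at a
#'   locus identical (and all downstream mismatch scores 0).
#' @param seed Integer seed; output is deterministic given the seed and the
#'   allele set (allele order does not matter).
#' @return An `hla_seqdb` object.
#' @export
generate_sequence_db <- function(alleles, alignment_length = 30L, n_exposed = 10L,
                                 polymorphic_fraction = 0.1, seed = NULL) {
  parsed <- parse_allele(unique(alleles))
  if (any(is.na(parsed$field2))) {
    abort("Sequence databases are defined for two-field alleles only.")
  }
  if (alignment_length < n_exposed || n_exposed < 1L) {
    abort("Need alignment_length >= n_exposed >= 1.")
  }
  parsed <- arrange(parsed, .data$locus, .data$allele)
  aa <- amino_acids()
  n_sub <- round(polymorphic_fraction * alignment_length)
  mutate_positions <- function(seq_chars, n) {
    if (n == 0L) return(seq_chars)
    pos <- sample.int(length(seq_chars), n)
    for (p in pos) {
      seq_chars[p] <- sample(setdiff(aa, seq_chars[p]), 1L)
    }
    seq_chars
  }
  run_seeded(seed, function() {
    seq_rows <- list()
    exp_rows <- list()
    for (locus in hla_loci()) {
      sub <- parsed[parsed$locus == locus, , drop = FALSE]
      consensus <- sample(aa, alignment_length, replace = TRUE)
      exp_rows[[locus]] <- tibble(locus = locus,
                                  position = sort(sample.int(alignment_length, n_exposed)))
      if (nrow(sub) == 0) next
      groups <- unique(sub$field1)
      group_seq <- lapply(setNames(nm = groups), function(g) {
        mutate_positions(consensus, min(alignment_length, 2L * n_sub))
      })
      seqs <- vapply(seq_len(nrow(sub)), function(i) {
        paste(mutate_positions(group_seq[[sub$field1[i]]], n_sub), collapse = "")
      }, character(1))
      seq_rows[[locus]] <- tibble(locus = locus, allele = sub$allele, sequence = seqs)
    }
    sequence_db(list_rbind(unname(seq_rows)), list_rbind(unname(exp_rows)))
  })
}

#' Write a sequence database to disk
#'
#' One aligned FASTA per locus (record ids are allele names) plus an
#' `exposure.tsv` with columns `locus`, `position`.
#'
#' @param db An `hla_seqdb`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence_db <- function(db, dir) {
  stopifnot(inherits(db, "hla_seqdb"))
  rlang::check_installed("Biostrings")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (locus in unique(db$sequences$locus)) {
    sub <- db$sequences[db$sequences$locus == locus, ]
    aas <- Biostrings::AAStringSet(setNames(sub$sequence, sub$allele))
    Biostrings::writeXStringSet(aas, file.path(dir, paste0(locus, ".fasta")))
  }
  readr::write_tsv(db$exposure, file.path(dir, "exposure.tsv"))
  invisible(dir)
}

#' Read a sequence database written by [write_sequence_db()]
#'
#' @param dir Directory holding per-locus FASTA files and `exposure.tsv`.
#' @return An `hla_seqdb` object.
#' @export
read_sequence_db <- function(dir) {
  rlang::check_installed("Biostrings")
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(fastas) == 0) abort(paste0("No FASTA files found in ", dir))
  seqs <- list_rbind(lapply(fastas, function(f) {
    aas <- Biostrings::readAAStringSet(f)
    tibble(locus = sub("\\.fasta$", "", basename(f)),
           allele = names(aas), sequence = unname(as.character(aas)))
  }))
  exposure <- readr::read_tsv(file.path(dir, "exposure.tsv"),
                              col_types = readr::cols(locus = readr::col_character(),
                                                      position = readr::col_integer()))
  sequence_db(seqs, exposure)
}

# ---- cached per-allele lookups used by the scorers ----------------------

db_cached <- function(db, key, fn) {
  if (!is.null(db$cache[[key]])) return(db$cache[[key]])
  val <- fn()
  assign(key, val, envir = db$cache)
  val
}

db_sequence <- function(db, allele) {
  map <- db_cached(db, ".seq_map", function() {
    setNames(db$sequences$sequence, db$sequences$allele)
  })
  s <- map[allele]
  if (anyNA(s)) {
    abort(paste0("Allele(s) missing from the sequence database: ",
                 paste(allele[is.na(s)], collapse = ", ")))
  }
  s
}

# All 9-mer windows of one allele's sequence.
db_windows <- function(db, allele) {
  db_cached(db, paste0("w|", allele), function() {
    s <- db_sequence(db, allele)
    L <- nchar(s)
    if (L < 9L) return(character(0))
    unique(substring(s, 1:(L - 8L), 9:L))
  })
}

db_exposed_positions <- function(db, locus) {
  sort(db$exposure$position[db$exposure$locus == locus])
}

# Exposed (locus, position, residue) tuples of one allele, as strings.
db_exposed_tuples <- function(db, allele) {
  db_cached(db, paste0("t|", allele), function() {
    locus <- sub("\\*.*$", "", allele)
    pos <- db_exposed_positions(db, locus)
    if (length(pos) == 0) return(character(0))
    s <- db_sequence(db, allele)
    unique(paste0(locus, ":", pos, ":", substring(s, pos, pos)))
  })
}

# Residues of a presenter (DRB1) sequence at its exposure-masked positions.
db_presenter_residues <- function(db, presenter_seq) {
  db_cached(db, paste0("p|", presenter_seq), function() {
    pos <- db_exposed_positions(db, "DRB1")
    unique(substring(presenter_seq, pos, pos))
  })
}
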