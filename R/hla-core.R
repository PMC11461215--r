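#' The five HLA loci handled by this package
#'
#' All objects in the package (haplotypes, genotypes, frequency tables,
#' scorers) work on the classical transplant-relevant loci HLA-A, -C, -B,
#' -DRB1 and -DQB1. The canonical order follows the physical gene order on
#' chromosome 6p21 as it appears in haplotype strings
#' (e.g. `A*11:01~C*12:03~B*27:12~DRB1*16:01~DQB1*05:02`).
#'
#' @return Character vector of the five locus names in canonical order.
#' @export
#' @examples
#' hla_loci()
hla_loci <- function() c("A", "C", "B", "DRB1", "DQB1")

#' Genotype column names used across the package
#'
#' A five-locus genotype is stored "wide" as ten character columns, two
#' unordered alleles per locus. Within a locus the two alleles are kept in
#' sorted string order so that genotype equality is a plain row comparison.
#'
#' @return Character vector `c("A_1", "A_2", ..., "DQB1_2")`.
#' @export
genotype_cols <- function() paste0(rep(hla_loci(), each = 2L), c("_1", "_2"))

allele_regex <- "^([A-Za-z0-9]+)\\*([0-9]+)(:([0-9]+))?$"

#' Parse HLA allele names
#'
#' Accepts standard two-field protein-level names (`"DRB1*15:01"`) and
#' first-field allele-group names (`"A*11"`). Expression suffixes (N/L/Q/...)
#' and names with more than two fields are rejected rather than truncated:
#' the package operates strictly at the two-field protein level.
#'
#' @param text Character vector of allele names.
#' @return A tibble with one row per input: `allele` (canonical form),
#'   `locus`, `field1`, `field2` (`NA` for first-field names).
#' @export
#' @examples
#' parse_allele(c("DRB1*15:01", "A*11"))
parse_allele <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    abort("`text` must be a non-empty character vector of allele names.")
  }
  m <- regmatches(text, regexec(allele_regex, text))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    abort(paste0("Malformed allele name(s): ",
                 paste(unique(text[bad]), collapse = ", "),
                 ". Expected LOCUS*F1 or LOCUS*F1:F2 with digit fields."))
  }
  locus <- vapply(m, `[[`, character(1), 2L)
  field1 <- vapply(m, `[[`, character(1), 3L)
  field2 <- vapply(m, `[[`, character(1), 5L)
  field2[field2 == ""] <- NA_character_
  unknown <- !locus %in% hla_loci()
  if (any(unknown)) {
    abort(paste0("Unsupported locus in allele name(s): ",
                 paste(unique(text[unknown]), collapse = ", "),
                 ". Supported loci: ", paste(hla_loci(), collapse = ", "), "."))
  }
  tibble(
    allele = format_allele(locus, field1, field2),
    locus = locus, field1 = field1, field2 = field2
  )
}

#' Format allele names from their parts
#'
#' @param locus,field1,field2 Character vectors; `field2` may be `NA` for
#'   first-field (allele-group) names.
#' @return Character vector of canonical allele names.
#' @export
format_allele <- function(locus, field1, field2 = NA_character_) {
  suffix <- ifelse(is.na(field2), "", paste0(":", field2))
  paste0(locus, "*", field1, suffix)
}

#' Test whether allele names are at two-field (high) resolution
#'
#' @param allele Character vector of allele names.
#' @return Logical vector.
#' @export
is_high_resolution <- function(allele) grepl(":", allele, fixed = TRUE)

# Fast unvalidated first-field truncation (works on alleles and on
# ~-joined haplotype strings alike).
ff_truncate <- function(x) gsub(":[0-9]+", "", x)

#' Reduce alleles, haplotypes or genotypes to first-field resolution
#'
#' Drops the second field of every allele name, yielding allele-group level
#' ("low resolution") data, which is the input resolution of the imputation
#' algorithm. The operation is idempotent and locus-preserving. For genotype
#' input the within-locus sorted order is re-established after truncation.
#'
#' @param x A character vector of allele or `~`-joined haplotype strings, a
#'   named genotype vector as returned by [as_genotype()], or a data frame
#'   containing (some of) the [genotype_cols()] columns, in which case those
#'   columns are reduced and the rest are passed through.
#' @return An object of the same shape as `x` at first-field resolution.
#' @export
#' @examples
#' reduce_to_first_field(c("DQB1*06:02", "DQB1*06:04"))
reduce_to_first_field <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(genotype_cols(), names(x))
    if (length(cols) == 0) {
      abort("No genotype columns found; expected columns like 'A_1', 'A_2', ...")
    }
    for (locus in hla_loci()) {
      c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
      if (c1 %in% cols && c2 %in% cols) {
        a <- ff_truncate(x[[c1]]); b <- ff_truncate(x[[c2]])
        swap <- a > b
        x[[c1]] <- ifelse(swap, b, a)
        x[[c2]] <- ifelse(swap, a, b)
      } else if (c1 %in% cols) {
        x[[c1]] <- ff_truncate(x[[c1]])
      } else if (c2 %in% cols) {
        x[[c2]] <- ff_truncate(x[[c2]])
      }
    }
    return(x)
  }
  if (!is.character(x)) abort("`x` must be a character vector or data frame.")
  out <- ff_truncate(x)
  if (!is.null(names(x)) && setequal(names(x), genotype_cols())) {
    out <- as_genotype(out[genotype_cols()])
  }
  out
}

#' Parse haplotype strings
#'
#' A haplotype is written as five `~`-joined alleles, one per locus.
#' Tokens may come in any order; the result is always serialized in the
#' canonical locus order A, C, B, DRB1, DQB1. Duplicate or missing loci are
#' an error.
#'
#' @param text Character vector of haplotype strings.
#' @return Character vector of canonical haplotype strings.
#' @export
#' @examples
#' parse_haplotype("DRB1*16:01~A*11:01~C*12:03~B*27:12~DQB1*05:02")
parse_haplotype <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    abort("`text` must be a non-empty character vector of haplotype strings.")
  }
  parts <- strsplit(text, "~", fixed = TRUE)
  n_tok <- lengths(parts)
  if (any(n_tok != 5L)) {
    abort(paste0("Haplotype(s) without exactly 5 '~'-separated alleles: ",
                 paste(unique(text[n_tok != 5L]), collapse = ", ")))
  }
  flat <- parse_allele(unlist(parts, use.names = FALSE))
  loci <- matrix(flat$locus, nrow = 5L)
  alle <- matrix(flat$allele, nrow = 5L)
  out <- character(length(text))
  canon <- hla_loci()
  for (i in seq_along(text)) {
    idx <- match(canon, loci[, i])
    if (anyNA(idx) || anyDuplicated(loci[, i])) {
      missing_loci <- setdiff(canon, loci[, i])
      dup <- unique(loci[, i][duplicated(loci[, i])])
      abort(paste0(
        "Invalid haplotype '", text[i], "': ",
        if (length(dup)) paste0("duplicate locus ", paste(dup, collapse = ", "), "; ") else "",
        if (length(missing_loci)) paste0("missing locus ", paste(missing_loci, collapse = ", ")) else ""
      ))
    }
    out[i] <- paste(alle[idx, i], collapse = "~")
  }
  out
}

# 5 x n character matrix of alleles, rows in canonical locus order.
# Assumes canonical haplotype strings.
haplotype_matrix <- function(h) {
  matrix(unlist(strsplit(h, "~", fixed = TRUE), use.names = FALSE), nrow = 5L)
}

#' Coerce to a genotype
#'
#' The package's working representation of a single five-locus genotype is a
#' named character vector of length 10 with names [genotype_cols()], the two
#' alleles of each locus kept in sorted string order (so that genotype
#' equality and hashing are invariant under within-locus allele swaps).
#'
#' @param x A named or unnamed character vector of 10 alleles (unnamed input
#'   is taken in [genotype_cols()] order), a list, or a one-row data frame
#'   with the genotype columns.
#' @param validate Parse every allele and check it sits in the column's
#'   locus (default `TRUE`).
#' @return Named character vector of length 10.
#' @export
#' @examples
#' as_genotype(c(A_1 = "A*02:01", A_2 = "A*01:01", C_1 = "C*01:02",
#'   C_2 = "C*01:02", B_1 = "B*08:01", B_2 = "B*07:02",
#'   DRB1_1 = "DRB1*15:01", DRB1_2 = "DRB1*03:01",
#'   DQB1_1 = "DQB1*06:02", DQB1_2 = "DQB1*02:01"))
as_genotype <- function(x, validate = TRUE) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort("Data frame input to as_genotype() must have exactly one row.")
    x <- unlist(x[, intersect(c(genotype_cols(), names(x)), names(x))])
  }
  if (is.list(x)) x <- unlist(x)
  if (!is.character(x) || length(x) != 10L) {
    abort("A genotype needs exactly 10 allele strings (2 per locus at 5 loci).")
  }
  if (is.null(names(x))) {
    names(x) <- genotype_cols()
  } else {
    if (!setequal(names(x), genotype_cols())) {
      abort(paste0("Genotype names must be exactly: ", paste(genotype_cols(), collapse = ", ")))
    }
    x <- x[genotype_cols()]
  }
  if (validate) {
    parsed <- parse_allele(unname(x))
    expected <- rep(hla_loci(), each = 2L)
    off <- parsed$locus != expected
    if (any(off)) {
      abort(paste0("Allele(s) in the wrong locus slot: ",
                   paste(unname(x)[off], collapse = ", ")))
    }
  }
  for (locus in hla_loci()) {
    c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
    if (x[[c1]] > x[[c2]]) {
      tmp <- x[[c1]]; x[[c1]] <- x[[c2]]; x[[c2]] <- tmp
    }
  }
  x
}

#' Build a genotype from two haplotypes
#'
#' The genotype is the locus-wise union of the two haplotypes (homozygous at
#' a locus when both haplotypes carry the same allele).
#'
#' @param h1,h2 Canonical haplotype strings (see [parse_haplotype()]).
#' @return Named character genotype vector (see [as_genotype()]).
#' @export
genotype_from_haplotypes <- function(h1, h2) {
  m1 <- haplotype_matrix(parse_haplotype(h1))
  m2 <- haplotype_matrix(parse_haplotype(h2))
  g <- character(10)
  for (i in seq_len(5L)) {
    a <- m1[i, 1L]; b <- m2[i, 1L]
    g[2L * i - 1L] <- if (a <= b) a else b
    g[2L * i] <- if (a <= b) b else a
  }
  names(g) <- genotype_cols()
  g
}

# Compact string key for caching / comparing genotypes.
genotype_key <- function(g) paste(g, collapse = "|")

# Inverse of genotype_key().
genotype_from_key <- function(key) {
  g <- strsplit(key, "|", fixed = TRUE)[[1]]
  names(g) <- genotype_cols()
  g
}

# Vectorized genotype columns from two vectors of canonical haplotypes.
# Returns a tibble of the 10 genotype columns, sorted within locus.
haplotypes_to_genotype_tbl <- function(h1, h2) {
  m1 <- haplotype_matrix(h1)
  m2 <- haplotype_matrix(h2)
  out <- vector("list", 10L)
  names(out) <- genotype_cols()
  for (i in seq_len(5L)) {
    a <- m1[i, ]; b <- m2[i, ]
    swap <- a > b
    out[[2L * i - 1L]] <- ifelse(swap, b, a)
    out[[2L * i]] <- ifelse(swap, a, b)
  }
  new_tibble(out, nrow = length(h1))
}
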