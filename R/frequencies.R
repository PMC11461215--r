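#' Read a population haplotype-frequency table
#'
#' Frequency tables are tab-separated with columns `population`, `haplotype`
#' (five `~`-joined alleles) and `frequency`, plus an optional `sample_size`
#' column carried through as metadata. Published tables are typically
#' cumulative-truncated upstream and need not sum to exactly one, so every
#' table is renormalized on load.
#'
#' @param path Path to a TSV file.
#' @param population Optional population id; if given, only that
#'   population's rows are kept (an error if absent from the file).
#' @param normalize Renormalize frequencies to sum to 1 within each
#'   population (default `TRUE`).
#' @return A tibble with columns `population`, `haplotype`, `frequency`
#'   (and `sample_size` when present), one row per haplotype.
#' @export
read_frequency_table <- function(path, population = NULL, normalize = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("population", "haplotype", "frequency")
  if (!all(need %in% names(raw))) {
    abort(paste0("Frequency table must have columns ",
                 paste(need, collapse = ", "), "; found: ",
                 paste(names(raw), collapse = ", ")))
  }
  raw$.line <- seq_len(nrow(raw)) + 1L  # account for the header line
  if (!is.null(population)) {
    raw <- raw[raw$population %in% population, , drop = FALSE]
    if (nrow(raw) == 0) abort(paste0("Population '", population, "' not found in ", path))
  }
  freq <- suppressWarnings(as.numeric(raw$frequency))
  bad <- is.na(freq) | freq <= 0
  if (any(bad)) {
    abort(paste0("Non-positive or unparseable frequency at line(s): ",
                 paste(raw$.line[bad], collapse = ", ")))
  }
  haplotype <- parse_haplotype(raw$haplotype)
  dup <- duplicated(paste(raw$population, haplotype))
  if (any(dup)) {
    abort(paste0("Duplicate haplotype row(s) at line(s): ",
                 paste(raw$.line[dup], collapse = ", ")))
  }
  out <- tibble(population = raw$population, haplotype = haplotype, frequency = freq)
  if ("sample_size" %in% names(raw)) {
    out$sample_size <- suppressWarnings(as.integer(raw$sample_size))
  }
  if (normalize) out <- normalize_frequencies(out)
  out
}

#' Write a frequency table to TSV
#'
#' @param freqs Frequency tibble (see [read_frequency_table()]).
#' @param path Output path.
#' @return `freqs`, invisibly.
#' @export
write_frequency_table <- function(freqs, path) {
  check_frequency_table(freqs)
  readr::write_tsv(freqs, path)
  invisible(freqs)
}

check_frequency_table <- function(freqs) {
  need <- c("population", "haplotype", "frequency")
  if (!is.data.frame(freqs) || !all(need %in% names(freqs))) {
    abort(paste0("A frequency table needs columns ", paste(need, collapse = ", "), "."))
  }
  if (any(freqs$frequency <= 0)) abort("All frequencies must be > 0.")
  if (anyDuplicated(paste(freqs$population, freqs$haplotype))) {
    abort("Duplicate haplotypes within a population are not allowed.")
  }
  invisible(freqs)
}

#' Renormalize frequencies to sum to one within each population
#'
#' @param freqs Frequency tibble.
#' @return The tibble with `frequency` rescaled per population.
#' @export
normalize_frequencies <- function(freqs) {
  check_frequency_table(freqs)
  freqs |>
    group_by(.data$population) |>
    mutate(frequency = .data$frequency / sum(.data$frequency)) |>
    ungroup()
}

#' Pool several population tables into one
#'
#' The pooled frequency of a haplotype is the weight-normalized sum of its
#' per-population frequencies, `f(h) = sum_p w_p f_p(h) / sum_p w_p`; the
#' pooled support is the union of the member supports. With equal weights
#' this is the construction behind the ancestry-agnostic "SUPER" assumption.
#'
#' @param freqs Frequency tibble holding one or more populations.
#' @param pooled_id Population id of the pooled table.
#' @param weights Optional numeric weights, either unnamed in the order of
#'   `unique(freqs$population)` or named by population id. Default: equal.
#'   Must be non-negative and not all zero.
#' @param populations Optional subset of population ids to pool.
#' @return A frequency tibble with the single population `pooled_id`.
#' @export
pool_populations <- function(freqs, pooled_id, weights = NULL, populations = NULL) {
  check_frequency_table(freqs)
  if (!is.null(populations)) {
    missing_pop <- setdiff(populations, unique(freqs$population))
    if (length(missing_pop)) {
      abort(paste0("Population(s) not in table: ", paste(missing_pop, collapse = ", ")))
    }
    freqs <- freqs[freqs$population %in% populations, , drop = FALSE]
  }
  pops <- unique(freqs$population)
  if (length(pops) == 0) abort("Cannot pool an empty set of populations.")
  if (is.null(weights)) weights <- rep(1, length(pops))
  if (!is.null(names(weights))) {
    if (!all(pops %in% names(weights))) {
      abort("Named `weights` must cover every pooled population.")
    }
    weights <- weights[pops]
  }
  if (length(weights) != length(pops) || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be non-negative, not all zero, one per population.")
  }
  w <- setNames(weights / sum(weights), pops)
  normalize_frequencies(freqs) |>
    mutate(frequency = .data$frequency * w[.data$population]) |>
    group_by(haplotype = .data$haplotype) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    mutate(population = pooled_id, .before = 1L) |>
    arrange(desc(.data$frequency), .data$haplotype)
}

#' Build the full set of imputation assumption tables from a scheme
#'
#' Given detailed population tables and a population scheme (the mapping of
#' detailed categories to broad categories), returns the detailed tables,
#' one equal-weight pooled table per broad category, and the pooled
#' SUPER table over all detailed populations — e.g. 21 detailed + 5 broad +
#' SUPER = 27 imputation assumptions.
#'
#' @param freqs Frequency tibble of the detailed populations.
#' @param scheme Optional data frame with columns `detailed_id`, `broad_id`
#'   mapping every detailed population to a broad category. `NULL` skips the
#'   broad level (detailed + SUPER only).
#' @param super_id Id of the pooled super-population (default `"SUPER"`).
#' @param sample_size_weights Pool with per-population `sample_size` weights
#'   instead of equal weights (requires a `sample_size` column; default
#'   `FALSE`, matching the equal-weight construction of the SUPER table).
#' @return A frequency tibble containing all assumption tables, with an
#'   `assumptions` attribute: a tibble of `assumption`,
#'   `level` (`"detailed"`, `"broad"`, `"super"`).
#' @export
build_scheme_tables <- function(freqs, scheme = NULL, super_id = "SUPER",
                                sample_size_weights = FALSE) {
  check_frequency_table(freqs)
  detailed_ids <- unique(freqs$population)
  if (super_id %in% detailed_ids) {
    abort("`super_id` clashes with a detailed population id.")
  }
  pop_weights <- function(ids) {
    if (!sample_size_weights) return(NULL)
    if (!"sample_size" %in% names(freqs)) {
      abort("sample_size_weights = TRUE needs a `sample_size` column.")
    }
    ss <- freqs |>
      distinct(.data$population, .data$sample_size) |>
      filter(.data$population %in% ids)
    setNames(as.numeric(ss$sample_size), ss$population)
  }
  out <- normalize_frequencies(freqs)
  levels <- tibble(assumption = detailed_ids, level = "detailed")
  if (!is.null(scheme)) {
    if (!all(c("detailed_id", "broad_id") %in% names(scheme))) {
      abort("`scheme` needs columns detailed_id and broad_id.")
    }
    if (anyDuplicated(scheme$detailed_id)) {
      abort("Every detailed id must map to exactly one broad id.")
    }
    missing_detail <- setdiff(scheme$detailed_id, detailed_ids)
    if (length(missing_detail)) {
      abort(paste0("Scheme detailed id(s) without a frequency table: ",
                   paste(missing_detail, collapse = ", ")))
    }
    unmapped <- setdiff(detailed_ids, scheme$detailed_id)
    if (length(unmapped)) {
      abort(paste0("Population(s) missing from the scheme: ",
                   paste(unmapped, collapse = ", ")))
    }
    for (broad in unique(scheme$broad_id)) {
      members <- scheme$detailed_id[scheme$broad_id == broad]
      if (length(members) == 0) abort(paste0("Broad category '", broad, "' has no members."))
      out <- bind_rows(out, pool_populations(freqs, broad, weights = pop_weights(members),
                                             populations = members))
      levels <- bind_rows(levels, tibble(assumption = broad, level = "broad"))
    }
  }
  out <- bind_rows(out, pool_populations(freqs, super_id,
                                         weights = pop_weights(detailed_ids),
                                         populations = detailed_ids))
  levels <- bind_rows(levels, tibble(assumption = super_id, level = "super"))
  attr(out, "assumptions") <- levels
  out
}

#' Read a population scheme file
#'
#' A scheme file is a CSV with columns `detailed_id,broad_id`, one row per
#' detailed population.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `detailed_id`, `broad_id`.
#' @export
read_population_scheme <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("detailed_id", "broad_id") %in% names(out))) {
    abort("Scheme file needs columns detailed_id, broad_id.")
  }
  out
}
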