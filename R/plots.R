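#' Heatmap of a grouped study metric
#'
#' The classic true-population-by-assumption heatmap: imputation failure
#' rate, mean allele mismatch of single-imputation calls, or
#' noticeable-deviation proportion for one scorer and imputed party.
#'
#' @param study An `hla_study`.
#' @param metric `"failure_rate"`, `"allele_mismatch"` or `"noticeable"`.
#' @param scorer,party For `metric = "noticeable"`: which scorer
#'   (`"pirche"`/`"snow"`) and imputed party (`"patient"`/`"donor"`).
#' @return A ggplot object.
#' @export
plot_study_heatmap <- function(study, metric = c("failure_rate", "allele_mismatch",
                                                 "noticeable"),
                               scorer = "pirche", party = "donor") {
  stopifnot(inherits(study, "hla_study"))
  metric <- match.arg(metric)
  dat <- switch(metric,
    failure_rate = rename(study$summary$failure_rate, value = "failure_rate"),
    allele_mismatch = rename(study$summary$allele_mismatch,
                             value = "mean_allele_mismatch"),
    noticeable = study$summary$noticeable |>
      filter(.data$scorer == !!scorer, .data$party == !!party) |>
      rename(value = "noticeable_proportion")
  )
  lab <- switch(metric, failure_rate = "Failure rate",
                allele_mismatch = "Mean allele mismatch",
                noticeable = paste0("Noticeable deviation (", scorer, ", ",
                                    party, " imputed)"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$assumption, y = .data$true_population,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)), size = 3) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b", name = lab) +
    ggplot2::labs(x = "Imputation ancestry assumption", y = "True ancestry",
                  title = lab) +
    ggplot2::theme_minimal()
}

#' Reliability percentile curves of a study
#'
#' Maximum absolute log-delta within each cumulative percentile of pairs,
#' by imputed party and ancestry-assumption class, contrasting multiple
#' (solid) and single (dashed) imputation.
#'
#' @param study An `hla_study`.
#' @param scorer `"pirche"` or `"snow"`.
#' @return A ggplot object.
#' @export
plot_reliability <- function(study, scorer = c("pirche", "snow")) {
  stopifnot(inherits(study, "hla_study"))
  scorer <- match.arg(scorer)
  dat <- filter(study$summary$reliability, .data$scorer == !!scorer)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$percentile,
                                    y = .data$max_abs_log_delta,
                                    colour = interaction(.data$party, .data$assumption_class),
                                    linetype = .data$strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(values = c(multiple = "solid", single = "dashed")) +
    ggplot2::labs(x = "Cumulative percentile of pairs",
                  y = paste0("|delta ln(", scorer, " score)|"),
                  colour = "party.assumption", linetype = "imputation",
                  title = paste0("Reliability of ", scorer, " under imputation")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for study objects
#'
#' @param object An `hla_study`.
#' @param type `"heatmap"` (default) or `"reliability"`.
#' @param ... Passed to [plot_study_heatmap()] or [plot_reliability()].
#' @return A ggplot object.
#' @method autoplot hla_study
#' @export
autoplot.hla_study <- function(object, type = c("heatmap", "reliability"), ...) {
  type <- match.arg(type)
  switch(type,
         heatmap = plot_study_heatmap(object, ...),
         reliability = plot_reliability(object, ...))
}
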