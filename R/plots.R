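
# ---- Plots ------------------------------------------------------------------

#' Histogram of technical or between-sample CVs
#'
#' @param data Tibble with a `cv` column (e.g. from [filter_technical_cv()]).
#' @param cutoffs Reference lines (default the 25/75 classification cutoffs).
#' @return A ggplot.
#' @export
plot_cv_distribution <- function(data, cutoffs = c(25, 75)) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cv)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = cutoffs, linetype = "dashed") +
    ggplot2::labs(x = "coefficient of variation (%)", y = "peptides") +
    ggplot2::theme_minimal()
}

#' Peptide abundance by mating system
#'
#' Boxplots of per-individual normalized RIA for one peptide, split into
#' uni-male and multi-male species.
#'
#' @param data QC-passed peptide table.
#' @param labels `species`/`mating` tibble or named vector.
#' @param peptide Peptide sequence to plot.
#' @return A ggplot.
#' @export
plot_abundance_by_mating <- function(data, labels, peptide) {
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(species = names(labels), mating = unname(labels))
  }
  df <- data |>
    dplyr::filter(.data$peptide == !!peptide) |>
    dplyr::inner_join(labels, by = "species")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mating, y = .data$mean_ria)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$species), width = 0.15) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "normalized RIA", title = peptide) +
    ggplot2::theme_minimal()
}

#' Posterior densities of trait-rate correlations
#'
#' @param object An `sfp_coevol_fit`.
#' @param ... Unused.
#' @return A ggplot of the posterior of each marginal correlation involving
#'   log omega, with the 0.975/0.025 decision region implied by r = 0.
#' @method autoplot sfp_coevol_fit
#' @export
autoplot.sfp_coevol_fit <- function(object, ...) {
  keep <- grepl("^log_omega:", colnames(object$r_samples))
  df <- tibble::as_tibble(object$r_samples[, keep, drop = FALSE]) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "pair", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "marginal correlation with log dN/dS", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
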