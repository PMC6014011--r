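
# ---- Internal-standard normalization and CV quality control ----------------

#' Normalize peptide RIA values by internal standards
#'
#' Removes run-level scale from relative isotope abundances using the spiked
#' internal standards (horse myoglobin and trypsin peptides, pooled). The
#' global reference is the geometric mean, across runs, of each run's
#' geometric mean of standard RIAs; each run's normalization factor is its
#' own standard geometric mean divided by that reference, and every peptide
#' value in the run is divided by the factor. Runs in which no standard was
#' detected cannot be normalized; their rows are dropped and reported.
#'
#' @param data Tibble with columns `species`, `individual`, `run`,
#'   `peptide`, `protein`, `is_standard`, `ria` (positive or `NA`).
#' @return A list: `data` (normalized tibble, excluded runs removed),
#'   `factors` (tibble `run`, `factor`, `n_standards`), `excluded_runs`
#'   (tibble `run`, `reason`), and `reference` (the global standard level).
#'   Within every run the run-level scale cancels exactly; the only scale
#'   shared across runs is the reported `reference`, so normalized values
#'   divided by it are invariant to rescaling any single run.
#' @export
normalize_by_standards <- function(data) {
  req <- c("species", "individual", "run", "peptide", "protein", "is_standard", "ria")
  if (!all(req %in% names(data))) {
    stop("quant table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  std <- dplyr::filter(data, .data$is_standard, !is.na(.data$ria))
  if (nrow(std) == 0L) {
    stop("no internal-standard measurements anywhere: cannot normalize", call. = FALSE)
  }
  run_gm <- std |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(gm = geom_mean(.data$ria), n_standards = dplyr::n(),
                     .groups = "drop")
  reference <- geom_mean(run_gm$gm)
  factors <- dplyr::mutate(run_gm, factor = .data$gm / reference)[,
    c("run", "factor", "n_standards")]

  all_runs <- unique(data$run)
  excluded <- setdiff(all_runs, factors$run)
  excluded_runs <- tibble::tibble(
    run = excluded,
    reason = rep("no_standards_detected", length(excluded)))

  norm <- data |>
    dplyr::inner_join(factors[, c("run", "factor")], by = "run") |>
    dplyr::mutate(ria = .data$ria / .data$factor) |>
    dplyr::select(-"factor")

  list(data = norm, factors = factors, excluded_runs = excluded_runs,
       reference = reference)
}

#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the n-1 sample standard deviation on the
#' untransformed values, the convention used for technical-replicate QC.
#'
#' @param values Positive measurements, `n >= 2` after removing `NA`s.
#' @return CV as a percentage.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("CV requires at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("CV requires a positive mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Technical-replicate CV filter
#'
#' Collapses normalized peptide measurements to one value per biological
#' sample: for each (species, individual, peptide), the mean across
#' technical replicates is retained iff at least two replicates are present
#' and their CV is at most `cv_max` percent. Exclusions carry
#' machine-readable reasons (`"single_replicate"`, `"cv_exceeds"`).
#'
#' @param data Normalized quant tibble (see [normalize_by_standards()]);
#'   standards are ignored here.
#' @param cv_max CV cutoff in percent (default 25).
#' @return A list: `data` (tibble `species`, `individual`, `peptide`,
#'   `protein`, `mean_ria`, `cv`, `n_reps`) and `excluded` (same keys plus
#'   `reason`).
#' @export
filter_technical_cv <- function(data, cv_max = 25) {
  by_sample <- data |>
    dplyr::filter(!.data$is_standard, !is.na(.data$ria)) |>
    dplyr::group_by(.data$species, .data$individual, .data$peptide, .data$protein) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      mean_ria = mean(.data$ria),
      cv = ifelse(dplyr::n() >= 2L, 100 * stats::sd(.data$ria) / mean(.data$ria), NA_real_),
      .groups = "drop")
  retained <- dplyr::filter(by_sample, .data$n_reps >= 2L, .data$cv <= cv_max)
  excluded <- by_sample |>
    dplyr::filter(.data$n_reps < 2L | .data$cv > cv_max) |>
    dplyr::mutate(reason = ifelse(.data$n_reps < 2L, "single_replicate", "cv_exceeds"))
  list(data = retained, excluded = excluded)
}

#' Classify between-sample variability from a CV
#'
#' Labels a coefficient of variation as `"conserved"` (CV below 25 percent),
#' `"high"` (CV above 75 percent) or `"intermediate"`. Values exactly at a
#' cutoff are classified intermediate.
#'
#' @param cv CV in percent (vectorized, non-negative).
#' @return Character vector of labels.
#' @export
classify_variation <- function(cv) {
  if (any(cv < 0, na.rm = TRUE)) stop("CV cannot be negative", call. = FALSE)
  dplyr::case_when(
    is.na(cv) ~ NA_character_,
    cv < 25 ~ "conserved",
    cv > 75 ~ "high",
    TRUE ~ "intermediate")
}

#' Protein-level mean RIA
#'
#' Rolls QC-passed peptide means up to proteins: the arithmetic mean of the
#' retained peptide means per (species, individual, protein), reported only
#' for proteins with at least `min_peptides` retained peptides (default 3).
#'
#' @param data The `data` tibble from [filter_technical_cv()].
#' @param min_peptides Minimum retained peptides per protein.
#' @return A list: `data` (tibble `species`, `individual`, `protein`,
#'   `mean_ria`, `n_peptides`) and `excluded` (proteins omitted, with
#'   reason `"too_few_peptides"`).
#' @export
protein_mean_ria <- function(data, min_peptides = 3) {
  rolled <- data |>
    dplyr::group_by(.data$species, .data$individual, .data$protein) |>
    dplyr::summarise(mean_ria = mean(.data$mean_ria), n_peptides = dplyr::n(),
                     .groups = "drop")
  list(
    data = dplyr::filter(rolled, .data$n_peptides >= min_peptides),
    excluded = rolled |>
      dplyr::filter(.data$n_peptides < min_peptides) |>
      dplyr::mutate(reason = "too_few_peptides"))
}

#' Normalized spectral abundance factor
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)` within one sample, where
#' `SpC` is the spectral count and `L` the protein length in amino acids.
#'
#' @param counts Non-negative integer spectral counts (named or not).
#' @param lengths Positive protein lengths, same order as `counts`.
#' @param protein Optional protein identifiers.
#' @return Tibble with `protein`, `spectral_count`, `length`, `nsaf`;
#'   `nsaf` sums to 1.
#' @export
nsaf <- function(counts, lengths, protein = NULL) {
  if (length(counts) != length(lengths)) stop("counts/lengths length mismatch", call. = FALSE)
  if (any(lengths <= 0)) stop("protein lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("spectral counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) stop("all spectral counts are zero", call. = FALSE)
  ratio <- counts / lengths
  tibble::tibble(
    protein = protein %||% names(counts) %||% sprintf("protein%d", seq_along(counts)),
    spectral_count = counts, length = lengths,
    nsaf = ratio / sum(ratio))
}
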