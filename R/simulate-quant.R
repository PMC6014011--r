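
# ---- Synthetic peptide quantification data ----------------------------------

#' Design for a synthetic peptide quantification experiment
#'
#' Describes the study conditions for [simulate_quant_dataset()]. The
#' defaults emulate the sampling design of a comparative primate
#' seminal-fluid experiment: five proteomic species with uni/multi mating
#' labels, eight biological individuals for human and rhesus macaque and two
#' for the other species, three randomized technical replicates per
#' biological sample, horse myoglobin and trypsin spiked at a fixed amount
#' per run as internal standards, multiplicative run-level scale factors,
#' lognormal biological variation, and lognormal technical noise.
#'
#' @param species Tibble with columns `species`, `mating` (`"uni"`/`"multi"`)
#'   and `n_individuals`.
#' @param n_proteins Number of non-standard proteins.
#' @param peptides_per_protein Quantifiable peptides per protein.
#' @param frac_shared Probability that a peptide's sequence is identical in
#'   every species (otherwise the peptide is specific to one species).
#' @param n_responsive Number of mating-responsive proteins (shifted in
#'   multi-male species by `mating_effect`).
#' @param mating_effect Log fold-change applied to responsive proteins in
#'   multi-male species.
#' @param tech_reps Technical replicates per biological sample.
#' @param biological_cv,technical_cv Coefficients of variation (proportions)
#'   of the lognormal biological and technical noise.
#' @param run_scale_sd Standard deviation of log run scale factors.
#' @param missing_rate Probability a (run, peptide) measurement is missing
#'   completely at random.
#' @param standard_spike True spiked abundance of each internal-standard
#'   peptide (arbitrary RIA units).
#' @param seed Integer seed.
#' @return A validated `sfp_quant_design` list.
#' @export
quant_design <- function(
    species = tibble::tibble(
      species = c("human", "drill", "rhesus_macaque", "cynomolgus_macaque", "vervet"),
      mating = c("uni", "uni", "multi", "multi", "multi"),
      n_individuals = c(8L, 2L, 8L, 2L, 2L)),
    n_proteins = 40, peptides_per_protein = 5, frac_shared = 0.2,
    n_responsive = 4, mating_effect = log(2), tech_reps = 3,
    biological_cv = 0.7, technical_cv = 0.15, run_scale_sd = 0.5,
    missing_rate = 0.05, standard_spike = 200, seed = 1) {
  stopifnot(
    all(c("species", "mating", "n_individuals") %in% names(species)),
    all(species$mating %in% c("uni", "multi")),
    n_proteins >= 1, peptides_per_protein >= 1,
    frac_shared >= 0, frac_shared <= 1,
    n_responsive >= 0, n_responsive <= n_proteins,
    tech_reps >= 1, biological_cv >= 0, technical_cv >= 0,
    run_scale_sd >= 0, missing_rate >= 0, missing_rate < 1,
    standard_spike > 0)
  structure(as.list(environment()), class = "sfp_quant_design")
}

# deterministic pseudo-peptide sequences (tryptic-looking, K/R terminated)
make_peptide_seqs <- function(n, min_len = 8, max_len = 15) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  vapply(len, function(l) {
    paste0(paste(sample(aa, l - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

STANDARD_PROTEINS <- c("STD_HORSE_MYOGLOBIN", "STD_TRYPSIN")

#' Simulate a peptide-level quantification dataset
#'
#' Generates a long-format table of relative isotope abundance (RIA)
#' measurements with the statistical structure the downstream pipeline
#' assumes: true peptide abundances lognormal per individual around species
#' means, mating-responsive proteins shifted in multi-male species, every
#' value in a run (internal standards included) multiplied by that run's
#' scale factor, lognormal technical noise at the target CV, and
#' completely-at-random missingness. Internal-standard peptides (horse
#' myoglobin, trypsin) are spiked at a fixed true amount in every run.
#'
#' @param design An `sfp_quant_design` from [quant_design()].
#' @return A list: `data` (tibble with columns `species`, `individual`,
#'   `run`, `peptide`, `protein`, `is_standard`, `ria`), `truth` (list with
#'   `true_abundance`, `responsive_proteins`, `run_factors`), and `design`.
#' @export
simulate_quant_dataset <- function(design = quant_design()) {
  stopifnot(inherits(design, "sfp_quant_design"))
  d <- design
  with_seed(d$seed, {
    proteins <- sprintf("PROT%03d", seq_len(d$n_proteins))
    responsive <- proteins[seq_len(d$n_responsive)]

    pep <- tidyr::expand_grid(protein = proteins,
                              pep_idx = seq_len(d$peptides_per_protein))
    pep$peptide <- make_peptide_seqs(nrow(pep))
    pep$shared <- stats::runif(nrow(pep)) < d$frac_shared
    pep$private_species <- sample(d$species$species, nrow(pep), replace = TRUE)
    # peptide-level true signal: protein abundance x ionization efficiency
    prot_ab <- setNames(exp(stats::rnorm(d$n_proteins, log(100), 1)), proteins)
    pep$base <- prot_ab[pep$protein] * exp(stats::rnorm(nrow(pep), 0, 0.5))

    sigma_b <- sqrt(log(1 + d$biological_cv^2))
    sigma_t <- sqrt(log(1 + d$technical_cv^2))

    ind <- d$species |>
      dplyr::rowwise() |>
      dplyr::reframe(species = .data$species, mating = .data$mating,
                     individual = sprintf("%s_i%d", .data$species,
                                          seq_len(.data$n_individuals)))
    runs <- tidyr::expand_grid(ind, rep = seq_len(d$tech_reps)) |>
      dplyr::mutate(run = sprintf("%s_r%d", .data$individual, .data$rep))
    run_factors <- tibble::tibble(
      run = runs$run,
      factor = exp(stats::rnorm(nrow(runs), 0, d$run_scale_sd)))

    # per-(species, peptide) presence and mean abundance
    sp_pep <- tidyr::expand_grid(species = d$species$species, pep) |>
      dplyr::filter(.data$shared | .data$private_species == .data$species) |>
      dplyr::left_join(d$species[, c("species", "mating")], by = "species") |>
      dplyr::mutate(mean_ab = .data$base *
                      ifelse(.data$protein %in% responsive & .data$mating == "multi",
                             exp(d$mating_effect), 1))

    # biological truth per (individual, peptide)
    truth <- dplyr::inner_join(ind, sp_pep, by = c("species", "mating"),
                               relationship = "many-to-many") |>
      dplyr::mutate(true_value = .data$mean_ab *
                      exp(stats::rnorm(dplyr::n(), 0, sigma_b)))

    obs <- dplyr::inner_join(runs, truth, by = c("species", "mating", "individual"),
                             relationship = "many-to-many") |>
      dplyr::left_join(run_factors, by = "run") |>
      dplyr::mutate(
        ria = .data$true_value * .data$factor *
          exp(stats::rnorm(dplyr::n(), 0, sigma_t)),
        is_standard = FALSE) |>
      dplyr::select("species", "individual", "run", "peptide", "protein",
                    "is_standard", "ria")

    # internal standards: fixed spike in every run
    std_pep <- tibble::tibble(
      protein = rep(STANDARD_PROTEINS, c(6L, 4L)),
      peptide = sprintf("STDPEP%02d", 1:10))
    std <- tidyr::expand_grid(runs[, c("species", "individual", "run")], std_pep) |>
      dplyr::left_join(run_factors, by = "run") |>
      dplyr::mutate(
        ria = d$standard_spike * .data$factor *
          exp(stats::rnorm(dplyr::n(), 0, sigma_t)),
        is_standard = TRUE) |>
      dplyr::select("species", "individual", "run", "peptide", "protein",
                    "is_standard", "ria")

    dat <- dplyr::bind_rows(obs, std)
    if (d$missing_rate > 0) {
      dat <- dat[stats::runif(nrow(dat)) >= d$missing_rate, , drop = FALSE]
    }
    dat <- dplyr::arrange(dat, .data$species, .data$individual, .data$run,
                          .data$protein, .data$peptide)

    list(
      data = dat,
      truth = list(
        true_abundance = dplyr::select(truth, "species", "individual",
                                       "peptide", "protein", "true_value"),
        responsive_proteins = responsive,
        run_factors = run_factors),
      design = d)
  })
}
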