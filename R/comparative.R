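
# ---- Cross-species peptide matching and rank-sum scans ----------------------

#' Match identical peptides across species
#'
#' Restricts a QC-passed quantification table to exact peptide-sequence
#' matches across species: only identical peptides are comparable because
#' sequence differences change ionization and hence the RIA scale. Returns
#' the full long table for the requested species, the subset of peptides
#' present in every requested species, and per-species specific counts.
#'
#' @param data Tibble with `species`, `individual`, `peptide`, `protein`,
#'   `mean_ria` (the `data` element of [filter_technical_cv()]).
#' @param species_subset Character vector of at least two species.
#' @return A list: `matched` (long tibble with a `n_species` column),
#'   `shared` (peptides present in all requested species), and `counts`
#'   (tibble `peptide_class`, `n`: shared vs single-species).
#' @export
match_identical_peptides <- function(data, species_subset = unique(data$species)) {
  if (length(species_subset) < 2L) stop("need at least two species", call. = FALSE)
  absent <- setdiff(species_subset, unique(data$species))
  if (length(absent)) {
    stop("species absent from input: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  sub <- dplyr::filter(data, .data$species %in% species_subset)
  presence <- sub |>
    dplyr::distinct(.data$peptide, .data$species) |>
    dplyr::count(.data$peptide, name = "n_species")
  matched <- dplyr::left_join(sub, presence, by = "peptide")
  shared_peps <- presence$peptide[presence$n_species == length(species_subset)]
  counts <- tibble::tibble(
    peptide_class = c("shared_all", "single_species", "partial"),
    n = c(length(shared_peps),
          sum(presence$n_species == 1L),
          sum(presence$n_species > 1L & presence$n_species < length(species_subset))))
  list(matched = matched,
       shared = dplyr::filter(matched, .data$n_species == length(species_subset)),
       counts = counts)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test via [stats::wilcox.test()]: the exact null
#' distribution is used when both samples are small (`n + m <= 16`) and
#' there are no ties; otherwise the normal approximation with midranks and
#' continuity correction. Comparisons where either group has fewer than 3
#' values are flagged low power.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (x relative to y).
#' @return One-row tibble: `statistic` (Mann-Whitney U for x), `p_value`,
#'   `method` (`"exact"`/`"approximate"`), `low_power`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = sub("_", ".", alternative),
    exact = exact, correct = TRUE))
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "approximate",
    low_power = min(length(x), length(y)) < 3L)
}

# direction-aware test of one peptide between two groups of individuals
peptide_group_test <- function(vx, vy, alpha, group_names = c("uni", "multi")) {
  two <- wilcoxon_rank_sum(vx, vy, "two_sided")
  gr <- wilcoxon_rank_sum(vx, vy, "greater")
  ls <- wilcoxon_rank_sum(vx, vy, "less")
  direction <- if (two$p_value < alpha) {
    if (gr$p_value <= ls$p_value) paste0(group_names[1], "_higher")
    else paste0(group_names[2], "_higher")
  } else "none"
  tibble::tibble(
    n_x = length(vx[!is.na(vx)]), n_y = length(vy[!is.na(vy)]),
    median_x = stats::median(vx, na.rm = TRUE),
    median_y = stats::median(vy, na.rm = TRUE),
    p_two_sided = two$p_value, p_greater = gr$p_value, p_less = ls$p_value,
    direction = direction, low_power = two$low_power)
}

#' Scan peptide abundances for mating-system differences
#'
#' For every peptide observed in both mating groups, pools the per-individual
#' peptide means within the uni-male and multi-male groups and applies a
#' two-sided Wilcoxon rank-sum test at level `alpha`; one-sided tests assign
#' the direction of significant differences. Optionally applies
#' Benjamini-Hochberg correction (off by default, mirroring raw-p candidate
#' calling).
#'
#' @param data QC-passed peptide table (`species`, `individual`, `peptide`,
#'   `protein`, `mean_ria`).
#' @param labels Tibble `species`, `mating` (e.g. from [mating_labels()]) or
#'   a named character vector.
#' @param alpha Significance level (default 0.05).
#' @param bh Apply Benjamini-Hochberg and test `q < alpha` instead.
#' @param unit Pool `"individuals"` (default) or collapse to `"species_means"`
#'   before testing.
#' @return A list: `results` (per-peptide tibble with p-values, medians and
#'   `direction` in uni_higher/multi_higher/none), `summary` (counts), and
#'   `skipped` (untestable peptides with reasons).
#' @export
mating_system_scan <- function(data, labels, alpha = 0.05, bh = FALSE,
                               unit = c("individuals", "species_means")) {
  unit <- match.arg(unit)
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(species = names(labels), mating = unname(labels))
  }
  df <- dplyr::inner_join(data, labels, by = "species")
  if (length(unique(df$mating)) < 2L) {
    stop("both mating groups must be represented", call. = FALSE)
  }
  if (unit == "species_means") {
    df <- df |>
      dplyr::group_by(.data$species, .data$mating, .data$peptide, .data$protein) |>
      dplyr::summarise(mean_ria = mean(.data$mean_ria), .groups = "drop") |>
      dplyr::mutate(individual = .data$species)
  }
  per_pep <- df |>
    dplyr::group_by(.data$peptide, .data$protein) |>
    tidyr::nest() |>
    dplyr::ungroup()
  res <- purrr::map(per_pep$data, function(dd) {
    vx <- dd$mean_ria[dd$mating == "uni"]
    vy <- dd$mean_ria[dd$mating == "multi"]
    if (length(vx) == 0L || length(vy) == 0L) return(NULL)
    peptide_group_test(vx, vy, alpha)
  })
  testable <- !vapply(res, is.null, logical(1))
  skipped <- per_pep[!testable, c("peptide", "protein")]
  skipped$reason <- "missing_in_one_group"
  results <- dplyr::bind_cols(per_pep[testable, c("peptide", "protein")],
                              dplyr::bind_rows(res[testable])) |>
    dplyr::rename(n_uni = "n_x", n_multi = "n_y",
                  median_uni = "median_x", median_multi = "median_y")
  if (nrow(results)) {
    if (bh) {
      results$q_value <- stats::p.adjust(results$p_two_sided, "BH")
      results$significant <- results$q_value < alpha
    } else {
      results$significant <- results$p_two_sided < alpha
    }
    results$direction[!results$significant] <- "none"
  }
  summary <- tibble::tibble(
    n_tested = nrow(results),
    n_significant = sum(results$significant %||% logical(0)),
    n_uni_higher = sum(results$direction == "uni_higher"),
    n_multi_higher = sum(results$direction == "multi_higher"),
    n_skipped = nrow(skipped))
  list(results = results, summary = summary, skipped = skipped)
}

#' Scan peptide abundances between two species
#'
#' Per-peptide Wilcoxon rank-sum comparison of the individuals of two
#' species, with direction assignment as in [mating_system_scan()];
#' peptides present in only one species are skipped with a reason.
#'
#' @param data QC-passed peptide table.
#' @param species_a,species_b Species names; direction is reported relative
#'   to `species_a`.
#' @inheritParams mating_system_scan
#' @return A list: `results`, `summary`, `skipped`.
#' @export
species_pair_scan <- function(data, species_a, species_b, alpha = 0.05, bh = FALSE) {
  df <- dplyr::filter(data, .data$species %in% c(species_a, species_b))
  per_pep <- df |>
    dplyr::group_by(.data$peptide, .data$protein) |>
    tidyr::nest() |>
    dplyr::ungroup()
  res <- purrr::map(per_pep$data, function(dd) {
    vx <- dd$mean_ria[dd$species == species_a]
    vy <- dd$mean_ria[dd$species == species_b]
    if (length(vx) == 0L || length(vy) == 0L) return(NULL)
    peptide_group_test(vx, vy, alpha, group_names = c(species_a, species_b))
  })
  testable <- !vapply(res, is.null, logical(1))
  skipped <- per_pep[!testable, c("peptide", "protein")]
  skipped$reason <- "present_in_one_species"
  results <- dplyr::bind_cols(per_pep[testable, c("peptide", "protein")],
                              dplyr::bind_rows(res[testable]))
  if (nrow(results)) {
    names(results)[names(results) == "n_x"] <- paste0("n_", species_a)
    names(results)[names(results) == "n_y"] <- paste0("n_", species_b)
    if (bh) {
      results$q_value <- stats::p.adjust(results$p_two_sided, "BH")
      results$significant <- results$q_value < alpha
    } else {
      results$significant <- results$p_two_sided < alpha
    }
    results$direction[!results$significant] <- "none"
  }
  summary <- tibble::tibble(
    n_tested = nrow(results),
    n_significant = sum(results$significant %||% logical(0)),
    n_skipped = nrow(skipped))
  list(results = results, summary = summary, skipped = skipped)
}

#' Peptide concordance within a protein
#'
#' Measures whether the peptides of one protein agree in their abundance
#' profile across samples: the squared Pearson correlation of log10 RIA
#' between each peptide pair over their shared (species, individual)
#' samples. Pairs with fewer than 3 shared samples, or with a constant
#' profile, are reported as missing.
#'
#' @param data QC-passed peptide table restricted to one protein (or with a
#'   `protein` column and `protein` argument given).
#' @param protein Optional protein id to filter on.
#' @param log10_scale Correlate log10 values (default) or raw RIAs.
#' @return A list: `pairs` (tibble `peptide_1`, `peptide_2`, `n_shared`,
#'   `r_squared`), `mean_r_squared`, and the peptide-by-sample `matrix`.
#' @export
peptide_concordance <- function(data, protein = NULL, log10_scale = TRUE) {
  if (!is.null(protein)) data <- dplyr::filter(data, .data$protein == !!protein)
  wide <- data |>
    dplyr::mutate(sample = paste(.data$species, .data$individual, sep = ":"),
                  value = if (log10_scale) log10(.data$mean_ria) else .data$mean_ria) |>
    dplyr::select("peptide", "sample", "value") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$peptide
  if (nrow(m) < 2L) stop("concordance needs at least two peptides", call. = FALSE)
  combos <- utils::combn(rownames(m), 2L)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- m[combos[1, i], ]; b <- m[combos[2, i], ]
    ok <- !is.na(a) & !is.na(b)
    r2 <- if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      NA_real_
    } else {
      stats::cor(a[ok], b[ok])^2
    }
    tibble::tibble(peptide_1 = combos[1, i], peptide_2 = combos[2, i],
                   n_shared = sum(ok), r_squared = r2)
  })
  list(pairs = pairs,
       mean_r_squared = mean(pairs$r_squared, na.rm = TRUE),
       matrix = m)
}
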