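
# ---- Evidence integration and pipeline orchestration ------------------------

#' Merge evolutionary and abundance evidence into a candidate table
#'
#' Builds the candidate-gene table: one row per gene with any qualifying
#' evidence, reporting the trait-rate correlation posterior probabilities
#' per sexual character (the numeric pp when it clears the strict 0.975 /
#' 0.025 cutoffs, `"ns"` otherwise), a branch-site flag (`"x"` when the test
#' is significant), and an abundance flag (`"x"` when at least one of the
#' gene's peptides differs significantly between mating systems).
#'
#' @param coevol_calls Tibble `gene`, `character`, `pp` (e.g. stacked
#'   [classify_correlation()] outputs); may be `NULL`.
#' @param branch_site Tibble `gene`, `p_value`; may be `NULL`.
#' @param abundance_scan Tibble `peptide`, `protein`, `significant` (the
#'   `results` of [mating_system_scan()]); may be `NULL`.
#' @param gene_map Tibble `protein`, `gene` (optionally `transcript`)
#'   mapping quantified proteins to genes.
#' @param pp_positive,pp_negative Coevol call cutoffs.
#' @param branch_site_alpha Branch-site significance level (default 0.01).
#' @return A list: `table` (candidate tibble), `counts` (evidence-category
#'   counts incl. overlaps), `unmapped_peptides` (report, never silently
#'   dropped).
#' @export
integrate_evidence <- function(coevol_calls = NULL, branch_site = NULL,
                               abundance_scan = NULL, gene_map = NULL,
                               pp_positive = 0.975, pp_negative = 0.025,
                               branch_site_alpha = 0.01) {
  coevol_wide <- NULL
  if (!is.null(coevol_calls) && nrow(coevol_calls)) {
    coevol_wide <- coevol_calls |>
      dplyr::mutate(cell = ifelse(
        .data$pp >= pp_positive | .data$pp <= pp_negative,
        sprintf("%.3f", .data$pp), "ns")) |>
      dplyr::select("gene", "character", "cell") |>
      tidyr::pivot_wider(names_from = "character", values_from = "cell",
                         values_fill = "ns")
    coevol_wide$coevol_any <- apply(coevol_wide[, -1, drop = FALSE], 1L,
                                    function(r) any(r != "ns"))
  }
  bs <- NULL
  if (!is.null(branch_site) && nrow(branch_site)) {
    bs <- tibble::tibble(
      gene = branch_site$gene,
      branch_site = ifelse(!is.na(branch_site$p_value) &
                             branch_site$p_value < branch_site_alpha, "x", "ns"))
  }
  ab <- NULL
  unmapped <- tibble::tibble(peptide = character(0), protein = character(0))
  if (!is.null(abundance_scan) && nrow(abundance_scan)) {
    if (is.null(gene_map)) {
      gene_map <- tibble::tibble(protein = unique(abundance_scan$protein),
                                 gene = unique(abundance_scan$protein))
    }
    mapped <- dplyr::left_join(abundance_scan, gene_map, by = "protein")
    unmapped <- mapped |>
      dplyr::filter(is.na(.data$gene)) |>
      dplyr::distinct(.data$peptide, .data$protein)
    ab <- mapped |>
      dplyr::filter(!is.na(.data$gene)) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(abundance = ifelse(any(.data$significant), "x", "ns"),
                       .groups = "drop")
  }

  tabs <- list(coevol_wide, bs, ab)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (!length(tabs)) {
    return(list(
      table = tibble::tibble(gene = character(0)),
      counts = tibble::tibble(category = character(0), n = integer(0)),
      unmapped_peptides = unmapped))
  }
  merged <- Reduce(function(a, b) dplyr::full_join(a, b, by = "gene"), tabs)
  for (cn in setdiff(names(merged), c("gene", "coevol_any"))) {
    merged[[cn]][is.na(merged[[cn]])] <- "ns"
  }
  merged$coevol_any <- merged$coevol_any %||% FALSE
  merged$coevol_any[is.na(merged$coevol_any)] <- FALSE
  has_bs <- (merged$branch_site %||% "ns") == "x"
  has_ab <- (merged$abundance %||% "ns") == "x"
  merged$any_evidence <- merged$coevol_any | has_bs | has_ab
  cand <- merged[merged$any_evidence, , drop = FALSE]

  keep <- merged$any_evidence
  cc <- cand$coevol_any; cb <- has_bs[keep]; ca <- has_ab[keep]
  counts <- tibble::tibble(
    category = c("total", "coevol_only", "branch_site_only", "abundance_only",
                 "multiple"),
    n = c(nrow(cand),
          sum(cc & !cb & !ca),
          sum(!cc & cb & !ca),
          sum(!cc & !cb & ca),
          sum(cc + cb + ca >= 2)))
  cand$coevol_any <- NULL
  list(table = cand, counts = counts, unmapped_peptides = unmapped)
}

#' Pipeline configuration
#'
#' One home for every tunable of the pipeline. Stage toggles control which
#' stages [run_full_pipeline()] executes.
#'
#' @param cv_max Technical-replicate CV cutoff (percent).
#' @param classify_cutoffs Conserved/high CV classification cutoffs.
#' @param alpha Abundance-scan significance level.
#' @param fdr Sites-test FDR threshold (q-value).
#' @param branch_site_alpha Branch-site p-value threshold.
#' @param pp_positive,pp_negative Coevol posterior cutoffs.
#' @param mcmc MCMC settings for the correlation stage.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional directory for stage TSV outputs.
#' @param stages Named logical vector of stage toggles.
#' @param simulation Simulation settings (see [run_full_pipeline()]).
#' @return A `sfp_pipeline_config` list.
#' @export
pipeline_config <- function(
    cv_max = 25, classify_cutoffs = c(conserved = 25, high = 75),
    alpha = 0.05, fdr = 0.01, branch_site_alpha = 0.01,
    pp_positive = 0.975, pp_negative = 0.025,
    mcmc = list(iterations = 2000L, burnin = 0.25, thin = 5L),
    seed = 1L, out_dir = NULL,
    stages = c(simulate = TRUE, normalize = TRUE, qc = TRUE, match = TRUE,
               scan_abundance = TRUE, scan_selection = TRUE,
               branch_site = TRUE, coevol = TRUE, integrate = TRUE),
    simulation = list()) {
  sim <- utils::modifyList(
    list(n_genes = 15L, n_selected = 5L, n_codons = 200L,
         tree_scale = 20,
         selection = list(p0 = 0.85, p = 0.4, q = 1.2, omega_s = 5),
         neutral = list(p0 = 0.9, p = 0.4, q = 1.2),
         design = quant_design()),
    simulation)
  structure(as.list(environment())[c(
    "cv_max", "classify_cutoffs", "alpha", "fdr", "branch_site_alpha",
    "pp_positive", "pp_negative", "mcmc", "seed", "out_dir", "stages")] |>
      c(list(simulation = sim)),
    class = "sfp_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages: (optional) simulation of every input, internal
#' standard normalization, CV quality control, cross-species peptide
#' matching, abundance scans, site-model selection tests with q-value FDR,
#' branch-site tests with multi-male foreground, the Brownian trait-rate
#' correlation, and evidence integration. Failure in one gene's
#' evolutionary fit flags that gene and continues. With `out_dir` set,
#' every stage writes its TSV plus a manifest with parameters and seeds.
#' Identical config and seed give identical outputs.
#'
#' @param config A `sfp_pipeline_config`.
#' @param inputs Optional list with pre-built `quant` (result of
#'   [simulate_quant_dataset()] or a raw tibble), `alignments` (named list),
#'   `tree`, `characters`, `gene_map`; required when the simulate stage is
#'   off.
#' @return A list of stage outputs: `quant`, `normalized`, `qc`, `matched`,
#'   `abundance_scan`, `selection_scan`, `branch_site`, `coevol`,
#'   `candidates`, `manifest`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), inputs = list()) {
  stopifnot(inherits(config, "sfp_pipeline_config"))
  st <- config$stages
  seeds <- derive_seeds(config$seed, 6L)
  out <- list()
  manifest <- list(seed = config$seed, stages = st,
                   parameters = config[c("cv_max", "alpha", "fdr",
                                         "branch_site_alpha", "pp_positive",
                                         "pp_negative")])

  tree <- inputs$tree
  characters <- inputs$characters
  alignments <- inputs$alignments
  gene_map <- inputs$gene_map
  quant <- inputs$quant
  truth <- NULL

  if (isTRUE(st[["simulate"]])) {
    sim <- config$simulation
    tree <- tree %||% fixed_primate_tree(branch_scale = sim$tree_scale)
    design <- sim$design
    design$seed <- seeds[1]
    qd <- simulate_quant_dataset(design)
    quant <- qd$data
    proteins <- sprintf("PROT%03d", seq_len(design$n_proteins))
    genes <- proteins[seq_len(min(sim$n_genes, length(proteins)))]
    selected <- rev(genes)[seq_len(sim$n_selected)]
    aseeds <- derive_seeds(seeds[2], length(genes))
    alignments <- purrr::map(seq_along(genes), function(i) {
      g <- genes[i]
      mdl <- if (g %in% selected) {
        codon_model("M8", kappa = 2, p0 = sim$selection$p0, p = sim$selection$p,
                    q = sim$selection$q, omega_s = sim$selection$omega_s)
      } else {
        codon_model("M8a", kappa = 2, p0 = sim$neutral$p0, p = sim$neutral$p,
                    q = sim$neutral$q)
      }
      simulate_codon_alignment(tree, mdl, sim$n_codons, seed = aseeds[i])
    })
    names(alignments) <- genes
    chars <- simulate_characters(tree, covariance = diag(6) * 0.02,
                                 seed = seeds[3])
    characters <- chars$characters
    gene_map <- tibble::tibble(protein = proteins, gene = proteins)
    truth <- list(responsive_proteins = qd$truth$responsive_proteins,
                  selected_genes = selected)
    out$quant <- quant
  } else if (!is.null(quant) && !is.data.frame(quant)) {
    truth <- quant$truth
    quant <- quant$data
  }

  if (isTRUE(st[["normalize"]])) {
    stopifnot(!is.null(quant))
    norm <- normalize_by_standards(quant)
    out$normalized <- norm
  }
  if (isTRUE(st[["qc"]])) {
    qc <- filter_technical_cv(out$normalized$data, cv_max = config$cv_max)
    out$qc <- qc
  }
  if (isTRUE(st[["match"]])) {
    out$matched <- match_identical_peptides(out$qc$data)
  }
  if (isTRUE(st[["scan_abundance"]])) {
    labels <- mating_labels(tree %||% fixed_primate_tree())
    out$abundance_scan <- mating_system_scan(out$qc$data, labels,
                                             alpha = config$alpha)
  }

  fit_gene <- function(g, f) {
    tryCatch(f(), error = function(e) {
      list(gene = g, failed = TRUE, error = conditionMessage(e))
    })
  }
  if (isTRUE(st[["scan_selection"]])) {
    res <- purrr::imap(alignments, function(aln, g) {
      fit_gene(g, function() {
        ctx <- site_model_context(aln, tree)
        null <- fit_site_model(aln, tree, "M8a", ctx = ctx, seed = seeds[4])
        alt <- fit_site_model(aln, tree, "M8", ctx = ctx, seed = seeds[4])
        lrt <- site_model_lrt(null, alt)
        list(gene = g, failed = FALSE, lnl_null = lrt$lnl_null,
             lnl_alt = lrt$lnl_alt, p_value = lrt$p_value,
             omega_s = alt$params$omega_s, ctx = ctx)
      })
    })
    failed <- vapply(res, function(r) isTRUE(r$failed), logical(1))
    ok <- res[!failed]
    tbl <- tibble::tibble(
      gene = vapply(ok, `[[`, character(1), "gene"),
      lnl_null = vapply(ok, `[[`, numeric(1), "lnl_null"),
      lnl_alt = vapply(ok, `[[`, numeric(1), "lnl_alt"),
      p_value = vapply(ok, `[[`, numeric(1), "p_value"),
      omega_s = vapply(ok, `[[`, numeric(1), "omega_s"))
    qv <- qvalue_fdr(tbl$p_value, fdr = config$fdr)
    tbl$q_value <- qv$q_value
    tbl$significant <- qv$significant
    out$selection_scan <- list(
      results = tbl,
      failures = tibble::tibble(
        gene = names(res)[failed],
        error = vapply(res[failed], `[[`, character(1), "error")))
  }
  if (isTRUE(st[["branch_site"]])) {
    res <- purrr::imap(alignments, function(aln, g) {
      fit_gene(g, function() {
        bs <- branch_site_test(aln, tree, seed = seeds[5])
        list(gene = g, failed = FALSE, statistic = bs$statistic,
             p_value = bs$p_value, omega2 = bs$omega2)
      })
    })
    failed <- vapply(res, function(r) isTRUE(r$failed), logical(1))
    ok <- res[!failed]
    out$branch_site <- list(
      results = tibble::tibble(
        gene = vapply(ok, `[[`, character(1), "gene"),
        statistic = vapply(ok, `[[`, numeric(1), "statistic"),
        p_value = vapply(ok, `[[`, numeric(1), "p_value"),
        omega2 = vapply(ok, `[[`, numeric(1), "omega2"),
        significant = vapply(ok, `[[`, numeric(1), "p_value") < config$branch_site_alpha),
      failures = tibble::tibble(
        gene = names(res)[failed],
        error = vapply(res[failed], `[[`, character(1), "error")))
  }
  if (isTRUE(st[["coevol"]])) {
    cseeds <- derive_seeds(seeds[6], length(alignments))
    res <- purrr::imap(alignments, function(aln, g) {
      i <- match(g, names(alignments))
      fit_gene(g, function() {
        bo <- estimate_branch_omega(aln, tree, sweeps = 1)
        fit <- fit_brownian_correlation(
          tree, bo, characters,
          mcmc = utils::modifyList(config$mcmc, list(seed = cseeds[i])))
        calls <- classify_correlation(fit$pairs, config$pp_positive,
                                      config$pp_negative)
        calls <- calls[calls$trait_1 == "log_omega", ]
        tibble::tibble(gene = g, character = calls$trait_2,
                       posterior_mean_r = calls$posterior_mean_r,
                       pp = calls$pp, call = calls$call)
      })
    })
    failed <- vapply(res, function(r) !is.data.frame(r) && isTRUE(r$failed),
                     logical(1))
    out$coevol <- list(
      results = dplyr::bind_rows(res[!failed]),
      failures = tibble::tibble(
        gene = names(res)[failed],
        error = vapply(res[failed], `[[`, character(1), "error")))
  }
  if (isTRUE(st[["integrate"]])) {
    out$candidates <- integrate_evidence(
      coevol_calls = out$coevol$results,
      branch_site = out$branch_site$results,
      abundance_scan = out$abundance_scan$results,
      gene_map = gene_map,
      pp_positive = config$pp_positive, pp_negative = config$pp_negative,
      branch_site_alpha = config$branch_site_alpha)
  }

  manifest$n_rows <- purrr::map(
    purrr::keep(out, is.data.frame), nrow)
  out$truth <- truth
  out$manifest <- manifest

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, nm) {
      if (!is.null(df) && nrow(df)) {
        write_stage_tsv(df, file.path(config$out_dir, paste0(nm, ".tsv")),
                        meta = c(seed = config$seed))
      }
    }
    wr(out$quant, "quant")
    wr(out$normalized$data, "normalized")
    wr(out$qc$data, "qc_retained")
    wr(out$qc$excluded, "qc_excluded")
    wr(out$abundance_scan$results, "abundance_scan")
    wr(out$selection_scan$results, "selection_scan")
    wr(out$branch_site$results, "branch_site")
    wr(out$coevol$results, "coevol")
    wr(out$candidates$table, "candidates")
  }
  out
}
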