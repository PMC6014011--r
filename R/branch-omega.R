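
# ---- Per-branch omega estimation (free-ratio-lite) --------------------------

#' Estimate a separate dN/dS per branch
#'
#' Two-stage lineage-rate estimation: kappa and branch lengths are fixed
#' from an M0 fit, then each branch's omega is maximized coordinate-wise
#' (repeated 1-D searches over log omega per branch, cycling until the
#' log-likelihood stabilizes). A Gaussian penalty on log omega, centered at
#' the M0 estimate, regularizes branches with no inferred nonsynonymous or
#' synonymous events, where the unpenalized likelihood is flat or maximized
#' at 0 or infinity. Each branch's uncertainty weight is proportional to its
#' length times the alignment length (in codons), so downstream models can
#' downweight short, information-poor branches. Zero-length branches are
#' reported as missing.
#'
#' @param alignment Named character vector of in-frame sequences.
#' @param tree Rooted `phylo` with branch lengths.
#' @param pi `"f3x4"` or `"uniform"` codon frequencies.
#' @param penalty_sd Standard deviation of the log-omega ridge (default 1.5).
#' @param sweeps Coordinate-descent sweeps over branches (default 2).
#' @return A tibble over postorder edges: `edge`, `parent`, `child`,
#'   `length`, `omega`, `log_omega`, `weight`, plus attributes `kappa`,
#'   `lnL`, and `m0_omega`. Identical sequences (no substitutions) give all
#'   omegas `NA` with a warning.
#' @export
estimate_branch_omega <- function(alignment, tree, pi = "f3x4",
                                  penalty_sd = 1.5, sweeps = 2) {
  ctx <- site_model_context(alignment, tree, pi = pi)
  tp <- ctx$tp
  nedge <- nrow(tp$edge)
  n_codons <- ctx$n_sites

  no_variation <- all(apply(ctx$tips_pat, 2L, function(col) {
    length(unique(col[!is.na(col)])) <= 1L
  }))
  base <- tibble::tibble(
    edge = seq_len(nedge), parent = tp$edge[, 1L], child = tp$edge[, 2L],
    length = tp$el,
    weight = tp$el * n_codons)
  if (no_variation) {
    warning("alignment has no substitutions; per-branch omega is undefined")
    out <- dplyr::mutate(base, omega = NA_real_, log_omega = NA_real_)
    attr(out, "kappa") <- ctx$kappa; attr(out, "m0_omega") <- ctx$m0$omega
    return(out)
  }

  mu0 <- log(ctx$m0$omega)
  dec_cache <- new.env(parent = emptyenv())
  get_dec <- function(om) {
    key <- sprintf("%.12g", om)
    d <- dec_cache[[key]]
    if (is.null(d)) {
      d <- codon_decompose(ctx$kappa, om, ctx$pi, rate_scale = ctx$rate_scale)
      dec_cache[[key]] <- d
    }
    d
  }
  om_edge <- rep(ctx$m0$omega, nedge)
  Plist <- lapply(seq_len(nedge), function(e) codon_pmat(get_dec(om_edge[e]), tp$el[e]))
  lnl_with <- function(e, om) {
    Pl <- Plist
    Pl[[e]] <- codon_pmat(get_dec(om), tp$el[e])
    sum(ctx$pat_wt * prune_loglik(tp, Pl, ctx$tips_pat, ctx$pi))
  }
  penalized <- function(e, lom) {
    lnl_with(e, exp(lom)) - (lom - mu0)^2 / (2 * penalty_sd^2)
  }
  free <- which(tp$el > 0)
  for (s in seq_len(sweeps)) {
    for (e in free) {
      op <- optimize(function(l) penalized(e, l),
                     interval = c(mu0 - 5, mu0 + 5), maximum = TRUE, tol = 1e-3)
      om_edge[e] <- exp(op$maximum)
      Plist[[e]] <- codon_pmat(get_dec(om_edge[e]), tp$el[e])
    }
  }
  lnl <- sum(ctx$pat_wt * prune_loglik(tp, Plist, ctx$tips_pat, ctx$pi))
  out <- dplyr::mutate(base,
    omega = ifelse(.data$length > 0, om_edge, NA_real_),
    log_omega = log(.data$omega))
  attr(out, "kappa") <- ctx$kappa
  attr(out, "lnL") <- lnl
  attr(out, "m0_omega") <- ctx$m0$omega
  out
}
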