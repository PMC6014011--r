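
# ---- Branch-site test of positive selection on foreground lineages ----------
#
# Standard branch-site model A: four site classes
#   0:  omega0 on all branches                (weight p0)
#   1:  omega = 1 on all branches             (weight p1)
#   2a: omega0 background / omega2 foreground (weight (1-p0-p1) p0/(p0+p1))
#   2b: 1 background / omega2 foreground      (weight (1-p0-p1) p1/(p0+p1))
# Null fixes omega2 = 1; alternative allows omega2 >= 1. The LRT uses
# chi-square with 1 df (not the 50:50 boundary mixture), so it is
# conservative. Kappa and branch lengths come from an M0 fit, as for the
# site models. The alternative optimizer profiles (omega0, omega2) in an
# outer Nelder-Mead search with the class weights optimized in a cheap inner
# step, and is seeded with the null solution so the nesting inequality
# lnL(alt) >= lnL(null) holds by construction.

branch_site_classes <- function(omega0, omega2, fg, nedge) {
  om0_edge <- rep(omega0, nedge)
  om2a <- ifelse(fg, omega2, omega0)
  om2b <- ifelse(fg, omega2, 1)
  list(
    list(omega = omega0, weight = NA),          # scalar: same on all branches
    list(omega = 1, weight = NA),
    list(omega = om2a, weight = NA),
    list(omega = om2b, weight = NA))
}

# lnL profile over weights for fixed class site log-likelihoods.
# weights: (p0, p1) via softmax(u1, u2, 0); class 2 mass split p0:(p1).
branch_site_weight_fit <- function(SL, pat_wt, n_starts = 2, seed = 1) {
  obj <- function(u) {
    ew <- exp(c(u[1], u[2], 0)); s <- sum(ew)
    p0 <- ew[1] / s; p1 <- ew[2] / s; w2 <- ew[3] / s
    w <- c(p0, p1, w2 * p0 / (p0 + p1), w2 * p1 / (p0 + p1))
    -sum(pat_wt * log_sum_exp_rows(SL + rep(log(w), each = nrow(SL))))
  }
  starts <- jitter_starts(c(1.5, 0.5), n_starts, seed, sd = 0.5)
  f <- best_start_fit(starts, obj, lower = c(-15, -15), upper = c(15, 15))
  ew <- exp(c(f$par[1], f$par[2], 0)); s <- sum(ew)
  list(lnL = -f$objective, p0 = ew[1] / s, p1 = ew[2] / s,
       convergence = f$convergence == 0)
}

#' Branch-site test for positive selection on foreground lineages
#'
#' Fits the branch-site model A with the designated lineages (by default the
#' multi-male ones) as foreground and tests whether a class of sites evolves
#' with omega > 1 on those lineages only, via a chi-square(1) LRT between
#' the model with free foreground `omega2 >= 1` and the null with
#' `omega2 = 1`.
#'
#' @param alignment Named character vector of in-frame sequences.
#' @param tree Rooted `phylo`; mating labels via `tree$mating` or `labels`.
#' @param labels Optional named `"uni"`/`"multi"` vector per tip.
#' @param foreground Label treated as foreground (default `"multi"`); set
#'   `"uni"` for the swapped-foreground control run.
#' @param rule Internal-branch assignment rule (see [foreground_edges()]).
#' @param pi Codon frequency option, `"f3x4"` or `"uniform"`.
#' @param n_starts Optimizer starts for the weight step.
#' @param seed Seed for start jitter.
#' @return An object of class `sfp_branch_site`: list with `lnl_null`,
#'   `lnl_alt`, `statistic` (2 delta lnL), `p_value`, `omega0`, `omega2`,
#'   `weights`, `foreground` (edge flags), `kappa`, `n_foreground`.
#' @export
branch_site_test <- function(alignment, tree, labels = NULL, foreground = "multi",
                             rule = "all_descendants", pi = "f3x4",
                             n_starts = 2, seed = 1) {
  fg <- foreground_edges(tree, labels, foreground = foreground, rule = rule)
  if (all(fg) || !any(fg)) {
    stop("foreground/background partition must be non-degenerate", call. = FALSE)
  }
  ctx <- site_model_context(alignment, tree, pi = pi)
  nedge <- nrow(ctx$tp$edge)
  pat_wt <- ctx$pat_wt

  class_sl <- function(omega0, omega2) {
    cl <- branch_site_classes(omega0, omega2, fg, nedge)
    vapply(cl, function(cc) {
      mixture_site_loglik(ctx$tp, ctx$tips_pat, list(list(omega = cc$omega, weight = 1)),
                          ctx$kappa, ctx$pi, rate_scale = ctx$rate_scale)
    }, numeric(length(pat_wt)))
  }
  profile <- function(omega0, omega2) {
    branch_site_weight_fit(class_sl(omega0, omega2), pat_wt,
                           n_starts = n_starts, seed = seed)
  }

  # null: omega2 = 1, outer 1-D over omega0
  null_prof <- function(l_om0) profile(stats::plogis(l_om0), 1)$lnL
  opt0 <- optimize(null_prof, c(-8, 0), maximum = TRUE, tol = 1e-3)
  om0_null <- stats::plogis(opt0$maximum)
  fit_null <- profile(om0_null, 1)

  # alternative: outer 2-D Nelder-Mead over (logit omega0, log(omega2 - 1)),
  # started at the null solution
  alt_obj <- function(u) {
    om0 <- stats::plogis(min(max(u[1], -9), 0))
    om2 <- 1 + exp(min(max(u[2], -15), log(30)))
    -profile(om0, om2)$lnL
  }
  st <- c(stats::qlogis(min(max(om0_null, 1e-4), 0.999)), log(0.8))
  oa <- optim(st, alt_obj, method = "Nelder-Mead",
              control = list(maxit = 120, reltol = 1e-7))
  om0_alt <- stats::plogis(min(max(oa$par[1], -9), 0))
  om2_alt <- 1 + exp(min(max(oa$par[2], -15), log(30)))
  fit_alt <- profile(om0_alt, om2_alt)
  if (fit_alt$lnL < fit_null$lnL) {   # nested at omega2 = 1
    fit_alt <- fit_null; om0_alt <- om0_null; om2_alt <- 1
  }

  stat <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  structure(list(
    lnl_null = fit_null$lnL, lnl_alt = fit_alt$lnL,
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    omega0 = om0_alt, omega2 = om2_alt,
    omega0_null = om0_null,
    weights = c(p0 = fit_alt$p0, p1 = fit_alt$p1),
    foreground = fg, n_foreground = sum(fg),
    kappa = ctx$kappa, n_sites = ctx$n_sites, n_taxa = ctx$n_taxa,
    foreground_label = foreground),
    class = "sfp_branch_site")
}

#' @export
print.sfp_branch_site <- function(x, ...) {
  cat(sprintf(
    "Branch-site test (foreground = %s, %d branches): 2dlnL = %.3f, p = %.4g\n",
    x$foreground_label, x$n_foreground, x$statistic, x$p_value))
  cat(sprintf("  foreground omega2 = %.3f, background omega0 = %.3f\n",
              x$omega2, x$omega0))
  invisible(x)
}
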