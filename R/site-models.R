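
# ---- Site-model machinery ---------------------------------------------------
#
# Fitting strategy: branch lengths and kappa are estimated once under M0
# (single omega) and then held fixed for all site-class mixtures. Mixture
# classes with omega in [0, 1] are evaluated through per-site log-likelihoods
# precomputed on a fixed omega grid and interpolated with a natural cubic
# spline (error << 0.01 lnL units, and shared between the members of each
# nested pair); the positive-selection class (omega >= 1) is always evaluated
# exactly by pruning and profiled in an outer one-dimensional optimization.
# Nesting lnL(alt) >= lnL(null) is guaranteed by seeding each alternative
# model with its null's solution.

# log-spaced below 0.1 (per-site log-likelihood is near-linear in
# log(omega) as omega -> 0, slope = number of nonsynonymous events) and
# dense-linear above; interpolation runs on the log10 scale and queries
# below the grid are clamped (the likelihood is flat there to O(1e-4))
OMEGA_GRID <- c(10^seq(-4, -1.1, length.out = 12), seq(0.1, 1, by = 0.025))

#' Shared fitting context for one gene
#'
#' Fits M0 (kappa, omega, and a global branch-length scale) and prepares the
#' likelihood machinery — compressed site patterns, codon frequencies, and a
#' lazily built per-site likelihood cache over an omega grid — that all site
#' models of the same gene share. Pass the returned context to
#' [fit_site_model()] via `ctx` to avoid repeating the M0 stage per model.
#'
#' @param alignment Named character vector of in-frame sequences.
#' @param tree Rooted `phylo` with branch lengths.
#' @param pi `"f3x4"` (default) or `"uniform"` codon frequencies.
#' @param kappa0,omega0 Optimizer starting values for the M0 stage.
#' @return A list with the M0 fit (`m0`), `kappa`, frequencies, and internal
#'   likelihood closures.
#' @export
site_model_context <- function(alignment, tree, pi = c("f3x4", "uniform"),
                               kappa0 = 2, omega0 = 0.4) {
  pi <- match.arg(pi)
  ai <- codon_index_matrix(alignment)
  pivec <- if (pi == "f3x4") codon_frequencies_f3x4(alignment) else rep(1 / 61, 61)
  tp <- prepare_tree(tree, ai)
  pat <- compress_patterns(ai)
  tips_pat <- pat$idx[tp$tip_row, , drop = FALSE]

  one_class_ll <- function(om, kappa, el_scale) {
    tpl <- tp; tpl$el <- tp$el * el_scale
    sum(pat$wt * mixture_site_loglik(
      tpl, tips_pat, list(list(omega = om, weight = 1)),
      kappa, pivec, rate_scale = codon_mean_rate(kappa, om, pivec)))
  }
  # M0: joint (kappa, omega, branch scale) by quasi-Newton on log scale
  obj <- function(par) {
    val <- tryCatch(
      -one_class_ll(exp(par[2]), exp(par[1]), exp(par[3])),
      error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }
  fit <- nlminb(log(c(kappa0, omega0, 1)), obj,
                lower = log(c(0.05, 1e-4, 1e-3)), upper = log(c(50, 20, 100)))
  kappa_hat <- exp(fit$par[1]); omega_hat <- exp(fit$par[2]); scale_hat <- exp(fit$par[3])

  tp_hat <- tp; tp_hat$el <- tp$el * scale_hat
  rate_scale <- codon_mean_rate(kappa_hat, omega_hat, pivec)

  # exact per-pattern log-likelihood for a single omega class, memoized
  sl_cache <- new.env(parent = emptyenv())
  exact_sl <- function(om) {
    key <- sprintf("%.12g", om)
    v <- sl_cache[[key]]
    if (is.null(v)) {
      v <- mixture_site_loglik(tp_hat, tips_pat,
                               list(list(omega = om, weight = 1)),
                               kappa_hat, pivec, rate_scale = rate_scale)
      sl_cache[[key]] <- v
    }
    v
  }

  ctx <- list(
    tp = tp_hat, tips_pat = tips_pat, pat_wt = pat$wt, pi = pivec,
    kappa = kappa_hat, rate_scale = rate_scale,
    m0 = list(model = "M0", kappa = kappa_hat, omega = omega_hat,
              scale = scale_hat, lnL = -fit$objective,
              convergence = fit$convergence == 0),
    exact_sl = exact_sl,
    n_sites = sum(pat$wt), n_taxa = nrow(ai)
  )
  # grid spline built lazily: branch-site and per-branch-omega contexts
  # never touch it
  spl_env <- new.env(parent = emptyenv())
  ctx$sl_interp <- function(omega) {
    if (is.null(spl_env$spl)) {
      SL <- vapply(OMEGA_GRID, exact_sl, numeric(length(pat$wt)))
      spl_env$spl <- grid_spline(log10(OMEGA_GRID), SL)
    }
    spl_env$spl(log10(pmax(omega, OMEGA_GRID[1L])))
  }
  ctx
}

# lnL of a mixture given per-pattern class log-likelihood columns
mix_lnl <- function(ctx, SLmat, w) {
  keep <- w > 0
  sum(ctx$pat_wt * log_sum_exp_rows(
    SLmat[, keep, drop = FALSE] +
      rep(log(w[keep]), each = nrow(SLmat))))
}

# start-point jitter for multiple optimizer starts
jitter_starts <- function(base, n_starts, seed, sd = 0.3) {
  with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) base else base + stats::rnorm(length(base), 0, sd)
    })
  })
}

best_start_fit <- function(starts, obj, lower, upper) {
  fits <- lapply(starts, function(s) {
    tryCatch(nlminb(pmin(pmax(s, lower), upper), obj, lower = lower, upper = upper),
             error = function(e) list(objective = Inf, par = s, convergence = 1L))
  })
  vals <- vapply(fits, `[[`, numeric(1), "objective")
  # best lnL; ties broken by smaller parameter norm
  ord <- order(vals, vapply(fits, function(f) sum(f$par^2), numeric(1)))
  fits[[ord[1L]]]
}

beta_class_omegas <- function(p, q, K) stats::qbeta((seq_len(K) - 0.5) / K, p, q)

#' Fit a codon site model
#'
#' Fits one of the standard GY94 site-class models by maximum likelihood:
#' `M0` (single omega), `M1a` (nearly neutral), `M2a` (positive selection),
#' `M7` (beta), `M8` (beta plus a free omega >= 1 class) or `M8a` (beta plus
#' a class fixed at omega = 1). Branch lengths and kappa are optimized under
#' M0 and held fixed for the mixtures; the beta component is discretized into
#' `K` equal-probability classes at quantile midpoints; mixture parameters
#' are optimized by bounded quasi-Newton from `n_starts` jittered starts, and
#' the free selection class is profiled in an outer one-dimensional search.
#'
#' @param alignment Named character vector of in-frame sequences.
#' @param tree Rooted `phylo` with branch lengths; tips must cover the
#'   alignment names.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`, `"M8a"`.
#' @param K Number of discrete beta classes (default 10).
#' @param pi `"f3x4"` (default) or `"uniform"` codon frequencies.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Seed for start-point jitter.
#' @param ctx Optional precomputed context from [site_model_context()] so
#'   several models of the same gene share the M0 fit and likelihood cache.
#' @return An object of class `sfp_site_fit`: a list with `model`, `lnL`,
#'   `kappa`, `scale`, a `classes` tibble (omega, weight), and `params`.
#' @export
fit_site_model <- function(alignment, tree,
                           model = c("M0", "M1a", "M2a", "M7", "M8", "M8a"),
                           K = 10, pi = "f3x4", n_starts = 3, seed = 1,
                           ctx = NULL) {
  model <- match.arg(model)
  if (is.null(ctx)) ctx <- site_model_context(alignment, tree, pi = pi)
  fit <- switch(model,
    M0 = c(ctx$m0, list(classes = tibble::tibble(omega = ctx$m0$omega, weight = 1),
                        params = list(omega = ctx$m0$omega))),
    M7 = fit_m7(ctx, K, n_starts, seed),
    M8a = fit_m8a(ctx, K, n_starts, seed),
    M8 = fit_m8(ctx, K, n_starts, seed),
    M1a = fit_m1a(ctx, n_starts, seed),
    M2a = fit_m2a(ctx, n_starts, seed)
  )
  structure(
    c(fit, list(kappa = ctx$kappa, scale = ctx$m0$scale,
                n_sites = ctx$n_sites, n_taxa = ctx$n_taxa)),
    class = "sfp_site_fit")
}

fit_m7 <- function(ctx, K, n_starts, seed) {
  obj <- function(u) {
    om <- beta_class_omegas(exp(u[1]), exp(u[2]), K)
    -mix_lnl(ctx, ctx$sl_interp(om), rep(1 / K, K))
  }
  starts <- jitter_starts(log(c(0.8, 1.8)), n_starts, seed)
  f <- best_start_fit(starts, obj, lower = log(c(0.005, 0.005)), upper = log(c(99, 99)))
  p <- exp(f$par[1]); q <- exp(f$par[2])
  list(model = "M7", lnL = -f$objective,
       classes = tibble::tibble(omega = beta_class_omegas(p, q, K), weight = 1 / K),
       params = list(p = p, q = q), convergence = f$convergence == 0)
}

# shared inner fit for M8/M8a: beta classes (weight p0) + one class at omega_s
fit_beta_plus <- function(ctx, K, omega_s, n_starts, seed, start_extra = NULL) {
  SLs <- ctx$exact_sl(omega_s)
  obj <- function(u) {
    p0 <- stats::plogis(u[1])
    om <- beta_class_omegas(exp(u[2]), exp(u[3]), K)
    -mix_lnl(ctx, cbind(ctx$sl_interp(om), SLs), c(rep(p0 / K, K), 1 - p0))
  }
  starts <- jitter_starts(c(stats::qlogis(0.9), log(0.8), log(1.8)), n_starts, seed)
  if (!is.null(start_extra)) starts <- c(starts, list(start_extra))
  f <- best_start_fit(starts, obj,
                      lower = c(-12, log(0.005), log(0.005)),
                      upper = c(12, log(99), log(99)))
  list(par = f$par, lnL = -f$objective,
       p0 = stats::plogis(f$par[1]), p = exp(f$par[2]), q = exp(f$par[3]),
       convergence = f$convergence == 0)
}

fit_m8a <- function(ctx, K, n_starts, seed) {
  # M7 is nested at p0 = 1: seed from its solution and never report less
  m7 <- fit_m7(ctx, K, n_starts, seed)
  st7 <- c(12, log(m7$params$p), log(m7$params$q))
  f <- fit_beta_plus(ctx, K, 1, n_starts, seed, start_extra = st7)
  if (f$lnL < m7$lnL) {
    f <- list(lnL = m7$lnL, p0 = stats::plogis(12), p = m7$params$p,
              q = m7$params$q, convergence = m7$convergence)
  }
  list(model = "M8a", lnL = f$lnL,
       classes = tibble::tibble(
         omega = c(beta_class_omegas(f$p, f$q, K), 1),
         weight = c(rep(f$p0 / K, K), 1 - f$p0)),
       params = list(p0 = f$p0, p = f$p, q = f$q, omega_s = 1),
       convergence = f$convergence)
}

fit_m8 <- function(ctx, K, n_starts, seed) {
  null_fit <- fit_m8a(ctx, K, n_starts, seed)
  start0 <- with(null_fit$params, c(stats::qlogis(p0), log(p), log(q)))
  prof <- function(ws) fit_beta_plus(ctx, K, ws, 1, seed, start_extra = start0)$lnL
  ws_grid <- c(1, 1.3, 1.7, 2.2, 3, 4, 5.5, 7.5, 10, 14)
  vals <- vapply(ws_grid, prof, numeric(1))
  i <- which.max(vals)
  lo <- ws_grid[max(1L, i - 1L)]; hi <- ws_grid[min(length(ws_grid), i + 1L)]
  opt <- if (hi > lo) optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-3) else
    list(maximum = ws_grid[i], objective = vals[i])
  cand_ws <- c(opt$maximum, ws_grid[i])
  cand_ll <- c(opt$objective, vals[i])
  j <- which.max(cand_ll)
  ws <- cand_ws[j]
  f <- fit_beta_plus(ctx, K, ws, n_starts, seed, start_extra = start0)
  # the null is nested at omega_s = 1: never report a worse alternative
  if (f$lnL < null_fit$lnL) {
    f <- c(null_fit$params, list(lnL = null_fit$lnL, convergence = null_fit$convergence))
    ws <- 1
  }
  list(model = "M8", lnL = f$lnL,
       classes = tibble::tibble(
         omega = c(beta_class_omegas(f$p, f$q, K), ws),
         weight = c(rep(f$p0 / K, K), 1 - f$p0)),
       params = list(p0 = f$p0, p = f$p, q = f$q, omega_s = ws),
       convergence = isTRUE(f$convergence))
}

fit_m1a <- function(ctx, n_starts, seed) {
  SL1 <- ctx$exact_sl(1)
  obj <- function(u) {
    om0 <- stats::plogis(u[1]); p0 <- stats::plogis(u[2])
    -mix_lnl(ctx, cbind(ctx$sl_interp(om0), SL1), c(p0, 1 - p0))
  }
  starts <- jitter_starts(stats::qlogis(c(0.15, 0.8)), n_starts, seed)
  f <- best_start_fit(starts, obj, lower = c(-12, -12), upper = c(0, 12))
  om0 <- stats::plogis(f$par[1]); p0 <- stats::plogis(f$par[2])
  list(model = "M1a", lnL = -f$objective,
       classes = tibble::tibble(omega = c(om0, 1), weight = c(p0, 1 - p0)),
       params = list(omega0 = om0, p0 = p0), convergence = f$convergence == 0)
}

fit_m2a <- function(ctx, n_starts, seed) {
  null_fit <- fit_m1a(ctx, n_starts, seed)
  SL1 <- ctx$exact_sl(1)
  inner <- function(om2) {
    SL2 <- ctx$exact_sl(om2)
    obj <- function(u) {
      om0 <- stats::plogis(u[1])
      ew <- exp(c(u[2], u[3], 0)); w <- ew / sum(ew)
      -mix_lnl(ctx, cbind(ctx$sl_interp(om0), SL1, SL2), w)
    }
    starts <- jitter_starts(c(stats::qlogis(null_fit$params$omega0),
                              log(pmax(null_fit$params$p0, 1e-3) / 0.02),
                              log(pmax(1 - null_fit$params$p0, 1e-3) / 0.02)),
                            n_starts, seed)
    f <- best_start_fit(starts, obj, lower = c(-12, -15, -15), upper = c(0, 15, 15))
    f
  }
  grid <- c(1, 1.5, 2.5, 4, 6, 9, 14)
  fits <- lapply(grid, inner)
  vals <- -vapply(fits, `[[`, numeric(1), "objective")
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(w2) -inner(w2)$objective, c(lo, hi), maximum = TRUE, tol = 1e-3)
  if (opt$objective >= vals[i]) { om2 <- opt$maximum; lnl <- opt$objective } else {
    om2 <- grid[i]; lnl <- vals[i]
  }
  f <- inner(om2)
  om0 <- stats::plogis(f$par[1])
  ew <- exp(c(f$par[2], f$par[3], 0)); w <- ew / sum(ew)
  lnl <- -f$objective
  if (lnl < null_fit$lnL) {
    return(list(model = "M2a", lnL = null_fit$lnL,
                classes = tibble::tibble(
                  omega = c(null_fit$params$omega0, 1, 1),
                  weight = c(null_fit$classes$weight, 0)),
                params = list(omega0 = null_fit$params$omega0,
                              p0 = null_fit$params$p0, p1 = 1 - null_fit$params$p0,
                              omega2 = 1),
                convergence = null_fit$convergence))
  }
  list(model = "M2a", lnL = lnl,
       classes = tibble::tibble(omega = c(om0, 1, om2), weight = w),
       params = list(omega0 = om0, p0 = w[1], p1 = w[2], omega2 = om2),
       convergence = f$convergence == 0)
}

#' @export
print.sfp_site_fit <- function(x, ...) {
  cat(sprintf("Codon site model %s: lnL = %.4f (kappa = %.3f, %d taxa, %d codons)\n",
              x$model, x$lnL, x$kappa, x$n_taxa, x$n_sites))
  print(x$classes)
  invisible(x)
}

# ---- Likelihood-ratio test and FDR ------------------------------------------

LRT_DF <- list(
  "M1a:M2a" = 2, "M7:M8" = 2, "M8a:M8" = 1
)

#' Likelihood-ratio test between nested site models
#'
#' Compares a null/alternative pair of site-model fits (`M1a` vs `M2a`,
#' `M7` vs `M8`, or `M8a` vs `M8`) with a chi-square test on twice the
#' log-likelihood difference (clamped at zero). The chi-square with the full
#' degrees of freedom is used rather than the boundary mixture, which makes
#' the test conservative.
#'
#' @param null_fit,alt_fit `sfp_site_fit` objects for a nested pair.
#' @return A one-row tibble: `null`, `alt`, `lnl_null`, `lnl_alt`,
#'   `statistic` (2 delta lnL), `df`, `p_value`.
#' @export
site_model_lrt <- function(null_fit, alt_fit) {
  key <- paste(null_fit$model, alt_fit$model, sep = ":")
  df <- LRT_DF[[key]]
  if (is.null(df)) {
    stop("models are not a supported nested pair: ", key, call. = FALSE)
  }
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  tibble::tibble(
    null = null_fit$model, alt = alt_fit$model,
    lnl_null = null_fit$lnL, lnl_alt = alt_fit$lnL,
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Storey q-values with FDR thresholding
#'
#' Estimates q-values from a vector of p-values using Storey's method:
#' the null proportion pi0 is estimated on a lambda grid and smoothed with a
#' cubic spline; when the estimate is unstable (too few p-values, or an
#' estimate outside (0, 1]) the method falls back to pi0 = 1, which is the
#' Benjamini-Hochberg procedure.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param fdr Significance threshold on q (default 0.01).
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 (e.g. `1` forces Benjamini-Hochberg).
#' @return A tibble with `p_value`, `q_value`, `significant`, and the
#'   `pi0` estimate as an attribute.
#' @export
qvalue_fdr <- function(p, fdr = 0.01, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NAs", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20L || min(p) == max(p)) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- tryCatch(stats::smooth.spline(lambda, pi0_l, df = 3),
                      error = function(e) NULL)
      pi0 <- if (is.null(fit)) 1 else stats::predict(fit, x = max(lambda))$y
      if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
    }
  }
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))          # enforce step-up monotonicity
  q <- pmin(q, 1)
  out <- numeric(m); out[ord] <- q
  res <- tibble::tibble(p_value = p, q_value = out, significant = out < fdr)
  attr(res, "pi0") <- pi0
  res
}
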