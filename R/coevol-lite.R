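
# ---- Bayesian trait-rate correlation on the phylogeny -----------------------
#
# A coevol-style two-stage model: the lineage-specific log dN/dS estimates
# (from estimate_branch_omega or a simulator) are treated as noisy
# observations of the branch-midpoint value of a latent multivariate
# Brownian process whose other coordinates are the sexual characters,
# observed exactly at the tips (missing entries marginalized). The sampler
# alternates (i) conditional-Gaussian Gibbs updates of the latent node
# states, (ii) a conjugate inverse-Wishart update of the trait covariance
# Sigma from the branch increments, and (iii) a conjugate inverse-gamma
# update of the observation-noise scale. Marginal correlations and their
# posterior probabilities Pr(r > 0) are derived from the Sigma samples.

LOG_TRANSFORMED_CHARACTERS <- c("mean_partners", "relative_testis_size",
                                "sexual_size_dimorphism")

#' Fit the Brownian trait-rate correlation model
#'
#' @param tree Rooted `phylo` with branch lengths (>= 4 tips with data).
#' @param branch_log_omega Tibble over postorder edges with columns `edge`,
#'   `log_omega` (NA allowed) and optionally `weight` (uncertainty weights,
#'   internally normalized to mean 1); the output of
#'   [estimate_branch_omega()] or `simulate_characters()$branch_rates`.
#' @param characters Tibble with `species` plus character columns. Columns
#'   named in `log_transform` are log-transformed before fitting (positive
#'   scale traits); binary and ordinal characters enter untransformed.
#' @param mcmc List of sampler settings: `iterations` (default 20000),
#'   `burnin` (fraction, default 0.25), `thin` (default 10), `seed`.
#' @param priors List: `nu0`, `S0` for the inverse-Wishart on Sigma
#'   (default df = dim + 3.5 with `S0 = NULL`, meaning
#'   `(nu0 - dim - 1) x` the empirical diagonal variances from a pilot run,
#'   which mildly shrinks correlations toward zero without distorting
#'   variances), and `a0`, `b0` for the inverse-gamma on the noise variance.
#' @param log_transform Character columns to log-transform.
#' @param obs_noise Optional known observation-noise variance (the variance
#'   of a branch log-omega observation at weight 1). When `NULL` (default)
#'   the noise scale is sampled with a conjugate inverse-gamma update; when
#'   supplied it is held fixed, which removes the weakly identified
#'   trade-off between noise and rate variance.
#' @return An object of class `sfp_coevol_fit`: `pairs` tibble (`trait_1`,
#'   `trait_2`, `posterior_mean_r`, `pp`, `ess`), `r_samples`,
#'   `sigma_samples`, `traits`, and `settings`.
#' @export
fit_brownian_correlation <- function(tree, branch_log_omega, characters,
                                     mcmc = list(), priors = list(),
                                     log_transform = LOG_TRANSFORMED_CHARACTERS,
                                     obs_noise = NULL) {
  mc <- utils::modifyList(
    list(iterations = 20000L, burnin = 0.25, thin = 10L, seed = 1L), mcmc)
  if (mc$iterations < 20) stop("too few MCMC iterations", call. = FALSE)
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  if (ntip < 4L) stop("need at least 4 tips", call. = FALSE)
  nnode <- ntip + phy$Nnode
  nedge <- nrow(phy$edge)

  char_cols <- setdiff(names(characters), "species")
  k <- length(char_cols)
  d <- 1L + k
  # Sigma prior: inverse-Wishart with df = dim + 2 + 1.5 extra pseudo-
  # contrasts. The scale defaults to (nu0 - d - 1) x the empirical diagonal
  # variances (estimated in a short pilot run), so the prior mean of Sigma
  # is diagonal at the data's own scale: correlations are shrunk toward
  # zero, variances are not distorted. The mild extra shrinkage tempers
  # sign overconfidence on small trees (13 tips = 12 character contrasts).
  pr <- utils::modifyList(
    list(nu0 = d + 3.5, S0 = NULL, a0 = 2, b0 = 0.02), priors)
  if (!is.null(pr$S0) &&
      !isTRUE(all(eigen(pr$S0, symmetric = TRUE, only.values = TRUE)$values > 0))) {
    stop("prior scale S0 must be positive-definite", call. = FALSE)
  }

  Y <- matrix(NA_real_, ntip, k, dimnames = list(phy$tip.label, char_cols))
  idx <- match(phy$tip.label, characters$species)
  for (j in seq_len(k)) {
    v <- as.numeric(characters[[char_cols[j]]])[idx]
    if (char_cols[j] %in% log_transform) v <- log(v)
    Y[, j] <- v
  }

  stopifnot(all(c("edge", "log_omega") %in% names(branch_log_omega)))
  ord <- match(seq_len(nedge), branch_log_omega$edge)
  y_b <- branch_log_omega$log_omega[ord]
  w_b <- if ("weight" %in% names(branch_log_omega)) {
    branch_log_omega$weight[ord]
  } else rep(1, nedge)
  obs_b <- is.finite(y_b) & is.finite(w_b) & w_b > 0
  if (!any(obs_b)) stop("no usable branch log-omega observations", call. = FALSE)
  w_b[obs_b] <- w_b[obs_b] / mean(w_b[obs_b])
  t_b <- pmax(phy$edge.length, 1e-8)

  E1 <- phy$edge[, 1L]; E2 <- phy$edge[, 2L]
  root <- ntip + 1L

  # tree precision over nodes (Brownian increments) plus a diffuse root
  # anchor; the full latent field X (nnode x d) is Gaussian given Sigma and
  # the noise scale, with precision kronecker(Sigma^-1, Tprec) plus an
  # observation block on the log-omega coordinate, so it is redrawn jointly
  # each iteration (a blocked Gibbs step: exact, fast-mixing)
  Tprec <- matrix(0, nnode, nnode)
  for (e in seq_len(nedge)) {
    it <- 1 / t_b[e]
    Tprec[E1[e], E1[e]] <- Tprec[E1[e], E1[e]] + it
    Tprec[E2[e], E2[e]] <- Tprec[E2[e], E2[e]] + it
    Tprec[E1[e], E2[e]] <- Tprec[E1[e], E2[e]] - it
    Tprec[E2[e], E1[e]] <- Tprec[E2[e], E1[e]] - it
  }
  Tprec[root, root] <- Tprec[root, root] + 1e-2   # root prior N(0, 100 Sigma)

  # observation quadratic on coordinate 1 (up to 1/sig2): midpoint design
  M0 <- matrix(0, nnode, nnode)
  h0 <- numeric(nnode)
  for (e in which(obs_b)) {
    w4 <- w_b[e] / 4
    M0[E1[e], E1[e]] <- M0[E1[e], E1[e]] + w4
    M0[E2[e], E2[e]] <- M0[E2[e], E2[e]] + w4
    M0[E1[e], E2[e]] <- M0[E1[e], E2[e]] + w4
    M0[E2[e], E1[e]] <- M0[E2[e], E1[e]] + w4
    h0[E1[e]] <- h0[E1[e]] + y_b[e] * w_b[e] / 2
    h0[E2[e]] <- h0[E2[e]] + y_b[e] * w_b[e] / 2
  }

  # fixed coordinates: observed tip characters (coordinate-major indexing)
  fixed_idx <- integer(0); fixed_val <- numeric(0)
  for (j in seq_len(k)) {
    obs_t <- which(!is.na(Y[, j]))
    fixed_idx <- c(fixed_idx, j * nnode + obs_t)
    fixed_val <- c(fixed_val, Y[obs_t, j])
  }
  free_idx <- setdiff(seq_len(nnode * d), fixed_idx)

  xvec <- numeric(nnode * d)
  colmeans <- colMeans(Y, na.rm = TRUE); colmeans[is.na(colmeans)] <- 0
  xvec[seq_len(nnode)] <- mean(y_b[obs_b])
  for (j in seq_len(k)) xvec[j * nnode + seq_len(nnode)] <- colmeans[j]
  xvec[fixed_idx] <- fixed_val
  Sigma <- diag(d)
  sig2 <- obs_noise %||% 0.1

  run_chain <- function(n_iter, burn, thin, S0, nu0) {
    n_keep <- floor((n_iter - burn) / thin)
    sigma_samples <- array(NA_real_, c(n_keep, d, d))
    sig2_samples <- numeric(n_keep)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      Sinv <- chol2inv(chol(Sigma))
      # --- latent field | Sigma, sig2 (joint Gaussian draw)
      P <- kronecker(Sinv, Tprec)
      co1 <- seq_len(nnode)
      P[co1, co1] <- P[co1, co1] + M0 / sig2
      h <- numeric(nnode * d)
      h[co1] <- h0 / sig2
      rhs <- h[free_idx] -
        P[free_idx, fixed_idx, drop = FALSE] %*% fixed_val
      U <- chol(P[free_idx, free_idx])
      mu <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
      xvec[free_idx] <- mu + backsolve(U, stats::rnorm(length(free_idx)))
      X <- matrix(xvec, nnode, d)
      # --- Sigma | increments (inverse-Wishart via Wishart of the inverse)
      D <- (X[E2, , drop = FALSE] - X[E1, , drop = FALSE]) / sqrt(t_b)
      S <- S0 + crossprod(D)
      W <- stats::rWishart(1L, nu0 + nedge, chol2inv(chol(S)))[, , 1L]
      Sigma <- chol2inv(chol(W))
      # --- observation noise | states (inverse-gamma), unless known
      if (is.null(obs_noise)) {
        mid <- (X[E1, 1L] + X[E2, 1L]) / 2
        rss <- sum(w_b[obs_b] * (y_b[obs_b] - mid[obs_b])^2)
        sig2 <- 1 / stats::rgamma(1L, pr$a0 + sum(obs_b) / 2, pr$b0 + rss / 2)
      }

      if (it > burn && (it - burn) %% thin == 0L) {
        kept <- kept + 1L
        sigma_samples[kept, , ] <- Sigma
        sig2_samples[kept] <- sig2
      }
    }
    list(sigma = sigma_samples, sig2 = sig2_samples)
  }

  burn <- floor(mc$burnin * mc$iterations)
  n_keep <- floor((mc$iterations - burn) / mc$thin)
  draws <- with_seed(mc$seed, {
    S0 <- pr$S0
    if (is.null(S0)) {
      pilot <- run_chain(300L, 100L, 2L, diag(d), d + 2)
      emp <- pmax(apply(pilot$sigma, c(2L, 3L), mean) |> diag(), 1e-8)
      S0 <- diag(emp * (pr$nu0 - d - 1), d)
      Sigma <- diag(d); sig2 <- 0.1   # reset chain state
    }
    run_chain(mc$iterations, burn, mc$thin, S0, pr$nu0)
  })
  sigma_samples <- draws$sigma
  sig2_samples <- draws$sig2

  traits <- c("log_omega", char_cols)
  pairs <- utils::combn(seq_len(d), 2L)
  r_samples <- matrix(NA_real_, n_keep, ncol(pairs))
  pair_names <- character(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    r_samples[, m] <- sigma_samples[, i, j] /
      sqrt(sigma_samples[, i, i] * sigma_samples[, j, j])
    pair_names[m] <- paste(traits[i], traits[j], sep = ":")
  }
  colnames(r_samples) <- pair_names

  ess <- apply(r_samples, 2L, chain_ess)
  pair_tbl <- tibble::tibble(
    trait_1 = traits[pairs[1L, ]], trait_2 = traits[pairs[2L, ]],
    posterior_mean_r = colMeans(r_samples),
    pp = colMeans(r_samples > 0),
    ess = ess)

  structure(list(
    pairs = pair_tbl, r_samples = r_samples, sigma_samples = sigma_samples,
    noise_samples = sig2_samples, traits = traits,
    settings = mc, priors = pr, n_tips = ntip),
    class = "sfp_coevol_fit")
}

# effective sample size from an AR spectral estimate at frequency zero
chain_ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(n)
  a <- tryCatch(stats::ar(x, aic = TRUE, order.max = min(20L, n %/% 4L)),
                error = function(e) NULL)
  if (is.null(a) || length(a$ar) == 0L) return(n)
  spec0 <- a$var.pred / (1 - sum(a$ar))^2
  max(1, min(n, n * v / spec0))
}

#' @export
print.sfp_coevol_fit <- function(x, ...) {
  cat(sprintf("Brownian trait-rate correlation fit (%d tips, %d kept samples)\n",
              x$n_tips, nrow(x$r_samples)))
  print(x$pairs)
  invisible(x)
}

#' Classify correlation posterior probabilities
#'
#' Three-way call from the posterior probability of a positive correlation:
#' `"positive"` when `pp >= positive_cutoff` (default 0.975), `"negative"`
#' when `pp <= negative_cutoff` (default 0.025), else `"ns"`.
#'
#' @param pp Numeric vector (or the `pairs` tibble of an `sfp_coevol_fit`).
#' @param positive_cutoff,negative_cutoff Strict posterior cutoffs.
#' @return Tibble with `pp` and `call` (plus trait columns when a fit's
#'   `pairs` tibble was given).
#' @export
classify_correlation <- function(pp, positive_cutoff = 0.975, negative_cutoff = 0.025) {
  if (is.data.frame(pp)) {
    out <- pp
    out$call <- classify_correlation(pp$pp, positive_cutoff, negative_cutoff)$call
    return(out)
  }
  if (any(pp < 0 | pp > 1, na.rm = TRUE)) stop("pp must lie in [0, 1]", call. = FALSE)
  tibble::tibble(
    pp = pp,
    call = dplyr::case_when(
      is.na(pp) ~ NA_character_,
      pp >= positive_cutoff ~ "positive",
      pp <= negative_cutoff ~ "negative",
      TRUE ~ "ns"))
}
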