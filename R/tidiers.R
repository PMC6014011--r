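
#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a site-model fit
#'
#' One row per omega class with its weight.
#' @param x An `sfp_site_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `omega`, `weight`.
#' @method tidy sfp_site_fit
#' @export
tidy.sfp_site_fit <- function(x, ...) {
  dplyr::mutate(x$classes, model = x$model, .before = 1L)
}

#' One-row summary of a site-model fit
#' @param x An `sfp_site_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `lnL`, `kappa`, `scale`, `n_taxa`,
#'   `n_sites`, `convergence`.
#' @export
glance.sfp_site_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lnL = x$lnL, kappa = x$kappa,
                 scale = x$scale, n_taxa = x$n_taxa, n_sites = x$n_sites,
                 convergence = isTRUE(x$convergence))
}

#' Tidy a branch-site test
#' @param x An `sfp_branch_site`.
#' @param ... Unused.
#' @return One-row tibble with the test statistic, p-value and estimates.
#' @method tidy sfp_branch_site
#' @export
tidy.sfp_branch_site <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 omega0 = x$omega0, omega2 = x$omega2,
                 p0 = unname(x$weights["p0"]), p1 = unname(x$weights["p1"]),
                 n_foreground = x$n_foreground)
}

#' @rdname tidy.sfp_branch_site
#' @method glance sfp_branch_site
#' @export
glance.sfp_branch_site <- function(x, ...) {
  tibble::tibble(lnl_null = x$lnl_null, lnl_alt = x$lnl_alt,
                 statistic = x$statistic, p_value = x$p_value,
                 kappa = x$kappa, n_taxa = x$n_taxa, n_sites = x$n_sites)
}

#' Tidy a Brownian correlation fit
#'
#' One row per trait pair with posterior mean correlation, posterior
#' probability of a positive correlation, and effective sample size.
#' @param x An `sfp_coevol_fit`.
#' @param ... Unused.
#' @method tidy sfp_coevol_fit
#' @export
tidy.sfp_coevol_fit <- function(x, ...) x$pairs

#' @rdname tidy.sfp_coevol_fit
#' @method glance sfp_coevol_fit
#' @export
glance.sfp_coevol_fit <- function(x, ...) {
  tibble::tibble(n_tips = x$n_tips, n_samples = nrow(x$r_samples),
                 iterations = x$settings$iterations,
                 min_ess = min(x$pairs$ess))
}
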