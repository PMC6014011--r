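
# ---- Multivariate Brownian simulation of rate and sexual characters ---------

DEFAULT_CHARACTERS <- c("mating_type", "mean_partners", "semen_coagulation",
                        "relative_testis_size", "sexual_size_dimorphism")

DEFAULT_TRANSFORMS <- c(
  mating_type = "binary_median", mean_partners = "exp",
  semen_coagulation = "ordinal4", relative_testis_size = "exp",
  sexual_size_dimorphism = "exp")

#' Simulate correlated evolution of log dN/dS and sexual characters
#'
#' Samples a multivariate Brownian motion along the tree whose first
#' coordinate is the latent log evolutionary rate (log omega) and whose
#' remaining coordinates are latent sexual characters, with the supplied
#' trait covariance per unit branch length. Tip values of the characters are
#' reported after per-character transforms: `"exp"` for positive-scaled
#' traits (testis size, dimorphism, partner number), `"ordinal4"` for the
#' semen-coagulation rating (quartile bins 1-4), `"binary_median"` for the
#' mating type (1 = above the tip median of the latent trait, recorded in
#' the output metadata), or `"identity"`. The true branch-average log omega
#' (midpoint of parent and child states) is returned per branch.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param covariance Symmetric positive-definite matrix of dimension
#'   `1 + length(characters)` over (log omega, characters).
#' @param root_state Root value of the latent process (default zeros).
#' @param seed Integer seed.
#' @param characters Character names; defaults to the five sexual characters
#'   when the covariance is 6 x 6, else `trait1..traitk`.
#' @param transforms Named vector of transforms per character (see above);
#'   defaults follow the character names.
#' @return A list: `characters` (tibble, one row per tip), `branch_rates`
#'   (tibble with postorder edge index, parent, child, length, `log_omega`),
#'   `latent` (tibble of untransformed tip states), and `meta` (thresholds
#'   and transforms used).
#' @export
simulate_characters <- function(tree, covariance, root_state = NULL, seed = NULL,
                                characters = NULL, transforms = NULL) {
  d <- nrow(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance)))) {
    stop("`covariance` must be symmetric", call. = FALSE)
  }
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch) && !all(covariance == 0)) {
    stop("`covariance` must be positive-definite", call. = FALSE)
  }
  if (is.null(characters)) {
    characters <- if (d == 6L) DEFAULT_CHARACTERS else paste0("trait", seq_len(d - 1L))
  }
  if (length(characters) != d - 1L) {
    stop("covariance dimension must be 1 + number of characters", call. = FALSE)
  }
  if (is.null(transforms)) {
    transforms <- DEFAULT_TRANSFORMS[characters]
    transforms[is.na(transforms)] <- "identity"
    names(transforms) <- characters
  }
  root_state <- root_state %||% rep(0, d)

  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  with_seed(seed, {
    X <- matrix(NA_real_, nnode, d)
    X[ntip + 1L, ] <- root_state
    for (e in rev(seq_len(nrow(phy$edge)))) {   # preorder
      p <- phy$edge[e, 1L]; chl <- phy$edge[e, 2L]
      t_b <- phy$edge.length[e]
      step <- if (is.null(ch) || t_b == 0) rep(0, d) else
        sqrt(t_b) * drop(crossprod(ch, stats::rnorm(d)))
      X[chl, ] <- X[p, ] + step
    }
    latent <- X[seq_len(ntip), , drop = FALSE]
    rownames(latent) <- phy$tip.label

    out <- tibble::tibble(species = phy$tip.label)
    meta <- list(transforms = transforms)
    for (j in seq_along(characters)) {
      v <- latent[, j + 1L]
      out[[characters[j]]] <- switch(transforms[[j]],
        exp = exp(v),
        identity = v,
        ordinal4 = {
          qs <- unique(stats::quantile(v, c(0.25, 0.5, 0.75)))
          pmin(findInterval(v, qs, left.open = TRUE) + 1L, 4L)
        },
        binary_median = {
          thr <- stats::median(v)
          meta$mating_threshold <- thr
          as.integer(v > thr)
        },
        stop("unknown transform: ", transforms[[j]], call. = FALSE))
    }
    branch_rates <- tibble::tibble(
      edge = seq_len(nrow(phy$edge)),
      parent = phy$edge[, 1L], child = phy$edge[, 2L],
      length = phy$edge.length,
      log_omega = (X[phy$edge[, 1L], 1L] + X[phy$edge[, 2L], 1L]) / 2)

    list(
      characters = out,
      branch_rates = branch_rates,
      latent = {
        colnames(latent) <- c("log_omega", characters)
        tibble::as_tibble(latent, rownames = "species")
      },
      meta = meta)
  })
}
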