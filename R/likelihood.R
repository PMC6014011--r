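
# ---- Felsenstein pruning for mixture codon models ---------------------------

# Postorder edge representation of an ape phylo, with tip rows of the
# alignment matched to tip labels.
prepare_tree <- function(tree, ai) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo", call. = FALSE)
  missing_tips <- setdiff(rownames(ai), tree$tip.label)
  if (length(missing_tips)) {
    stop("sequences not in tree: ", paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  list(
    phy = phy,
    edge = phy$edge,
    el = phy$edge.length,
    ntip = ntip,
    nnode = ntip + phy$Nnode,
    root = ntip + 1L,
    tip_row = match(phy$tip.label, rownames(ai))
  )
}

# One-class pruning. Plist: per-edge transition matrices (postorder order).
# Returns per-pattern log-likelihood, root weighted by pi.
prune_loglik <- function(tp, Plist, tips_pat, pi) {
  npat <- ncol(tips_pat)
  partial <- vector("list", tp$nnode)
  logscale <- matrix(0, tp$nnode, npat)
  ones <- matrix(1, 61, npat)
  for (e in seq_len(nrow(tp$edge))) {
    parent <- tp$edge[e, 1L]; child <- tp$edge[e, 2L]
    P <- Plist[[e]]
    if (child <= tp$ntip) {
      st <- tips_pat[child, ]
      contrib <- ones
      obs <- which(!is.na(st))
      if (length(obs)) contrib[, obs] <- P[, st[obs]]
      ls <- 0
    } else {
      contrib <- P %*% partial[[child]]
      sc <- colSums(contrib) / 61   # any positive scaler prevents underflow
      sc[sc <= 0] <- 1
      contrib <- contrib / rep(sc, each = 61L)
      ls <- logscale[child, ] + log(sc)
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
      logscale[parent, ] <- ls
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      logscale[parent, ] <- logscale[parent, ] + ls
    }
  }
  lik <- colSums(pi * partial[[tp$root]])
  log(lik) + logscale[tp$root, ]
}

# Per-pattern log-likelihood for a list of classes. Each class is
# list(weight, omega) where omega is a scalar or a per-edge vector
# (branch-site classes). Transition matrices are cached per distinct omega.
# `rate_scale` divides all generators by a common factor so every class
# shares one time scale.
mixture_site_loglik <- function(tp, tips_pat, classes, kappa, pi, rate_scale) {
  dec_cache <- new.env(parent = emptyenv())
  get_dec <- function(om) {
    key <- sprintf("%.15g", om)
    d <- dec_cache[[key]]
    if (is.null(d)) {
      d <- codon_decompose(kappa, om, pi, rate_scale = rate_scale)
      dec_cache[[key]] <- d
    }
    d
  }
  nedge <- nrow(tp$edge)
  npat <- ncol(tips_pat)
  K <- length(classes)
  ll <- matrix(0, npat, K)
  for (k in seq_len(K)) {
    om <- classes[[k]]$omega
    om_edge <- if (length(om) == 1L) rep(om, nedge) else om
    if (length(om_edge) != nedge) stop("per-edge omega has wrong length", call. = FALSE)
    Plist <- lapply(seq_len(nedge), function(e) codon_pmat(get_dec(om_edge[e]), tp$el[e]))
    ll[, k] <- prune_loglik(tp, Plist, tips_pat, pi)
  }
  w <- vapply(classes, `[[`, numeric(1), "weight")
  log_sum_exp_rows(ll + rep(log(w), each = npat))
}

#' Log-likelihood of a codon alignment under a site-class mixture
#'
#' Computes the phylogenetic log-likelihood of an in-frame codon alignment
#' under a GY94-style model whose sites fall into omega classes with given
#' weights. Conditional likelihoods are propagated by Felsenstein pruning
#' with per-site rescaling; gaps and ambiguous codons are treated as missing
#' states. All class generators share a common time scale so that branch
#' lengths are expected substitutions per codon at the mixture-mean rate.
#'
#' @param alignment Named character vector of equal-length in-frame
#'   nucleotide sequences (names must match tree tips).
#' @param tree A rooted `phylo` with branch lengths.
#' @param omega Numeric vector of per-class dN/dS values.
#' @param weight Class weights (default uniform); must sum to 1.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (61); default uniform.
#' @param per_site If `TRUE`, return the vector of per-site log-likelihoods
#'   instead of their sum.
#' @return The total log-likelihood (scalar), or per-site values.
#' @export
site_log_likelihood <- function(alignment, tree, omega, weight = NULL,
                                kappa = 2, pi = NULL, per_site = FALSE) {
  ai <- codon_index_matrix(alignment)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  if (is.null(weight)) weight <- rep(1 / length(omega), length(omega))
  if (abs(sum(weight) - 1) > 1e-8) stop("class weights must sum to 1", call. = FALSE)
  tp <- prepare_tree(tree, ai)
  pat <- compress_patterns(ai)
  tips_pat <- pat$idx[tp$tip_row, , drop = FALSE]
  rate_scale <- sum(weight * vapply(omega, function(o) codon_mean_rate(kappa, o, pi), numeric(1)))
  classes <- purrr::map2(omega, weight, ~ list(omega = .x, weight = .y))
  ll_pat <- mixture_site_loglik(tp, tips_pat, classes, kappa, pi, rate_scale)
  if (per_site) {
    key <- apply(ai, 2L, paste, collapse = ",")
    ukey <- apply(pat$idx, 2L, paste, collapse = ",")
    return(ll_pat[match(key, ukey)])
  }
  sum(ll_pat * pat$wt)
}

# ---- Vectorized natural cubic spline over a shared knot grid ----------------
#
# Fits one natural cubic spline per row of Y on common knots x; used to
# interpolate per-site log-likelihoods across an omega grid. The tridiagonal
# system is factored once for all rows.
grid_spline <- function(x, Y) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n - 2L, n - 2L)
  for (i in seq_len(n - 2L)) {
    A[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i > 1L) A[i, i - 1L] <- h[i] / 6
    if (i < n - 2L) A[i, i + 1L] <- h[i + 1L] / 6
  }
  D <- Y[, -1L, drop = FALSE] - Y[, -n, drop = FALSE]
  rhs <- sweep(D, 2L, h, "/")
  rhs <- rhs[, -1L, drop = FALSE] - rhs[, -(n - 1L), drop = FALSE]
  Mint <- t(solve(A, t(rhs)))
  M <- cbind(0, Mint, 0)
  function(q) {
    q <- pmin(pmax(q, x[1L]), x[n])
    iv <- findInterval(q, x, rightmost.closed = TRUE)
    out <- matrix(0, nrow(Y), length(q))
    for (m in seq_along(q)) {
      i <- iv[m]
      hi <- h[i]
      a <- (x[i + 1L] - q[m]) / hi
      b <- (q[m] - x[i]) / hi
      out[, m] <- a * Y[, i] + b * Y[, i + 1L] +
        ((a^3 - a) * M[, i] + (b^3 - b) * M[, i + 1L]) * hi^2 / 6
    }
    out
  }
}
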