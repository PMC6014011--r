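
# ---- Codon alignment simulation ---------------------------------------------

#' Specify a codon substitution model for simulation
#'
#' Builds a model specification for [simulate_codon_alignment()]. Supported
#' families: `M0` (single `omega`); `M7` (beta with shape `p`, `q`,
#' discretized into `K` classes); `M8` (beta with weight `p0` plus a class at
#' `omega_s >= 1`); `M8a` (as M8 with `omega_s = 1`); `branch_site`
#' (model A: proportions `p0`, `p1` for classes with background omega
#' `omega0` and 1, plus foreground-only selection at `omega2` on the
#' designated foreground branches).
#'
#' @param name Model family name.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (61) or `NULL` for uniform.
#' @param omega,p,q,p0,p1,omega_s,omega0,omega2 Family parameters (see above).
#' @param K Discrete beta classes.
#' @param foreground For `branch_site`: logical vector over postorder edges
#'   (as from [foreground_edges()]).
#' @return A `sfp_codon_model` list.
#' @export
codon_model <- function(name = c("M0", "M7", "M8", "M8a", "branch_site"),
                        kappa = 2, pi = NULL,
                        omega = NULL, p = NULL, q = NULL, p0 = NULL, p1 = NULL,
                        omega_s = NULL, omega0 = NULL, omega2 = NULL,
                        K = 10, foreground = NULL) {
  name <- match.arg(name)
  need <- function(val, nm) {
    if (is.null(val)) stop(sprintf("model %s requires parameter `%s`", name, nm), call. = FALSE)
    val
  }
  spec <- switch(name,
    M0 = list(omega = need(omega, "omega")),
    M7 = list(p = need(p, "p"), q = need(q, "q"), K = K),
    M8 = list(p0 = need(p0, "p0"), p = need(p, "p"), q = need(q, "q"),
              omega_s = need(omega_s, "omega_s"), K = K),
    M8a = list(p0 = need(p0, "p0"), p = need(p, "p"), q = need(q, "q"),
               omega_s = 1, K = K),
    branch_site = list(p0 = need(p0, "p0"), p1 = need(p1, "p1"),
                       omega0 = need(omega0, "omega0"),
                       omega2 = need(omega2, "omega2"),
                       foreground = need(foreground, "foreground"))
  )
  structure(c(list(name = name, kappa = kappa, pi = pi), spec),
            class = "sfp_codon_model")
}

# site-class table of a model spec: weights plus background/foreground omegas
model_classes <- function(model) {
  with(model, switch(name,
    M0 = tibble::tibble(weight = 1, omega_bg = omega, omega_fg = omega),
    M7 = tibble::tibble(weight = rep(1 / K, K),
                        omega_bg = beta_class_omegas(p, q, K),
                        omega_fg = beta_class_omegas(p, q, K)),
    M8 = ,
    M8a = tibble::tibble(weight = c(rep(p0 / K, K), 1 - p0),
                         omega_bg = c(beta_class_omegas(p, q, K), omega_s),
                         omega_fg = c(beta_class_omegas(p, q, K), omega_s)),
    branch_site = {
      w2 <- 1 - p0 - p1
      if (w2 < -1e-9) stop("branch-site weights require p0 + p1 <= 1", call. = FALSE)
      w2 <- max(w2, 0)
      tibble::tibble(
        weight = c(p0, p1, w2 * p0 / (p0 + p1), w2 * p1 / (p0 + p1)),
        omega_bg = c(omega0, 1, omega0, 1),
        omega_fg = c(omega0, 1, omega2, omega2))
    }))
}

#' Simulate a codon alignment along a tree
#'
#' Draws a root codon per site from the stationary frequencies, assigns each
#' site an omega class from the model's mixture, and evolves sites along the
#' tree under the GY94 process of that class (for branch-site models the
#' class omega differs between foreground and background branches). All
#' class generators share a common time scale equal to the mixture-mean
#' substitution rate, so branch lengths are expected substitutions per codon.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param model An `sfp_codon_model` from [codon_model()].
#' @param n_codons Number of codon sites (positive integer).
#' @param seed Integer seed; fixed seed gives a byte-identical alignment.
#' @return Named character vector of in-frame sequences (one per tip) with
#'   attributes `site_class` (integer per site) and `model`.
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, seed = NULL) {
  if (!inherits(model, "sfp_codon_model")) stop("`model` must come from codon_model()", call. = FALSE)
  if (n_codons < 1) stop("`n_codons` must be positive", call. = FALSE)
  tab <- codon_table()
  pi <- model$pi %||% rep(1 / 61, 61)
  cls <- model_classes(model)
  phy <- ape::reorder.phylo(tree, "postorder")
  nedge <- nrow(phy$edge)
  ntip <- length(phy$tip.label)
  fg <- if (model$name == "branch_site") {
    if (length(model$foreground) != nedge) {
      stop("`foreground` must be a logical over postorder edges", call. = FALSE)
    }
    model$foreground
  } else rep(FALSE, nedge)

  # common time scale: mixture mean of background rates (weighted over
  # classes); foreground classes share it so branch lengths stay comparable
  mus <- vapply(cls$omega_bg, function(o) codon_mean_rate(model$kappa, o, pi), numeric(1))
  rate_scale <- sum(cls$weight * mus)

  with_seed(seed, {
    site_class <- sample.int(nrow(cls), n_codons, replace = TRUE, prob = cls$weight)
    states <- matrix(NA_integer_, ntip + phy$Nnode, n_codons)
    root <- ntip + 1L
    states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    dec_cache <- new.env(parent = emptyenv())
    get_P <- function(om, t) {
      key <- sprintf("%.12g", om)
      d <- dec_cache[[key]]
      if (is.null(d)) {
        d <- codon_decompose(model$kappa, om, pi, rate_scale = rate_scale)
        dec_cache[[key]] <- d
      }
      codon_pmat(d, t)
    }
    for (e in rev(seq_len(nedge))) {     # preorder: parents before children
      parent <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
      om_col <- if (fg[e]) cls$omega_fg else cls$omega_bg
      for (k in sort(unique(site_class))) {
        sites <- which(site_class == k)
        if (!length(sites)) next
        if (phy$edge.length[e] == 0) {
          states[child, sites] <- states[parent, sites]
          next
        }
        P <- get_P(om_col[k], phy$edge.length[e])
        ps <- states[parent, sites]
        for (s in unique(ps)) {
          idx <- sites[ps == s]
          states[child, idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
        }
      }
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                  function(row) paste(tab$codons[row], collapse = ""))
    names(seqs) <- phy$tip.label
    attr(seqs, "site_class") <- site_class
    attr(seqs, "model") <- model
    seqs
  })
}
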