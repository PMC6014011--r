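# Shared fixtures and independent oracles, built in code.

small_quant_fixture <- function() {
  # two species, two individuals each, two runs, hand-sized
  tibble::tibble(
    species = rep(c("human", "rhesus_macaque"), each = 4),
    individual = rep(c("h1", "h1", "h1", "h1", "r1", "r1", "r1", "r1")),
    run = rep(c("run1", "run1", "run2", "run2", "run3", "run3", "run4", "run4")),
    peptide = rep(c("PEPTIDEK", "STDPEP01"), 4),
    protein = rep(c("PROT001", "STD_HORSE_MYOGLOBIN"), 4),
    is_standard = rep(c(FALSE, TRUE), 4),
    ria = c(10, 4, 20, 9, 30, 6, 40, 24))
}

# Independent Wilcoxon oracle: full enumeration of rank assignments.
# Returns the one-sided (greater) and two-sided p for the observed samples.
enumerate_wilcoxon <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  r_all <- rank(pooled)
  us <- apply(combos, 2L, function(ix) sum(r_all[ix]) - n * (n + 1) / 2)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  list(u = u_obs,
       p_greater = p_ge, p_less = p_le,
       p_two = min(1, 2 * min(p_ge, p_le)))
}

# Independent dN/dS oracle: Nei-Gojobori-style pathway counting on a pair
# of sequences (used against simulated two-taxon alignments). Site counts
# weight transitions by kappa (the modified-NG convention), matching the
# mutational opportunity of the generating process.
ng_dnds <- function(seq1, seq2, kappa = 2) {
  tab <- sfpevol::codon_table()
  syn_sites <- function(cd) {
    i <- match(cd, tab$codons)
    nbr <- tab$pairs[tab$pairs$i == i | tab$pairs$j == i, ]
    w <- ifelse(nbr$transition, kappa, 1)
    3 * sum(w[nbr$synonymous]) / sum(w)
  }
  count_path <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
    pos <- which(a != b)
    if (length(pos) == 1L) {
      aa1 <- tab$aa[match(c1, tab$codons)]; aa2 <- tab$aa[match(c2, tab$codons)]
      if (aa1 == aa2) c(1, 0) else c(0, 1)
    } else {
      # average over orderings of single changes, skipping stop intermediates
      perms <- if (length(pos) == 2L) list(pos, rev(pos)) else {
        do.call(c, lapply(seq_along(pos), function(i) {
          rest <- pos[-i]
          lapply(list(rest, rev(rest)), function(r) c(pos[i], r))
        }))
      }
      acc <- c(0, 0); nvalid <- 0
      for (pm in perms) {
        cur <- a; s <- c(0, 0); ok <- TRUE
        for (p in pm) {
          nxt <- cur; nxt[p] <- b[p]
          ci <- paste(cur, collapse = ""); ni <- paste(nxt, collapse = "")
          if (!(ni %in% tab$codons) && ni != c2) { ok <- FALSE; break }
          if (!(ni %in% tab$codons)) { ok <- FALSE; break }
          s <- s + count_path(ci, ni)
          cur <- nxt
        }
        if (ok) { acc <- acc + s; nvalid <- nvalid + 1 }
      }
      if (nvalid == 0) c(0, length(pos)) else acc / nvalid
    }
  }
  n1 <- nchar(seq1) / 3
  S <- 0; Ns <- 0; sd_count <- 0; nd_count <- 0
  for (k in seq_len(n1)) {
    c1 <- toupper(substr(seq1, 3 * k - 2, 3 * k))
    c2 <- toupper(substr(seq2, 3 * k - 2, 3 * k))
    s_k <- (syn_sites(c1) + syn_sites(c2)) / 2
    S <- S + s_k; Ns <- Ns + (3 - s_k)
    cnt <- count_path(c1, c2)
    sd_count <- sd_count + cnt[1]; nd_count <- nd_count + cnt[2]
  }
  pS <- sd_count / S; pN <- nd_count / Ns
  dS <- -3 / 4 * log(1 - 4 * pS / 3)
  dN <- -3 / 4 * log(1 - 4 * pN / 3)
  dN / dS
}

# Independent-contrasts correlation oracle (known tree)
pic_correlation <- function(tree, x, y) {
  px <- ape::pic(x, tree); py <- ape::pic(y, tree)
  sum(px * py) / sqrt(sum(px^2) * sum(py^2))
}

quick_mcmc <- list(iterations = 1500L, burnin = 0.3, thin = 3L, seed = 1L)

# Independent likelihood oracle: exact summation over all internal-node
# state assignments (vectorized over the 61^n_internal grid).
brute_force_loglik <- function(aln, tree, omega, weight, kappa, pi) {
  ai <- sfpevol:::codon_index_matrix(aln)
  tp <- sfpevol:::prepare_tree(tree, ai)
  rate_scale <- sum(weight * vapply(omega, function(o)
    sfpevol:::codon_mean_rate(kappa, o, pi), numeric(1)))
  nint <- tp$nnode - tp$ntip
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))  # internal states
  node_state <- function(node, tipstate) {
    if (node <= tp$ntip) rep(tipstate[node], nrow(grid)) else grid[, node - tp$ntip]
  }
  ll <- numeric(ncol(ai))
  for (s in seq_len(ncol(ai))) {
    tipstate <- ai[match(tp$phy$tip.label, rownames(ai)), s]
    tot_s <- 0
    for (k in seq_along(omega)) {
      dec <- sfpevol:::codon_decompose(kappa, omega[k], pi, rate_scale)
      pr <- pi[grid[, tp$root - tp$ntip]]
      for (e in seq_len(nrow(tp$edge))) {
        P <- sfpevol:::codon_pmat(dec, tp$el[e])
        a <- node_state(tp$edge[e, 1], tipstate)
        b <- node_state(tp$edge[e, 2], tipstate)
        if (tp$edge[e, 2] <= tp$ntip && is.na(tipstate[tp$edge[e, 2]])) next
        pr <- pr * P[cbind(a, b)]
      }
      tot_s <- tot_s + weight[k] * sum(pr)
    }
    ll[s] <- log(tot_s)
  }
  sum(ll)
}
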