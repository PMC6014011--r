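# GY94 machinery, pruning likelihood, site models, LRT, q-values.

test_that("the rate matrix has generator structure and respects omega and kappa", {
  tab <- codon_table()
  set.seed(3)
  pi <- as.numeric(rexp(61)); pi <- pi / sum(pi)
  Q <- build_codon_rate_matrix(kappa = 3.1, omega = 0.7, pi = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # purifying limit: omega = 0 zeroes all nonsynonymous entries
  Q0 <- build_codon_rate_matrix(2, 0, pi)
  ns <- tab$pairs[!tab$pairs$synonymous, ]
  expect_true(all(Q0[cbind(ns$i, ns$j)] == 0))
  # stationarity and detailed balance
  expect_lt(max(abs(pi %*% Q)), 1e-12)
  bal <- pi * Q - t(pi * Q)      # pi_i q_ij - pi_j q_ji
  expect_lt(max(abs(bal)), 1e-14)
  # unit mean rate at stationarity
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
})

test_that("uniform-frequency kappa = omega = 1 matrix is the nucleotide-change adjacency", {
  Q <- build_codon_rate_matrix(1, 1, scale = FALSE)
  tab <- codon_table()
  off <- Q[upper.tri(Q)]
  expect_true(all(off %in% c(0, 1 / 61)))
  expect_equal(sum(off > 0), nrow(tab$pairs))
})

test_that("pruning equals brute-force enumeration on random small trees", {
  set.seed(101)
  tab <- codon_table()
  for (rep in 1:6) {
    ntip <- sample(3:4, 1)
    tree <- ape::rtree(ntip, br = function(n) runif(n, 0.05, 0.6))
    ncod <- sample(2:3, 1)
    seqs <- vapply(seq_len(ntip), function(i)
      paste(sample(tab$codons, ncod, replace = TRUE), collapse = ""), character(1))
    names(seqs) <- tree$tip.label
    kappa <- runif(1, 1, 4)
    omega <- sort(runif(2, 0.05, 2))
    w <- {x <- runif(2); x / sum(x)}
    pi <- as.numeric(rexp(61)); pi <- pi / sum(pi)
    ll <- site_log_likelihood(seqs, tree, omega, w, kappa = kappa, pi = pi)
    bf <- brute_force_loglik(seqs, tree, omega, w, kappa, pi)
    expect_lt(abs(ll - bf), 1e-10)
  }
})

test_that("likelihood is invariant to rerooting and gaps act as missing data", {
  tr <- fixed_primate_tree(branch_scale = 15)
  aln <- simulate_codon_alignment(tr, codon_model("M0", omega = 0.4, kappa = 2),
                                  30, seed = 5)
  ll1 <- site_log_likelihood(aln, tr, omega = 0.4, kappa = 2)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "marmoset", resolve.root = TRUE)
  ll2 <- site_log_likelihood(aln, rerooted, omega = 0.4, kappa = 2)
  expect_lt(abs(ll1 - ll2), 1e-8)
  # knocking a codon out to gaps cannot raise information: lnL changes, and
  # an all-gap column contributes zero
  gapped <- aln
  substr(gapped[1], 1, 3) <- "---"
  llg <- site_log_likelihood(gapped, tr, omega = 0.4, kappa = 2)
  expect_gt(llg, ll1)   # marginalized tip has fewer constraints
})

test_that("zero-length star tree with identical sequences gives sum log pi, and site duplication doubles lnL", {
  tab <- codon_table()
  star <- ape::read.tree(text = "(A:0,B:0,C:0);")
  seq1 <- paste(tab$codons[c(1, 5, 20)], collapse = "")
  aln <- c(A = seq1, B = seq1, C = seq1)
  pi <- as.numeric(rexp(61)); pi <- pi / sum(pi)
  ll <- site_log_likelihood(aln, star, omega = 0.5, kappa = 2, pi = pi)
  expect_equal(ll, sum(log(pi[c(1, 5, 20)])), tolerance = 1e-10)
  dup <- vapply(aln, function(s) paste0(s, s), character(1))
  names(dup) <- names(aln)
  lld <- site_log_likelihood(dup, star, omega = 0.5, kappa = 2, pi = pi)
  expect_equal(lld, 2 * ll, tolerance = 1e-10)
})

test_that("M0 recovers simulated omega and kappa on a mid-sized alignment", {
  tr <- ape::keep.tip(fixed_primate_tree(branch_scale = 20),
                      c("human", "chimpanzee", "gorilla", "rhesus_macaque",
                        "baboon", "vervet", "colobus", "marmoset"))
  aln <- simulate_codon_alignment(tr, codon_model("M0", omega = 0.3, kappa = 2),
                                  400, seed = 42)
  fit <- fit_site_model(aln, tr, "M0", pi = "uniform")
  expect_lt(abs(fit$params$omega - 0.3) / 0.3, 0.2)
  expect_lt(abs(fit$kappa - 2) / 2, 0.25)
})

test_that("interpretive contract: fitted omega maps to selection regime labels", {
  # the dN/dS scale itself carries the interpretation: > 1 positive
  # selection, = 1 neutral, < 1 purifying; the fit must preserve the scale
  tr <- ape::keep.tip(fixed_primate_tree(branch_scale = 20),
                      c("human", "rhesus_macaque", "marmoset", "vervet"))
  for (om_true in c(0.2, 1.6)) {
    aln <- simulate_codon_alignment(tr, codon_model("M0", omega = om_true, kappa = 2),
                                    500, seed = round(om_true * 100))
    fit <- fit_site_model(aln, tr, "M0", pi = "uniform")
    expect_equal(fit$params$omega > 1, om_true > 1)
  }
})

test_that("site-model nesting holds and the LRT machinery matches chi-square quantiles", {
  tr <- fixed_primate_tree(branch_scale = 20)
  aln <- simulate_codon_alignment(
    tr, codon_model("M8a", p0 = 0.9, p = 0.5, q = 1.5), 150, seed = 8)
  ctx <- sfpevol:::site_model_context(aln, tr)
  m7 <- fit_site_model(aln, tr, "M7", ctx = ctx)
  m8a <- fit_site_model(aln, tr, "M8a", ctx = ctx)
  m8 <- fit_site_model(aln, tr, "M8", ctx = ctx)
  expect_gte(m8$lnL, m8a$lnL)
  expect_gte(m8a$lnL, m7$lnL)
  expect_true(all(abs(sum(m8$classes$weight) - 1) < 1e-8))
  # chi-square(1) quantile: 2dlnL = 3.841 -> p ~ 0.05
  fake_null <- structure(list(model = "M8a", lnL = 0), class = "sfp_site_fit")
  fake_alt <- structure(list(model = "M8", lnL = 3.841459 / 2), class = "sfp_site_fit")
  expect_equal(site_model_lrt(fake_null, fake_alt)$p_value, 0.05, tolerance = 1e-4)
  fake_equal <- structure(list(model = "M8", lnL = 0), class = "sfp_site_fit")
  expect_equal(site_model_lrt(fake_null, fake_equal)$p_value, 1)
  expect_error(site_model_lrt(m7, m8a), "not a supported nested pair")
})

test_that("q-values reproduce Benjamini-Hochberg under pi0 = 1 and are step-up monotone", {
  out <- qvalue_fdr(c(0.001, 0.5, 0.9), pi0 = 1)
  expect_equal(out$q_value, c(0.003, 0.75, 0.9))
  allone <- qvalue_fdr(rep(1, 10))
  expect_true(all(allone$q_value == 1))
  expect_false(any(allone$significant))
  set.seed(2)
  p <- c(runif(50)^2, runif(150))
  q <- qvalue_fdr(p)
  ord <- order(p)
  expect_true(all(diff(q$q_value[ord]) >= -1e-12))
  expect_true(attr(q, "pi0") <= 1 && attr(q, "pi0") > 0)
  expect_error(qvalue_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("branch-site alternative never falls below its null and detects planted foreground selection", {
  tr <- fixed_primate_tree(branch_scale = 20)
  fg <- foreground_edges(tr)
  mdl <- codon_model("branch_site", p0 = 0.6, p1 = 0.25, omega0 = 0.15,
                     omega2 = 4, foreground = fg)
  aln <- simulate_codon_alignment(tr, mdl, 250, seed = 17)
  bs <- branch_site_test(aln, tr)
  expect_gte(bs$lnl_alt, bs$lnl_null)
  expect_lt(bs$p_value, 0.01)
  expect_gt(bs$omega2, 1)
  # swapped-foreground control: selection planted on multi branches should
  # not register as uni-male foreground selection
  bs_swap <- branch_site_test(aln, tr, foreground = "uni")
  expect_gt(bs_swap$p_value, bs$p_value)
})

test_that("foreground assignment follows descendant labels; degenerate partitions error", {
  tr <- fixed_primate_tree()
  fg <- foreground_edges(tr)
  phy <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(phy$tip.label)
  tip_edges <- phy$edge[, 2] <= ntip
  lab <- tr$mating[phy$tip.label[phy$edge[tip_edges, 2]]]
  expect_equal(unname(fg[tip_edges]), unname(lab == "multi"))
  # macaque pair ancestor is foreground; root path to mixed clades is not
  fitch <- foreground_edges(tr, rule = "fitch")
  expect_true(sum(fitch) >= sum(fg))  # parsimony can only add internal branches
  all_uni <- setNames(rep("uni", ntip), phy$tip.label)
  expect_error(suppressWarnings(branch_site_test(
    simulate_codon_alignment(tr, codon_model("M0", omega = 0.5), 5, seed = 1),
    tr, labels = all_uni)), "non-degenerate")
})
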