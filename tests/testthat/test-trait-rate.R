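# Brownian trait-rate correlation and per-branch omega estimation.

test_that("correlation calls follow the strict 0.975/0.025 cutoffs", {
  out <- classify_correlation(c(0.004, 1.0, 0.5, 0.975, 0.025, NA))
  expect_equal(out$call, c("negative", "positive", "ns", "positive", "negative", NA))
  expect_error(classify_correlation(1.2), "\\[0, 1\\]")
})

test_that("the sampler is deterministic under a fixed seed", {
  tr <- fixed_primate_tree(branch_scale = 20)
  sim <- simulate_characters(tr, matrix(c(1, 0.5, 0.5, 1), 2), seed = 3,
                             characters = "trait1", transforms = c(trait1 = "identity"))
  br <- sim$branch_rates
  br$weight <- br$length / mean(br$length)
  f1 <- fit_brownian_correlation(tr, br, sim$characters, mcmc = quick_mcmc,
                                 log_transform = character(0))
  f2 <- fit_brownian_correlation(tr, br, sim$characters, mcmc = quick_mcmc,
                                 log_transform = character(0))
  expect_identical(f1$r_samples, f2$r_samples)
  expect_identical(f1$pairs, f2$pairs)
})

test_that("posterior correlations are bounded and Sigma samples positive-definite", {
  tr <- fixed_primate_tree(branch_scale = 20)
  sim <- simulate_characters(tr, diag(3), seed = 5,
                             characters = c("trait1", "trait2"),
                             transforms = c(trait1 = "identity", trait2 = "identity"))
  br <- sim$branch_rates; br$weight <- br$length / mean(br$length)
  fit <- fit_brownian_correlation(tr, br, sim$characters, mcmc = quick_mcmc,
                                  log_transform = character(0))
  expect_true(all(abs(fit$r_samples) <= 1))
  dets <- apply(fit$sigma_samples, 1L, function(S) min(eigen(S, symmetric = TRUE,
                                                             only.values = TRUE)$values))
  expect_true(all(dets > 0))
  expect_true(all(fit$pairs$pp >= 0 & fit$pairs$pp <= 1))
})

test_that("on a large star tree the posterior tracks the sample correlation of tip values", {
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:30), collapse = ","), ");"))
  set.seed(9)
  Sig <- matrix(c(1, 0.6, 0.6, 1), 2)
  Z <- matrix(rnorm(60), 30) %*% chol(Sig)
  chars <- tibble::tibble(species = star$tip.label, trait1 = Z[, 2])
  phy <- ape::reorder.phylo(star, "postorder")
  # root state 0: tip-branch midpoints are half the tip values
  br <- tibble::tibble(edge = seq_len(nrow(phy$edge)),
                       log_omega = Z[phy$edge[, 2], 1] / 2, weight = 1000)
  fit <- fit_brownian_correlation(star, br, chars,
                                  mcmc = list(iterations = 3000, burnin = 0.25,
                                              thin = 3, seed = 1),
                                  priors = list(nu0 = 2 + 2),  # no extra shrink
                                  log_transform = character(0))
  expect_lt(abs(fit$pairs$posterior_mean_r[1] - cor(Z[, 1], Z[, 2])), 0.1)
})

test_that("binary mating covariate has the documented sign convention", {
  # construct: multi species (mating_type = 1) have higher log omega
  tr <- fixed_primate_tree(branch_scale = 20)
  lab <- mating_labels(tr)
  phy <- ape::reorder.phylo(tr, "postorder")
  is_multi <- setNames(lab$mating == "multi", lab$species)[phy$tip.label]
  base <- ifelse(is_multi, 1, -1)
  br <- tibble::tibble(
    edge = seq_len(nrow(phy$edge)),
    log_omega = ifelse(phy$edge[, 2] <= 13, base[phy$edge[, 2]], 0),
    weight = 1)
  chars <- tibble::tibble(species = phy$tip.label,
                          mating_type = as.integer(is_multi))
  fit <- fit_brownian_correlation(tr, br, chars, mcmc = quick_mcmc)
  # positive r means higher log omega in multi-male lineages
  expect_gt(fit$pairs$posterior_mean_r[1], 0)
  expect_gt(fit$pairs$pp[1], 0.5)
})

test_that("doubling the chain leaves posterior probabilities stable", {
  tr <- fixed_primate_tree(branch_scale = 20)
  sim <- simulate_characters(tr, matrix(c(1, 0.7, 0.7, 1), 2), seed = 8,
                             characters = "trait1", transforms = c(trait1 = "identity"))
  br <- sim$branch_rates; br$weight <- br$length / mean(br$length)
  f1 <- fit_brownian_correlation(tr, br, sim$characters,
                                 mcmc = list(iterations = 2500, burnin = 0.25,
                                             thin = 3, seed = 2),
                                 log_transform = character(0))
  f2 <- fit_brownian_correlation(tr, br, sim$characters,
                                 mcmc = list(iterations = 5000, burnin = 0.25,
                                             thin = 3, seed = 7),
                                 log_transform = character(0))
  expect_lt(abs(f1$pairs$pp[1] - f2$pairs$pp[1]), 0.03)
})

test_that("missing characters are tolerated and degenerate inputs error", {
  tr <- fixed_primate_tree(branch_scale = 20)
  sim <- simulate_characters(tr, diag(2), seed = 4, characters = "trait1",
                             transforms = c(trait1 = "identity"))
  br <- sim$branch_rates; br$weight <- br$length / mean(br$length)
  chars <- sim$characters
  chars$trait1[1:3] <- NA
  fit <- fit_brownian_correlation(tr, br, chars, mcmc = quick_mcmc,
                                  log_transform = character(0))
  expect_true(is.finite(fit$pairs$pp[1]))
  br_na <- br; br_na$log_omega <- NA_real_
  expect_error(fit_brownian_correlation(tr, br_na, chars, mcmc = quick_mcmc),
               "no usable branch")
  expect_error(fit_brownian_correlation(ape::read.tree(text = "(A:1,B:1);"),
                                        br, chars, mcmc = quick_mcmc),
               "at least 4 tips")
})

test_that("per-branch omega finds the elevated branch and flags saturated inputs", {
  tr <- ape::keep.tip(fixed_primate_tree(branch_scale = 20),
                      c("human", "chimpanzee", "rhesus_macaque", "baboon",
                        "vervet", "marmoset"))
  phy <- ape::reorder.phylo(tr, "postorder")
  ntip <- length(phy$tip.label)
  target_edge <- which(phy$edge[, 2] == which(phy$tip.label == "marmoset"))
  hits <- 0
  for (s in 1:5) {
    # p0, p1 ~ 0 puts essentially all sites in the 2a class: omega0 on the
    # background, omega2 on the single foreground branch
    mdl <- codon_model("branch_site", p0 = 1e-6, p1 = 1e-9, omega0 = 0.15,
                       omega2 = 2.5,
                       foreground = seq_len(nrow(phy$edge)) == target_edge)
    aln <- simulate_codon_alignment(tr, mdl, 300, seed = 40 + s)
    bo <- estimate_branch_omega(aln, tr, sweeps = 1)
    if (which.max(bo$omega) == target_edge) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # identical sequences: all omegas undefined, flagged by warning
  const <- setNames(rep(strrep("ATGAAA", 20), ntip), phy$tip.label)
  expect_warning(bo0 <- estimate_branch_omega(const, tr), "no substitutions")
  expect_true(all(is.na(bo0$omega)))
})

test_that("two-taxon branch omegas agree with the pairwise M0 estimate", {
  tr2 <- ape::read.tree(text = "(A:1.5,B:1.5);")
  aln <- simulate_codon_alignment(tr2, codon_model("M0", omega = 0.5, kappa = 2),
                                  500, seed = 77)
  m0 <- fit_site_model(aln, tr2, "M0", pi = "uniform")
  bo <- estimate_branch_omega(aln, tr2, pi = "uniform", penalty_sd = 10)
  # a two-taxon tree has a single path: both branch omegas estimate the
  # same pairwise quantity
  expect_lt(abs(log(mean(bo$omega, na.rm = TRUE) / m0$params$omega)), 0.25)
})
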