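# Generators: tree, codon alignments, characters, quantification data.

test_that("the reference primate tree has 13 labelled tips with both mating systems", {
  tr <- fixed_primate_tree()
  expect_equal(length(tr$tip.label), 13)
  lab <- mating_labels(tr)
  expect_true(all(lab$mating %in% c("uni", "multi")))
  expect_equal(nrow(lab), 13)
  expect_equal(lab$mating[lab$species == "human"], "uni")
  expect_equal(lab$mating[lab$species == "drill"], "uni")
  expect_equal(lab$mating[lab$species == "chimpanzee"], "multi")
  expect_equal(sum(lab$mating == "uni") + sum(lab$mating == "multi"), 13)
  expect_true(all(tr$edge.length >= 0))
  expect_false(any(duplicated(tr$tip.label)))
})

test_that("zero branch lengths copy the root codons to every tip", {
  tr <- fixed_primate_tree()
  tr$edge.length[] <- 0
  aln <- simulate_codon_alignment(tr, codon_model("M0", omega = 0.5), 20, seed = 1)
  expect_equal(length(unique(unname(aln))), 1L)
})

test_that("simulated site classes match the model mixture weights", {
  tr <- fixed_primate_tree(branch_scale = 10)
  mdl <- codon_model("M8", p0 = 0.9, p = 0.5, q = 1.5, omega_s = 3)
  aln <- simulate_codon_alignment(tr, mdl, 2000, seed = 2)
  cls <- attr(aln, "site_class")
  frac_sel <- mean(cls == 11)   # the omega_s class
  expect_lt(abs(frac_sel - 0.1), 3 * sqrt(0.1 * 0.9 / 2000) + 0.005)
})

test_that("neutral two-taxon simulation gives counting dN/dS near 1", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.15);")
  aln <- simulate_codon_alignment(tr, codon_model("M0", omega = 1, kappa = 2),
                                  8000, seed = 3)
  dnds <- ng_dnds(aln[["A"]], aln[["B"]])
  expect_lt(abs(dnds - 1), 0.1)
})

test_that("alignment simulation is seed-deterministic and respects n_codons", {
  tr <- fixed_primate_tree()
  a1 <- simulate_codon_alignment(tr, codon_model("M0", omega = 0.3), 50, seed = 9)
  a2 <- simulate_codon_alignment(tr, codon_model("M0", omega = 0.3), 50, seed = 9)
  expect_identical(a1, a2)
  expect_equal(unique(nchar(a1)), 150)
  expect_error(simulate_codon_alignment(tr, codon_model("M0", omega = 0.3), 0), "positive")
  expect_error(codon_model("M8", p0 = 0.9), "requires parameter")
})

test_that("zero covariance keeps every tip at the root state; ordinal rating stays in 1..4", {
  tr <- fixed_primate_tree()
  sim <- simulate_characters(tr, covariance = matrix(0, 6, 6),
                             root_state = c(0, 1, 2, 3, 4, 5), seed = 1)
  expect_true(all(abs(sim$latent$log_omega - 0) < 1e-12))
  expect_true(all(sim$branch_rates$log_omega == 0))
  sim2 <- simulate_characters(tr, covariance = diag(6) * 0.5, seed = 2)
  expect_true(all(sim2$characters$semen_coagulation %in% 1:4))
  expect_true(all(sim2$characters$mating_type %in% 0:1))
  expect_true(all(sim2$characters$relative_testis_size > 0))
  bad <- diag(3); bad[1, 3] <- bad[3, 1] <- 2
  expect_error(simulate_characters(tr, bad, seed = 1), "positive-definite")
})

test_that("independent contrasts recover the simulated trait correlation", {
  tr <- fixed_primate_tree(branch_scale = 5)
  phy <- ape::reorder.phylo(tr, "postorder")
  Sig <- matrix(c(1, 0.9, 0.9, 1), 2)
  rs <- vapply(1:150, function(s) {
    sim <- simulate_characters(tr, Sig, seed = s, characters = "trait1",
                               transforms = c(trait1 = "identity"))
    lat <- sim$latent[match(phy$tip.label, sim$latent$species), ]
    pic_correlation(phy, setNames(lat$log_omega, phy$tip.label),
                    setNames(lat$trait1, phy$tip.label))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.05)
})

test_that("Brownian tip covariance follows the shared-path-length structure on a 4-tip tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # closed form: var(tip) = depth = 2; cov(A,B) = shared path = 1; cov(A,C) = 0
  sims <- sapply(1:400, function(s) {
    sim <- simulate_characters(tree, covariance = matrix(1, 1, 1), seed = s,
                               characters = character(0), transforms = character(0))
    setNames(sim$latent$log_omega, sim$latent$species)[c("A", "B", "C")]
  })
  expect_lt(abs(var(sims["A", ]) - 2), 0.35)
  expect_lt(abs(cov(sims["A", ], sims["B", ]) - 1), 0.3)
  expect_lt(abs(cov(sims["A", ], sims["C", ])), 0.3)
})

test_that("quantification rows are keyed uniquely and counts follow the design", {
  des <- quant_design(seed = 4, missing_rate = 0, frac_shared = 1)
  res <- simulate_quant_dataset(des)
  dat <- res$data
  expect_false(any(duplicated(dat[, c("species", "individual", "run", "peptide")])))
  expect_true(all(dat$ria > 0))
  # bookkeeping: rows = (individuals x reps) x (peptides + standards)
  n_ind <- sum(des$species$n_individuals)
  n_pep <- des$n_proteins * des$peptides_per_protein + 10L
  expect_equal(nrow(dat), n_ind * des$tech_reps * n_pep)
  expect_true(all(c("STD_HORSE_MYOGLOBIN", "STD_TRYPSIN") %in% dat$protein))
})

test_that("the noiseless limit gives identical technical replicates", {
  des <- quant_design(seed = 6, technical_cv = 0, run_scale_sd = 0,
                      missing_rate = 0, n_proteins = 5)
  dat <- simulate_quant_dataset(des)$data
  spread <- dat |>
    dplyr::group_by(species, individual, peptide) |>
    dplyr::summarise(d = diff(range(ria)), .groups = "drop")
  expect_lt(max(spread$d), 1e-9)
})

test_that("quant simulation is byte-deterministic and run factors are recoverable", {
  des <- quant_design(seed = 12, missing_rate = 0)
  r1 <- simulate_quant_dataset(des)
  r2 <- simulate_quant_dataset(des)
  expect_identical(r1$data, r2$data)
  # normalization recovers the true run factors up to the global reference
  norm <- normalize_by_standards(r1$data)
  cmp <- dplyr::inner_join(norm$factors, r1$truth$run_factors, by = "run")
  ratio <- cmp$factor.x / cmp$factor.y
  # equal up to one global constant, with small error from technical noise
  expect_lt(sd(log(ratio)), 0.1)
})

test_that("a null mating effect yields near-nominal scan rates on simulated data", {
  des <- quant_design(seed = 31, n_proteins = 120, peptides_per_protein = 4,
                      n_responsive = 0, frac_shared = 1, missing_rate = 0,
                      biological_cv = 0.5)
  res <- simulate_quant_dataset(des)
  norm <- normalize_by_standards(res$data)
  qc <- filter_technical_cv(norm$data)
  labels <- des$species[, c("species", "mating")]
  scan <- mating_system_scan(qc$data, labels, alpha = 0.05)
  rate <- scan$summary$n_significant / scan$summary$n_tested
  expect_gt(scan$summary$n_tested, 400)
  expect_lt(rate, 0.09)
})
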