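# Peptide matching, rank-sum scans, concordance.

test_that("identical-peptide matching separates shared and species-specific peptides", {
  dat <- tibble::tibble(
    species = c("human", "human", "rhesus_macaque", "rhesus_macaque", "vervet"),
    individual = c("h1", "h1", "r1", "r1", "v1"),
    peptide = c("SHAREDPEPK", "HUMANONLYK", "SHAREDPEPK", "ALMOSTSAMEK", "SHAREDPEPK"),
    protein = "P1", mean_ria = c(1, 2, 3, 4, 5), cv = 1, n_reps = 3)
  out <- match_identical_peptides(dat, c("human", "rhesus_macaque", "vervet"))
  expect_equal(unique(out$shared$peptide), "SHAREDPEPK")
  # one-residue difference means no match
  expect_false("ALMOSTSAMEK" %in% out$shared$peptide)
  expect_equal(out$counts$n[out$counts$peptide_class == "single_species"], 2)
  expect_error(match_identical_peptides(dat, c("human", "gibbon")), "absent")
  # disjoint sets: empty shared subset
  dj <- dat[dat$peptide != "SHAREDPEPK", ]
  expect_equal(nrow(match_identical_peptides(dj, c("human", "rhesus_macaque"))$shared), 0)
})

test_that("rank-sum p-values match full enumeration for small samples", {
  # x = (1,2,3) vs y = (4,5,6), alternative less: 1 of C(6,3) = 20 rank
  # assignments is as extreme, so p = 1/20
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, "less")$p_value, 0.05)
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(1000, n + m)   # no ties
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    oracle <- enumerate_wilcoxon(x, y)
    expect_equal(wilcoxon_rank_sum(x, y, "greater")$p_value, oracle$p_greater)
    expect_equal(wilcoxon_rank_sum(x, y, "less")$p_value, oracle$p_less)
    expect_equal(wilcoxon_rank_sum(x, y, "two_sided")$p_value, oracle$p_two)
  }
})

test_that("identical samples give p = 1 and exact/approximate p agree for n = m = 8", {
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    exact <- enumerate_wilcoxon(x, y)$p_two
    approx <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("two-sided p dominates one-sided p and direction follows the medians", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(6); y <- rnorm(6, sample(c(-2, 0, 2), 1))
    two <- wilcoxon_rank_sum(x, y, "two_sided")$p_value
    gr <- wilcoxon_rank_sum(x, y, "greater")$p_value
    ls <- wilcoxon_rank_sum(x, y, "less")$p_value
    expect_gte(two + 1e-12, gr * (gr < 0.5))
    expect_gte(two + 1e-12, min(gr, ls))
  }
})

make_scan_data <- function(n_pep, effect, seed, n_uni = 8, n_multi = 8) {
  set.seed(seed)
  labels <- tibble::tibble(
    species = c("human", "rhesus_macaque"), mating = c("uni", "multi"))
  inds <- tibble::tibble(
    species = rep(labels$species, c(n_uni, n_multi)),
    individual = c(sprintf("h%d", seq_len(n_uni)), sprintf("r%d", seq_len(n_multi))))
  df <- tidyr::expand_grid(inds, peptide = sprintf("PEP%04dK", seq_len(n_pep)))
  df$protein <- sub("PEP", "PR", df$peptide)
  # sdlog 0.4 ~ 42% biological CV of the per-individual peptide means
  # (post technical-replicate averaging)
  df$mean_ria <- exp(rnorm(nrow(df), log(100), 0.4) +
                       ifelse(df$species == "rhesus_macaque", effect, 0))
  list(data = df, labels = labels)
}

test_that("null peptides are flagged at about the nominal 5% rate", {
  sc <- make_scan_data(400, 0, seed = 5)
  out <- mating_system_scan(sc$data, sc$labels, alpha = 0.05)
  rate <- out$summary$n_significant / out$summary$n_tested
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("a 2-fold multi-male shift is detected with high power and the right direction", {
  hits <- 0
  for (s in 1:30) {
    sc <- make_scan_data(1, log(2), seed = 100 + s)
    out <- mating_system_scan(sc$data, sc$labels, alpha = 0.05)
    if (out$results$significant[1] && out$results$direction[1] == "multi_higher") {
      hits <- hits + 1
    }
  }
  expect_gt(hits / 30, 0.8)
})

test_that("alpha = 0 flags nothing and scan is invariant to row order", {
  sc <- make_scan_data(30, log(2), seed = 9)
  none <- mating_system_scan(sc$data, sc$labels, alpha = 0)
  expect_equal(none$summary$n_significant, 0)
  out1 <- mating_system_scan(sc$data, sc$labels)
  set.seed(1)
  out2 <- mating_system_scan(sc$data[sample(nrow(sc$data)), ], sc$labels)
  o1 <- dplyr::arrange(out1$results, peptide)
  o2 <- dplyr::arrange(out2$results, peptide)
  expect_equal(o1$p_two_sided, o2$p_two_sided)
  expect_equal(o1$direction, o2$direction)
})

test_that("species pair scan reports direction relative to the first species and skips singletons", {
  sc <- make_scan_data(5, -log(3), seed = 13)   # human-elevated
  out <- species_pair_scan(sc$data, "human", "rhesus_macaque", alpha = 0.05)
  expect_true(all(out$results$direction[out$results$significant] == "human_higher"))
  # identical tables: nothing significant
  same <- sc$data
  same$mean_ria <- rep(1:16, times = 5)
  out2 <- species_pair_scan(same, "human", "rhesus_macaque")
  expect_equal(out2$summary$n_significant, 0)
  # peptide in one species only is skipped with a reason
  solo <- sc$data[!(sc$data$peptide == "PEP0001K" & sc$data$species == "human"), ]
  out3 <- species_pair_scan(solo, "human", "rhesus_macaque")
  expect_true("PEP0001K" %in% out3$skipped$peptide)
  expect_equal(unique(out3$skipped$reason), "present_in_one_species")
})

test_that("peptide concordance equals the hand-computed squared Pearson correlation", {
  dat <- tibble::tibble(
    species = "s", individual = c("a", "b", "c", "a", "b", "c"),
    peptide = rep(c("P1pep", "P2pep"), each = 3),
    protein = "TGM4", mean_ria = c(1, 2, 3, 2, 4, 7))
  out <- peptide_concordance(dat, log10_scale = FALSE)
  # r = 2.5 / sqrt(1 * 6.3333...) hand-computed
  expect_equal(out$pairs$r_squared, (2.5 / sqrt(19 / 3))^2, tolerance = 1e-12)
  # identical profiles: R^2 = 1; negated log profile: also R^2 = 1
  dat2 <- dat; dat2$mean_ria <- c(1, 2, 3, 1, 2, 3)
  expect_equal(peptide_concordance(dat2, log10_scale = FALSE)$pairs$r_squared, 1)
  dat3 <- dat; dat3$mean_ria <- c(10, 100, 1000, 1000, 100, 10)
  expect_equal(peptide_concordance(dat3)$pairs$r_squared, 1)
  # constant vector: undefined, reported missing
  dat4 <- dat; dat4$mean_ria[4:6] <- 5
  expect_true(is.na(peptide_concordance(dat4)$pairs$r_squared))
})
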