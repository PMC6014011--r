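---
title: "Models and methods behind sfpevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sfpevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfpevol)
```

# What the package models

`sfpevol` studies how mating systems shape seminal fluid proteins (SFPs)
along two molecular axes: **abundance** (label-free peptide quantification
compared between uni-male and multi-male primates) and **sequence evolution**
(dN/dS-based selection tests and a Bayesian correlation between
lineage-specific evolutionary rate and sexual characters). Every input the
pipeline consumes can be generated by the package's own simulators, so the
whole chain is testable end to end without external data.

This vignette records the models, the tunable parameters with their defaults
and rationale, the numerical choices, what the simulators do and do not
emulate, and the known limitations. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

# Proteomic quantification

## Normalization by internal standards

Relative isotope abundances (RIA) are positive, run-scaled quantities: every
mass-spectrometry run multiplies all of its peptide values by an unknown
factor. Two spiked proteins (horse myoglobin and trypsin) are present at a
fixed amount in every run, so their measured level identifies the run scale.
`normalize_by_standards()` computes each run's geometric mean of standard
RIAs (in log space; missing values are treated as missing, never as zero),
a global reference equal to the geometric mean of those per-run means, and
divides every value in a run by `run_mean / reference`. Runs with no
detected standard cannot be normalized and are excluded with a report.

One point deserves care: after normalization, the run-level scale cancels
*exactly* within each run, and every run's standard geometric mean equals
the global reference. The reference itself is data-derived, so rescaling one
run's raw values changes all normalized values by a common factor
`c^(1/R)`; no data-derived reference can avoid this (a function of the
per-run means that is invariant to rescaling any one of them must be
constant). The reference is therefore returned, and the invariance tests
assert bit-level invariance of normalized values *recentre by the reported
reference*, plus the standard-mean identity verbatim.

## Quality control and rollup

The technical-replicate filter follows the standard clinical-proteomics
convention: a peptide is kept within a biological sample only when at least
two technical replicates are present and their coefficient of variation
(n−1 standard deviation over mean, untransformed values) is at most 25%.
Exclusions carry machine-readable reasons. Between-sample variability is
classified as conserved (CV < 25%), high (CV > 75%) or intermediate;
values exactly at a cutoff are intermediate. Protein abundance is the
arithmetic mean of retained peptide means, reported only for proteins with
three or more retained peptides. `nsaf()` implements the normalized spectral
abundance factor, `(SpC/L) / sum(SpC/L)`, which sums to one per sample.

## Comparative scans

Only *identical* peptide sequences are compared across species, because
sequence changes alter ionization and hence the RIA scale — a single
substituted residue excludes a peptide from the comparison.
`mating_system_scan()` pools per-individual peptide means within the
uni-male and multi-male groups and applies a two-sided Wilcoxon rank-sum
test at `alpha = 0.05` (raw p-values by default; a Benjamini–Hochberg
switch exists but is off, mirroring candidate-table semantics); one-sided
tests assign direction. The sampling unit is the individual by default;
`unit = "species_means"` collapses to species first, since pooling
individuals across species is itself a modeling choice. Rank-sum p-values
are exact (full null enumeration) when `n + m <= 16` without ties, else the
midrank normal approximation with continuity correction. Peptide
concordance within a protein is the squared Pearson correlation of log10
abundances across shared samples (raw scale optional); pairs with fewer
than three shared samples or a constant profile are reported missing.

# Codon models of selection

## The substitution process

All sequence-level inference uses the Goldman–Yang codon process on the 61
sense codons of the universal genetic code: single-nucleotide changes occur
at rate proportional to the target codon's frequency, times `kappa` for
transitions, times `omega` for nonsynonymous changes. Codon frequencies are
F3x4 by default (positional nucleotide frequencies, stops removed), uniform
on request. Generators are scaled so branch lengths count expected
substitutions per codon at the mixture-mean rate. Likelihoods come from
Felsenstein pruning over 61-state conditional vectors with per-node
rescaling; gaps and ambiguous codons are missing data. The pruning
implementation is verified in the test suite against exact enumeration over
all internal-node states on small trees.

## Site models and their fitting strategy

The site models are the standard mixtures: M0 (one omega), M1a
(nearly-neutral), M2a (M1a plus a free omega ≥ 1 class), M7 (beta on
[0, 1], discretized into K = 10 equal-probability classes at quantile
midpoints), M8 (beta plus a free omega_s ≥ 1 class) and M8a (M8 with
omega_s = 1). Positive selection is tested by likelihood-ratio tests of the
nested pairs M1a–M2a (2 df), M7–M8 (2 df) and M8a–M8 (1 df), with the
chi-square on the full degrees of freedom — not the 50:50 boundary mixture —
which is deliberately conservative. Across genes, false discovery is
controlled by Storey q-values (`qvalue_fdr()`; pi0 from a smoothed lambda
grid, falling back to pi0 = 1, i.e. Benjamini–Hochberg, when the estimate
is unstable) at q < 0.01.

Two numerical decisions keep desk-scale runtimes without touching the
contrasts that matter:

* **Branch lengths and kappa are estimated once under M0** (joint
  quasi-Newton over kappa, omega, and a global branch scale) **and then held
  fully fixed** for all site models of that gene. A per-model rescale would
  change each lnL slightly but near-identically for the null and alternative
  member of a nested pair, so the LRTs are insensitive to it; fixing the
  scale is what makes the per-site likelihood cache below possible.
* **Mixture classes with omega in [0, 1] are evaluated through a per-site
  log-likelihood table** precomputed on a fixed omega grid (log-spaced below
  0.1, where log-likelihood is near-linear in log omega, dense-linear
  above) **and interpolated with a natural cubic spline**; interpolation
  error is well below 0.1 lnL units on realistic alignments and cancels
  between nested models. The selection class (omega_s ≥ 1) is always
  evaluated exactly by pruning and profiled in an outer one-dimensional
  search. Optimizers run from three jittered starts; each alternative model
  is additionally started at its null's solution, which guarantees
  `lnL(M7) <= lnL(M8a) <= lnL(M8)` by construction.

## The branch-site test

`branch_site_test()` implements branch-site model A: four site classes with
background omega0 ∈ (0, 1) and 1, and a foreground-only class at omega2 ≥ 1
on the designated lineages; the null fixes omega2 = 1, and the LRT uses
chi-square(1) (conservative, as above). Foreground branches default to the
multi-male lineages: a branch is foreground iff all its descendant tips are
multi-male (a Fitch-parsimony reconstruction is selectable, which can add
internal branches when reversals are parsimonious). The swapped-foreground
control (`foreground = "uni"`) is available. The outer optimization is a
Nelder–Mead search over (omega0, omega2) with the class weights profiled in
an inexpensive inner step, seeded from the null fit.

## Per-branch rates

`estimate_branch_omega()` is a free-ratio-lite estimator: kappa and branch
lengths from M0, then coordinate-wise 1-D maximization of each branch's
omega, with a Gaussian ridge on log omega centered at the M0 estimate
(sd 1.5 by default). The ridge is the continuous analogue of a pseudocount:
branches with no inferred synonymous or nonsynonymous events have flat or
boundary-maximized likelihoods, and the ridge returns them toward the gene
average instead of 0 or infinity. Each branch carries an uncertainty weight
proportional to branch length times alignment length — a first-order proxy
for the Fisher information about that branch's rate. Zero-length branches
are reported missing.

# Trait–rate correlation

## Model

The correlation stage is a two-stage, coevol-style analysis. A latent
multivariate Brownian motion runs along the tree; its first coordinate is
log omega and the remaining coordinates are the sexual characters (binary
mating type 0/1 and the ordinal semen-coagulation rating untransformed;
testis size, size dimorphism and partner number log-transformed).
Characters are observed exactly at the tips (missing entries are
marginalized); the per-branch log omega estimates are observed as the
branch-midpoint value of the latent rate coordinate plus Gaussian noise
with variance `sigma2 / weight`. This replaces coevol's joint substitution
mapping with a tractable approximation whose inputs are exactly what
`estimate_branch_omega()` produces. The sign convention for the binary
character: positive correlation means higher log omega in multi-male
lineages.

## Sampler

Three blocked Gibbs updates alternate: (i) the entire latent field —
all node states, all coordinates — is redrawn jointly from its Gaussian full
conditional, whose precision is `kronecker(solve(Sigma), T)` (T the tree's
increment precision plus a diffuse root anchor) plus the observation block
on the rate coordinate; (ii) Sigma from its conjugate inverse-Wishart given
the branch increments; (iii) the noise scale from its conjugate
inverse-gamma (or held fixed via `obs_noise` when the observation variance
is known, as in calibration simulations — estimating it is the default in
the pipeline). The joint latent draw is what gives the chain its mixing:
effective sample sizes are typically a substantial fraction of the kept
draws even on 13-taxon trees.

The Sigma prior is inverse-Wishart with `nu0 = dim + 2 + 1.5` and scale
`(nu0 - dim - 1)` times the empirical diagonal variances (estimated in a
300-iteration pilot). This keeps the prior mean of Sigma diagonal at the
data's own scale: correlations are shrunk toward zero by roughly 1.5
pseudo-contrasts — enough to temper sign overconfidence on 13-taxon trees,
where only 12 independent character contrasts exist, while leaving strong
correlations detectable. `priors` exposes `nu0` and `S0` for sensitivity
analyses. Defaults: 20,000 iterations, 25% burn-in, thinning 10, fixed
seed; identical seeds give identical posteriors.

Marginal correlations `r_ij` are computed from each Sigma sample; the
posterior probability `pp = Pr(r > 0)` is called positive at pp ≥ 0.975,
negative at pp ≤ 0.025, else `ns` — deliberately strict cutoffs to limit
false sign calls.

# Synthetic data: what it emulates, and what it does not

`fixed_primate_tree()` provides a 13-species primate phylogeny (apes,
Old World monkeys, two New World monkeys) with uni/multi mating labels;
branch lengths are plausible defaults in substitutions per site — explicit
configuration, not estimates. Codon-level simulations typically scale them
(`branch_scale` 10–30) so that alignments of a few hundred codons carry
signal comparable to mammalian coding divergence.

`simulate_codon_alignment()` draws root codons from the stationary
frequencies, assigns sites to omega classes by the model's weights, and
evolves codons branch by branch under the class generator (foreground
branches use the foreground omega in branch-site models). Site classes are
returned for power/calibration accounting.

`simulate_characters()` runs the multivariate Brownian motion forward,
returns transformed tip characters, the latent tip states, and the true
branch-midpoint log omega per branch. The binary mating type is a median
split of its latent trait (threshold recorded in the metadata) — this keeps
rate–mating correlations well defined in simulation; the ordinal rating is
a quartile cut.

`simulate_quant_dataset()` emulates the sampling design of the comparative
proteomic experiment: five species with mating labels (human and drill
uni-male; rhesus and cynomolgus macaque and vervet multi-male), eight
individuals for human and rhesus and two elsewhere, three randomized
technical replicates per biological sample, standards spiked at a fixed
amount per run. Biological variation is lognormal at CV 0.70 (within-species
peptide variability in seminal fluid is high), technical noise lognormal at
CV 0.15, run scale factors lognormal with sd(log) 0.5, mating-responsive
proteins shifted by log(2) in multi-male species, and 5% of measurements
missing completely at random. The default fraction of peptides identical
across species is 0.20 — chosen so that cross-species comparisons are
informative at simulation scale; in real seminal-fluid data the shared
fraction is far smaller, which the simulator does not attempt to reproduce.
Also not modeled: spectrum-level physics (m/z, retention time, isotope
envelopes), peptide detectability, informative missingness, and
protein-inference ambiguity. Passing tests therefore validate the
*statistical* pipeline, not MS signal processing.

# Pipeline and integration

`run_full_pipeline()` chains simulate → normalize → QC → match → abundance
scans → site-model scan (M8a vs M8 with q < 0.01) → branch-site test
(p < 0.01, multi-male foreground) → trait–rate correlation → integration.
Every tunable lives once in `pipeline_config()`; stage TSVs are written
with `#` metadata lines and 12-significant-digit floats so reruns are
byte-identical; a failing gene is flagged and skipped, never fatal.
`integrate_evidence()` builds the candidate table: one row per gene with
any qualifying evidence — per-character coevol pp (numeric only beyond the
0.975/0.025 cutoffs, else `ns`), a branch-site `x`/`ns` flag, and an
abundance `x`/`ns` flag (a protein qualifies when at least one of its
peptides is significant); union and per-category counts are reported
because the deduplication rule affects the headline candidate count.

# Verification problem sizes

The acceptance checks (test suite and `scripts/acceptance.R`) use these
sizes, chosen to give stable Monte Carlo estimates at desk scale:
likelihood-oracle comparison on 50 random ≤4-taxon, ≤3-codon draws
(agreement to 1e-10); M0 recovery on 20 alignments of 8 taxa × 500 codons;
M8-vs-M8a null calibration on 60–80 alignments of 13 taxa × 300 codons;
branch-site type-I on 60–80 neutral alignments and power on 20 alignments
with foreground omega2 = 4 at 250–300 codons; Wilcoxon enumeration on 200
random small-sample cases and type-I on 1,000 null peptides; Brownian
correlation calibration on 100 null and 50 correlated (r = 0.9) datasets on
the 13-taxon tree (correlation studies use observation noise sd 0.1 at
weight 1 with the noise variance supplied as known — the quantity the
uncertainty weights are designed to carry); and an end-to-end run with 10
responsive proteins and 5 positively selected genes among 15. The
chain length for calibration studies is 2,500 iterations (burn-in 25%,
thin 3), at which doubling the chain moves posterior probabilities by less
than 0.03.

# Known limitations

* Site models fix branch lengths and kappa at M0 estimates; very long
  branches or extreme compositional bias would warrant joint re-optimization.
* The chi-square LRT reference distributions are conservative at the
  boundary; power figures are correspondingly cautious.
* The trait–rate stage is an approximation to coevol: no time calibration,
  no joint substitution mapping, marginal (not partial) correlations only.
* Per-branch omega estimates on short branches are ridge-dominated; their
  weights encode this, but a branch with near-zero length contributes
  essentially nothing.
* The binary mating covariate is treated as a continuous 0/1 trait under
  Brownian motion, as coevol does; a threshold model would be more faithful
  but is out of scope.
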