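---
title: "Geographically exclusive clades and migration-history inference"
author: "phylogec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographically exclusive clades and migration-history inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
set.seed(1)
```

## The problem

Phylogeographic studies of maternally inherited loci (whole mitogenomes in
the motivating application: samples from Wallacea, New Guinea and Australia)
typically end with a posterior sample of rooted, time-calibrated trees whose
tips carry a sampling region. Three downstream questions then recur:

1. **When did regional matrilines arise?** A *geographically exclusive clade*
   (GEC) — a monophyletic group of at least two samples all drawn from one
   region — represents a regionally endemic matriline, and its TMRCA (time to
   most recent common ancestor, in years before present) is a minimum bound
   on occupancy of that region. Clusters of GEC TMRCAs point to concentrated
   migration or expansion episodes.
2. **Which migration regimes are compatible with the tree?** Treating the
   region as a discrete character evolving along the tree under a
   continuous-time Markov generator \(Q\) (rows sum to zero, off-diagonal
   entries are migration rates per lineage per year), constrained versions of
   \(Q\) encode hypotheses (migration prohibited between a pair, rates tied,
   etc.) that can be compared by Bayes factors between marginal likelihoods.
3. **When did the migration events happen?** Stochastic character mapping
   simulates full transition histories conditional on the tip regions, and
   the transition times can be aggregated through time — after correcting for
   the fact that a constant-rate process accumulates more events where the
   tree has more branch length.

`phylogec` implements this pipeline end to end, together with a
synthetic-data generator so that every stage can be validated against known
truth. This vignette records the models, the tunable parameters, the
numerical choices, and what the validation does and does not demonstrate.

## GEC extraction

For each posterior tree, every internal node whose descendant tips share one
region is an exclusive clade; the *largest* such clade containing each
sample is kept (nested pure clades are absorbed, and samples in no pure
clade of two or more tips are discarded). Candidates from all trees are
pooled by their tip-label set — the only tree-independent notion of clade
identity — and a candidate is retained when it is monophyletic in strictly
more than `support_threshold` (default 0.5) of the posterior trees. Its
TMRCA samples are the MRCA ages in exactly the trees where it is
monophyletic, so the sample count divided by the number of trees equals its
support by construction.

Two details are worth making explicit:

* **Occurrence = monophyly.** A tree "contains" a clade when the exact tip
  set is monophyletic there, whether or not it is also maximal in that tree.
  Maximality is applied once, at candidate generation.
* **Disjointness is enforced, not assumed.** At a strict-majority threshold
  two *properly overlapping* clades can never both qualify (they cannot both
  be monophyletic in the same tree, so their supports sum to at most one),
  but a clade and one of its nested sub-clades can. Retained clades are
  therefore made pairwise tip-disjoint deterministically: higher support
  wins, ties broken by larger size, then older median TMRCA, then
  lexicographic tip set. A practical consequence, visible in the tests: when
  topology noise occasionally pulls one tip out of a true clade, a
  better-supported sub-clade may legitimately displace the full clade.

## Equal-mass TMRCA densities

Clades appear in different numbers of posterior trees, so pooling raw TMRCA
samples would weight well-supported clades more heavily. Instead each clade
gets its own Gaussian kernel density estimate, normalised to unit mass, and
the regional aggregate is the unweighted mean of the per-clade curves: every
clade contributes mass \(1/n_\text{clades}\). Percentiles are read off the
aggregate CDF by linear interpolation.

Numerical choices: the bandwidth is Silverman's rule of thumb
\(0.9\,\min(\mathrm{SD}, \mathrm{IQR}/1.34)\,n^{-1/5}\) (`stats::bw.nrd0`,
the default rule of R's `density()`); clades with fewer than three samples
or zero spread fall back to a floor bandwidth of 100 years to avoid
zero-bandwidth singularities; the shared grid has 512 points from 0 to 1.1
times the oldest sample; each curve is truncated at age 0 and renormalised,
since ages cannot be negative. Normalisation is per clade curve rather than
global — the only reading under which every clade contributes equally.

The clade-size/TMRCA relationship (larger clades are older, almost by
construction) is summarised by per-region linear and quadratic OLS fits
(`size_age_regression`), which lets users check whether regional TMRCA
differences survive conditioning on clade size.

## Migration models

The state space defaults to AUS, PAP, WLC (Australia, New Guinea, Wallacea).
A model is a constraint pattern over the six ordered pairs — `free`, `zero`,
or `tie:<group>` — so the parameter count is the number of free pairs plus
the number of tie groups. Five presets ship: the saturated model (`all`, 6
parameters), the equal-rates null (1), and three intermediates discussed in
the motivating analysis: `m4` (only WLC→AUS, WLC→PAP, PAP→WLC allowed; 3),
`m9` (as m4 with the two New Guinea–Wallacea rates tied; 2), and `m12`
(bidirectional AUS↔PAP and PAP↔WLC, no direct Wallacea–Australia exchange;
4). Any other pattern can be built with `build_model()`.

The likelihood is Felsenstein pruning with per-branch transition matrices
\(e^{Qt}\); the 3×3 exponentials come from a single spectral decomposition
of \(Q\) per likelihood evaluation (with a scaling-and-squaring fallback for
near-defective generators), implemented in C++. The root is handled by a
prior: uniform (`equal`), the normalised root conditional likelihoods
(`empirical`), a point mass (`fixed:WLC`), or an explicit vector.

**Priors.** The rates get independent exponential priors with mean
\(1/\text{root age}\) — proper (required for stepping-stone sampling) and
scale-aware: one expected transition per root-to-tip path is the natural
unit. The prior is configurable; a point-mass prior is supported as a
degenerate test hook under which the marginal likelihood collapses to a
plain likelihood.

**Sampling.** `fit_mcmc` is an adaptive random-walk Metropolis on log rates
(Robbins–Monro adaptation toward 0.44 acceptance, frozen after burn-in).
Non-convergence (minimum effective sample size below a threshold) is a
warning, not an error. `stepping_stone` estimates the log marginal
likelihood along the power-posterior path with temperatures at quantiles of
Beta(0.4, 1) — the standard schedule that concentrates stones near the
prior, where the integrand changes fastest. The prior stone is sampled
exactly; each subsequent stone continues the previous chain. The reported
Monte-Carlo standard error sums per-stone delta-method variances with an
autocorrelation (effective-sample-size) adjustment. Bayes factors are
reported as \(2(\log_{10} L_j - \log_{10} L_k)\) with the conventional
bands: ≤ 2 weak, 2–5 strong, ≥ 5 very strong.

The defaults mirror production-scale settings (10,000 iterations; 250
stones × 10,000 iterations); the examples and tests scale these down — and
state the sizes they use — because the estimators' correctness, not their
production tuning, is what the test suite establishes.

Model fitting defaults to a single (consensus) tree. Averaging the
log-likelihood over a posterior tree subsample is a caller-level loop left
to the user, since the right summary (mean likelihood vs per-tree fits)
depends on the question.

## Stochastic mapping and the branch-length correction

`simulate_mappings` draws joint node states from their exact conditional
distribution (root from prior × root partials, then each child given its
parent), and fills in each branch's path conditioned on its endpoints by
**uniformization**: the number of dominated jumps is drawn from its exact
conditional distribution, the jump chain is filled in backward using cached
powers of \(R = I + Q/\Omega\), virtual jumps are dropped, and jump times
are uniform order statistics. This is exact for small state spaces; a
rejection sampler (simulate forward, keep paths matching the endpoints)
serves as the independent oracle in the tests, never as the implementation.
A cheap pre-screen skips the path sampler on the many branches with equal
endpoints and no dominated jumps, with the jump-count distribution
conditioned accordingly so the shortcut is distribution-preserving.

Because a constant-rate process generates more events where the tree has
more total branch length (toward the present), raw transition-time
histograms are corrected: the tree is cut into successive intervals
(default 1000 years) from the tips to the root; each interval's *expected*
count redistributes the pair's total in proportion to the branch length the
interval contains; *corrected = observed − expected*, which sums to zero
over intervals by construction. Events on an interval boundary belong to
the older interval. A finer reporting histogram (default 500-year bins) is
produced alongside; the correction interval and the reporting bin are
deliberately independent parameters.

Three root parameterisations mirror common practice: the fitted model's
empirical root, a uniform root, and a fixed root state.

One subtlety of the correction deserves emphasis. Even when the data truly
evolved at a constant rate, the *per-pair* corrected series conditional on a
given tip configuration is not centred at zero: observing a WLC tip
concentrates WLC occupancy — and therefore WLC→X transition flux — near the
present, and the expected-count baseline knows nothing about occupancy. The
constant-rate null is exact only for the transition counts *pooled over
ordered pairs* (for a symmetric generator every uniformized jump is real
and its time is a uniform order statistic), or for per-pair counts averaged
over independent datasets. The validation suite checks the pooled form;
users interpreting per-pair corrected curves should read them as
occupancy-weighted signals, strongest where the corresponding source region
was plausibly occupied.

## The synthetic-data generator

The generator provides what validation needs: a dated tree (`simulate_tree`:
coalescent via `ape::rcoal` scaled by \(N_e \times\) generation time, or
birth–death via `ape::rphylo` with per-year rates), a region history evolved
forward under a known \(Q\) with every transition recorded
(`evolve_trait`), and an emulated posterior (`emulate_posterior`):
mean-one lognormal branch-length jitter, re-dating that keeps tips at their
ages (internal ages are the mean over children of child age + jittered
length, clamped above the children), and an occasional rooted
nearest-neighbour interchange. Jitter + NNI gives controllable support
levels at desk scale; it mimics the *shape* of posterior uncertainty, not
its calibration — real posteriors have correlated node ages, clock-model
structure, and sequence-driven topology support, so passing tests here
demonstrate algorithmic correctness, not field performance on real data.

Default conditions are desk-scale analogues of a realistic human-mitogenome
study: coalescent trees with \(N_e = 1000\) matrilines and a 28-year
generation interval (root ages of a few tens of thousands of years),
mean-one jitter with σ = 0.05, and a 10% NNI probability.

**Study conditions for the parameter-recovery experiment** (the model-9
recovery test and the acceptance script): 500-tip Yule trees with birth rate
1.5 × 10⁻⁴ per lineage-year (root age ≈ 40 ka), and a model-9 truth with
tied PAP↔WLC rate 8 × 10⁻⁵ and WLC→AUS rate 1.5 × 10⁻⁵ per year, root
Wallacea. These were fixed by a power analysis before the experiment:
coalescent trees are unusable here because their total-length-to-depth
ratio (≈ \(H_{n-1}\) ≈ 6.8) caps the expected number of WLC→AUS founding
transitions near three regardless of the rate, whereas a Yule tree's
exponential lineage growth yields ≈ 19 WLC→AUS and ≈ 200 tied transitions
on average — enough for factor-of-two recovery of both parameters — while
keeping regional tip counts (~120/195/185) in the realistic, unbalanced
regime. Recovery is assessed at reduced sampler sizes (1500 MCMC sweeps;
8 stones × 150 iterations), stated here as the package's chosen experiment
scale.

## Worked example

```{r example}
library(phylogec)
states <- c("AUS", "PAP", "WLC")
Q <- matrix(2e-5, 3, 3, dimnames = list(states, states))
diag(Q) <- -4e-5

ds <- synthetic_dataset(n_tips = 40, Q = Q, root_state = "WLC",
                        n_trees = 80, jitter_sd = 0.05, nni_prob = 0.1,
                        Ne = 1000, gen_time = 28, seed = 7)
ds

gecs <- extract_gecs(ds$trees, ds$regions)
gecs$clades[, c("clade_id", "region", "size", "support", "median_tmrca")]

d <- aggregate_density(gecs, "PAP")
tmrca_percentile(d, c(0.5, 0.9))
plot(d)
plot(gecs)
```

```{r models}
mcc <- mcc_consensus(ds$trees)
fit <- fit_mcmc(mcc, ds$regions, migration_model("null"),
                n_iter = 2000, burnin = 500, thin = 5, seed = 11)
fit

ss_null <- stepping_stone(mcc, ds$regions, migration_model("null"),
                          stones = 16, iter_per_stone = 400, seed = 12)
ss_m9 <- stepping_stone(mcc, ds$regions, migration_model("m9"),
                        stones = 16, iter_per_stone = 400, seed = 13)
bayes_factor(ss_null, ss_m9, c("null", "m9"))
```

```{r simmap}
maps <- simulate_mappings(mcc, ds$regions, fit$Q_median,
                          root_prior = "empirical", n = 500, seed = 14)
cr <- corrected_rates(maps, interval = 1000, reporting_bin = 500)
cr
plot(cr)
```

## Known limitations

* Clade identity across trees is tip-set equality; clades that differ by a
  single unstable tip are distinct candidates, and the disjointness rule
  arbitrates between them.
* The likelihood machinery targets small state spaces (the spectral
  per-branch exponentials and uniformization caches are tuned for 3–5
  states); it is generic in \(k\) but not optimised for large \(k\).
* No rate heterogeneity across branches or through time in the migration
  model — the correction stage exists precisely to diagnose departures from
  the constant-rate assumption rather than to model them.
* The MCC implementation searches the sampled topologies only (as
  TreeAnnotator does); with severe topology noise the true topology may not
  be in the sample.
* `emulate_posterior` is a noise model, not an inference engine; statements
  about posterior calibration on real data are out of its reach.
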