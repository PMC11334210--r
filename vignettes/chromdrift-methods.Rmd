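---
title: "Models and methods in chromdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chromdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chromdrift` asks whether lineages in one state of a binary character —
canonically small versus large geographic range, standing in for small
versus large effective population size — gain and lose chromosomes faster
than lineages in the other state. This vignette documents the model, the
estimation machinery, the choices that were genuinely open, and what the
package's synthetic checks do and do not establish.

## The model

The evolving unit is the pair (n, h): the haploid chromosome number
`n` and the binary hyperstate `h ∈ {S, L}` (small, large). On the
combined state space — counts `k_min..k_max` crossed with the two
hyperstates, ordered count-major — the instantaneous rate matrix allows:

* fusion `(k, h) → (k − 1, h)` at rate δ_h,
* fission `(k, h) → (k + 1, h)` at rate γ_h,
* polyploidy `(k, h) → (2k, h)` at rate ρ_h (default 0: no evidence of
  whole-genome duplication in mammals),
* hyperstate flips `(k, S) ↔ (k, L)` at rates q_SL, q_LS.

Moves that would leave the space get rate 0; diagonals make rows sum to
zero. Six free parameters remain: δ_S, δ_L, γ_S, γ_L, q_SL, q_LS.

The data are one observed (count, hyperstate) pair per extant species;
each tip's conditional likelihood puts probability one on that pair.
`tree_log_likelihood()` runs Felsenstein's pruning algorithm over the
combined space with per-node rescaling against underflow. Polytomies are
handled naturally (the per-edge formulation never assumes a binary tree).

**State-space bounds.** Observed counts padded by one on each side
(`default_state_space`), so boundary species can move both ways without
inflating the matrix; wider bounds are one argument away. The likelihood
refuses tip counts outside the space rather than silently truncating.

**Root treatment.** Two options: `obs_weighted` (FitzJohn-style; root
states weighted by their own conditional likelihoods) and `flat`
(uniform). The default is `obs_weighted`, matching the default behavior
of the comparative-methods software family this model descends from. The
marginal ancestral reconstruction uses the same root prior, so ancestral
states and the likelihood are mutually consistent.

**Matrix exponential.** `transition_probabilities()` uses a dense Padé
`expm`. Inside the pruning kernel, where one tree evaluation needs
P(t) for every distinct branch length, Q is eigendecomposed once and
P(t) = V e^{Dt} V⁻¹ assembled per length in O(S²); the decomposition is
guarded by a reciprocal-condition-number check and a row-sum check, with
a per-branch Padé fallback. A test pins the two routes to each other at
1e−8, and exhaustive state-enumeration oracles pin both to first
principles on small trees.

## Estimation

Trees are rescaled to unit root-to-tip height before fitting
(`scale_to_unit_height`), so rates are per total tree depth; after
fitting, `back_transform()` divides each rate by the tree's original height
in MY to give rates per million years. Height scaling (rather than
total-branch-length scaling) is used because per-MY back-transformation
is exact under it; the scaling happens in one exported function, so the
alternative convention is a one-line change for anyone who needs it.

Priors are independent exponentials on the six free rates, default rate
2 (mean 0.5 per unit height — of order one event per tree depth, a
biologically plausible magnitude). The phrase "shape parameter" for a
one-parameter exponential is ambiguous; rate is the canonical reading,
and `prior_spec(mean = )` offers the other parameterization.

`sample_posterior()` is a univariate slice sampler (step-out and
shrinkage, width `w = 1` by default) sweeping the six rates once per
generation on `[0, ∞)`. Slice sampling needs no tuned proposal scale,
which matters because the protocol this package mirrors tuned its
sampler in unreported preliminary runs. Chains start from uniform(0, 10)
draws, re-drawn up to 20 times if the posterior is non-finite.

`fit_tree_set()` mirrors the replication protocol: per tree, several
replicate chains from different derived seeds (master seed + fixed
multipliers, documented in `derive_seed`); the chain with the highest
final-generation log posterior is kept — a guard against chains stuck on
local likelihood plateaus — then burnin is dropped and samples pooled
across trees, propagating phylogenetic uncertainty into the posterior.
The replication-mode defaults (500 generations, 6 replicates, 450
burnin) are short by general MCMC standards; they are defaults, not
recommendations, and the functions warn nowhere against longer runs.

## ΔR and its interpretation

For each pooled posterior sample, ΔR_δ = δ_S − δ_L (fusion) and
ΔR_γ = γ_S − γ_L (fission), reported as the posterior mean plus a 95%
highest-posterior-density interval (shortest window over sorted samples
containing ⌈0.95 n⌉ of them — deterministic, matches the common
empirical-HPD estimator, and is brute-force-checked in the tests). An
interval entirely above zero is read as elevated rates in small-range
lineages; entirely below zero, the reverse; otherwise indeterminate.
ΔR_q = q_SL − q_LS is computed as a diagnostic only.

## Tip rates

`get_tip_rates()` reconstructs marginal ancestral states under the
pooled posterior-mean rate matrix on the unit-height tree, marginalizes
each tip's immediate ancestor over the hyperstate, takes the most
probable count (ties broken toward the lower count and flagged), and
reports |tip count − ancestral count| / branch length in MY. The
absolute difference is used: the metric is a speed, not a direction.
Zero-length terminal branches with a reconstructed change yield `NA`
with a warning rather than an infinite rate.

## The branch rate-bin scan

The scan asks where in the tree the fitted clade-wide matrix under- or
over-predicts change. Every branch gets one of 21 multiplicative
scalars, equally spaced on [0.5, 2]. That grid — kept as stated — does
not contain 1.0 (spacing 0.075), so the root's "rate category of one" is
resolved as the bin nearest 1.0 (scalar 1.025); any odd grid containing
1.0 exactly can be supplied instead. Branches are visited in preorder;
each may take its parent branch's bin or the two adjacent bins
(autocorrelation; limits overfitting), scored by the full-tree
log-likelihood with all other branches at their current assignment
(unvisited branches start at the root bin), under the fixed
posterior-mean matrix. Ties keep the parent's bin. Clade summaries pool
the branches of each family's MRCA subtree (families with ≥ 5 sampled
species), reporting proportions of elevated (scalar > 1) and depressed
(scalar < 1) branches and the mean scalar, averaged across the tree set.

Two behaviors of this greedy, single-character procedure deserve
emphasis. First, a branch along which no change is reconstructed almost
always gains likelihood from being shortened, so no-change branches
drift toward low scalars; most branches of a typical dataset end up
"depressed" and the informative signal is the *contrast* between clades,
not the absolute scalar level. Second, the one-pass greedy is a
coordinate-ascent heuristic, not a global optimizer: on 4-tip trees with
a 2-point grid, where the constrained configuration space can be
enumerated, it attains the exhaustive optimum in most but not all
simulated datasets (the acceptance script reports the agreement
fraction), and a planted twofold rate elevation in one clade shifts that
clade's mean scalar by much less than the between-replicate spread of
the contrast, because the ±1 parental constraint makes whole subtrees
shift bins together.
The scan is a heterogeneity *diagnostic* — good at flagging where signal
concentrates, not a calibrated branch-rate estimator; single planted
clades are detected only a little better than chance at desk scale.

## Range sizes

`estimate_range()` takes the convex hull of a species' deduplicated
occurrence points (longitudes unwrapped when the raw spread exceeds
180°) and returns the spherical polygon area on a sphere of radius
6371.0088 km, in km²; fewer than three distinct non-collinear points
give area 0. Convex hulls overestimate fragmented ranges and are
sensitive to outlying records — acceptable here because downstream
analysis only uses the small/large split at the dataset median
(`discretize_by_median`, area ≥ median ⇒ large). Coordinates out of
bounds are dropped with a count, not an error: occurrence exports are
dirty by nature.

## Synthetic data and what the checks mean

`simulate_chromosomes()` is an exact Gillespie simulation of the joint
(count, hyperstate) chain along each branch, using the same move set as
the rate matrix: counts floored at 1, *no upper cap* (the fitted model's
k_max is an inference approximation, not a biological truth), polyploidy
available but default 0. Defaults emulate the Carnivora-like study
system: ~110 tips, root count 19, hyperstate 50/50 at the root and
flipping at rate 2 on unit-height trees, fusion/fission 1.5 per unit
height in small-range lineages versus 0.25 in large — a strong,
detectable state effect. Every event is logged, and a replay check
confirms tips equal the log's end states. Consistency between simulator
and likelihood is tested where it bites: tip-state frequencies on a
two-tip star tree against rows of exp(Qt) by chi-squared.

The null/false-positive machinery holds counts fixed, simulates neutral
binary traits (symmetric rate 2, uniform root), refits, and reports how
often the ΔR interval excludes zero and how often |mean ΔR| reaches a
reference effect size. The adequacy check compares the sample variance
(n − 1 denominator) of observed counts against simulated datasets.

What passing these checks shows: the likelihood is exact, the sampler
targets the stated posterior, a strong simulated state effect is
recovered in direction, and a state-*independent* world produces ΔR
centered on zero. What they do not show: real posterior tree sets are
not birth–death trees (branch-length error, topological uncertainty
beyond resampling); real karyotype change is not a homogeneous ±1 chain
(rearrangement hotspots, chromosome-arm structure); and the binary range
proxy discards most of the abundance information relevant to effective
population size. The adequacy check exists precisely because the fitted
process can fail to reproduce the empirical count variance even when
rates are estimated cleanly.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately desk-scale problem sizes,
chosen as the smallest sizes at which each property is expected to be
decidable: exhaustive likelihood oracles on trees of ≤ 4 tips and
spaces of ≤ 8 states; simulator–likelihood consistency at 10,000 draws;
parameter recovery on 20 datasets of 150-tip unit-height trees at 250
generations (2 replicates, 150 burnin) — the replication protocol's
shape at half its generation count; null calibration on 50 datasets of
60-tip trees at 60 generations; prior recovery on 5,000 slice-sampling
generations against exponential quantiles by Kolmogorov–Smirnov. The
ultrametricity tolerance is 1e−6 relative; HPD needs ≥ 10 samples;
likelihood row-sum guards sit at 1e−8/1e−9; ties (ancestral counts, bin
choices) break deterministically as documented above, so every result
is bit-reproducible from the master seed.

## Known limitations

* The rate-bin scan's absolute scalars are biased low for no-change
  branches and its greedy search is not globally optimal (above).
* Short replication-mode chains can leave the uniform(0, 10)
  initialization's imprint on rate magnitudes; orderings and ΔR signs
  stabilize much earlier than magnitudes.
* The ΔR false-positive rate under heterogeneous-but-state-independent
  data is substantial (the package reproduces this known property of
  state-dependent models rather than fixing it); conclusions should lean
  on effect magnitudes and the neutral-trait calibration, not interval
  exclusion alone.
* Convex hulls are a coarse range estimator; only the median split is
  consumed downstream.
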