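---
title: "Models and methods for biogeochemical niche evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for biogeochemical niche evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A species' *biogeochemical niche* is its characteristic multi-element leaf
composition — here the concentrations of C, N, P, K, Ca and Mg (mg g⁻¹ dry
mass). Communities of co-occurring plants show two kinds of structure in this
six-dimensional space: differences between life forms (ferns, herbs,
evergreen and deciduous woody species), and phylogenetic conservatism —
related species resembling each other more than chance. `bgcniche` implements
the comparative toolkit needed to characterize both: phylogenetic-signal
testing, competing trait-evolution models, optimum-shift detection,
phylogenetically corrected trait–trait regression, and non-phylogenetic
descriptives, together with simulators that make every stage verifiable
against known ground truth.

All analyses operate on log10 concentrations on a rooted ultrametric tree
rescaled to unit depth (`rescale_depth`), so rates and selection strengths
are expressed per unit of total tree height and are comparable across trees.

# Models

All fitted models are Gaussian on the tips: `x ~ MVN(mean, sigma2 * V)`.
The mean is always profiled by generalized least squares and `sigma2`
analytically, so each fit reduces to a one-dimensional search over the single
shape parameter of its covariance (or nothing at all for BM):

* **BM** (drift): `V = C`, the shared-ancestry matrix (`phylo_vcv`); the mean
  is the root state. Closed form, k = 2.
* **BMM** (two rates): `V = sigma2_H * C_H + sigma2_W * C_W`, where `C_r`
  accumulates only branch segments painted in regime *r*. Regimes come from
  Fitch-parsimony painting of tip life forms (`paint_regimes`); an edge takes
  its child node's state, so pendant edges always match the observed tip
  state — the property the group-specific models need. k = 3.
* **Pagel's δ** (tempo): on a unit-depth tree the node-depth power transform
  is an elementwise power of C. δ > 1 means change concentrated toward the
  present ("niche shifting"), δ < 1 an early burst. k = 3.
* **OU1** (stabilizing selection): pull of strength α toward an optimum θ,
  root fixed at the optimum; `V(i,j) = sigma2/(2α) e^{-α d_ij}(1 - e^{-2α s_ij})`
  with `s` the MRCA depth and `d` the patristic distance. k = 3.
* **OUM** (regime-specific optima, Hansen model): same covariance, mean
  `W(α) θ` where the weight a lineage segment in regime *r* contributes is
  the integral of the OU kernel over that segment
  (`oum_design_weights`); rows of `W` sum to one, so OU1 is nested in OUM at
  any α. k = 4.

Fits are compared by AICc, with ΔAICc < 2 treated as approximate model
equivalence and the lowest AICc best. Nesting inequalities
(`lnL(BMM) ≥ lnL(BM)`, `lnL(OUM) ≥ lnL(OU1)`, `lnL(δ̂) ≥ lnL(δ=1)`) are
guaranteed numerically by always evaluating the nested parameter value as an
optimizer candidate.

## Phylogenetic signal

`blomberg_k` implements the variance-ratio statistic: the observed
mean-squared error of the data about the phylogenetically corrected mean,
divided by the GLS mean-squared error, scaled by its Brownian-motion
expectation. K = 1 under BM; K near 0 when trait similarity ignores the
phylogeny. The null of "trait values randomly distributed over the tree" is
tested by permuting values across tips (`k_permutation_test`), with the
add-one estimator `p = (1 + #{K_perm ≥ K_obs})/(n_perm + 1)`; ties count as
extreme and p is never exactly zero. The default 999 permutations bound p
below at 0.001.

## Optimum shifts

`search_shifts` detects changes of the OU optimum along branches under a
single α and σ². A shift on edge *e* takes effect at the *parent* end of the
edge (the whole edge evolves toward the new optimum) and adds a design column
`1 - e^{-α(T - t_e)}` for tips descending through *e*. The search is greedy
forward: at each step the single best edge by likelihood is proposed (α
re-optimized), and accepted only if the criterion

```
crit(m) = -2 lnL + (3 + m) ln(n) + m * (2 ln(E) + per_shift_penalty)
```

improves, where `E` is the number of candidate edges. The `2 ln E` term is a
placement-cost surrogate for the singular/partial-BIC penalties used in the
shift-detection literature: the exact singular-BIC involves determinant terms
of the local information matrix that we deliberately do not reproduce; our
criterion has the same structure (a per-shift parameter cost plus a per-shift
placement cost) and is an explicit, documented knob (`per_shift_penalty`,
with `Inf` disabling shifts). Shifts on pendant edges are flagged
`tip_specific`, since a single-species optimum is indistinguishable from an
outlier accommodation. Backward elimination is not performed.

## PGLS

`fit_pgls` estimates trait–trait regressions with residual covariance
`sigma2 * lambda_transform(C, λ)`, λ by bounded ML on [0, 1] with the
endpoints included (boundary estimates are reported as such, not nudged
inward). At λ = 0 the fit is exactly OLS, at λ = 1 exactly BM-GLS; both
identities are tested. Coefficients are tested on n − p degrees of freedom.
`pairwise_element_pgls` builds the lower-triangular element-interaction
matrix (row regressed on column) on log10 concentrations, with no
multiplicity correction by default (a `holm` switch is available).

# Key numerical choices

* **Solvers.** All quadratic forms go through Cholesky factorizations;
  explicit inverses are avoided except in the vectorized permutation engine,
  where a precomputed `C^{-1}` turns 999 permutations into one matrix
  product. Covariance matrices with condition estimates above 1e12 are
  refused.
* **Optimizers.** 1-D bounded searches (Brent) over the log of α, δ, or the
  BMM rate ratio, with log-spaced restarts (3 by default) plus the bound and
  nested-value candidates. The δ upper bound defaults to 500 — far above
  common library defaults, because strongly tipward evolution genuinely
  produces δ in the hundreds. Estimates landing at a bound set a `boundary`
  flag rather than erroring.
* **Root treatment for OU.** The root state is fixed *at* the (root-regime)
  optimum — the simplest identifiable choice on ultrametric trees; a
  stationary-root variant would add `e^{-2αT}`-scale terms to the covariance
  and is intentionally not the default, since different published
  implementations disagree here.
* **δ significance.** Tested by a likelihood-ratio test against BM (χ², 1
  df) — a methodological substitution for regression-package-based tests of
  δ = 1, chosen because the LRT is exact within this likelihood framework.
* **Ultrametricity** is checked with relative tolerance 1e-6 on tip depths;
  OU machinery refuses non-ultrametric trees. Grafting artifacts of length 0
  are nudged to 1e-9 to keep covariances non-singular.
* **Ties.** Model-comparison ties go to fewer parameters, then declaration
  order. Fitch root ambiguity resolves to the majority tip state, ties
  lexicographic.

# The synthetic world

`simulate_tree` draws crown-conditioned pure-birth (Yule) trees, rescaled to
unit depth; `simulate_regimes` produces either a clean two-block clade
regime or a 2-state Markov character; `simulate_trait` draws exact
multivariate-normal samples from the mean and covariance each model implies
(no Euler stepping), so simulator and fitter agree by construction up to
Monte Carlo error, and an independent path-enumeration oracle in the test
suite guards against shared mistakes.

`make_study_fixture` emulates a 102-species subtropical forest community:
life-form blocks of 19 ferns, 16 herbs, 43 evergreen and 24 deciduous woody
species assigned contiguously in tip order (so life forms are
phylogenetically clustered); log10-scale group means fixed at the community's
reported life-form means (e.g. woody C 420, herbaceous K 16.8 mg g⁻¹);
within-group dispersions back-computed from the reported group standard
errors; and a residual correlation structure with a strong positive N–P–K
block, Ca–Mg at 0.95, negative C–N/P/K correlations, and C–Ca/C–Mg set to
zero (C varies so little that even small correlations would generate visible
slopes on the C column, which the reported interaction matrix does not
show). Residuals mix a BM component (weight 0.35) with independent noise,
giving the weak-but-real signal regime (K roughly 0.1–0.3) typical of leaf
stoichiometry.

What the fixture does *not* emulate: measurement error and within-species
replicate structure; polytomies and calibration uncertainty of real
supertrees; non-Gaussian tails; any systematic environment covariate. A green
test on the fixture therefore establishes that the machinery recovers the
stated structure from data that *obey the model assumptions* — not that the
original field data do.

# What the acceptance checks establish

There are no replication targets against the published per-element numbers:
those depend on the study's supplementary species table and on random
grafting into an external mega-tree, neither of which ships with the text.
Acceptance is property-based: likelihoods agree with brute-force
multivariate-normal evaluation on small trees (< 1e-6); Blomberg's K is
exactly 1 on star trees, averages 1 under BM, and its permutation test is
calibrated at the 5% level; simulated rates, optima and δ are recovered at
stated tolerances; shift detection keeps false positives ≤ 10% and recovers
a 4-SD shift ≥ 80% of the time; PGLS covers a true slope at nominal rate and
produces uniform null p-values; and the transform identities hold exactly.
`scripts/acceptance.R` recomputes all of these from scratch.

# Known limitations

* BMM rate matrices are built per regime pair; only two regimes are
  supported, matching the herbaceous/woody contrast.
* The shift criterion is a documented surrogate, not the exact singular BIC;
  absolute criterion values are not comparable across implementations, only
  the selected configurations.
* OUM standard errors for the optima are not reported (the study's tables
  report point optima only); use the simulators for uncertainty assessment.
* Fitch painting of polytomies uses the intersection/union rule, which can
  overcount changes on polytomies; the parsimony-score guarantee is tested
  on binary trees.
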