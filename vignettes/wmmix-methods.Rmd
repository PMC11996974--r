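---
title: "Models, priors, and numerical choices in wmmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, priors, and numerical choices in wmmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmmix)
```

This vignette documents the statistical models implemented in `wmmix`,
the default choices a user may want to change, what the synthetic-data
generator does and does not emulate, and the numerical decisions that
shape the results. It states no empirical claim that the package's test
suite does not itself compute.

## The measurement models

In a continuous-reproduction task the response error `x` is an angle in
`(−π, π]`. All three model families treat the observed error
distribution as a finite mixture:

* a **target** component, `vM(x; 0, κ)` — a von Mises centred at the
  target (location 0 because the data are errors);
* `n − 1` **non-target** components `vM(x; μ_j, κ)` at the lure
  locations `μ_j` (relative to the target), sharing the target's
  precision `κ` — swap errors;
* a **guessing** component — the circular uniform, implemented as a von
  Mises with `log κ_u = −100`. Any `κ < 10⁻³` is already visually
  uniform; `exp(−100)` leaves the uniform density exact to ~1e−40.

The two-parameter model drops the non-target components; the
three-parameter model splits the total non-target probability equally
over lures; the interference measurement model (IMM) replaces the free
mixture weights with item activations `A_j = a + c·e^{−s·D_j}`
(target distance `D = 0`) normalised against background noise `b`:
`p_mem = A_target/(b + ΣA_j)`, `p_nt_j = A_j/(b + ΣA_j)`,
`p_guess = b/(b + ΣA_j)`.

### Reading of the IMM activation equations

Published typeset versions of the IMM probability equations sometimes
place a single `+a` outside the sums over items. `wmmix` deliberately
uses the **per-item activation** form above, because it is the only
reading under which the standard equivalences hold exactly, and those
equivalences are part of this package's test contract:

* `imm_abc` (lures receive only `a`; the target receives `a + c`) is
  mathematically identical to the three-parameter mixture model;
* setting `a = 0` in `imm_abc` recovers the two-parameter model;
* `abc` is the `s → ∞` limit of `full` (the generalization gradient
  vanishes and context activation reaches only the target). Note that
  `s = 0` is **not** the `abc` model: it is full generalization, where
  every lure receives the target's activation.

### Mixing weights and identifiability

The 2P/3P mixing weights are estimated on an unbounded scale and mapped
to probabilities with a softmax. One weight must be fixed for
identifiability; following common practice the **guessing** weight is
the reference at 0, so a memory weight of 2 gives
`p_mem = e²/(e²+1) = 0.88`. With two components the transform is the
inverse logit. At set size 1 there are no lures: the non-target weight
(`thetant`) drops out of the likelihood entirely and the non-target
probability is structurally zero, rather than being estimated.

## Parameters, links, and formulas

| parameter | meaning | link | default prior |
|---|---|---|---|
| `kappa` | memory precision | log | normal(2, 1) on cell means; normal(0, 1) on difference coefficients |
| `thetat`, `thetant` | mixing weights | identity (weight scale) | normal(0, 2) |
| `c`, `a`, `s` | IMM activations / slope | log | normal(0, 2) |
| random-effect SDs | between-subject variation | log (sampled) | half-normal(0, 1) |
| random-effect correlations | only for `(… | group)` | partial correlations | uniform |

`normal(2, 1)` on log-κ covers κ from roughly 1 (circular SD ≈ 65°) to
55 (≈ 8°) within ±2 SD — weakly informative for color/orientation
reproduction. It is applied only to intercept/cell-mean columns;
difference-type coefficients (treatment or successive-difference
contrasts, interaction columns) are centred at zero with unit scale,
because centring a *difference* at +2 would bias effect estimates.
All defaults are visible via `default_priors()` before fitting and are
replaceable row by row (`set_prior()`, most specific selector wins).

Formulas are per parameter (`wmf()`): `0 +` gives cell-means coding,
`(terms || group)` uncorrelated random effects, `(terms | group)`
correlated ones, and `gr(group, by = stratum)` estimates separate
random-effect SDs per stratum (e.g. age groups). Random effects are
centred normals within each stratum. Monotonicity constraints are
implemented exactly as in standard regression practice: a
successive-difference (forward) contrast — row `i` has 1s in the first
`i − 1` difference columns, so the intercept is the first level's mean
and coefficient `j` is `mean(level j+1) − mean(level j)` — combined
with `lb = 0` priors on those coefficients. The bound is enforced by an
exp-transform with Jacobian, so *every* stored draw respects it.

## Estimation

The sampler is an in-package static Hamiltonian Monte Carlo:

* analytic gradients of the mixture likelihood (compiled C++ core,
  Bessel functions from R's math library; asymptotic expansions above
  `κ = 10⁵` where `besselI` loses accuracy);
* non-centered random effects `u = diag(σ) L z`, `z ~ N(0, 1)`, with σ
  sampled on the log scale; correlation Cholesky factors `L`
  parameterised by tanh-transformed canonical partial correlations with
  independent uniform priors (the backend's standard choice);
* dual-averaging step-size adaptation (target acceptance 0.8) and a
  diagonal mass matrix estimated from the 50–95% warmup window;
* trajectory length ≈ 1.2 time units, step size jittered ±10%,
  leapfrog steps capped at 128;
* a transition is **divergent** when the Hamiltonian error exceeds 1000
  or the gradient becomes non-finite; post-warmup divergences are
  counted and reported;
* defaults follow common practice: 4 chains, 1000 warmup, 1000 kept
  draws; `R-hat > 1.05` triggers a warning. R-hat is the split-chain
  version; ESS uses Geyer's initial positive-sequence estimator.

Chains are seeded `seed + chain − 1`; identical seeds reproduce draws
exactly. `sample_prior = TRUE` runs a second, likelihood-free pass with
matched dimensions, which is what Savage–Dickey ratios require.

## Hypothesis tests

`hypothesis()` supports point (`"expr = 0"`) and directional
(`"expr > 0"`) statements over (combinations of) coefficients.
The point-hypothesis evidence ratio is the Savage–Dickey density ratio
**posterior/prior at the point** — the Bayes factor BF01 *in favour of*
the stated equality; its reciprocal BF10 is reported alongside to avoid
orientation confusion. Densities at the point are Gaussian-kernel
estimates with a Sheather–Jones plug-in bandwidth (nrd0 fallback). Two
estimator limitations are documented rather than hidden: (i) with ~4000
draws the density estimate is accurate to ~10–15% at points up to
~1.5 posterior SDs from the mean, and acquires an upward kernel bias
deeper in the tail — extreme BF01 values are therefore *conservative*;
(ii) a degenerate derived combination (zero variance) is flagged and
returns `NA` instead of a ratio. Directional statements are evaluated by
draw counting; when every draw satisfies the direction the odds are
reported as `Inf`.

## Posterior predictive checks

`pp_check()` draws posterior parameter vectors, simulates a complete
replicate dataset for each — same subjects, per-trial set sizes, lure
locations and context distances as the fitted data, new component draws
and response errors — and smooths observed and replicated errors with a
von Mises kernel (fixed concentration 25, a kernel SD of ≈ 11.6°; large
enough to show mixture structure, small enough not to blur the guessing
floor). Curves integrate to 1 over the circle by construction.

## The synthetic-data generator

`generative_config()` + `simulate_trials()` is the generative mirror of
the likelihood: group-level parameter values per condition cell are
supplied on the native scale, between-subject deviations are drawn on
the link scales from centred normals (per subject *and* cell,
matching a `(0 + cell || subject)` random-effect structure), lure
locations are uniform on the circle, IMM context distances uniform on
`(0, π]`, the generating component is drawn from the model's
probabilities, and the response from the matching von Mises (uniform
for guessing). Latent component labels are returned for diagnostics.

What it does **not** emulate: realistic lure geometry (real displays
enforce minimum separations), categorical biases toward focal colors,
response-time dependence, serial position or inter-trial effects, and
any non-von-Mises error kernel. A green recovery test therefore
establishes that the estimator inverts its own generative model at
realistic sizes — not that the model is true of any particular
experiment.

The recovery study fixed in the acceptance suite uses 20 subjects, set
sizes {1, 2, 3, 6} with 60 trials per cell (above the ≈ 50
retrievals/condition guidance for hierarchical estimation), true
`κ = (12, 10, 8, 6)` and `p_mem = (0.97, 0.93, 0.85, 0.55)` — a
monotone decline of both precision and recall probability of the size
typical for color-wheel experiments — and between-subject SDs of 0.2
(log κ) and 0.3 (weight scale). These values were chosen once, before
the tests were run, and are not tuned.

## Numerical choices

* **Wrapping convention**: all angles live in `(−π, π]`; wrapping is
  idempotent and applied on load, after recoding, and after simulation.
* **Log-sum-exp everywhere**: mixture densities and the softmax are
  computed with max-subtraction; the guessing component contributes a
  finite floor, so trial log-likelihoods stay finite for any finite
  parameters.
* **"Virtually uniform" pin**: the package tests the near-uniformity of
  `κ = 10⁻³` with the symmetric relative difference
  `|d − u|/max(d, u) < 10⁻³`. The one-sided ratio `d/u − 1` equals
  `κ + κ²/4` at the mode — over the bound by exactly the second-order
  term `2.5×10⁻⁷` — so a one-sided test at the stated boundary would
  fail for a reason that has nothing to do with uniformity.
* **Zero vs missing slot padding**: both are accepted; zeros in slots
  beyond `set_size − 1` are normalised to missing on validation (zero
  is a legal relative location for an *active* slot, so activity is
  governed by set size, not by the value).
* **Degenerate inputs**: set size 1 drops all lure terms; `sd2k` of an
  SD above the `κ → 0` plateau returns 0; rank-deficient fixed designs
  are rejected with the aliased columns named; non-finite likelihood at
  initialisation reports the first offending trial row.

## Known limitations

* Static HMC with a diagonal mass matrix, not NUTS: strongly correlated
  posteriors (e.g. `a` vs `c` in near-degenerate IMM fits) mix more
  slowly; the diagnostics (R-hat, ESS, divergences) are the guardrail.
* Bridge-sampling marginal-likelihood Bayes factors for whole-model
  comparison are out of scope; `hypothesis()` covers coefficient-level
  questions only.
* The IMM `bsc` version sets `a = 0` exactly (no floor activation for
  lures).
* Context distances are treated as nonnegative reals on an arbitrary
  scale; their units in any given experiment are the user's
  responsibility (they interact with the scale of `s`).
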