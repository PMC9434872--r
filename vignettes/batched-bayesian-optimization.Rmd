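---
title: "Batched Bayesian optimization over discrete reaction search spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batched Bayesian optimization over discrete reaction search spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput reaction optimization asks: out of every combination of
reactants, ligands, catalysts and bases a chemist could plate, which handful
should actually be run to find the highest-yielding conditions? The search
space is a finite cartesian product — a few thousand rows, one per
configuration — and each evaluation is an expensive experiment. reactbo
implements the standard answer, batched Bayesian optimization, and the
machinery needed to study its *robustness*: how sensitive the outcome is to
the acquisition function, the batch size, the initial batch, and to
incomplete candidate tables.

Every campaign follows the same loop. Encode the candidates numerically, fit
a Gaussian-process (GP) surrogate to the configurations evaluated so far,
score every untried candidate with an acquisition function, select a batch
of `q` candidates, look up (or run) their objective values, and repeat until
the experimental budget `B` is spent. The budget counts every evaluation
including the initial random batch, so a run with batch size `q` and `R`
rounds performs exactly `q * R` evaluations — batch size 3 with 17 rounds is
a budget of 51, batch size 8 with 6 rounds a budget of 48, and so on.
Because the studies here are retrospective (the full objective table is
known in advance), evaluation is an exact, noiseless table lookup, and a
run is fully determined by `(space, objective, config)` including the master
seed.

## Encoding the search space

Each factor level carries either a numeric descriptor vector or a SMILES
string; SMILES are converted to radius-2 circular fingerprints (ECFP4-like)
folded to 512 bits. Candidate rows concatenate the per-factor descriptors.
Before the GP sees them, constant columns are dropped (they carry no
information and make Pearson correlation undefined), columns whose absolute
correlation with an already-retained column exceeds 0.95 are pruned
left-to-right (the threshold is configurable; 0.95 is the conventional
"highly correlated" cut), and the retained columns are z-scored over the
available candidates. Standardization matters because a single shared GP
length-scale behaves poorly on mixed-scale descriptors. Candidates are
enumerated in lexicographic order of level indices, so a space rebuilds
identically every time.

Incomplete tables — common when only some reactant pairs were ever run —
are handled in one of two modes: `zero_fill_domain()` assigns missing
combinations an objective of 0 and leaves them selectable (a deliberately
flawed mode kept for comparison), while `restrict_domain()` masks them out
so acquisition, initialization and batching never see them. The packaged
`synth-pd` benchmark exists to compare the two.

## The Gaussian-process surrogate

`gp_fit()` is an exact GP with a Matern-5/2 kernel and a single shared
length-scale (no ARD — with a few dozen observations per run,
per-dimension length-scales are poorly identified). Targets are z-scored
internally and predictions inverse-transformed, making the fit invariant to
affine rescaling of the objective (percent yield and PCE-like scales are
treated identically).

Hyperparameters maximize the log marginal likelihood from five fixed,
deterministic starts (length-scale multiples 1, 0.25, 0.5, 2, 4 of the
median pairwise training distance) with analytic gradients, so refitting the
same data reproduces the same model. Two stabilizing choices deserve
explanation because bare maximum likelihood fails visibly at the sample
sizes seen early in a run:

* **Weak MAP priors.** With 5-15 observations the marginal likelihood is
  often maximized by degenerate fits — zero noise with a collapsed
  length-scale, or "everything is noise" with a huge one — and the first
  rounds of a campaign are then wasted. We therefore add weak log-normal
  priors: length-scale centered on the median pairwise training distance
  (sd 0.75 in log space), signal variance centered on 1 (the targets are
  standardized), and noise centered on 5% of the target variance (sd 1.5).
  These are regularizers in the spirit of the defaults modern BO toolkits
  ship, not informative beliefs; all are configurable and can be flattened.
* **Noise model.** By default the observation-noise variance is *learned*.
  On surfaces whose objective contains scatter the descriptors cannot
  explain, a jitter-only GP is forced to interpolate that scatter and its
  calibration collapses. When the objective is an exactly reproducible
  lookup (the 1-D demos, real retrospective tables), `noise = "fixed"`
  reduces the model to the interpolating GP with a jitter of 1e-6 times the
  signal variance, giving near-zero predictive uncertainty at observed
  points. Both modes are exercised by the tests.

With fewer than three observations no optimization is attempted; the model
falls back to a domain-scale length-scale (half the median pairwise distance
of the candidate set, computed once per run from a deterministic subsample)
so that uncertainty still grows with distance from the observed points and
the first proposed batch is meaningfully spread.

`gp_predict()` returns the latent (noise-free) posterior mean and sd, and
optionally the full joint covariance; `gp_sample()` draws joint, seeded
posterior samples — joint rather than marginal, because batched Thompson
sampling with independent marginals collapses onto near-duplicate picks.

## Acquisition functions

The improvement utility of a value `y` against an incumbent `x+` with
exploration offset `delta` is `max(y - x+ - delta, 0)`. Expected Improvement
is its expectation under the Normal posterior, in closed form
`EI = (mu - x+ - delta) * pnorm(z) + sd * dnorm(z)` with
`z = (mu - x+ - delta) / sd`, degenerating to the clamped improvement at
`sd = 0`. A Monte-Carlo integration of the utility is kept in the test suite
as the independent oracle for the closed form. `delta` defaults to 0.01 on
the standardized-target scale (the objective units an offset should live in
are otherwise ambiguous across yield and PCE scales); it is configurable
and its effect on this package's benchmarks is small.

Variants: **EI-k** scores against the kth highest observed value
(duplicates counted), reducing to plain EI at `k = 1` — useful when the goal
is a strong top-k set rather than a single best hit. **E3I** draws `m` joint
posterior samples, scores EI against each sample's maximum with
`delta = 0`, and averages; as the posterior tightens it converges to EI
against the posterior maximum (a tested property). **Thompson sampling**
draws one joint sample and takes its argmax. Three controls — maximal
predictive mean, maximal uncertainty, mean plus sd — and the model-free
random selector complete the set.

All acquisitions are maximized by scanning the finite candidate table.
Already-observed candidates are excluded from the argmax by default
(re-running a known configuration wastes budget in a noiseless setting;
a flag restores re-evaluation). All ties break to the lowest candidate
index, for the sake of seeded reproducibility.

## Batch construction

* **Kriging Believer** (EI family and controls): pick the acquisition
  argmax, *believe* the model's predictive mean there as if observed,
  condition the model on that belief, and repeat until `q` picks are
  assembled; the believed values are then discarded and the true values
  looked up. Two fidelity details: kernel hyperparameters are frozen during
  the loop (believed values are fabrications and must not move kernel
  estimates), and beliefs are conditioned *noise-free* (jitter only) — the
  believer's premise is that the value is known, so uncertainty at the pick
  must collapse and the next pick be pushed elsewhere. For marginal
  acquisitions the loop runs as an incremental rank-one update of the
  Cholesky factor and the pool cross-kernel, which is algebraically
  identical to refit-with-frozen-hyperparameters and verified against a
  hand-rolled condition-and-refit loop in the tests.
* **Parallel Thompson sampling**: `q` joint posterior samples, one argmax
  each, no model updates between picks. Within-batch duplicates are redrawn
  with fresh derived sub-seeds up to 10 times, then fall back to the best
  not-yet-picked candidate of the last sample.
* **Random**: a seeded uniform draw without replacement.

Joint sampling over thousands of candidates would require a dense Cholesky
factorization of the full posterior covariance each round, so TS and E3I
operate on a seeded random subsample of the unobserved pool, capped at
`max_joint` (default 1000) candidates per round, with exact joint sampling
inside the subset. Marginal acquisitions always score the entire pool.

## Seeding

Every random stream derives deterministically from the run's master seed via
a fixed congruential hash (`derive_seed(seed, round, pick, ...)`):
initialization, each round's batch, each TS pick and redraw, each E3I
sample set. Reproducibility therefore does not depend on the order in which
streams are consumed, and the global RNG state of the calling session is
saved and restored around every internal draw.

## The evaluation harness

`replicate_runs()` repeats a configuration over consecutive seeds
(`seed_base .. seed_base + n_runs - 1`; 50 replicates is the default
protocol) and reports the per-seed final best values, their mean, standard
error and quartiles, the number of runs whose best equals the global maximum
(exact lookup equality — the retrospective setting has no measurement noise;
a tolerance exists for noisy objectives) and, failing that, the
second-highest value, plus the per-replicate top-5 values.
Configurations are compared with Welch's unequal-variance two-sided t-test
at alpha = 0.05, matching standard reporting practice; no multiple-testing
correction is applied by default (the comparisons mirror a study that did
not correct), and `p.adjust` can be layered on by the caller.
`batch_size_sweep()` runs the near-constant-budget grid
(3,17) (4,12) (5,10) (6,8) (7,7) (8,6) (9,6) (10,5) — budgets 51, 48, 50,
48, 49, 48, 54, 50; for batch size 9 the 6-round (budget 54) variant is
used. `missing_domain_experiment()` pairs zero-fill and restricted runs
under identical seeds, and `top5_rank_distribution()` summarizes the
across-replicate distribution of the rank-1..5 values.

## What the synthetic surfaces emulate — and what they do not

The generators produce objective tables with the *structure* of the real
campaigns this machinery is normally pointed at, with known ground truth:

* `generate_yield_surface(shape, ...)`: each factor level receives a latent
  quality score; descriptors equal
  `informativeness * quality + sqrt(1 - informativeness^2) * noise`
  per column, so `informativeness` smoothly interpolates between perfectly
  predictive descriptors (1) and useless ones (0). The latent response is
  the sum of level qualities plus pairwise level-pair interaction effects
  (sd `interaction` relative to unit main effects), squashed onto
  [0, 100] by a fixed scaled logistic of the standardized latent value —
  preserving ranking, hence a well-defined ground truth, while bounding the
  response like a percentage yield. Gaussian noise with sd in *yield points*
  is then added and clamped: the noise knob is specified on the 0-100 scale
  because that is the scale on which a chemist would state assay
  variability, and adding it before the squashing would make its magnitude
  depend on where the latent value sits on the logistic.
* `drop_combinations()` removes whole (factor 1, factor 2) level-pair
  blocks, mirroring data sets where only some reactant pairs were run; the
  block holding the global maximum is retained unless explicitly allowed to
  drop, so "find the optimum" remains well-posed.
* `generate_library_surface()`: a single factor of `n` molecules with
  sparse random 512-bit fingerprints and a response that is a sparse linear
  function of the bits plus a few bit-pair epistatic terms and noise,
  shifted positive (a PCE-like scale).

Packaged benchmarks fix these choices once: `synth-suzuki`
(4 x 3 x 12 x 8 x 5 = 5760 candidates, interaction 0.25, noise sd 5,
informativeness 0.8, seed 20220901), `synth-pd` (6 x 11 x 6 x 8 = 3168
candidates with 32 of 66 level pairs kept, 1536 available), and `synth-cep`
(10000 molecules by default). Interaction 0.25 and three descriptor columns
per level were chosen as "moderate": interactions contribute noticeably but
do not dominate the additive structure, which matches the intuition that
reaction components contribute largely independently with meaningful
pairwise exceptions.

The informativeness knob demonstrably controls optimizer advantage — with
perfect descriptors and no noise EI clearly beats random selection, while
with uninformative descriptors the two are statistically indistinguishable
(a tested property). What the synthetic surfaces do *not* emulate: real DFT
or cheminformatics descriptor distributions (heavy tails, block
correlation), systematic rather than iid noise, the heavily zero-inflated
yield distributions of real plates, and chemistry-specific structure in
which combinations are missing. Passing tests here show the optimizer
machinery is correct and behaves sanely under controlled conditions; they
do not certify performance on any particular laboratory data set.

One caveat worth stating openly: with noise sd 5 and the logistic
saturating near 100, the very top of the `synth-suzuki` table is
noise-dominated — candidates within a point or two of the maximum are
effectively exchangeable. Exact-hit counts on this benchmark are therefore
less informative than mean best values, which is why the headline
comparisons are phrased in terms of means.

## Problem sizes and numerical choices

The studies shipped in `analysis/` and exercised by the acceptance script
use the full packaged benchmarks (5760 and 3168/1536 candidates) with 50
seeded replicates per cell, batch 5 and budget 50 unless the sweep grid says
otherwise; the library screen runs a reduced protocol (1000 molecules, 10
replicates) chosen to keep a full desk run in minutes. Other fixed
numerics: jitter 1e-6 of signal variance (inflated with a warning if the
kernel matrix is not factorizable, e.g. duplicate inputs with conflicting
targets); posterior covariance factorizations retry with growing ridge
before failing; E3I default `m = 64` samples; `max_joint` 1000; the
bottom-decile initialization pool is the `ceiling(N/10)` lowest-valued
candidates with boundary ties included. Degenerate inputs error early and
loudly: empty matrices, rank-out-of-range incumbents, batches larger than
the pool, budgets not divisible by the batch size.

## Known limitations

Exact GP algebra limits training sets to a few thousand observations —
ample for budget-50 campaigns, unsuitable for large active-learning loops.
The Kriging-Believer loop is inherently sequential in `q`; no parallel
approximation is attempted. Joint-sampling acquisitions see a subsampled
pool at large domain sizes (above `max_joint`), an approximation the
marginal acquisitions never make. Fingerprint encoding requires OpenBabel
via ChemmineOB and covers one fingerprint family; plugging in other
encoders means supplying descriptor matrices directly. The stopping rule is
a fixed budget; threshold- or patience-based early stopping is not
implemented because every study here uses fixed budgets.
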