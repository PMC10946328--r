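---
title: "Modeling gene expression cascades along pseudotime trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene expression cascades along pseudotime trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadefit)
```

## The problem

During differentiation, cells move through transcriptional states: some genes
switch from one steady expression level to another, others are expressed in a
transient pulse, and the order of these events defines a transcriptional
cascade. Given single cells ordered along a pseudotime trajectory, cascadefit
asks, for each gene: does its expression change along the trajectory at all,
what shape does the change take, and *when* do the switches happen — with
what uncertainty? From the switch times it then orders genes into a cascade
and proposes directed regulatory interactions.

The input is deliberately minimal: a raw gene-by-cell UMI count matrix and a
per-cell pseudotime value. Pseudotime is used only through the rank ordering
`t = 1..N`; estimating pseudotime itself (diffusion pseudotime, Slingshot,
Monocle 3, ...) is out of scope.

## The model

### Response functions

Four parametric families describe a gene's profile in log-normalized space:

* **uniform** `f(t) = b` — no dynamics;
* **gaussian** `f(t) = a exp(-(t - t0)^2 / (2 sigma^2)) + b` — a transient
  pulse;
* **sigmoidal** `f(t) = L / (1 + exp(-k (t - t0))) + bmin` — a state switch
  (the slope `k` may be negative, modeling down-regulation);
* **double sigmoidal** — the sum of two sigmoidal transitions anchored at
  `t1 < t2` between levels `bmin`, `bmid`, `bmax`, capturing asymmetric
  impulses (up-down or down-up) and stepwise two-stage transitions.

All level parameters are constrained positive; locations lie in `[1, N]`.

### Likelihood

Raw UMI counts are modeled by a negative binomial with gene- and
time-specific mean and a *global* dispersion `phi`
(`Var = mu + mu^2 / phi`). Fitting a dispersion per gene overfits UMI data,
so `phi` is estimated once per dataset from genes whose variability is mostly
technical: per-gene mean/variance pairs are binned into five equally spaced
log10-mean bins, a linear log10 mean-variance fit within each bin defines an
expected variance, the top 20% variance-excess genes per bin are dropped,
and `sigma^2 = mu + mu^2 / phi` is fit to the remaining genes by least
squares over `log(phi)` (initialized at `phi = 10`; the log parameterization
enforces positivity). Equal weights are used across genes; all genes with a
nonzero mean enter the procedure, not only those later fit — neither choice
is forced by the model, and both are recorded here as the package's
convention.

Curves are fit in log-normalized space but scored in count space: with
per-cell totals `M_t` and size factor `M~ = median(M_t)`, the mapping
`ytilde = ln(y M~ / M_t + 1)` is inverted to turn a curve value into a NB
mean for each cell, and the likelihood is the product of NB pmfs over cells.
Because a valid curve can touch zero, NB means are floored at `1e-10`
(counts against a zero mean would otherwise have undefined likelihood); the
floor is far below one count and never binds for realistic fits. Cells with
zero total UMIs are rejected at ingest since the size-factor mapping is
undefined for them.

### Priors

Level parameters get uniform priors on `(0.01, 2 max ytilde)` and locations
on `[1, N]` — uninformative, but bounding parameters to interpretable
ranges scaled to the data. Slopes (`k`, `k1`, `k2`) get a folded-normal
prior with mean 0 and variance 0.1: once a slope is large the curve shape
barely changes, so shrinking towards gentle transitions regularizes an
otherwise flat likelihood direction. For the sigmoidal family the prior is
applied to `|k|`, leaving the switch direction free. The Gaussian width gets
a folded-normal prior with variance `N/10`, discouraging degenerate flat
pulses. Exact prior bounds are configurable; the defaults above are the
package's own choice of "interpretable range".

### Inference

Each family is sampled with the affine-invariant ensemble sampler
(stretch move, scale `a = 2`), using four walkers per parameter (4, 16, 16,
28 for the four families) and the two-half update scheme. The default run is
10,000 sweeps with a 5,000-sweep burn-in. Gaussian and sigmoidal walkers
start from a least-squares point fit perturbed with Gaussian noise (1% of
each parameter's prior range); the point fit scans a coarse grid over the
nonlinear parameters, solving the level parameters in closed form at each
node, before a local refinement — single-start descent proved prone to
step-function local minima. Double sigmoidal walkers are drawn to cover the
four qualitative shapes (impulse up/down, step up/down) with randomized
`t1 < t2`. Uniform walkers draw from `(0.01, max ytilde)`.

After sampling, the half of the walkers with the lowest acceptance fractions
(computed over all sweeps, burn-in included) is pruned to remove stuck
walkers, and no thinning is applied. Convergence is monitored through the
per-parameter integrated autocorrelation time
`tau = max_T (1 + 2 sum_{lag<=T} rho(lag))` (delays up to `T = 1000`) and
the effective sample size `ESS = M N_ret / tau`.

### The inflection gate

Inflection points carry the timing signal: the Gaussian switches at
`t0 - sigma` (up) and `t0 + sigma` (down); the sigmoid at `t0` with the
sign of `k`; the double sigmoidal at `t1` and `t2` with signs given by the
level differences. The double sigmoidal's inflection count can vary, so a
move is accepted only when the closed-form second derivative changes sign
within `t1 +/- 1` and `t2 +/- 1`; draws failing this gate get posterior
density zero. Every retained double-sigmoidal draw therefore carries exactly
two parameter-anchored inflection points — the anchored times `t1`, `t2`
are reported even when the exact curvature zero deviates slightly.

### Model selection

The BIC `k ln(n) - 2 ln L` is evaluated with the likelihood at the
posterior-mean parameters `<theta>` rather than a maximum-likelihood point.
To reduce sensitivity to outlier cells, the BIC is recomputed on 10,000
random 98% subsets of the cells (500 in the test suite, for speed); the same
subset sequence is shared by all four families so comparisons share their
Monte-Carlo noise — the procedure does not prescribe sharing, but sharing
strictly reduces comparison variance. `n` is the subset's own size. The
decision cascade requires a non-uniform family's *worst* subset BIC to beat
the uniform family's *best*, plus mean-BIC comparisons ordered so that
simpler families win ties; the branches fire in a fixed order
(double sigmoidal, sigmoidal, Gaussian, uniform), which resolves their
non-exclusivity. When `<theta>` violates a constraint (possible for
multimodal posteriors, e.g. the means of `t1` and `t2` crossing), it is
projected back onto the constraint set rather than rejected, because the
cascade needs a BIC for every family.

A symmetric impulse generated from a double sigmoidal is routinely selected
as Gaussian: with the two shapes near-indistinguishable the branch order
prefers the 4-parameter family, which is the intended parsimony behavior,
not a recovery failure. Family-recovery checks therefore use
double-sigmoidal shapes only that family can express (transient-down and
stepwise patterns).

### Downstream comparisons

For a pair of genes, the posterior samples of one inflection locus each are
binned into 100 equal bins spanning their pooled range, and the overlap
`P(A=B) = sum_i min(p_A(x_i), p_B(x_i))` measures whether the switches are
simultaneous. At overlap >= 1% the interaction is mutual (positive for equal
signs, negative otherwise); below it, the sign pattern (earlier, later)
maps to directed regulation — (+,+) and (-,-) give "earlier activates
later", (+,-) gives mutual antagonism in direction, (-,+) gives no call.
Cascades order genes by the posterior median of the first inflection time
(the method reports full posterior distributions; the median is this
package's choice of point estimate for ordering, with lexicographic gene-id
tie-breaks). The upstream-regulator screen admits candidates with a positive
switch simultaneous-with-or-before the target's first inflection or a
negative switch after it; designated co-regulators are additionally required
to show a transient-up pattern. "Simultaneous" reuses the 1% overlap
threshold throughout.

## The synthetic-data generator

`simulation_config()` / `make_benchmark_dataset()` generate datasets by the
model's own generative process: true curves in fit space, inverted to
per-cell NB means using per-cell totals, counts drawn `NB(mu_t, phi)`.
Per-cell totals default to lognormal with median 5000 and sdlog 0.3 —
a realistic droplet library-size spread that exercises the size-factor
normalization — with a constant-total option for clean moment checks. A
spacer gene absorbs the difference between the sampled gene counts and each
cell's target total so that column sums equal the intended totals exactly.
Gene means in dispersion-recovery checks are drawn log-uniformly between 0.5
and 50 counts, spanning the lowly- to highly-expressed range that anchors
the mean-variance fit.

What the generator does *not* emulate: pseudotime estimation error, doublets,
batch effects, zero inflation, ambient RNA, or gene-gene correlation beyond
the shared totals. Passing recovery tests therefore demonstrates correctness
of the inference machinery under the model's own assumptions, not robustness
to the full messiness of real scRNA-seq data.

## Problem sizes and numerical choices

The test and acceptance runs use reduced, fixed problem sizes chosen to
exercise every code path at desk scale: 2,000 sweeps with 1,000 burn-in and
500 BIC subsets, trajectories of 300-500 cells, panels of 10 genes per
family plus 50 uniform genes for specificity, and 20 seeded replicates for
recovery rates. Full-scale defaults (10,000 sweeps, 10,000 subsets) remain
the package defaults. All randomness flows from explicit integer seeds;
equal seeds give bit-identical chains, selections, and output files.

Other numerical conventions: pseudotime ties are broken by lexicographic
cell id so ranks are deterministic; dispersion bins span the min-max of
log10 means with a right-closed last bin, and "top 20th percentile" means
strictly above the 80th percentile within a bin; bins with fewer than three
genes skip the within-bin filter; fewer than five nonempty bins triggers a
three-bin fallback with a warning; Matrix Market orientation is resolved by
matching sidecar lengths, with an explicit transpose override.

## Known limitations

* The double sigmoidal's two inflection points are anchored at `t1`, `t2` by
  the gate; curves whose genuine curvature zeros sit far from the anchors
  are excluded from its posterior by construction.
* Model selection compares exactly these four families; slow monotone drifts
  that none of them capture well tend to land on the sigmoidal family with
  wide uncertainty.
* Pairwise interaction calls are timing-based; assembling them genome-wide
  would accumulate false positives from coincidentally ordered genes, so the
  intended use is directed hypotheses on curated gene sets.
* The acceptance-fraction pruning rule always removes half the walkers, even
  when all walkers mixed well; this is harmless for converged chains (the
  retained half is a valid sample) but halves the posterior sample size.
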