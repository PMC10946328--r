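# cascadefit

Bayesian modeling of gene expression cascades along single-cell pseudotime
trajectories.

## What it does, and for whom

Given a raw gene-by-cell UMI count matrix and a per-cell pseudotime ordering
(from diffusion pseudotime, Slingshot, Monocle 3, or any other trajectory
method), cascadefit decides for each gene whether and how its expression
changes along the trajectory, and *when*. It is aimed at developmental and
stimulus-response scRNA-seq analyses where the ordering and timing of
transcription-factor switches — not just differential expression — is the
question.

Each gene's log-normalized profile is fit by four response functions:

| family | form | pattern |
|---|---|---|
| uniform | `b` | no dynamics |
| gaussian | `a·exp(-(t-t0)²/(2σ²)) + b` | transient pulse |
| sigmoidal | `L/(1+e^(-k(t-t0))) + bmin` | state switch (up or down) |
| double sigmoidal | two transitions between `bmin`, `bmid`, `bmax` at `t1 < t2` | impulse / stepwise |

Counts are modeled by a negative binomial `NB(μ_t, φ)` with a single
dataset-wide dispersion `φ` estimated from low-variability genes
(`Var = μ + μ²/φ`). Curves are fit in log-normalized space
(`ỹ = ln(y·M̃/M_t + 1)`, size factor `M̃ = median` cell total) and scored in
count space. Posteriors are sampled per family with an affine-invariant
ensemble MCMC (stretch move; 4 walkers per parameter; 10,000 sweeps with
5,000 burn-in by default; low-acceptance walkers pruned). Families are
compared by the BIC at the posterior-mean parameters, recomputed on 10,000
random 98% subsets of the cells, with a decision cascade that prefers
simpler families on ties.

Signed inflection points are then read off each retained draw — `(t0-σ, +)`
and `(t0+σ, -)` for the Gaussian, `(t0, sign k)` for the sigmoid, `(t1, t2)`
with level-difference signs for the double sigmoidal — giving a posterior
distribution of switch times per gene. These drive:

* **cascade ordering** — genes sorted by posterior median first switch time;
* **switch-overlap estimates** — `P(A=B) = Σ min(p_A, p_B)` over 100 shared
  histogram bins, a percentage-overlap p-value for "do these genes switch
  simultaneously?";
* **directed interaction calls** — timing- and sign-based rules
  (e.g. "+ then +" means the earlier gene positively regulates the later);
* **upstream-regulator screens** for a target gene of interest.

## Worked example

Simulate a 300-cell trajectory with a known switch, a pulse, and a flat
gene, fit all three, and compare their timing (reduced MCMC settings for a
quick run):

```r
library(cascadefit)

genes <- list(
  list(name = "SwitchUp", family = "sigmoidal",
       theta = c(k = 0.1, L = 2, t0 = 120, bmin = 0.3)),
  list(name = "Pulse",    family = "gaussian",
       theta = c(a = 2, b = 0.3, t0 = 150, sigma = 30)),
  list(name = "Flat",     family = "uniform", theta = c(b = 1)))
cfg <- simulation_config(300, genes, phi = 10, seed = 42)
td  <- filter_genes(make_benchmark_dataset(cfg)$td, 0.01)

fits <- lapply(c("SwitchUp", "Pulse", "Flat"), function(g)
  fit_gene(td, g, phi = 10, n_iterations = 2000, burn_in = 1000,
           n_subsets = 500, seed = 7))
for (f in fits) print(f)
```

```
Gene SwitchUp: best fit sigmoidal (state_switch_up)
 locus median  lo95  hi95 sign
     1  117.3 112.1 121.8    1
Gene Pulse: best fit gaussian (transient_up)
 locus median  lo95  hi95 sign
     1  122.9 118.8 126.7    1
     2  177.7 173.7 182.2   -1
Gene Flat: best fit uniform (none)
```

Each gene recovers its generating family; the switch gene's inflection
posterior (median 117.3, 95% interval 112.1–121.8) brackets the true switch
at t0 = 120, and the pulse gene's two inflections bracket the true
up/down switches at 120 and 180. Ordering and interaction inference:

```r
order_cascade(fits)
infer_interaction(gene_inflection_locus(fits[[1]]),
                  gene_inflection_locus(fits[[2]]))
```

```
      gene    family   dynamic_class first_inflection_median
1 SwitchUp sigmoidal state_switch_up                117.2509
2    Pulse  gaussian    transient_up                122.9086

    source   target        relation  overlap
1 SwitchUp    Pulse mutual_positive 0.205125
2    Pulse SwitchUp mutual_positive 0.205125
```

The two up-switches overlap in 20.5% of posterior mass — simultaneous under
the 1% threshold — so the call is a mutual positive interaction rather than
a directed edge.

For shell use, `inst/cli/cascadefit.R` wraps reading (`.mtx`/TSV counts +
pseudotime TSV), fitting, and cascade export:

```sh
Rscript inst/cli/cascadefit.R fit --counts counts.mtx --genes genes.txt \
  --cells cells.txt --pseudotime pt.tsv --out fits/ --seed 1
```

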