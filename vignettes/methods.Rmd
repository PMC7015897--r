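---
title: "Models and design choices in polyGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in polyGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

polyGP compares linear Bayesian whole-genome regression with a small
convolutional network for genomic prediction in polyploids, on simulated
allele-dosage panels with controlled additive and epistatic architecture.
This vignette is the package's own account of the models, the tunable
parameters, and the places where the design was genuinely open and a choice
had to be made.

## Genotype and trait simulation

`simulate_genotypes()` draws an individuals × markers panel of reference-
allele dosages at an even ploidy. Each marker's allele frequency is uniform
on `maf_range` (default 0.05–0.5, the usual post-QC spectrum). A dosage is a
sum of `ploidy` allele indicators; within an LD block (default 10 markers)
the latent state of each chromosome copy follows a Gaussian AR(1) with
neighbour correlation 0.9, so adjacent markers are correlated while marginal
frequencies are exact. This emulates blocky short-range LD only: there is no
coalescent history, no population structure, no genotype-calling error. A
test passing on these panels therefore says nothing about robustness to
structure or call-rate artefacts in real data.

`sample_architecture()` implements three architectures — 200 additive causal
loci; 100 multiplicative epistatic pairs (the pair genotype is the raw
product of the two dosages, not a centered product); or 80 loci plus 60
pairs. Effect magnitudes are Gamma(shape = 1, scale = 0.2). Two points were
genuinely open:

* **Rate vs scale.** We use the scale parameterization. Because residual
  variance is calibrated to the target heritability afterwards, the trait is
  rescaled anyway and nothing downstream depends on this choice.
* **Effect signs.** Magnitudes are given random ± signs. All-positive
  effects would make every trait monotone in total dosage and a trivial
  mean-dosage predictor would do well; randomized signs avoid that
  degeneracy. Per-pair variance arithmetic is unaffected.
* **Disjointness.** Additive loci and pair members are mutually disjoint
  within a replicate, which keeps variance attribution unambiguous.

`simulate_phenotypes()` sets the residual variance to
`var(g) * (1 - H2) / H2` so the expected broad-sense heritability equals the
target (0.50 by default); the realized ratio `var(g)/var(y)` is recorded per
replicate.

A consequence worth knowing: at this MAF spectrum a raw product
`X1 X2 = mu1 x2 + mu2 x1 + x1 x2 + const` carries roughly twice as much
*additive* (marginal) variance as interaction variance, so a "pure
epistatic" trait is majority-additive in the narrow-sense. Variance
decompositions on these traits correctly report `h2_a > h2_e`; observing the
opposite requires a lower-frequency allele spectrum (typical `p < 0.2`)
than this generator's default.

## Relationship kernels

`additive_kernel()` is `Z Z' / c` with `Z` the column-centered dosages and
`c = sum_j m p_j (1 - p_j)` at ploidy `m` — the classical diploid
`2 sum p(1-p)` generalized so the mean self-relationship stays near 1 under
random mating. The diploid dominance coding is the classical one
(−2p², 2p(1−p), −2(1−p)² for genotypes 0/1/2, denominator `4 Σ [p(1−p)]²`).
For autotetraploids no single printed coding is canonical; we use the
digenic heterozygosity covariate `q(4−q)` (the count of heterozygous allele
pairs among the six digenic combinations), centered, with the cross-product
normalized by the summed covariate variances so the mean diagonal is 1. This
is an explicit stand-in and is labelled as such in the documentation. The
epistatic kernel is the Hadamard square `A ⊙ A` (PSD by the Schur product
theorem). The Gaussian kernel is
`K(x_i, x_k) = exp(-h ||x_i - x_k||² / p)`; dividing by the marker count `p`
keeps the bandwidth `h` on a panel-size-free scale (the alternative reading,
`p` as part of the norm notation, would tie `h` to the number of markers).
Since no bandwidth is canonical, `h` is chosen from {0.1, 0.5, 1, 2.5} by
inner-training validation in the study driver.

Processing order is QC filter → (optional) diploidization → mean imputation
→ matrix construction. Diploidization (0,1,…,m → 0,1,…,1,2) needs integer
dosages, so it must precede imputation, which produces fractional means.
Kernels are checked for symmetry and positive semidefiniteness
(eigenvalue ≥ −1e−8); `repair_psd()` adds a diagonal jitter of 1e−8 (plus
the eigenvalue deficit) and records it, rather than failing.

## Gibbs samplers

All Bayesian fitters share `gibbs_config()`: default 6,000 cycles with 1,000
burn-in, thin 1. Variance components get scaled-inverse-χ² priors with
df = 5; prior scales are set so the prior *mode* of each component equals
`prior_R2` (default 0.5) of `var(y)`, split equally across components in
multi-component models, the rest going to the residual. These hyperpriors
are deliberately explicit — the common practice of inheriting a package's
defaults hides them.

* **BRR** samples marker effects one at a time from their normal
  conditionals. A fixed-variance mode skips the variance updates so the
  posterior mean can be checked against the closed-form ridge solution.
* **BL** uses the Park–Casella scale mixture: `beta_j ~ N(0, s2_e tau2_j)`,
  `tau2_j ~ Exp(lambda²/2)`, `lambda²` gamma-distributed (shape 1.1, rate
  matched to a prior guess of the penalty). Effects are shrunk, never
  zeroed.
* **BRR-GM** is BRR on the centered/scaled dosage-class dummy design Ω
  (one indicator per dosage class per marker, zero-variance classes
  dropped), allowing arbitrary within-locus genotype effects.
* **RKHS** and the multi-kernel model sample in each kernel's eigenbasis:
  writing `g = U sqrt(D) alpha` makes the conditional of `alpha` Gaussian
  with *diagonal* covariance, so the whole coefficient vector is drawn at
  once. Eigenvalues below 1e−8 of the largest are truncated. Validation
  predictions use the conditional-mean rule
  `K_new,train K_train^{-1} g_hat`; the training/validation partition of the
  full kernel is the only place genotypes of validation individuals enter —
  their phenotypes never do (a test perturbs validation phenotypes and
  asserts bitwise-identical fits).
* The multi-kernel variance ratios `h2_i = s2_i / (s2_a+s2_d+s2_e+s2_eps)`
  are computed draw by draw and summarized by posterior mean and sd.

All chains draw through R's RNG, so a seed makes them bitwise reproducible;
scaling `y` by `c` scales effect means by `c` and variance draws by `c²`
along the identical RNG path.

## The CNN stage

The fixed topology is: input `n × p` (per-marker centered/scaled dosages,
one channel) → one convolution block (kernel width 3, stride 1, `n_filters`
filters, chosen activation, optional dropout) → max-pooling of width 3 →
flatten → `hidden_layers` dense layers of `dense_neurons` → one linear
output. Width 3/stride 1 and pool 3 are fixed; the searched menus are
activation {relu, tanh, linear}, filters {16, 32, 64, 128}, weight decay
{0, 0.1, 0.01, 0.001} and dropout {0, 0.01, 0.1, 0.2} separately for the
convolution and dense blocks, learning rate {0.1, 0.01, 0.001, 0.0025},
dense neurons {4, 8, 12, 16}, hidden layers {1, 5, 10}.

Two numerical choices matter and were forced by experiment:

* **Optimizer.** With plain SGD the stable step size is bounded by the
  curvature of the flatten layer, roughly `2 / ||a||²` with several thousand
  flatten features — orders of magnitude below most of the learning-rate
  menu, and most sampled configurations exploded within an epoch. The
  trainer therefore uses Adam (β₁ = 0.9, β₂ = 0.999) at the point's learning
  rate, whose per-parameter normalization makes the whole menu usable; L2
  weight decay is added to the gradient. The menu value 0.0025 is itself an
  adaptive-optimizer-typical rate.
* **Response scaling.** Training runs on the standardized response (MSE on
  raw phenotype scales makes the loss landscape depend on effect sizes);
  predictions are mapped back.

Unstated training knobs are declared, not inferred: 50 epochs, batch 32,
early stopping on a monitored split with patience 10, restoring the best
weights. `search_hyperparams()` samples points uniformly without replacement
from the grid *before* any evaluation (so the sampled set is independent of
how points are scored), fixes a single 80/20 inner split, trains point *i*
with seed `seed + i` (accuracies do not depend on evaluation order), and
scores by inner-validation Pearson correlation. Diverged runs score `NA` and
are excluded, with a logged count. Ties break by fewer parameters, then
earlier sampling. Refitting the winner reuses its search seed; if its
predictions degenerate anyway, the next-ranked point is used.

## Hyperparameter importance

`rf_importance()` regresses inner-validation accuracy on the hyperparameter
values with a random forest (500 trees) and reports mean impurity decrease.
The categorical menu (activation) is one-hot encoded and its per-level
scores summed back into the parent; numeric menus stay numeric. The trait is
not a predictor. `rf_importance_null()` supplies a permutation-null
threshold for judging whether a score is distinguishable from noise.

## The study driver and problem sizes

`run_simulation_study()` chains everything: simulate panel and trait →
random 30% validation split → multi-kernel decomposition on the combined
data (descriptive only, mirroring the design where that stage feeds nothing
downstream) → fit each requested method on training phenotypes only →
validation predictive ability (Pearson correlation). Replicate `r` uses seed
`base_seed + r`; the same panel is shared across architectures, as when
architectures are simulated on one real panel.

Default sizes are a reduced desk scale chosen so a Bayesian-only study runs
in minutes on one core: n = 600, p = 2,000, five replicates, 2,000-cycle
chains (500 burn-in), CNN budget 20. The package's own test suite runs
smaller still (method-ordering checks at n = 350, p = 400, CNN budget 8,
chains 1,200/300) — sizes picked so the full suite stays fast while the
qualitative comparisons remain stable; the full printed-scale settings
(6,000/1,000 chains) are one `study_config()` call away. At the reduced
scale the CNN is handicapped more than the linear models (a few hundred
training individuals is little for ~10⁵ weights), so CNN-vs-linear margins
are noisier than the Bayesian-vs-Bayesian ones; ordering assertions in the
tests are therefore soft (a fixed −0.05 slack on mean-PA margins, with the
observed margins printed).

## Known limitations

* The LD generator is plumbing: no realistic haplotype structure, no
  population stratification, no G×E.
* The autotetraploid dominance coding is a declared stand-in, not a
  canonical published matrix.
* Variance-ratio estimates inherit the usual confounding of weakly
  identified kernels (D and E are nearly diagonal in unstructured panels and
  absorb some share from the residual); parameter-recovery tolerances are
  correspondingly wide.
* Dosage inputs are trusted: no genotype-calling error model, no support for
  odd ploidy, and missing phenotypes must be subset by the caller.
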