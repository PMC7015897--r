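# polyGP

Genomic prediction for polyploid species with allele-dosage genotypes:
Bayesian whole-genome regression, kernel methods, and a small convolutional
network, plus the simulation machinery to compare them under controlled
genetic architectures.

## Who this is for

Breeders and quantitative geneticists working with clonally propagated
polyploids (strawberry, blueberry, potato, sugarcane...) who want to (a)
partition genetic variance into additive, dominance and epistatic
components from dosage data, (b) rank candidates by predicted merit, and
(c) understand when a non-linear predictor (dosage-class dummy models,
Gaussian kernels, CNNs) is worth its complexity over plain additive models.

## The models

With dosages `X` (entries `0..ploidy`) and phenotype `y`:

* **Variance decomposition** — `y = mu 1 + a + d + e + eps` with
  `a ~ N(0, A s2_a)`, `d ~ N(0, D s2_d)`, `e ~ N(0, E s2_e)`, where
  `A = ZZ'/ sum_j m p_j(1-p_j)` (centered dosages `Z`, ploidy `m`), `D` is
  the classical diploid dominance coding (or a digenic `q(4-q)` covariate
  for autotetraploids) and `E = A ⊙ A`. Posterior ratios
  `h2_i = s2_i / (s2_a + s2_d + s2_e + s2_eps)` are reported per Gibbs draw.
* **Whole-genome regression** — `y = mu 1 + X beta + eps` with a common
  normal prior on effects (BRR), a Laplace prior via the Park–Casella scale
  mixture (Bayesian lasso), or BRR on a per-dosage-class dummy expansion
  (BRR-GM) that absorbs arbitrary within-locus effects.
* **RKHS regression** — `g ~ N(0, K s2_g)` with the Gaussian kernel
  `K(x_i, x_k) = exp(-h ||x_i - x_k||^2 / p)`, sampled in the kernel
  eigenbasis.
* **CNN** — conv(width 3, stride 1) → maxpool(3) → dense layers → linear
  output on per-marker standardized dosages, with random search over the
  activation / filters / decay / learning-rate / neurons / layers / dropout
  menus and random-forest importance of those hyperparameters.

All samplers and the CNN trainer are seeded and bitwise reproducible.

## Worked example

```r
library(polyGP)

# a tetraploid panel with 2% missing calls; QC + imputation first
g <- simulate_genotypes(n = 300, p = 1000, ploidy = 4,
                        missing_rate = 0.02, seed = 1)
panel <- impute_mean(filter_markers(g, maf_min = 0.05, missing_max = 0.05))

# a mixed trait (80 additive loci + 60 multiplicative pairs) at H2 = 0.5
arch <- sample_architecture(panel, "mixed", seed = 2)
trait <- simulate_phenotypes(compute_genetic_values(panel, arch),
                             target_H2 = 0.5, seed = 3)
trait
#> <sim_trait> n = 300, residual variance = 19.73, realized H2 = 0.507

# variance decomposition on A / D / E kernels
A <- additive_kernel(panel)
D <- dominance_kernel_tetraploid(panel)
E <- epistasis_kernel(A)
mk <- fit_multikernel(list(a = A, d = D, e = E), trait$phenotypes,
                      gibbs_config(n_iter = 2000, burn_in = 500, seed = 4))
mk$decomposition
#> <variance_decomp> posterior variance ratios
#> # A tibble: 3 × 3
#>   component  mean     sd
#>   <chr>     <dbl>  <dbl>
#> 1 a         0.239 0.0809
#> 2 d         0.167 0.0627
#> 3 e         0.168 0.0814

# train/validate an additive Bayesian model
ids   <- individual_ids(panel)
split <- split_data(ids, "random_fraction", 0.3, seed = 5)
Z     <- additive_design(panel)
fit   <- fit_brr(Z[match(split$training, ids), ],
                 trait$phenotypes[match(split$training, ids)],
                 gibbs_config(seed = 6))
pred  <- predict(fit, Z[match(split$validation, ids), ])
predictive_ability(trait$phenotypes[match(split$validation, ids)], pred)
#> [1] 0.4083629
```

The decomposition attributes roughly a quarter of phenotypic variance to
additive relationships with genuine dominance-like and epistatic shares
(the trait has 60 multiplicative pairs); the purely additive BRR model then
predicts held-out phenotypes with correlation ≈ 0.41 at a broad-sense
heritability of 0.5.

Replicated comparisons across architectures run through one driver:

```r
res <- run_simulation_study(study_config(
  architectures = c("additive", "epistatic"),
  methods = c("BRR", "BRR-GM", "RKHS"), replicates = 5))
summary(res)
autoplot(res)
```

A thin command-line wrapper over the same functions is in
`inst/scripts/polyGP` (subcommands `simulate`, `kernels`, `fit`, `study`,
`importance`).

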