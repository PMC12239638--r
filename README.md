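# morphoquant

Landmark morphometrics and quantitative genetics of two life-history loci
in juvenile Atlantic salmon.

Two genomic regions of large effect, *vgll3* and *six6*, are major
determinants of age at maturity in Atlantic salmon and are under local
selection. morphoquant implements the full analysis needed to ask whether
these loci also shape body morphology in a factorial common-garden
experiment: landmark coordinates in, per-locus contributions to additive
genetic variance out. It is aimed at quantitative geneticists and fish
biologists who want each step of such an analysis as a tested, composable,
tibble-first function rather than a one-off script.

The pipeline:

1. **Landmark I/O and quality control** — TPS and wide-CSV readers, an
   ordered individual filter (fork length < 9 cm, missing genotypes/sex,
   precociously mature males) with an exact audit trail,
   thin-plate-spline imputation of missing landmarks, and exclusion of
   configurations with two or more landmarks deviating more than 4 RMS-SD
   from the consensus.
2. **Generalized Procrustes analysis** — iterative superimposition removing
   translation, unit-centroid-size scaling, and proper SVD rotation;
   centroid size is the usual square root of summed squared distances from
   the centroid.
3. **Trait extraction** — 21 linear and centroid-size traits across three
   body planes, defined in an editable YAML config; bilateral measures are
   averaged, replicates kept for repeatability estimation; Fulton's
   condition factor K = 100·W/L³.
4. **Shape model** — multivariate regression of shape variables on scaled
   length, condition factor, feed, tank, sex, the additive genotype codes
   (0/1/2 for EE/EL/LL) and family, tested term-by-term with type-III SSCP,
   residual-randomization permutations (RRPP), Pillai's trace
   tr[H(H+E)⁻¹], permutation z and p, and 10×-magnified genotype
   displacement vectors.
5. **Animal model** — per-trait linear mixed model
   y = Xβ + u_ID + u_tank + u_animal + e with the additive genetic effect
   covarying as σ²ₐA for the pedigree relationship matrix A (tabular
   recursion; sparse inverse by Henderson's rules), fitted by ML/REML on
   sparse mixed-model equations; Satterthwaite type-III F tests;
   additive-vs-dominance AIC comparisons; length-by-genotype interaction
   checks; composite traits.
6. **Variance decomposition** — h² = V_animal/(V_animal+V_tank+V_ID),
   repeatability R = 100·V_ID/(V_ID+V_error), evolvability I_A = V_A/ȳ²,
   per-locus contributions 100·2pq(β²−se²)/V_A truncated at zero, all with
   medians and 95% CIs from 10,000 draws of the variance components'
   large-sample sampling distribution.
7. **Synthetic data** — a generator reproducing the study's 11-unit
   two-by-two factorial breeding design (44 parents; vgll3 fixed within
   family, six6 segregating), tanks, feed restriction, bimodal lengths,
   replicate measurements and planted exclusions, with a ground-truth
   record attached — so every estimator above is testable against known
   truth.

## Worked example

Simulate the study design, filter, fit the animal model for the synthetic
trait, and decompose its variance:

```r
library(morphoquant)
library(dplyr)

sim   <- simulate_dataset(simulation_config(), seed = 42)
filt  <- filter_individuals(sim$individuals)
filter_audit(filt)
#>   rule          n_removed
#> 1 short_length         68
#> 2 missing_vgll3         2
#> 3 missing_six6         12
#> 4 missing_sex           4
#> 5 mature_male          19

traits <- semi_join(sim$traits, filt, by = c(specimen_id = "id"))
rel    <- additive_relationship_inverse(sim$breeding$pedigree)

fit <- fit_animal_model(traits, "synthetic_trait", relationship = rel,
                        method = "ML")
fit
#> Animal model (ML) for trait synthetic_trait
#>   n = 1544  logLik = 1204.931  AIC = -2387.863
#> Variance components:
#>         id       tank     animal      error
#> 0.01216100 0.00059516 0.00199540 0.00442630
#> Fixed effects:
#>             term estimate       se
#> 1    (Intercept)  1.96781 0.018973
#> 2              L  0.14960 0.006287
#> 3             CF  0.01399 0.004461
#> 4 feedrestricted -0.03805 0.019388
#> 5        sexmale  0.02884 0.008911
#> 6          vgll3 -0.04812 0.009218
#> 7           six6  0.03671 0.007934

full <- fit_animal_model(traits, "synthetic_trait",
                         fixed = ~ L + CF + feed + sex,
                         relationship = rel, method = "REML")
genos <- distinct(traits, specimen_id, vgll3, six6)
decompose_variance(full, fit, genos, trait_mean = mean(traits$value),
                   n_sims = 10000, seed = 1)
#>   trait           statistic     estimate   median    ci_low  ci_high
#> 1 synthetic_trait V_A            0.00617  0.00619  0.00239   0.0100
#> 2 synthetic_trait h2             0.358    0.359    0.153     0.537
#> 3 synthetic_trait I_A            0.00159  0.00160  0.000616  0.00259
#> 4 synthetic_trait repeatability 69.9     69.9     62.8      75.0
#> 5 synthetic_trait pct_VA_vgll3  18.1     18.0     11.1      46.6
#> 6 synthetic_trait pct_VA_six6    9.22     9.18     5.65     23.7
```

Reading the output: the audit reproduces the planted exclusion counts; the
allele-substitution estimates (−0.048 cm for *vgll3*, +0.037 cm for *six6*)
recover the planted effects (−0.05, +0.03) within their standard errors;
repeatability near 70% against a planted 75%; and the loci account for
roughly 18% and 9% of the additive genetic variance of this 2 cm trait.
`run_pipeline()` drives the same stages end to end from a YAML config
(simulated or file-based inputs) and writes the three report tables —
shape MANOVA, per-trait coefficients, variance decomposition — plus an
audit log and a run manifest.

Each fitted object supports `tidy()`, `glance()` and `autoplot()`;
`plot_shape_effects()` draws genotype displacement arrows on the consensus
shape.

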