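---
title: "Methods: landmark morphometrics and quantitative genetics of two life-history loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark morphometrics and quantitative genetics of two life-history loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoquant)
library(dplyr)
```

morphoquant implements an analysis pipeline for a common-garden experiment
on juvenile Atlantic salmon that asks whether two large-effect genomic
regions associated with age at maturity — *vgll3* and *six6* — also shape
body morphology. The pipeline runs from raw landmark coordinates to
quantitative-genetic summaries, and ships a synthetic-data generator that
reproduces the experiment's statistical structure with known ground truth,
so that every stage can be validated end to end without any external data.

## The experimental design the generator emulates

Parents are crossed in eleven 2-by-2 factorial units: each unit has two
males and two females, one of each sex homozygous *vgll3*^EE^ and the other
*vgll3*^LL^, and all four male-by-female crosses are made. This gives 44
parents and 44 full-sib families, and every family carries exactly one
*vgll3* genotype (EE, EL, LE or LL). *six6* is not controlled by the design:
parental *six6* genotypes are drawn in Hardy–Weinberg proportions (default
L-allele frequency 0.3, a configurable placeholder — the realized frequencies
in the source hatchery population are not fixed by the design) and segregate
within families.

Offspring are mixed across 8 rearing tanks; half the tanks get a restricted
feeding regime. Genotypes are coded additively — 0, 1, 2 for EE, EL/LE, LL —
so a unit change is one E-to-L allele substitution.

Generator defaults are chosen to match the study conditions: 21 offspring
per family (924 fish, about 820 after filtering), a bimodal fork-length
distribution with the lower mode at 8 cm so the < 9 cm inclusion rule
removes a known subset, planted missing genotypes and sexes (2 for *vgll3*,
12 for *six6*, 4 for sex) and 19 precociously mature males, 90% of
individuals measured twice, and trait-model truth
$V_\text{animal} = 0.003$, $V_\text{tank} = 0.001$, $V_\text{ID} = 0.012$,
$V_\text{error} = 0.004$ (cm²) with allele-substitution effects
$\beta_{vgll3} = -0.05$ and $\beta_{six6} = 0.03$ cm on a trait with mean
2 cm. These imply a polygenic heritability near 0.19, a repeatability of
75% and locus contributions to additive variance in the tens of percent —
all inside the ranges the study design was built to detect.

What the generator does *not* emulate: real landmark digitisation error is
neither Gaussian nor landmark-independent, growth is not a similarity
transform of a single template, and tank effects in a real hatchery include
husbandry gradients. Passing recovery tests therefore demonstrates the
*estimators* are correct under the stated model, not that the model captures
every feature of real fish.

## Landmark processing

**Input.** Classic TPS files (`LM=`, coordinate pairs, `ID=`, optional
`SCALE=`) and a wide CSV dialect (`id, plane, replicate, x0, y0, ...`), both
with 0-based landmark indices. Missing landmarks are carried as `NA`, never
zero-filled. Three planes are supported: whole body (21 landmarks), small
and large cross-sections (9 and 16).

**Filtering.** `filter_individuals()` applies, in order: fork length
strictly below 9 cm; missing *vgll3*, *six6*, or sex; flagged mature males.
Each removed row is counted under the first rule it fails, so the audit log
sums exactly to the rows removed — this is the invariant the acceptance
suite checks against the generator's planted counts.

**Imputation.** Missing landmarks are imputed by a thin-plate-spline warp of
the consensus shape onto each specimen's observed landmarks
(`impute_missing_landmarks()`). The kernel is $U(r) = r^2 \log r$; the
spline reproduces affine maps exactly, which the tests exploit as an oracle.
At least 3 observed landmarks are required.

**Alignment.** `gpa_align()` performs generalized Procrustes analysis:
centre, scale to unit centroid size, rotate to the running consensus by the
SVD-optimal rotation, iterate until the summed squared deviation from the
consensus changes by less than 1e-8 (at most 100 sweeps). Two choices are
deliberate: rotations are restricted to proper rotations (a reflection would
flip fish chirality), and aligned configurations keep centroid size exactly
1 rather than receiving the extra cos-angle shrink of the alternative
full-Procrustes convention — "normalised for centroid size" is the
convention reported for the study's alignment.

**Outliers.** After alignment, a landmark is an outlier if its Euclidean
deviation from the consensus exceeds 4 times that landmark's root-mean-square
deviation across configurations, and a configuration is excluded only when
two or more of its landmarks are outliers. The RMS reading of "4 SD from the
mean" is the simplest one; since the consensus *is* the mean, the RMS
deviation is the relevant spread. One caveat found in simulation: a grossly
displaced landmark leaks a little of its displacement into the whole
configuration through centring and rotation, so the single-outlier-retained
rule is reliable only when landmark counts are not very small.

## Trait extraction

The 21 traits are distances between landmark pairs, averages of paired
distances (bilateral measures averaged prior to analysis), or centroid
sizes of landmark subsets, computed on the raw (unscaled) coordinates so
values are in cm. Definitions live in a YAML config
(`inst/extdata/trait_definitions.yaml`), not code, because landmark
numbering is a property of the digitisation protocol; the shipped file
transcribes the study's formula table against the package's landmark
template. The printed eye-diameter formula is read as the mean of the
horizontal (2:3) and vertical (4:5) orbit distances. Replicate measurements
are kept as rows; `average_replicates()` collapses them where a model needs
one value per fish. Fulton's condition factor is $K = 100 W / L^3$ (g, cm);
length and condition enter all models centred and scaled to unit sample SD.

## Shape model with residual randomization

`fit_shape_model()` fits $Y = X\beta$ with the aligned coordinates as a
multivariate response and tests each term with type-III (marginal) SSCP
matrices: the effect SSCP is the residual SSCP of the model without the term
minus that of the full model. Significance uses residual randomization
(RRPP): permute the reduced model's residual rows, add them back to its
fitted values, recompute Pillai's trace
$\mathrm{tr}\,[H(H+E)^{-1}]$; $p = (\#\{\text{perm} \ge \text{obs}\}+1)/(B+1)$
with ties counted inclusively (conservative), and the standard deviate
$z = (\text{obs}-\bar{s})/\mathrm{sd}(s)$ on the permutation distribution.
The default $B = 999$ gives the familiar $p$-floor of 0.001. Because shape
variables have rank below $2k$ (alignment removes 4 degrees of freedom),
$H+E$ is singular; Pillai is computed on the non-null subspace through a
symmetric pseudo-inverse.

Two open choices were resolved as follows. The $z$ statistic is computed on
untransformed Pillai values by default, with `z_transform = "log"` available
— the log convention of some permutation software changes $z$ but not $p$,
and the untransformed version is the plainer default. Second, tank and
family enter this model as fixed dummy-coded terms (the study did the same
because its permutation software has no random terms); since feed is
assigned at tank level and *vgll3* is constant within family, the full dummy
design is rank deficient by construction, and `drop_aliased = TRUE` (used by
the pipeline) reproduces the standard behaviour of dropping aliased columns
of later terms so that earlier terms keep their full span.

Genotype shape displacements (`shape_effect_vectors()`) are the predicted
per-landmark displacement for an EE-to-LL substitution (code 0 to 2), other
covariates cancelling by linearity, magnified 10-fold for display as is
conventional for small shape effects.

## The animal model

Each trait is modelled as

$$y = X\beta + u_\text{ID} + u_\text{tank} + u_\text{animal} + e,$$

with fixed effects (intercept, scaled length, scaled condition factor, feed,
sex, *vgll3*, *six6*), i.i.d. individual and tank effects, an additive
genetic effect with covariance $\sigma^2_a A$ for the pedigree relationship
matrix $A$, and replicate-level error. With repeated measurements,
$V_\text{ID}$ and $V_\text{error}$ are separately identified:
$V_\text{error}$ is pure measurement noise and $V_\text{ID}$ the individual
residual.

$A$ is built by the tabular recursion ($A_{ii} = 1 + A_{sd}/2$,
$A_{ij} = (A_{j,s}+A_{j,d})/2$), dense at this scale (~1000 individuals);
its sparse inverse comes from Henderson's rules, which also give
$\log\det A$ for free. Unknown parents are founders, non-inbred and
unrelated — the convention matching hatchery broodstock of unknown ancestry.

Estimation maximises the ML or REML log-likelihood over log-variance
components by bounded quasi-Newton (`nlminb`) with three starts (spread
multiplicatively around an equal-split heuristic) to avoid boundary traps;
convergence is 1e-8 on the relative objective. Each evaluation solves
Henderson's mixed-model equations with a sparse Cholesky factorisation
(CHOLMOD through the Matrix package), reusing the symbolic analysis across
evaluations; the REML criterion adds $\log|X'V^{-1}X|$ via the Schur
complement of the fixed-effect block. The implementation reproduces lme4
log-likelihoods, variance components and standard errors to at least 1e-6
on identity-relationship designs (a test oracle, not a dependency of the
fitter). Components can land on the zero boundary (bounded at 1e-10 times
the phenotypic variance) without failure.

Conventions: ML fits provide coefficients and AICs
($\mathrm{AIC} = -2\ell + 2(p + k_\text{vc})$, variance components counted);
REML provides unbiased variance components. Reference levels are fixed so
reported signs read "ad libitum to restricted", "female to male", "E to L".

**Satterthwaite type-III tests.** For a contrast $c$,
$\nu = 2 v^2 / (g' \Sigma_\theta g)$ with $v = c' \widehat{\mathrm{cov}}(\hat\beta) c$,
$g$ its gradient in the variance components (central finite differences)
and $\Sigma_\theta = 2H^{-1}$ from the finite-difference Hessian of the
$-2\ell$ surface; multi-df terms combine eigencontrast dfs in the usual way.
Finite-difference steps are 1% of each component (0.01 on the log scale for
the Hessian used by the CI sampler) — small enough for quadratic accuracy,
large enough to sit far above solver noise; components at the zero boundary
are excluded from differentiation (their sampling distribution collapses
onto the constraint) and a singular information matrix falls back to
residual df with a warning. With no variance parameters beyond the residual
the df reduce to the exact classical $n - p$.

**Model variants.** `compare_additive_dominance()` refits by ML with the
genotype as a free 3-level factor and as the two constrained dominance
codings (heterozygote = LL, heterozygote = EE), reporting
$\Delta\mathrm{AIC} = \mathrm{AIC}_\text{additive} - \mathrm{AIC}_\text{factor}$
with the conventional support threshold of 2. All three non-additive
parameterisations are reported as a labelled set because the best-supported
dominance direction is itself of interest.
`length_genotype_interaction()` adds L-by-locus terms and reports the
interaction $t$ values together with the shift in the main genetic effects —
the check that locus-trait associations are not mediated by length.
`composite_trait()` builds composite traits as means of z-scored components
(equal weights by default); z-scoring prevents the component with the
largest variance from dominating, which is the natural reading of combining
several related muscle measures into one value.

## Variance decomposition

From the genotype-free REML fit ("full" model): $V_A = V_\text{animal}$,
heritability $h^2 = V_\text{animal}/(V_\text{animal}+V_\text{tank}+V_\text{ID})$
(measurement error deliberately excluded), evolvability
$I_A = V_A/\bar{y}^2$, repeatability
$R = 100\,V_\text{ID}/(V_\text{ID}+V_\text{error})$. From the
genotype-including ML fit: allele-substitution effects and their standard
errors, giving each locus's percent contribution
$100 \cdot 2 p q (\hat\beta^2 - \mathrm{se}^2) / V_A$, truncated at zero.
The $-\mathrm{se}^2$ term corrects the upward sampling bias of $\hat\beta^2$.
The denominator is always the genotype-free $V_\text{animal}$, which is the
total additive variance including what the loci themselves contribute.

**Confidence intervals.** `posterior_ci()` draws 10,000 variance-component
vectors from the large-sample sampling distribution of the fit — Gaussian at
the REML estimates with covariance $2H^{-1}$, truncated at zero — evaluates
the derived statistic on each draw, and reports rank statistics: the 250th
and 9750th order statistics as the 95% interval and the midpoint of the
5000th/5001st as the median. Against the alternative of log-normal draws,
the truncated-natural sampler was chosen after a calibration experiment at
the default design size: its interval widths match the empirical sampling
spread of the estimator almost exactly and its coverage sits near nominal,
whereas log-normal draws over-cover for ratio statistics such as $h^2$. The
simulation approximates a sampling distribution, not a Bayesian posterior;
the interval mechanics (ranked draws) mirror common practice but are not
claimed identical to any particular other implementation. Point estimates
and simulation medians are both reported, since they differ for ratio
statistics.

**A structural caveat for the *vgll3* design.** Because every *vgll3*
heterozygous-by-design family is genotypically uniform, the locus's
trait covariance between full sibs equals its full population variance —
twice what the expected relationship matrix ascribes to full sibs. A
genotype-free animal model therefore absorbs the *vgll3* variance with an
inflation factor, and $V_A$ from that model overstates
$V_\text{poly} + 2pq\beta^2$ for this locus. This is a property of the
breeding design, not of the estimator; the parameter-recovery suite
therefore validates the locus-contribution formula on the *six6*-type
architecture (founders in Hardy–Weinberg proportions, within-family
segregation), where the relationship matrix is correctly specified and
$100\cdot 2pq\beta^2/V_A$ is recovered within Monte-Carlo error, and
validates component unbiasedness on the genotype-including model, where the
locus effects are fixed and $V_\text{animal}$ cleanly estimates the
polygenic variance.

## Problem sizes used by the tests

The test suite exercises the study-scale design (924 offspring before
filtering) for single-fit checks, 50 replicates at full scale for the
parameter-recovery and CI-coverage checks, 80 replicates for the
Hardy–Weinberg locus-contribution check (bias taken as the ratio of
replicate-averaged numerator and denominator, which removes the Jensen
inflation a noisy per-replicate denominator would add), 1,000 pure-noise
datasets of
$n = 60$ with 199 permutations for the type-I-error check, and a
100,000-drop gene-dropping oracle on a 28-individual pedigree for the
relationship matrix. The pipeline's own report tables are generated in the
tests from reduced designs (2–3 factorial units) — the orchestration logic,
not the estimators, is what those tests pin down.

## Known limitations

- Univariate animal models only; genetic correlations between traits are
  not estimated.
- Dominance variance is not modelled (dominance enters only as fixed-effect
  codings in the AIC comparison); additive variance estimates absorb it.
- The CI sampler is a large-sample approximation; at small scale
  (tens of families) it is mildly conservative for ratio statistics.
- The landmark CSV reader expects one plane per file (or uniform landmark
  counts); planes with different landmark counts go in separate files.
- Type-III tests with `drop_aliased = TRUE` are order-dependent for the
  aliased terms themselves, exactly as in the mirrored software behaviour.
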