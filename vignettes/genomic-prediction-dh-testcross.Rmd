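---
title: "Genomic prediction for early-stage DH testcross testing: models, simulator and validation designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for early-stage DH testcross testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a maize doubled-haploid (DH) breeding program, thousands of new fully
homozygous lines arrive every year.  Each line is testcrossed to a tester
from the complementary heterotic group and the testcrosses are evaluated
for grain yield in multi-location trials — the first, and most expensive,
stage of yield testing.  Genomic selection offers a way to skip much of
that phenotyping: genotype every line cheaply with dominant
(presence/absence) sequence-tag markers, train a prediction model on the
lines that were phenotyped, and advance the rest on their genomic
estimated breeding values (GEBVs).

`dhgs` implements the pieces needed to study that strategy end to end:

1. a breeding-program simulator that generates multi-year DH populations
   with realistic full-sib/half-sib overlap between years, dominant
   markers, and replicated multi-environment trial phenotypes;
2. marker handling — minor-allele-frequency (MAF) filtering,
   standardization, and the genomic relationship matrix (GRM);
3. stage-one analysis — incomplete-block mixed models per trial giving
   line BLUPs and broad-sense heritabilities;
4. two Bayesian GBLUP models fitted with the package's own Gibbs sampler —
   a single-environment model and a reaction-norm multi-environment model;
5. the validation designs used to judge such a program: fivefold
   cross-validation, across-year prediction, size-adjusted training sets,
   sibship-partitioned sets, and partial conversion of the testing
   population.

No real dataset ships with the package: the simulator is the data source,
and it is itself a first-class, tested component.

## Models

**Single-environment model (SM).**  Within one environment $i$ (a
year–location combination), the stage-one BLUP $y_{ij}$ of line $j$ is
modelled as

$$y_{ij} = \mu_i + g_j + e_{ij}, \qquad
  \mathbf g \sim \mathrm{MN}(\mathbf 0,\, \mathbf G\,\sigma_g^2), \qquad
  e_{ij} \sim N(0, \sigma_e^2),$$

where $\mathbf G = \mathbf Z \mathbf Z' / p$ is the genomic relationship
matrix built from the $p$ centred and standardized dominant marker
columns.  For a dominant marker the allele frequency is the fraction $f$
of lines carrying the tag; markers with $\min(f, 1-f) < 0.05$ are
discarded beforehand (strictly less than: a marker at exactly 0.05 is
kept).  Standardization uses the sample (n−1) standard deviation, which
gives the clean invariant $\mathrm{tr}(\mathbf G) = n - 1$; the population-sd
alternative would only rescale $\sigma_g^2$.

**Multi-environment reaction-norm model (MM).**  Across environments the
model adds an environment main effect and a genotype-by-environment
interaction whose covariance is the cell-by-cell (Hadamard) product of the
expanded genetic and environmental kernels:

$$y_{ij} = \mu + E_i + g_j + gE_{ij} + e_{ij},$$
$$E_i \sim N(0, \sigma_E^2), \quad
  \mathbf g \sim \mathrm{MN}(\mathbf 0, \mathbf Z_g \mathbf G \mathbf Z_g'\,\sigma_g^2), \quad
  \mathbf{gE} \sim \mathrm{MN}\!\left(\mathbf 0,
    [\mathbf Z_g \mathbf G \mathbf Z_g'] \odot [\mathbf Z_E \mathbf Z_E']\,
    \sigma_{gE}^2\right).$$

**Prediction.**  SM: $\hat\mu_i + \hat g_j$.  MM in an observed
environment: $\hat\mu + \hat E_i + \hat g_j + \widehat{gE}_{ij}$.  For a
line in a year whose trials are absent from training, the environment and
interaction effects are unidentifiable, so the main-effect prediction
$\hat\mu + \hat g_j$ is used — this is the across-year situation.
Accuracy ($r_{MG}$) is always the Pearson correlation between predicted
values and the stage-one BLUPs of the evaluation lines, the only
line-level "observed phenotype" available after the plot data are
adjusted.

## The Gibbs sampler

Both models are fitted by a dedicated Gibbs sampler
(`fit_sm()`, `fit_mm()`):

* **Eigendecomposition parameterization.**  Every Gaussian-process kernel
  is eigendecomposed once and the effect is sampled in its eigenbasis, so
  each coordinate update is univariate (diagonal precision).  On the
  complete line-by-environment grid the two MM kernels inherit their
  eigenstructure from $\mathbf G$ itself
  ($[\mathbf 1\mathbf 1'] \otimes \mathbf G$ and
  $\mathbf I \otimes \mathbf G$ under environment-major ordering), which
  makes the fits fast; the structured operators are verified against the
  dense Hadamard form in the tests.
* **Missing responses.**  Unphenotyped lines (or cells) are carried as
  missing data and re-imputed each sweep from their current conditional
  distribution, so GEBVs come from the joint kernel rather than a post-hoc
  regression.
* **PSD repair.**  Kernels receive $10^{-8}$ diagonal jitter and
  eigenvalues below $10^{-10}$ are truncated; $\mathbf{ZZ}'/p$ on filtered
  dominant markers can be numerically singular.
* **Priors.**  Each variance has a scaled-inverse-$\chi^2$ prior with 5
  degrees of freedom, its scale set so the prior mode of every random term
  accounts for an equal share of half the sample phenotypic variance (the
  conventional default rule of Bayesian GBLUP software).  All variances
  can be pinned (`fixed_var`) — with fixed variances and no missing data
  the posterior mean has a closed form, which is how the sampler is
  validated (correlation > 0.999, RMSE < 0.02 against the closed-form
  GBLUP solution on 50-line instances).
* **Chain presets.**  `"full"` (300 000 samples, 250 000 burn-in, thin
  10) is the full-scale analysis setting; `"test"` (4 000/1 000/5) is the
  desk-scale default; `"quick"` (2 000/500/5) is used inside replicated
  validation schemes, where tens of independent short chains are averaged
  and mixing is fast because every update is diagonal; `"oracle"`
  (20 000/5 000/5) is for closed-form comparisons.  Chains are seeded and
  exactly reproducible.

## Stage-one analysis

Each year–location trial is analysed with the standard α-lattice model:
replicate fixed, incomplete block nested in replicate random, line random,
fitted by REML (via `lme4`).  The across-location analysis of a year adds
the environment main effect (fixed) and the line-by-environment
interaction (random).  Broad-sense heritabilities use the repeatability
forms

$$H^2_{\text{within}} = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_\varepsilon^2 / r},
\qquad
H^2_{\text{across}} = \frac{\sigma_g^2}
 {\sigma_g^2 + \sigma_{gE}^2/n + \sigma_\varepsilon^2/(nr)}.$$

Negative variance estimates are truncated at zero (the REML fit does this
itself) and $H^2$ is computed from the truncated values.  Exactly
noise-free data (every replicate identical) are detected and short-cut to
centred line means, since REML is degenerate there.

## The simulator and what it emulates

`sim_config("reference")` encodes the package's reference study: a
three-year tropical maize DH program at desk scale.

| parameter | default | meaning / why |
|---|---|---|
| `n_populations_per_year` | 40 | many small biparental crosses per year, the granularity of real early-stage programs |
| `lines_per_population` | 1–66, mean 5 | skewed (truncated-geometric) population sizes; ~200 lines/year, ~600 total |
| `n_parents` | 40 | parental pool per year |
| `shared_parent_fraction` | 0.25 | fraction of the parent pool recycled into the next year; puts the adjacent-year line-level sib overlap in the 30–50 % band while years 1 and 3 share almost nothing |
| `shared_cross_fraction` | 0.0625 (= 0.25²) | fraction of crosses repeated verbatim (the chance both parents were kept); across-year **full**-sibs stay rare while **half**-sibs are common, as in real multi-year programs |
| `n_markers` | 1000 | dominant markers on 10 chromosomes of 1.5 Morgan |
| `founder_beta_shape` | 0.75 | Beta(0.75, 0.75) presence-frequency spectrum; ~13 % of markers fall below MAF 0.05, so the filter has realistic work |
| `founder_ld_morgan` | 0.05 | ancestral-LD correlation length: a Gaussian-copula AR(1) process along each chromosome gives nearby tags population-level LD while leaving every marginal frequency exact |
| `n_qtl` | 200 | additive QTL drawn among segregating markers |
| `variance_targets` | g 1, E 2, gE 0.5, e 1.5 | plot-scale components; within-trial plot H² ≈ 0.6, across-location H² ≈ 0.65, inside the moderate-to-high range typical of early-stage yield trials |
| `locations_per_year` | AF/Cot/TL; Cot absent in year 3 | unbalanced multi-location layout the schemes must tolerate |
| `n_reps`, `block_size` | 2, 20 | two replicates, incomplete blocks of 20 plots, block variance 0.25 σe² |

Genetic values are built from QTL effects and rescaled so their sample
variance hits `sigma_g2` exactly; interaction deviations are per-environment
QTL-effect perturbations, double-centred and calibrated on the
$(n-1)(E-1)$ interaction degrees of freedom so both an ANOVA interaction
mean square and the reaction-norm model recover the target.  A zero
target gives an exactly zero surface.  DH meiosis uses Poisson crossover
counts per chromosome with uniform positions — one gamete defines the
line.

The causal loci are *masked* from the observed panel by default
(`observe_qtl = FALSE`): founders are simulated without ancestral LD, so
if the causal tags were genotyped, GBLUP would read their effects
directly and predict even completely unrelated families — the opposite of
how anonymous intergenic tags behave.  With the causal columns hidden,
marker information flows only through cosegregation within and between
related families, which is the regime in which training-set relatedness
matters and the across-year designs are informative.  Testers are assigned per population but contribute no effect:
the reference analysis deliberately excludes tester effects, so simulating
them would only add unmodelled confounding.

What the simulator does **not** emulate: selection during the program
(lines are a random sample of each cross), dominance/epistasis,
genotyping error and missing marker calls, spatial field trends, tester
effects, and genetic trend across years.  Passing tests therefore show
that the methods behave correctly under the stated stochastic model, not
that real-data accuracies will match any particular value.

## Validation designs

All schemes keep training and evaluation line sets disjoint (asserted in
every replicate) and draw per-replicate randomness from streams spawned
off one master seed.

* **Fivefold CV** (`run_cv5`), 50 replications at full scale.  Two units
  are available.  With `unit = "line"` (default) all records of a line
  move between folds together — the right design for the question "how
  well do we predict *untested* lines", and the unit under which SM and MM
  coincide when there is no simulated G×E (a property test).  With
  `unit = "observation"` the response cells are split independently, so a
  testing cell's line may be phenotyped in other environments; this is the
  classical fivefold scheme of multi-environment genomic prediction
  studies, and it is where the reaction-norm model visibly gains by
  borrowing a line's own records across environments.  Replicate accuracy
  is the mean over folds (and environments within folds).
* **Across-year validation** (`run_across_year`): train on one or two
  whole years, predict another year's lines as completely unphenotyped.
* **Size-adjusted training** (`run_size_adjusted`): the two-year pool is
  repeatedly subsampled (30 replicates at full scale) to the size of a
  one-year pool, separating training-set size from environmental
  coverage.
* **Sibship partition** (`run_sibship_partition`): the across-year
  prediction restricted to lines with a shared parent on the other side
  (full- or half-sibs), or to lines with no shared parent; subsets smaller
  than 10 lines on either side are skipped with a notice — exactly the
  situation of distant year pairs with no sib overlap.
* **Partial conversion** (`run_partial_conversion`): two years plus a
  random half of the test year converted into training (resampled every
  replicate; 50 replicates at full scale), evaluated on the untouched
  half.

Because single across-year accuracies are noisy, summary comparisons
(one-year vs two-year training, sibship modes) aggregate over all
train/test year combinations, the way multi-year studies report these
schemes.

## Problem sizes and runtime choices

The packaged tests and the acceptance script run the whole battery at
reduced scale — the reference program (~600 lines, 1000 markers), 500-line
single-year trials for variance-component recovery, 50-line instances for
the closed-form oracle — with the `"quick"`/`"test"` chain presets and a
handful of replicates per scheme.  These sizes are the package's choice of
desk-scale study conditions; the full-scale settings (1500+ lines, 6000+
markers, the `"full"` chain, 30–50 replicates per scheme) are reached by
changing only the configuration, not the code.

## Known limitations

* The MM cannot predict environment-specific performance in a year absent
  from training; it falls back to main-effect GEBVs (flagged above).
* With `unit = "line"` CV and no interaction, MM and SM are redundant;
  the MM's extra variance component is then only weakly identified and
  its posterior mean depends on the family structure of **G** (strong
  eigenvalues are what separate the interaction kernel from the
  residual).
* Stage-one and stage-two are sequential (two-stage analysis); no
  weighting by stage-one precision is carried forward.
* The sampler is single-chain; convergence is monitored through batch-means
  effective sample sizes of the variance draws, which is adequate for the
  diagonal updates used here but no substitute for multi-chain diagnostics
  at full scale.
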