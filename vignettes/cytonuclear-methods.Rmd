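---
title: "Models and methods in cytonuclear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cytonuclear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonuclear)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices made where more than one reasonable convention exists.

## The cytoplasmic effect models

A reciprocal cross pair produces progeny with the same expected nuclear
composition but different maternally inherited cytoplasms (mitochondrial +
chloroplast genomes). Treating cytoplasm class as a two-level factor C
(wild donor vs cultivated), environment as E, and — where nuclear markers
are available — marker genotype as a categorical factor G, the package fits

$$y_{ijk} = \mu + C_i + E_j + (C{\times}E)_{ij} + \varepsilon_{ijk}$$

per population and trait, and the marker-resolved three-way model

$$y_{ijkl} = \mu + G_i + C_j + E_k + (GC)_{ij} + (GE)_{ik} + (CE)_{jk} +
(GCE)_{ijk} + \varepsilon_{ijkl}.$$

Assumptions are those of fixed-effects ANOVA: independent Gaussian residuals
with common variance, and fixed factor levels. Sums of squares are Type III,
computed by full-vs-reduced least-squares comparison in the sum-to-zero
parameterisation: the full design matrix is built with `contr.sum`
contrasts, and each term's SS is the increase in residual SS when exactly
that term's columns are removed while all others (including higher-order
interactions) are retained. On balanced data this coincides with the
sequential (Type I) decomposition; on unbalanced data it is the
marginal-adjustment convention that makes main effects interpretable in the
presence of interactions. Empty design cells make the affected terms
inestimable; `anova_two_way()` treats an empty cytoplasm-by-environment cell
as an error (the design question must be resolved by the analyst), while
`anova_three_way()` — where a rare genotype can empty a cell — reports the
affected terms as undefined with a warning rather than dropping them.

### Effect size, confidence bound and the significance gate

Effect size is total eta squared, $\eta^2 = SS_{term}/SS_{total}$ with
$SS_{total}$ the corrected total sum of squares, i.e. the fraction of total
phenotypic variance attributed to the term. (Partial $\eta^2$ is not used in
any decision rule here.) The lower confidence bound for $\eta^2$ comes from
pivoting the noncentral-F distribution at the observed F: the bound is the
largest noncentrality $\lambda$ with $P(F_{df_1,df_2,\lambda} \le F_{obs})
\ge 0.95$, mapped to the effect-size scale by $\eta^2 = \lambda/(\lambda +
df_1 + df_2 + 1)$. The default interval is one-sided (upper bound 1) because
the decision rule below uses only the lower bound; a central two-sided
interval is available via `ci_two_sided = TRUE`. Numerically, the inversion
brackets $\lambda$ by doubling and finishes with `uniroot` at tolerance
1e-8; the search is capped at $\lambda = 10^6$ (bound $\approx 0.9999$),
beyond which R's noncentral-beta routine loses precision without affecting
any use of the bound.

A term is *significant* only when all three of these hold:

* $p \le 0.05$,
* $\eta^2 \ge 1\%$,
* lower confidence bound for $\eta^2 > 0$.

The gate is deliberately conjunctive: it never passes a term the plain
p-value test would reject, which also makes its null false-positive rate
bounded by the nominal rate by construction. Its magnitude summary is
$\Delta\% = \text{mean over environments of } 100(\mu_{wild} -
\mu_{cult})/\mu_{cult}$, undefined when a cultivated mean is zero.

### Outlier removal and aggregation

Before modelling, univariate outliers are removed within each environment ×
population combination, per trait, by an asymmetric boxplot rule built from
median-split semi-interquartile ranges:

$$\text{lower} = Q_1 - 2k(Q_2 - Q_1), \qquad
  \text{upper} = Q_3 + 2k(Q_3 - Q_2), \qquad k = 1.5 .$$

With symmetric quartiles this reduces to the ordinary $k \cdot IQR$ fence; a
skewed tail widens its own fence, which suits right-skewed agronomic traits.
A zero IQR removes nothing (the degenerate rule), and groups with fewer than
five values are left untouched. The fence formula is isolated in
`remove_outliers_asymmetric()` so an alternative convention can be swapped
in. Fixed-line panels are then aggregated to one mean per line ×
environment × trait; single-plant panels (each individual a unique F2
genotype) are used directly. The same outlier treatment precedes both the
two-way and the three-way models.

### Marker filtering and multiplicity

Markers are screened against the 1:2:1 Mendelian expectation for an F2 by a
$\chi^2$ test with 2 df on non-missing calls, removing markers with
$p < 0.01$. No cross-marker multiple-testing correction is applied in the
scan — the relevant decision rule is the three-condition gate above — but
`gcxe_scan()` reports the number of models fitted so users can judge the
multiplicity themselves.

## The NIRS calibration workflow

Spectra are absorbance (log(1/R)) on a strictly increasing wavelength grid.
Candidate pretreatments: SNV (per-spectrum standardisation), MSC (regression
of each spectrum on a reference — by default the training-set mean — and
correction $(x - a)/b$), polynomial detrending, baseline correction, and
Savitzky–Golay smoothing/derivatives, composable left to right. Derivatives
are scaled by the grid step, so they are per nm regardless of sampling
density. Two conventions had to be fixed where common practice varies: the
detrend polynomial degree defaults to 2, and baseline correction defaults to
per-spectrum minimum subtraction (a linear endpoints fit is the alternative);
both are explicit `pt_*()` parameters.

Spectral outliers are flagged per pretreatment from PCA scores (columns
scaled to unit variance for this purpose; five components by default) using
Mahalanobis distances under a minimum covariance determinant estimate of
location and scatter, thresholded at the empirical 99.5th percentile of the
distances; a sample is a *global* outlier when flagged in at least 75% of
the pretreatments evaluated. The MCD is made deterministic by running
`MASS::cov.rob` under a fixed internal seed with coverage
$h = \lfloor (n + k + 1)/2 \rfloor$, so flags are reproducible run to run.
Wet-chemistry references are cleaned per analyte by the $Q_1 - 1.5\,IQR$ /
$Q_3 + 1.5\,IQR$ rule, replacing outliers with missing values while keeping
the sample's other analytes. All quantile-type thresholds in the package
(IQR fences, outlier percentiles, divergence threshold) use linear
interpolation — sample-quantile type 7, the R default — a convention that
matters at these small n and is therefore stated rather than left implicit.

Representative subsets (e.g. which samples to send for wet chemistry, or a
held-out test set) are chosen by the Kennard–Stone max–min algorithm, by
default on Mahalanobis distances (equivalently, Euclidean distances after
whitening the score covariance). Ties are broken by the lowest sample index,
making selection deterministic.

Calibration itself is PLS1 (NIPALS; coefficients reproduce the classical
result, and at full rank the predictions equal ordinary least squares).
Model size is chosen by repeated cross-validation: five iterations of
5-fold CV with random fold assignment from the seed, RMSEP per candidate
component count on the pooled out-of-fold predictions, standard error as the
sd of per-fold RMSEPs over $\sqrt{folds}$, and the one-sigma rule — the
smallest component count within one SE of the minimum. An explicit override
models the manual scree-plot adjustment and is recorded on the result.
Pretreatments are compared by mean RMSEP and mean Pearson r; r is computed
on the pooled out-of-fold predictions of each iteration and then averaged
(per-fold averaging is the other convention; pooling is less noisy at fold
sizes of ~12). The component count reported per candidate is the one chosen
in the final iteration. A supplementary Kennard–Stone 80/20 train–test split
on the first two PCs of the pretreated spectra provides an independent check
that fold randomness did not drive the comparison.

## Grain traits

Seed-analyzer output that arrives as percentage mass in contiguous bins is
summarised by the interpolated median: the value where cumulative mass first
reaches 50%, assuming linearity within the crossing bin. "First reaches" is
implemented with $\ge$, so a cumulative total hitting exactly 50% at a bin
boundary returns that boundary. Compositional mass traits combine dry matter
$DM = (100 - \text{moisture})/100$ with concentrations (% dry basis):
$Trait_{1000} = TGW \cdot DM \cdot C/100$ (g per 1000 grains) and
$Trait_P = GWP \cdot DM \cdot C/100$ (g per plant), giving Prot1000/Fat1000/
Ash1000 and ProtP/FatP/AshP.

## Phenomics divergence

High-throughput phenotyping yields many strongly redundant traits, so the
divergence analysis first prunes traits greedily in input order, keeping a
trait only if its absolute pairwise-complete Pearson correlation with every
already-kept trait is below 0.95 (vectors pooled over all plants and days).
Input order determines which member of a correlated pair survives; this is
stated because no canonical ordering exists, and `trait_order` makes the
choice explicit. For each kept trait and population, Cohen's d (df-weighted
pooled sd) compares wild vs cultivated cytoplasm per measurement day; the
*weighted effect* is the unweighted mean of per-day d multiplied by the
fraction of days significant in a two-sided pooled-variance t-test at
p < 0.05. The pooled-variance t-test is chosen to match the pooled-sd
convention inside d. Whether the weighting should multiply the mean, the
median, or each day's d before averaging is genuinely open; the mean is
adopted and isolated in `weighted_effect()`. Divergence between two
populations is the absolute difference of their weighted effects —
symmetric by construction — and traits are flagged when divergence strictly
exceeds the empirical 90th percentile (type 7) of all divergences.

## The synthetic-data generators

The generators exist so that every downstream stage has inputs with known
ground truth.

`simulate_reciprocal_f2()` draws marker calls independently from 1:2:1 (or a
configured distorted triple) and builds traits as a grand mean plus
categorical effects plus Gaussian noise. Two choices are worth noting.
First, each term's effect pattern is projected onto its interaction-contrast
subspace (zero sum over every margin) and then rescaled so the *realised*
population variance share equals the target exactly, not merely in
expectation — parameter-recovery tests are much sharper this way. Residual
variation is likewise rescaled to its exact sd. Second, genotype enters the
trait model as a three-level factor at one designated causal marker
(additive dosage coding is available but off by default), matching how the
ANOVA engine treats G. When `residual_sd = 0` the total-variance scale is
set to 1 so pure-effect degenerate cases remain well defined. The defaults
emulate a two-environment reciprocal F2 field panel: balanced reciprocal
halves, two environments, Gaussian residuals (the residual distribution of
field traits is not otherwise specified anywhere, so Gaussian is assumed and
stated). What the generator does *not* emulate: linkage and recombination
between markers (markers are independent), spatial field structure, block
effects, or plant architecture — so passing recovery tests demonstrates
correctness of the estimation machinery, not robustness to linked markers
or spatial correlation in real trials.

`simulate_spectra()` builds absorbance as composition-weighted Gaussian
bands (default grid 400–2500 nm at 0.5 nm, the full instrument range) plus a
polynomial baseline shared by all samples, per-sample affine scatter
(multiplicative and additive), and white noise. Because scatter is affine
per sample, SNV removes it exactly in the noise-free limit — a property the
tests exploit. Real NIR spectra add wavelength-dependent scatter, band
overlap with temperature shifts, and instrument drift; none of these are
modelled, so calibration-recovery results bound what the workflow achieves
under ideal mixture conditions.

`simulate_phenomics()` produces daily trait values in equicorrelated blocks
(one latent factor per plant-day per block) with cytoplasm effects as
constant mean shifts in residual-sd units, plus a common linear growth
trend. Days are conditionally independent given the trend; real phenomics
series have temporally autocorrelated residuals, which would make the
per-day significance weighting less informative than it is here.

`simulate_marvin_bins()` discretises a Gaussian centred on the target median
(sd of one bin width) with mild per-bin perturbation, renormalised to 100% —
enough structure to exercise the interpolation rule and its boundary cases.

## Problem sizes and runtime choices

The shipped tests and the verification script use: 55+ random ANOVA
instances (n = 40–80) for oracle equivalence; 20 simulated populations of
n = 2000 observations for parameter recovery, with 200 null populations of
n = 400 for gate calibration; 200 simulated spectra on the full 4201-point
grid with three candidate pretreatments for calibration recovery; and 100
null phenomics traits (60 plants × 10 days) for the divergence null. These
sizes were chosen to estimate each quantity stably while keeping a full
verification run in the low minutes on a single core; they are stated here
so users scaling up know what the defaults were measured at.

## Known limitations

* Fixed-effects models only: no mixed/spatial models, no stability variance
  or reaction-norm regression; blocks can be added as a covariate but are
  off by default to mirror the stated models.
* Type III inference relies on estimable cells; severely unbalanced marker
  classes in small populations will surface as undefined terms.
* The eta-squared confidence bound uses the fixed-effects noncentral-F
  pivot; it is not corrected for the two-stage nature of outlier removal
  followed by modelling.
* The deterministic MCD (fixed internal seed) trades a little robustness
  optimality for exact reproducibility of outlier flags.
* No cross-marker multiplicity correction is applied anywhere; reported test
  counts are the user's handle on that.
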