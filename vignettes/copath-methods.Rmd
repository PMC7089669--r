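---
title: "Methods: multivariate analysis of regional PET binding in frontotemporal dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate analysis of regional PET binding in frontotemporal dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copath)
```

## The scientific problem

Frontotemporal dementia (FTD) syndromes — behavioural variant (bvFTD),
semantic variant (svPPA) and non-fluent variant (nfvPPA) primary
progressive aphasia — are heterogeneous in both clinic and neuropathology.
Two PET radioligands probe complementary processes: a TSPO ligand indexes
activated microglia (neuroinflammation), and a second ligand indexes
aggregated non-amyloid protein (tau or TDP-43).  Because the second
ligand's affinity differs across protein conformations and patients, the
*magnitude* of its binding potential (BP~ND~) is not comparable between
subjects; the *spatial distribution* of binding across regions is.
`copath` implements a pipeline of four analyses of subjects × regions
BP~ND~ tables (83 regions by default), plus a stereological analysis of
post-mortem section point patterns, and a synthetic-cohort generator that
makes every stage testable without scan data.

## The synthetic cohort generator

No scan data accompany the motivating study, so the generator defines the
study conditions for all calibration and recovery tests.  For subject
$i$ in group $g$ with regions $r = 1 \dots R$:

$$ s_{i r} = \sum_m \big( w_{g m}\,\gamma_i + \zeta_{i m} \big)\, M_{m r},
\qquad
x^{(L)}_{i r} = a_i\,\big(b^{(L)}_r + \beta_L\, s_{i r}\big) +
\varepsilon_{i r}, $$

where $M_m$ are unit-norm spatial modes (a global mode, a temporal-pole
mode and a frontal mode built from the region metadata), $w_{gm}$ are
group amplitudes, $\gamma_i \sim N(1, \sigma_\gamma)$ truncated at zero is
a per-subject severity, $\zeta_{im} \sim N(0, \sigma_\zeta w_{gm})$ is
independent per-mode expression variability, $b^{(L)}$ is a fixed
non-specific baseline per ligand (low temporal, high deep-nuclei, with a
deterministic ripple so no two regions tie), $a_i = e^{N(0,
\sigma_a)}$ is a multiplicative affinity gain, and $\varepsilon$ is
i.i.d. Gaussian regional noise (an AR(1) option along the region ordering
exists to stress-test spatial dependence; default off).  Both ligands
share the same latent field $s$ — their coupling is the planted truth.
Regional grey+white volume falls with pathology
($v_{ir} = v_{0r}(1 - \kappa s_{ir})(1 + \text{noise})$) and the CSF
fraction rises with it, which drives the partial-volume and atrophy
analyses.

Default parameter choices, made once:

* group sizes 15/10/11/10 (control/bvFTD/svPPA/nfvPPA), ages and sex
  ratios per group emulating a published FTD PET cohort;
* $\sigma_a = 0.2$, $\sigma_\gamma = 0.3$, $\sigma_\zeta = 0.3$,
  noise SD $0.05$, $\kappa = 0.15$, CSF slope $0.1$;
* group mode amplitudes (svPPA temporal $0.85$, nfvPPA frontal $0.65$,
  bvFTD frontal $0.70$ with smaller cross-loadings).  No effect sizes for
  group separation are published, so these amplitudes are arbitrary; they
  are calibrated once so that the planted structure is recoverable by the
  pipeline (classifier accuracy, mode recovery) and are not otherwise
  meaningful.

The generator emulates the *statistical* structure the analyses assume —
shared baseline, affinity gains, coupled ligands, atrophy, CSF
contamination — but not image-level effects (scanner resolution, motion,
kinetic-model misfit, genuine anatomical covariance).  Passing tests
therefore validate the machinery, not claims about real scans.

## Analysis 1: regional repeated-measures ANOVA

`rm_anova()` fits a split-plot ANCOVA: region is the $k$-level
within-subject factor, diagnosis the between-subject factor, and age/sex
optional between-subject covariates (mean-centred, so the region main
effect is evaluated at the covariate mean).  It is implemented with
orthonormal within-subject contrasts and Type-III hypothesis SSCPs under
sum-to-zero coding; `car::Anova` on the equivalent multivariate model is
used in the test suite as an independent oracle.  Non-sphericity is
handled by Greenhouse–Geisser correction: with $\Sigma_c$ the error
covariance in contrast space,

$$ \hat\varepsilon = \frac{\operatorname{tr}(\Sigma_c)^2}
{(k-1)\operatorname{tr}(\Sigma_c^2)} \in \left[\tfrac{1}{k-1},\, 1\right], $$

and both numerator and denominator degrees of freedom are scaled by
$\hat\varepsilon$.  `gg_epsilon()` exposes the same quantity for a
double-centred $k \times k$ covariance.  Post hoc maps use Welch
(unequal-variance) two-sample $t$-tests per region — the fractional
degrees of freedom this produces match how such post hocs are
conventionally reported — with Benjamini–Hochberg FDR and Bonferroni
adjustment across the $R$ regions (a pooled-variance option exists).
Partial-volume correction divides each regional value by its grey+white
tissue fraction; in the source study this division is applied upstream of
kinetic modelling, and applying the identical algebraic form at the
regional level is a deliberate simplification.

## Analysis 2: between-ligand coupling

`regional_coupling()` correlates per-region group means of the two
ligands over regions (df $= R-2$), both with and without subtraction of
the control-mean regional profile (`control_adjust()`), because any PET
ligand shows a shared non-specific profile that can inflate raw
correlations.  Atrophy is summarised per region as a Welch $t$ comparing
patient grey+white volumes to controls (`atrophy_tscores()`), and
first-order partial correlations (df $= R-3$) are computed between the
ligands given atrophy, and between each ligand and atrophy given the
other ligand.  The lobe-wise ANCOVA (`lobe_ancova()`) is a robustness
check against the non-specific profile: within one lobe, AV regional
group means are regressed on PK regional group means, diagnosis and their
interaction, the observational unit being the region-within-lobe per
diagnostic group.  This observational unit is inferred from the reported
error degrees of freedom in comparable analyses (e.g. $F(1, 54)$ for a
temporal lobe of 20 regions across three groups: $60 - 6 = 54$); effects
are Type-III $F$ tests with sum-to-zero contrasts.  Whether region means
or subject-level values were the original unit is not fully documented;
the region-level reading is implemented because the df reconstruction
supports it.

## Analysis 3: principal spatial modes

`pca_modes()` performs covariance PCA (column mean-centred, unscaled —
BP~ND~ shares units across regions, and scaling to correlations would
upweight noisy low-variance regions) of the pooled subjects × regions
matrix.  Patients and controls are pooled for the fit, since group tests
compare component *expressions* in a common space; a patients-only fit is
a caller option by subsetting.  Loading signs are fixed so each
component's largest-magnitude element is positive.  Retention follows
Cattell's scree criterion, operationalized as the maximizer of the second
forward difference of the explained-variance curve, with components
strictly before the elbow retained; ties break toward fewer components
with a warning, and a manual override is honoured because elbow placement
is ultimately a judgement call.  `component_group_tests()` reuses the
repeated-measures machinery with component as the within-subject factor
and Welch post hocs per component against controls (FDR over components);
with one retained component it falls back to a one-way ANCOVA with a
warning.

## Analysis 4: affinity-blind classification

This is the core method.  For each ligand, each subject's 83-region
vector is reduced to ranks, and subjects are compared pairwise by
Spearman's $\rho$ (average-rank ties); the dissimilarity is $d = 1 -
\rho \in [0, 2]$.  (The alternative readings of "inverse" of a similarity
matrix — $-\rho$ or $1/\rho$ — do not yield a dissimilarity with a zero
diagonal, so the complement is implemented.)  Because ranks are invariant
to any strictly increasing per-subject transform, every downstream result
is *exactly* invariant to per-subject affinity rescaling — the package's
defining property, and an exact (bit-identity) test, not an approximate
one.

The dissimilarities are embedded in two dimensions by metric MDS under
the squared-stress criterion

$$ S = \sqrt{ \frac{\sum_{i<j} \big(\hat\delta_{ij}^2 - d_{ij}^2\big)^2 }
{ \sum_{i<j} d_{ij}^4 } }, $$

minimized by BFGS with the analytic gradient from a classical-scaling
start plus seeded random restarts (default 8; the best configuration is
kept and the reported stress always equals the stress recomputed from the
returned coordinates).  An all-zero dissimilarity matrix returns a
degenerate all-zero embedding with a warning.

The embedded coordinates feed a stratified 10-fold cross-validated linear
SVM (fixed $C = 1$, no feature scaling; the original hyperparameters are
undocumented, so the simplest fixed choice is used) whose loss is the
pooled misclassification fraction.  Significance comes from a permutation
null: the *same* embedding (the scaling does not depend on labels) is
re-classified under shuffled labels, default 1000 times, and

$$ p = \frac{1 + \#\{\text{null loss} \le \text{observed loss}\}}
{1 + n_\text{perm}}, $$

the add-one rule, so $p$ is never exactly zero (minimum
$1/(n_\text{perm}+1)$, consistent with reporting $p < 0.001$ at 1000
permutations).  Fold assignment is stratified and re-drawn (up to 10
attempts) if any training set lacks a class.  For subjects scanned with
both ligands, `classify_pair(multimodal = TRUE)` standardizes each
ligand's 2-D embedding to unit RMS coordinate scale and concatenates them
into four dimensions; subjects missing a ligand are dropped with a
message.

## Post-mortem stereology

`place_fields()` superimposes a virtual grid of pitch 1875 µm with a
uniformly random origin in $[0, \text{pitch})^2$ (drawn per section) and
centres 125 µm × 125 µm fields of view at grid intersections falling in
grey matter.  `count_fields()` tallies classed points (inclusions,
amoeboid/ramified microglia, macrophages, nuclei) over the fields with
half-open membership so boundary points count once; density is count over
sampled area ($n_\text{FOV} \times 0.015625$ mm²), per mm².  Correlations
between pathology and microglial densities are controlled for atrophy by
partialling out nuclei density.  The generalized linear model
(`pathology_microglia_glm()`) regresses microglial density on pathology
density with region, diagnosis, their interaction, nuclei density, and
subject factors nested within diagnostic group (sum-to-zero deviation
columns scoped to each group); each term is assessed by a Wald chi-square
on its coefficient block.  A Gaussian identity link is the default — the
densities are continuous, with many counts per sample — and companion
fits with amoeboid-only and ramified-only responses test whether the
pathology association is specific to activated (amoeboid) microglia, as
the generator plants.

The simulated density study (`histology_study()`) uses a much denser
grid (pitch 250 µm) than the default stereological parameters so that
the counting error on each density is small relative to between-sample
spread — the regressor (pathology density) is itself an estimate, and
appreciable sampling error in it attenuates the fitted slope — and
includes a between-sample biological-variability term on the amoeboid
intensity; both choices make the Gaussian identity-link model well
specified.  The confidence interval for the pathology slope uses the
$t$ quantile at the residual degrees of freedom (the design spends 26
parameters on 48 samples, so the normal quantile would undercover).
Fields of view are retained only when fully inside the section outline:
a frame straddling the boundary samples empty space and would bias the
density estimate downward.

## Numerical choices and degenerate inputs

* `gg_epsilon` clips to $[1/(k-1), 1]$ and requires symmetry to
  $10^{-8}$ relative tolerance.
* A constant region vector makes Spearman's $\rho$ undefined; the
  offending subject is named in the error.
* Zero variance in both groups flags a region untested rather than
  producing NaN.
* The MDS optimizer uses `reltol = 1e-14` and 500 iterations per start;
  exact embeddings reach stress below $10^{-6}$.
* Permutation seeds are derived deterministically from the master seed
  (`seed + 7919 b` for shuffle $b$), keeping all derived seeds well below
  $2^{31}$ for the seed ranges used here.
* The pipeline writes a manifest with the seed and a config hash but no
  timestamps, so identical runs are byte-identical.

## Problem sizes used in the shipped tests

Simulation-based checks use sizes chosen to keep the full suite
comfortably within a desktop run: null classifier calibration uses 200
datasets of 10+10 subjects × 83 regions at 200 permutations each; signal
recovery uses 50 seeds at 199 permutations; ANOVA type-I calibration uses
500 simulated datasets at 8 regions; histology calibration uses 500
Poisson sections and 100 simulated density studies.  Exact and oracle
checks (rank invariance, BH step-up, partial correlations, grid counts,
MDS embeddability, GG limits) run at small sizes because they are exact.

## Known limitations

* Regions are abstract labels; no images, atlases or kinetic modelling
  are read or fitted, and the shipped 83-region metadata file is a
  synthetic stand-in for a modified Hammers-style parcellation.
* The generator's noise is Gaussian and (by default) independent across
  regions; real PET noise is spatially structured and signal-dependent.
* Classification is strictly pairwise and linear, as in the motivating
  design; multi-class or nonlinear extensions are out of scope.
* Published accuracies, correlations and variance fractions from the
  motivating study derive from undeposited patient data and are not
  reproduction targets; all empirical statements in this vignette are
  computed by the package's own tests and scripts.
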