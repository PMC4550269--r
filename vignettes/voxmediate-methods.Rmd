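---
title: "Methods: gene–brain–trait suppression analysis with voxmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene–brain–trait suppression analysis with voxmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmediate)
```

## The model

voxmediate implements an imaging-genetics mediation pipeline in which a
polygenic **gene score** $X$ (a weighted sum of additively coded genotypes,
$X_i = \sum_j w_j\,c_{ij}$ with codes $c \in \{1,2,3\}$ for major
homozygote / heterozygote / minor homozygote) predicts a personality trait
$Y$ (a 27-item scale total, range 27–189), with voxel-wise **regional
homogeneity** (ReHo) of resting-state BOLD as the candidate mediator $M$ and
gender as a covariate throughout.

ReHo at a voxel is Kendall's coefficient of concordance over the
$3\times3\times3$ neighbourhood:
$$W = \frac{12\sum_i (R_i - \bar R)^2}{K^2 (n^3 - n)},$$
with $K$ member series, $n$ time points, and $R_i$ the cross-series rank sum
at time $i$. $W \in [0,1]$ measures how similarly the neighbouring series
rise and fall.

The structural model is the standard single-mediator path diagram on
standardized variables:
$$M = aX + \varepsilon_M,\qquad Y = c'X + bM + \varepsilon_Y,\qquad
  Y = cX + \varepsilon,$$
(each equation also carrying the gender covariate). OLS on standardized data
gives the algebraic identity $c = c' + ab$, which the code asserts to
machine precision. The indirect effect is $ab$; the quantity reported as the
*suppression ratio* is $100\,ab/c$ — negative when the indirect and direct
effects have opposite signs, i.e. when adjusting for the mediator
*strengthens* the gene–trait association. `classify_effect()` labels a fit
`suppression` (opposite signs, both paths significant), `mediation` (same
signs, both significant) or `none`.

## Voxel-wise scan and multiplicity control

`mediation_scan()` applies a three-step test at every in-mask voxel:
(1) $X \to Y$ once globally, (2) $X \to M_v$ per voxel, (3) $M_v \to Y$
controlling $X$. A voxel is flagged only when all three $p$-values are below
$\alpha = 0.05$; the joint null rate of this intersection is at most
$\alpha^3 = 1.25\times10^{-4}$, which is also the voxel-level threshold fed
to the cluster-extent correction. Per-voxel coefficients are computed by
Frisch–Waugh partialling, which is algebraically identical to refitting the
full regression at each voxel (tested exhaustively on a $4^3$ grid).

Two cluster-extent calibrations are provided, and the pipeline applies the
stricter:

* **Monte-Carlo** (`cluster_threshold_mc`): smooth Gaussian null fields are
  simulated at the estimated smoothness (FFT convolution, empirical
  within-mask standardization, two-sided thresholding at $p_{vox}$,
  connected components at 26-connectivity), and the threshold is the
  smallest extent whose exceedance probability is $\le 0.05$.
* **Permutation** (`cluster_threshold_perm`): the gene score is rebuilt from
  random draws of 10 loci out of the genotyped pool, the full scan is
  re-run, and the 95th-percentile maximum cluster size — the
  $\lceil 0.95 (n_{perm}+1)\rceil$-th order statistic — is the threshold.

Because each voxel's ReHo can relate to the trait in either direction, the
Monte-Carlo simulation thresholds two-sided and clusters positive and
negative excursions separately.

### Numerical and design choices

* **Mask geometry.** The true grey-matter mask of the emulated study is not
  available, so the simulation uses a compact quasi-spherical mask of
  exactly the requested voxel count. A ball minimises surface-to-volume
  ratio, so suprathreshold blobs are truncated less than in a folded
  cortical ribbon; empirically this biases the threshold upward by about one
  voxel (we obtain 9 voxels at the published parameters — 50,296 voxels,
  3 mm grid, FWHM $8.19\times8.15\times7.93$ mm, $p_{vox}=1.25\times10^{-4}$
  — where the ribbon-mask analysis reported 8).
* **Permutation weights.** How the random 10-locus scores were weighted is
  not recorded; the default re-estimates weights by multiple regression of
  the trait on the 10 codes, mirroring how the real score's weights were
  obtained. Unit weights are available (`weight_policy = "unit"`).
* **Connectivity** defaults to 26 (corners touch); 6 and 18 are options. At
  the smoothness levels involved the choice moves the threshold by at most
  one voxel.
* **Tie handling** in Kendall's $W$ uses average ranks with no tie
  correction in the denominator (the convention of the classic resting-state
  toolkits); the tie-corrected denominator is available as a switch.
* **Neighbourhood clipping.** ReHo neighbourhoods are clipped to the mask
  and $K$ adjusted per voxel rather than requiring complete 27-voxel cubes;
  voxels with fewer than two member series get $W = 0$.
* **Demeaning** of ReHo maps subtracts the in-mask mean by default (a
  literal reading of the published step); division by the mean is available
  since both conventions circulate. In subtract mode the transform is affine
  per subject and leaves across-subject voxel correlations unchanged.
* **Filtering** is an ideal rectangular DFT filter with inclusive band
  edges (0.01–0.08 Hz), not a Butterworth design, and is exactly idempotent.
  Nuisance regression (six motion parameters, global/WM/CSF means) runs
  *after* filtering, matching the published stage order, despite the known
  critique that unfiltered regressors can reintroduce frequencies.
* **Global signal** uses the supplied analysis mask by default (whole
  mask = whole brain in the synthetic studies); which mask the original
  analysis used is unstated, so it is configurable.
* **Smoothness estimation** uses the classic per-axis difference-ratio
  estimator $\mathrm{FWHM} = \Delta x\sqrt{-2\ln 2 / \ln(1 - s^2_{diff}/2s^2)}$,
  averaged over maps; axes rougher than white noise report 0. On pure white
  noise the ratio sits at the estimator's boundary, so per-axis estimates
  are bounded below a voxel rather than exactly zero.

## ROI model, bootstrap, validation

`path_model()` fits the standardized equations on the mean ReHo of the
surviving cluster and reports paths, $ab$, the suppression ratio, and the
outcome-equation $R^2$ (the published $R^2$ is treated as this squared
multiple correlation). `bootstrap_paths()` resamples subjects with
replacement (5000 draws by default — the original report gives no count —
with percentile intervals, bias-corrected optional; degenerate resamples
such as single-gender draws are redrawn and counted). `loo_validate()`
refits the *unstandardized* outcome equation with intercept on $n-1$
subjects and predicts the held-out trait score; the summary is the Pearson
correlation between predicted and observed values.

A caution established by simulation in this package's tests: the percentile
CI of the *product* $ab$ is strongly conservative at the complete null
($a=b=0$), covering zero essentially always rather than 95% of the time.
The per-path intervals are calibrated (null coverage ≈ 95%), and at the
package's default non-null effect sizes the $ab$ interval covers the
generating value in well over 90% of replicates.

Cohort descriptives (`describe_phenotype`) use small-sample-corrected
skewness and excess kurtosis (the legacy statistical-package convention;
uncorrected moments are a switch) and the classical one-sample
Kolmogorov–Smirnov statistic against a normal with sample-estimated
parameters, reported as $Z = \sqrt{n}\,D$. With estimated parameters this
$p$ is conservative (the Lilliefors caveat). The gender comparison is a
pooled-variance t-test; published trait statistics for the emulated cohort
include a gender t/p pair that is internally inconsistent for its sample
size, and this package simply reports the standard computation.

## The synthetic-data generator

`synth_config()` fixes the study conditions: $n = 298$ subjects with a
96/298 male fraction (gender ~ Bernoulli(0.322), coded 0/1), standardized
paths $a = -0.176$, $b = 0.139$, $c' = 0.399$, the trait rescaled to mean
122.4, SD 15.77 and clipped to $[27, 189]$ (clipping rate < 1% at the
default residual SDs, asserted in tests), TR 2 s, and a 0.01–0.08 Hz
passband for the coherent signal. Values the emulated design does not pin
down were chosen once as field-plausible and are not tuned: ten scored-locus
minor-allele frequencies spread evenly over 0.10–0.45 and a 98-locus pool
over 0.05–0.50 (common variants typical of candidate-gene panels); signed
weights of order one with mixed signs (only the standardized score enters
the model, so the scale is immaterial); residual SDs 0.98 and 0.90 keeping
latent variances near one; gender effect −0.05 (small, like the cohort's
non-significant gender difference).

The imaging arm couples a planted cluster's temporal coherence to the latent
mediator: in-cluster series are
$\lambda\,s_t + (1-\lambda)\,\eta_{vt}$ with a shared band-limited signal
$s_t$, voxel-private white noise $\eta$, and
$\lambda(M) = \mathrm{logit}^{-1}(kM)$ — monotone, bounded in $(0,1)$, with
$k = 1$ by default so that $\lambda$ spans roughly 0.12–0.88 over $\pm 2$
SD of $M$. Cluster Kendall's $W$ is then monotone in $M$ (verified by
simulation), which is all the downstream scan requires. The generator does
**not** simulate scanner artifacts, slice-timing, spatial misregistration,
anatomical folding, or physiological noise; passing tests therefore
demonstrate the statistical machinery under the assumed causal structure,
not robustness to real acquisition artifacts.

### The reference cohort

The ROI-level per-subject table of the emulated study (gender, gene score,
cluster ReHo, trait) is a supplementary document we cannot redistribute.
`synthetic_s1_cohort()` constructs a synthetic stand-in whose *sample*
moments match every published ROI-level statistic exactly: the required
$4\times4$ correlation matrix (gender, $X$, $M$, $Y$) is solved from the
published $a$, $b$, suppression ratio, $R^2$, and gene–trait correlation,
and imposed exactly through an orthonormal basis and its Cholesky factor.
Only the rotation of the basis is random. Leave-one-out accuracy is *not*
constrained; it emerges at $r \approx 0.37$, close to the published 0.366 —
a useful consistency check, since it depends on the whole covariance
structure rather than any single imposed moment.

## Problem sizes used in validation

The test-suite simulations use sizes chosen to make the statistical checks
sharp while keeping a full run comfortable on one CPU: planted-cluster
recovery at the study's $n = 298$ on a $20^3$ grid with 60 frames, 20
seeded replicates; Monte-Carlo thresholds from 300–1000 simulated fields;
permutation thresholds from 120–250 draws; bootstrap calibrations from
200–500 replicate datasets at 300–500 resamples each. The acceptance script
reproduces the cluster-extent threshold from 1000 fields at the full
published mask size and smoothness.

## Known limitations

* The Monte-Carlo mask is a ball, not a cortical ribbon; thresholds carry a
  ≈ +1 voxel bias (documented above, and covered by the ±1 band used in
  validation).
* The spatial preprocessing that precedes this pipeline (slice timing,
  realignment, normalization, segmentation) is out of scope; volumes are
  assumed already normalized on a common grid.
* Percentile bootstrap inference on $ab$ is conservative near the null; use
  the per-path intervals or the bias-corrected option when testing small
  indirect effects.
* The permutation threshold inherits whatever weight policy is chosen;
  re-estimated weights make random scores mildly overfit the trait, which is
  the conservative direction for the threshold.
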