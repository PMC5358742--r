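---
title: "From canopy images to QTL: the idcpheno methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From canopy images to QTL: the idcpheno methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idcpheno)
```

## The problem

Iron deficiency chlorosis (IDC) in soybean is scored in the field on an
ordinal 1-5 scale: 1 is a uniformly green canopy, intermediate scores show
progressive interveinal yellowing (chlorosis), and 5 shows necrotic (brown)
tissue. Visual rating is slow and rater-dependent, which limits the scale of
the replicated trials that quantitative genetics needs. `idcpheno`
implements an image-based alternative: a top-down RGB photograph of each
plot is reduced to two interpretable features — the percentage of canopy
pixels that are yellow (Y%) and brown (B%) — which are then mapped to an
ordinal score by a hierarchical classifier and to a continuous 0-100
severity index. The machine-derived phenotypes feed a standard
quantitative-genetics chain: line BLUPs, a kinship-aware mixed-model
association scan with FDR control and LD clumping, and RR-BLUP genomic
prediction with optional fixed covariates.

Every stage is testable without field data because the package ships two
synthetic generators with exact ground truth: canopy images with known pixel
fractions, and inbred genotypes with planted QTL and a trait of stated
heritability.

## Image processing

**Segmentation.** Images are converted to HSV (hue in degrees, 0 = red). A
pixel is provisional foreground iff saturation >= `saturation_min` (default
0.15) and hue lies in `keep_hue_ranges` (default 10-160 degrees, brown
through green). Soil is mostly grey (low saturation) and hues outside the
green-brown arc (blue, magenta) are neither plant nor necrosis, so both
rules are cheap and robust. The defaults suit the synthetic soil palette and
typical field imagery but are deliberately configuration-exposed: the right
saturation cut depends on the camera and soil, and should be re-tuned per
campaign.

**Cleanup.** The provisional mask still contains plant-coloured debris.
Connected-component labeling (8-connectivity by default, so diagonally
touching leaf pixels stay joined; 4-connectivity is available) keeps only
the largest component — the canopy — and discards everything smaller. On an
exact area tie the component whose first pixel comes earliest in row-major
scan order wins, a deterministic rule that matters only for pathological
inputs. An empty mask is an error, never a silent all-background result.

**Calibration.** When colour-chart patch means are supplied, a per-channel
affine map (gain and offset by least squares over the 24 patches) is fitted
and applied before segmentation. A full 3x3 colour matrix would need
stronger assumptions about the chart math than the acquisition protocol
fixes; the affine model corrects the dominant illumination drift and
degrades gracefully (identity per channel) on degenerate charts.

**Features.** Within the final mask, Y% and B% are pixel-count percentages
of the yellow band (40-70 degrees) and brown band (10-40 degrees); green is
70-160. Bands are half-open `[lo, hi)` so boundary hues are counted exactly
once. Masked pixels falling in no band count toward the denominator only,
keeping Y% + B% <= 100.

## Classification and severity

**Hierarchical classifier.** Scores are grouped into LOW = {1,2},
MEDIUM = {3}, HIGH = {4,5}. Level 1 assigns a group from (B%, Y%) with
pairwise linear SVMs (majority vote, ties to the lowest group index);
level 2 separates 1 from 2 inside LOW and 4 from 5 inside HIGH with binary
linear SVMs, while MEDIUM routes deterministically to 3. Features are
z-scored with training statistics before fitting, the standard practice for
margin methods whose solution is not scale-invariant. We use pairwise rather
than one-vs-rest coupling at level 1 because the MEDIUM band lies between
LOW and HIGH in feature space: a single hyperplane cannot isolate the middle
class from both sides, and in testing the uncalibrated one-vs-rest margins
misranked clearly-HIGH points, whereas every pairwise subproblem is linearly
separable. The SVM cost defaults to 1 and is exposed; on separable fixtures
a large cost approximates the hard-margin limit.

**Severity.** The continuous index is
`clip(w1 * B% + w2 * Y%, 0, 100)` with `w1 >= w2 >= 0`. Clipping rather than
normalising enforces both anchors — severity(0,0) = 0 and heavy necrosis at
100 — without an extra scale parameter, with `w1` fixed at 1 so the brown
axis carries the anchor. Fitting searches `w2/w1` on a 0.01 grid; for each
candidate, the four cutpoints that read severity bands as scores are chosen
to minimise training misclassification by an exact dynamic program over
blocks of tied severity values (a threshold cannot separate ties, so
candidate boundaries sit only between distinct values). The DP is
equivalent to exhaustive midpoint search and is verified against a
brute-force oracle in the tests. Nonnegative weights make severity monotone
in both features, which yields the within-class ordering one wants from a
severity index; on labeled fixtures the class-mean severity increases
strictly from score 1 to 5.

## Synthetic canopies

`generate_canopy()` draws a connected canopy (a central disc plus
overlapping leaflet discs) over a low-chroma soil texture, assigns exactly
`round(frac * n_canopy)` pixels to the yellow and brown generator bands
(the remainder green), and optionally scatters small plant-coloured debris
blobs disjoint from the canopy. Three choices make ground truth exact
rather than approximate:

* generator hue bands sit ~4 degrees inside the extraction bands, so 8-bit
  quantisation cannot move a pixel across a band edge — feature extraction
  is exact on these images;
* soil tones keep saturation below 0.12 even after the per-pixel brightness
  offset, so the default 0.15 threshold removes soil by construction;
* debris is painted with green hues and placed with a one-pixel clearance,
  so it survives thresholding (as real debris does) but can never 8-connect
  to the canopy, making largest-component cleanup the stage under test.

Illumination jitter scales pixel value only (default range 0.9-1.1), which
leaves hue and saturation — hence the features — untouched.

The labeled image sets used in tests draw per-class (Y%, B%) clusters whose
adjacent class centres are about five within-class standard deviations
apart, and label each image from its *true* fractions with a fixed
generative rule (score 1: Y<5, B<1; 2: 5<=Y<25, B<2; 3: 25<=Y<50, B<5;
4: Y>=50 or 5<=B<15; 5: B>=15). These cutoffs are fixture parameters of the
simulation, not estimates from field data. What passing tests show is that
the pipeline recovers planted colour fractions and separable class
structure; they cannot show robustness to shadows, specular leaves,
overlapping plots, stunting (which distinguishes field score 4 and is
invisible to a single top-down colour image), or colour casts beyond the
affine calibration model.

## Synthetic genotypes and phenotypes

`simulate_genotypes()` emits homozygous 0/2 dosages for fully inbred lines
(the 0/2 coding keeps the VanRaden formulas in their standard form). Local
LD follows a latent Gaussian AR(1) along each chromosome: a line's latent
value has adjacent-SNP correlation `ld_rho` and is thresholded at each
SNP's allele frequency. This keeps marginal MAFs exact (drawn from
`maf_range`, default 0.1-0.5) while dosage correlation is monotone in
`ld_rho` though attenuated by dichotomisation; the default `ld_rho = 0.9`
gives adjacent dosage r^2 around 0.5, comfortably exercising the r^2 > 0.2
clumping rule. A direct allele-copying chain was rejected because it
distorts marginal frequencies when they vary along the chromosome. There is
no recombination-map or coalescent realism, and no population structure —
deliberately, since the association model is run without principal
components.

`simulate_phenotypes()` builds line genetic values as planted-QTL
contributions plus a marker-based polygenic term (small effects on every
non-QTL SNP, hence automatically kinship-correlated), then emits
`line x rep` records with a common block effect and i.i.d. residuals. The
residual variance is derived so the line-mean heritability
`Vg / (Vg + Ve/n_reps)` equals the architecture's `h2` (default 0.7,
with 4 replications — the intermediate heritability and replication level
typical of IDC trials). A QTL given as `r2` gets the effect size that makes
it explain that fraction of line-mean phenotypic variance, which requires
`r2 <= h2`; violating this raises an "unreachable heritability" error. The
SPAD-like surrogate is a line-level linear function of the genetic value
plus matched noise at the configured correlation (default -0.6: more
chlorosis, less chlorophyll).

## Mixed-model association scan

Replicated records are aggregated to line BLUPs with
`value ~ (1|line) + (1|rep)` fitted by REML (lme4); BLUPs shrink line means
toward the grand mean by `r*sg2 / (r*sg2 + se2)` in the balanced case.
Kinship is VanRaden's `K = WW' / (2 sum p(1-p))` on frequency-centred
dosages, excluding monomorphic SNPs.

The null model `y = mu + u + e` with `Var(u) = Vg * 2K`, `Var(e) = Ve * I`
is fitted by REML on the spectral decomposition of `2K`, profiling the
variance ratio `delta = Ve/Vg` over a log grid followed by local
refinement. When the likelihood is flat in `delta` (e.g. `K` proportional
to the identity, where the two components are not separately identifiable)
ties break toward the largest `delta`, attributing the variance to noise —
the conservative choice for downstream testing. The per-marker scan holds
the covariance *shape* `Vg*2K + Ve*I` fixed (population parameters
previously determined) and re-estimates only the residual scale per marker,
so each test is a GLS t-test with n-2 degrees of freedom that reduces
*exactly* to ordinary least squares when `Vg = 0` and `K` is
identity-proportional — an oracle the tests exercise to 1e-10. Per-SNP
variance explained is reported as the R^2 of the plain linear model of the
trait on that SNP, separate from the mixed-model test. A numerically
constant response (which a zero line-variance BLUP fit produces) yields
p = 1 everywhere with a warning rather than tests on floating-point noise.

Significance is Benjamini-Hochberg FDR at 0.05; significant SNPs are
clumped greedily — lowest p becomes a peak, same-chromosome SNPs with
r^2 > 0.2 to the peak join it, repeat — so reported QTL peaks are pairwise
unlinked or on different chromosomes. Cross-chromosome merging is never
allowed. The two-locus phase summary classifies each inbred line as
coupling (both favorable or both unfavorable alleles) or repulsion, and
counts favorable-favorable carriers.

Treating the ordinal 1-5 machine score as a continuous response in the BLUP
and mixed-model stages is a documented simplification; the severity index
is continuous by construction and needs no such caveat.

## RR-BLUP genomic prediction

`fit_rrblup()` solves `y = X b + Z u + e` with `Var(u) = su2 * I` on the
column-centred dosage matrix `Z`. The variance ratio `lambda = se2/su2` is
estimated by the same spectral REML machinery applied to `ZZ'` (the search
grid is centred on the mean nonzero eigenvalue, since the spectrum scale
depends on marker count); with `lambda` fixed the solution is the exact
closed form `u = Z'(ZZ' + lambda I)^{-1}(y - Xb)`, verified against a dense
mixed-model-equations solve to 1e-8 and against the GBLUP identity
(`Zu` equals genomic values under the `ZZ'` relationship) to 1e-6.

Fixed covariates — the dosage of a GWAS-identified major QTL and/or the
SPAD surrogate — enter `X` alongside the intercept; a rank-deficient `X` is
rejected naming the collinear columns. In k-fold cross-validation (default
k = 10, folds by seeded shuffle, no stratification) the held-out lines'
fixed covariates are used at prediction time. Both are observable without
the phenotype being predicted — the QTL genotype from the marker data, SPAD
from a meter reading — but this choice does inflate accuracy relative to
genotype-only prediction and is therefore stated prominently. The reported
accuracy is the Pearson correlation between observed values and pooled
out-of-fold predictions. Note that under a null signal this pooled
correlation is biased negative (fold-specific training means anti-correlate
with held-out deviations), so null calibration checks use the mean of
per-fold correlations, whose null expectation is zero. The peak SNP used as
a fixed covariate is selected once from the full-data scan by default,
matching the analysis workflow this package models; per-fold re-selection
would avoid the associated selection leakage at the cost of a scan per fold
and can be done by calling the scan on each training fold explicitly.

## Problem sizes and numerical choices

The package's own validation (tests and the acceptance script) uses
synthetic panels sized to make the statistical properties sharp while
staying light: 80x96-pixel canopies (1,000 images for classifier checks),
400 lines x 2,000 SNPs over 4 chromosomes for QTL recovery with a planted
9%-variance QTL at h2 = 0.7 (20 replicates, with matched no-QTL null
panels), and 240 lines x 1,200 SNPs for the three-model genomic-prediction
comparison with a 10%-variance QTL and a 0.6-correlated surrogate. REML
uses an 81-121 point log-grid plus `optimize()` refinement (tolerance
1e-8); eigenvalues are floored at zero; the severity grid step is 0.01 in
`w2/w1`; cutpoints are kept strictly increasing inside (0, 100) by an
epsilon nudge when optimal bands are empty.

## Known limitations

* Colour is the only cue: stunting and interveinal patterning, which help
  field raters distinguish adjacent scores, are not represented.
* The affine chart calibration cannot correct channel cross-talk.
* LD is first-order; long-range LD and structure are absent, so the
  clumping behaviour on real panels with complex LD is only partially
  exercised.
* The mixed model treats ordinal scores as Gaussian; a threshold model
  would be more principled for heavily unbalanced score distributions.
* Accuracy with fixed covariates assumes those covariates are measured for
  prediction candidates; prediction of wholly unphenotyped, unmeasured
  lines should use the random-only model.
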