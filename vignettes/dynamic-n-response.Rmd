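---
title: "Dissecting nitrogen response in wheat: models and methods"
author: "wheatNRES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting nitrogen response in wheat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatNRES)
```

## The problem

Nitrogen (N) responsiveness — the degree to which a wheat variety converts
additional N fertilizer into yield — is usually assessed from snapshots of
canopy traits at a few time points. That misses the dynamics: after a
jointing-stage fertilization, varieties diverge over a roughly 25-day
window, and *how fast* a trait changes in that window carries more
information than *where* it sits on any single day. `wheatNRES` implements
a complete desk-scale pipeline for this dissection:

1. extract six plot-level canopy traits from aerial rasters;
2. fit seasonal **profile curves** to sparse flight-day observations;
3. restrict each curve to the post-fertilization **response window** and
   summarize it as five-day **compound growth rates (CGR)**;
4. score varieties on twelve postharvest yield/N indices via PCA
   (**NECS**) and classify them into four responsiveness quadrants;
5. predict the quadrant from CGR features with a weighted random forest
   (**RF-NRES**);
6. contrast **static** (time-point) and **dynamic** (CGR) phenotypes in
   single-marker GLM association scans.

Because the original field, image and genotype data are not deposited,
the package ships a first-class synthetic-trial generator that reproduces
the study's statistical structure with planted ground truth, so every
stage is testable end to end.

## Trait extraction from plot rasters

A `PlotRaster` holds an RGB reflectance array in $[0,1]$ and an optional
canopy height model (CHM) in meters (0–1.2 m scale). Six traits are
computed:

* **canopy coverage** — fraction of vegetation pixels. Vegetation is
  segmented by Otsu autothresholding of the excess-green transform
  $ExG = 2G - R - B$. Plain Otsu always splits an image in two, so an
  all-soil or all-canopy plot would be cut in half; we therefore use
  Otsu's separability statistic $\eta = \sigma_B^2/\sigma_T^2$ and fall
  back to a fixed greenness floor ($ExG > 0.05$) when $\eta < 0.8$. A
  unimodal Gaussian image has $\eta \approx 2/\pi \approx 0.64$ while a
  genuine soil/canopy mixture scores near 1, so the cut sits safely
  between the two regimes.
* **VARI** $=(G-R)/(G+R-B)$ and **NDYI** $=(G-B)/(G+B)$, averaged over
  vegetation pixels (greenness and flowering/senescence yellowness).
  Pixels with $|$denominator$| < 10^{-9}$ are excluded; whether indices
  are averaged over vegetation-only or all pixels is not standardized in
  aerial phenotyping platforms, so vegetation-only is the default with a
  `maskAll` switch.
* **ASM** — the angular second moment $\sum_{ij} p(i,j)^2$ of a
  symmetric, normalized gray-level co-occurrence matrix: 8 gray levels,
  offsets $\{(0,1),(1,0)\}$ (the smallest rotation-balanced setting),
  averaged over offsets. Constant canopies give 1.
* **plant height** — the 95th percentile of the CHM over the vegetation
  mask, matching how plot-level height is usually read off a CHM without
  being dominated by single noisy pixels.
* **3DCI proxy** — the published 3D Canopy Index measures canopy spatial
  structure, but its exact formula lives in platform internals we do not
  reproduce. We implement a documented proxy, $1 - \mathrm{CV}$ of
  masked height (population CV, clipped to $[0,1]$), behind a stable
  interface so a faithful definition can be swapped in. Higher = more
  uniform canopy, which is the property the downstream analysis uses.

## Profile curves

Each variety × treatment × trait series (10 flight days, replicate
means) is fitted with the family that matches its seasonal shape:

| family | closed form | traits | parameters |
|---|---|---|---|
| Gaussian | $a\,e^{-(x-b)^2/2c^2}$ | height, 3DCI, VARI | amplitude $a$, peak day $b$, spread $c$ |
| Weibull | $L(1-e^{-(x/x_0)^b})$ | coverage | plateau $L$, scale day $x_0$, shape $b$ |
| Fourier | $\sum_{n\le u} a_n\cos\frac{n\pi x}{L}+b_n\sin\frac{n\pi x}{L}$ | ASM, NDYI | order $u$, half-period $L$, coefficients |

Numerical choices:

* Gaussian/Weibull fits use Levenberg–Marquardt nonlinear least squares
  (`minpack.lm`), tolerance $10^{-10}$ on the cost, at most 5000
  evaluations per start, with data-driven initial values
  ($a_0=\max y$, $b_0=\arg\max$, $c_0=$ range$/4$; $L_0=\max y$,
  $x_{0,0}=$ day at half-max, $b_0=2$) and five multiplicatively
  jittered restarts, keeping the best RSS.
* The Fourier fit is linear in its coefficients once $L$ is fixed to the
  DAS span of the data, and is solved by minimum-norm least squares via
  the SVD pseudoinverse. A conventional order of $u=6$ (one harmonic per
  key growth stage) implies 12 coefficients, more than the 10 flight
  days, so the default order is capped at $\lfloor (n-2)/2\rfloor$; the
  pseudoinverse keeps even an order-inflated basis well-behaved.
* Family selection (`selectFamily`) ranks candidate fits by least-squares
  AIC with an RMSE tiebreak; the per-trait default mapping above is the
  recommended override for production runs.
* Fits are per variety × treatment × season on replicate means; a
  `byPlot` flag fits individual plots instead. Per-season fitting is the
  default because pooling seasons would mix different sowing calendars.

Collections of curves are summarized by pointwise empirical percentile
bands (e.g. 15th–85th), the representation behind seasonal ribbon plots.

## The response window and CGR

The jointing fertilization lands at 130 days after sowing (DAS) by
default; day $d$ after fertilization (DAF) maps to DAS $129+d$, so the
25-day window spans 130–154 DAS and splits into five 5-day sections
(1–5, …, 21–25 DAF). Under this convention adjacent sections do **not**
share endpoints; the compound growth rate over a section starting at
DAF $i$ is

$$\mathrm{CGR} = \left(\frac{f(x_{i+4})}{f(x_i)}\right)^{1/5} - 1,$$

the compound daily rate carrying the curve from the section's first day
to its last. A constant curve gives 0 and a doubling gives
$2^{1/5}-1 \approx 0.1487$. Non-positive curve values at either endpoint
raise an error rather than being clamped: all six traits are
non-negative, so a non-positive fitted value signals a failed fit, and
silently clipping would fabricate rates. Key response phases are flagged
where the absolute group-mean CGR reaches 1 %/day (a display threshold
the analysis exposes as a parameter; the ±15 % pseudo-color bins of the
CGR heat map are display-only).

## NECS and the four quadrants

Twelve postharvest indices — six yield-production (spike number, grains
per spike, thousand-grain weight, aboveground biomass, straw biomass,
grain yield) and six N-utilization (N in biomass, N in straw, grain N
content, NUE, NUpE, NHI) — are z-standardized per treatment and
decomposed by PCA on their correlation structure. Components are
sign-oriented so the grain-yield loading is non-negative (PCA signs are
arbitrary, the composite is not). The smallest $k$ whose cumulative
contribution rate reaches 85 % is retained, and

$$\mathrm{NECS}_i = \sum_{j \le k} \lambda_j\, PC_{ij},$$

with $\lambda_j$ the contribution rates as fractions. Index weights are
contribution-weighted absolute loadings, normalized to 1.

A single scalar cannot place varieties in four quadrants, so the
quadrant model uses two explicit composite axes: the mean z-score of the
six yield indices and of the six N indices. "High" means at or above the
cohort mean (ties to High), giving HYHN / LYHN / LYLN / HYLN. The NECS
ranking is kept separately. Whether the published two-axis scatter uses
PCA sub-scores or raw composite means is not stated anywhere we could
verify; the composite-mean choice is documented as ours. Consistent
performers are the set intersection of a group's membership across the
three N treatments; on the packaged published lists this yields the six
HYHN and five LYLN overlap varieties.

## RF-NRES

The classifier consumes the 30 CGR features (6 traits × 5 sections).
PCA compound weights are computed exactly as for NECS (retained
components at 85 % CCR, contribution-weighted absolute loadings; trait
weights are the sums of their five section weights). "Using the weights
as hyperparameters" is not a defined operation in any RF library, so two
concrete mechanisms are exposed:

* **sampling** (default): the per-feature weights become the
  split-candidate sampling probabilities at every node
  (`ranger::ranger(split.select.weights = ...)`);
* **scaling** (fallback): features are multiplied by their weights
  before training, which biases nothing in tree induction but preserves
  the weighting for distance-free learners.

The forest uses 26 trees of maximum depth 16. Data are split into
stratified training/testing/verification sets (70/20/10); classes are
balanced *in the training split only* by bootstrap oversampling with 2 %
multiplicative jitter. (Published evaluation-set sizes for this kind of
design imply the evaluation sets were augmented too; we deliberately do
not, since augmented test sets overstate accuracy.) The report carries
overall, per-class and verification accuracy, a MAPE on one-hot class
probabilities (with the denominator floored at 0.5 so absent classes do
not divide by zero — the basis of the published MAPE is unstated), and a
5-fold stratified CV accuracy. Baselines (SVM, naive Bayes, k-NN, a
compact SAMME AdaBoost on depth-2 trees, XGBoost, plain RF) are compared
on identical stratified splits.

## GWAS on static vs dynamic phenotypes

Markers are QC-filtered (missingness > 10 % or MAF < 5 % removed,
computed on non-missing calls). Population structure is estimated by
genotype PCA (mean-imputed, centered): the leading $k-1$ axes are the Q
covariates and k-means on those axes gives hard subgroup assignments —
a deterministic, desk-scale stand-in for Bayesian admixture estimation
whose output drops directly into the association model. The association
model itself is ordinary least squares per marker,

$$y = \mu + \beta g + Q\gamma + \varepsilon,$$

with $g$ the 0/1/2 minor-allele dosage (mean-imputed per marker) and the
genotype term tested by its t statistic (equivalent to the partial F
test). Significant markers use the conventional $P < 10^{-5}$ threshold
and, when multiple seasons are scanned, must pass in every season; a
Bonferroni option exists but is off by default, mirroring common
practice for small panels. Candidate genes are annotation intervals
overlapping ±500 kb around a hit on the same chromosome (interval
overlap, not midpoint distance — the same semantics as `bedtools
window`). Static phenotypes are curve evaluations at DAF 5/10/15/20/25
(a raw-interpolation flag is deliberately not needed because curve
evaluation is exact on noiseless fits); dynamic phenotypes are the five
section CGRs.

## What the synthetic generator emulates — and what it does not

`generateTrial()` reproduces the trial's structure: 54 varieties × 3 N
treatments (0/180/270 kg N ha⁻¹) × 3 replicates = 486 plots, observed at
10 flight days between 30 and 196 DAS (including 130 and 154). Each
variety draws noiseless generating curves from the same families the
fits assume (so fitting is well-specified by construction; a family
mismatch can be injected by fitting a non-default family). The treatment
response multiplies the post-fertilization increment of the curve by
$1 + \beta\,(N/N_{max})\,s_v$, with $\beta = 0.6$ and $s_v$ the
variety's latent responsiveness score in $[0,1]$ — zero effect before
fertilization, ordering N270 ≥ N180 ≥ N0 for height and coverage by
construction, and a negative direction for NDYI (more N delays
senescence). Observation noise is Gaussian and homoscedastic per trait
(defaults 0.01–0.02 in trait units, chosen as a realistic few-percent
measurement error for drone-derived traits; the source study reports no
noise magnitudes, so these are free parameters of the emulation).

`generateYNTable()` draws two latent axes (yield potential, N
utilization) per variety and emits the twelve indices as positive-loading
affine functions of the axes plus noise, at agronomically plausible
scales (e.g. grain yield ≈ 600 g m⁻²). Planted labels are derived from
the realized latents *relative to the cohort mean* — the same threshold
the quadrant rule uses — so requested group proportions are approximate
targets, and at zero noise the downstream classification recovers the
planted labels exactly.

`generateGenotypes()` uses a Balding–Nichols model (ancestral frequency
uniform on the MAF range, subpopulation frequencies Beta-distributed
with differentiation parameter $F_{st}$, default 0.15 across 3
subpopulations) at a reduced scale of ~10³ markers standing in for a
~44 K array. Causal markers are planted at common frequency (MAF ≥ 0.2)
and act additively on a designated (trait, section) CGR via
`attachCausalEffects()` — never on static phenotypes, which is what
makes the static/dynamic contrast testable. The planted "large effect"
used in the power checks is 2 phenotypic SD per allele.

What the generator does **not** emulate: spatial field heterogeneity and
plot neighbor effects, weather-driven season differences, linkage
disequilibrium structure along chromosomes (markers are exchangeable
within subpopulation), genotype × environment interaction, and family
mismatch between trait dynamics and the fitted curves. Passing tests
therefore demonstrate internal correctness and statistical behaviour of
the machinery under the stated model, not performance on real field
data.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale by design:
full 486-plot trials for cardinality and ordering checks; 10–20 seeded
replicates for noisy-recovery, calibration and power summaries;
2 000 null association tests for type-I error; 10 000 for the
uniformity check; forests of 26 trees throughout. All stochastic steps
are seeded (generators take explicit seeds; the pipeline driver derives
a per-stage seed from the configuration), so every artifact is
bit-reproducible.

## Known limitations

* The 3DCI proxy is a height-uniformity measure, not the platform's
  published index; treat absolute 3DCI values as package-specific.
* The Fourier family with a fixed half-period is a smoother, not a
  periodic model; extrapolation beyond the fitted season is meaningless
  (and flagged).
* The GLM scan assumes homoscedastic Gaussian residuals; no kinship
  matrix is fitted, so close relatedness beyond the Q axes would inflate
  test statistics.
* Accuracies printed for RF-NRES on synthetic trials characterize the
  synthetic conditions only; headline accuracies from the original field
  data are not reproducible without that data and are not targeted.
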