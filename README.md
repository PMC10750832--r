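# wheatNRES

Dynamic phenotypic analysis of nitrogen (N) response in winter wheat.

Breeders assessing N responsiveness — N-dependent yield increase — need
more than snapshots of canopy traits: after a jointing-stage N
fertilization, varieties diverge over a ~25-day window, and the *rate*
of change in that window is the informative phenotype. `wheatNRES`
implements the full dissection pipeline for plot-based aerial
phenotyping trials:

* **Trait extraction** — six plot-level traits from RGB + canopy-height
  rasters: plant height (95th-percentile CHM), canopy coverage (Otsu on
  excess-green), VARI, NDYI, GLCM angular second moment (ASM), and a 3D
  canopy-structure proxy.
* **Profile curves** — per variety × treatment × trait fits of the
  seasonal trajectory from ~10 flight days: Gaussian
  `a·exp(−(x−b)²/2c²)` for peaked traits, Weibull `L(1−exp(−(x/x₀)^b))`
  for saturating coverage, and a fixed-period Fourier series for
  rise-then-fall textural/spectral traits; AIC-based family selection
  and percentile bands.
* **CGR dynamics** — restriction of each curve to the 1–25 DAF response
  window (130–154 DAS) and five-day compound growth rates
  `CGR = (f(x_{i+4})/f(x_i))^{1/5} − 1` assembled into the CGR
  performance matrix, with key-phase flagging.
* **NECS & quadrants** — PCA of twelve yield/N-utilization indices,
  N efficiency comprehensive scores `NECS_i = Σ_j λ_j·PC_ij` over the
  components reaching 85 % cumulative contribution, and a two-axis
  quadrant classification into HYHN/LYHN/LYLN/HYLN with cross-treatment
  consistent performers.
* **RF-NRES** — a weighted random forest (26 trees, depth 16) predicting
  the quadrant from the 30 CGR features, with PCA compound weights used
  as split-candidate sampling probabilities, plus SVM / naive Bayes /
  k-NN / AdaBoost / XGBoost / plain-RF baselines.
* **GWAS** — marker QC (missingness > 10 %, MAF < 5 %), genotype-PCA +
  k-means population structure, per-marker GLM association with Q
  covariates, P < 1e−5 hits intersected across seasons, ±500 kb
  candidate-gene windows, and a static-vs-dynamic phenotype contrast.
* **Synthetic trials** — a seeded generator reproducing the 54-variety ×
  3-treatment × 3-replicate design (486 plots) with planted ground truth
  (responsiveness scores, quadrant labels, subpopulations, causal
  markers) for end-to-end validation.

## Worked example

```r
library(wheatNRES)

cfg <- trialConfig(nVarieties = 12, seed = 2024)
ds  <- generateTrial(cfg)
ds
#> TrialDataset: 12 varieties x 3 treatments x 3 replicates x 1 season(s)
#>   108 plots, 6480 series rows, flights at 30,50,70,90,110,130,142,154,175,196 DAS

curves <- fitTrialCurves(ds$series)     # replicate-mean fits, default families
curves$curve[[1]]
#> ProfileCurve [gaussian] on DAS [30, 196]
#>   parameters: a=0.7632, b=161.6, c=46.07
#>   fit: R2=0.9991 RMSE=0.008346 AIC=-87.72 (n=10, converged=TRUE)
#>   meta: variety=V01, treatment=0, trait=3dci, season=S1

cgrTab <- buildCGRMatrix(curves)        # 5-day CGRs over 1-25 DAF
h <- subset(cgrTab, trait == "height" & section == "11-15")
round(100 * tapply(h$cgr, h$treatment, mean), 2)   # %/day
#>    0  180  270
#> 1.34 1.47 1.52
```

Mean height growth in the 11–15 DAF section rises with the N level
(1.34 → 1.52 %/day from N0 to N270): the fertilized treatments
accelerate post-jointing growth, and the CGR matrix quantifies by how
much, per trait and five-day phase.

```r
yn <- generateYNTable(nVarieties = 12, noiseSd = 0, seed = 2024)
q  <- classifyQuadrants(yn$table, treatment = 180)
table(q$group)
#> HYHN HYLN LYHN LYLN
#>    3    2    3    4
mean(q$group == yn$truth$group)         # planted labels recovered
#> [1] 1

gl <- nresGroupLists()                  # published HYHN/LYLN lists
hy <- split(gl$variety[gl$group == "HYHN"], gl$treatment[gl$group == "HYHN"])
consistentPerformers(hy, "HYHN")
#> [1] "CP02-1" "WM108"  "ZM168"  "ZM5"    "ZM8"    "ZM9523"
```

On a noiseless index table the quadrant classifier recovers every
planted label, and intersecting the packaged published HYHN lists across
the three N treatments yields the six consistently high-performing
varieties.

The staged pipeline driver chains everything through tidy CSV artifacts
with manifest tracking:

```r
runPipeline(pipelineConfig(nVarieties = 8L, nMarkers = 80L, seed = 5L),
            outDir = "artifacts")
```

or from a shell: `Rscript -e 'wheatNRES::runPipeline(outDir = "artifacts")'`.

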