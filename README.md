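# nodulect

Quantitative CT texture analysis of lung adenocarcinoma nodules and the
tumor-free lung around them, aimed at non-invasive prediction of EGFR
mutation status.

Pulmonary nodules of the adenocarcinoma spectrum range from indolent,
ground-glass ("lepidic") lesions to aggressive solid tumors, and the driver
mutation a tumor harbors (EGFR vs KRAS) steers therapy: EGFR-mutant tumors
respond to tyrosine-kinase inhibitors, but confirming the mutation normally
requires invasive tissue sampling. `nodulect` implements, at desk scale, an
exemplar-based radiomics pipeline for this problem:

- **Nodule texture (CANARY-style).** Nine color-coded texture exemplars
  (V, I, B, G, Y, O, R, C, P) are learned from 9×9-voxel ROI patches by
  affinity propagation on the pairwise similarity
  s(a, b) = −‖f(a) − f(b)‖², where f clips HU to [−1024, 200] and scales to
  [0, 1]. Every voxel of a segmented nodule is assigned the color of its
  nearest exemplar, summarized as a *glyph* (the percentage of each color)
  and as composite features V-I-R-O (invasive component), B-C-G (lepidic
  component), Y-P, and Y+G, with V-I-R-O + Y-P + B-C-G = 100 by
  construction. Registered screening cutoffs: V-I-R-O ≤ 71% and
  Y-P ≥ 23.5% of tumor volume, each targeting 80% sensitivity for EGFR
  mutation. Glyph clustering (k-medoids) stratifies nodules into
  Good/Intermediate/Poor risk groups.
- **Peritumoral lung (CALIPER-style).** A 10 mm shell of tumor-free lung
  around the nodule (exact anisotropic Euclidean distance transform) is
  tiled into 15×15×15 VOIs and classified into normal, low-attenuation,
  ground-glass, reticular and honeycomb parenchyma by a transparent rule
  table; *fibrosis* = GG + R + HC fraction, *low attenuation* = LA
  fraction.
- **Cohort statistics.** Fisher/chi-square contingency tests, exact
  Wilcoxon rank-sum, logistic regression with p-value stepwise selection
  (score-test entry, Wald-test removal), odds-ratio rescaling
  OR = exp(β·Δ), ROC curves with cutoffs at a target sensitivity,
  single-split recursive partitioning, Kaplan-Meier and Cox (Breslow)
  survival.
- **Synthetic data.** A lung CT phantom (ellipsoidal lungs, tunable
  emphysema and subpleural fibrosis, part-solid nodules with known truth
  masks) and a feature-level cohort generator whose EGFR labels follow a
  logistic model on Y%, G%, never-smoking and fibrosis — so every stage is
  testable against ground truth without patient data.

## Worked example

```r
library(nodulect)

# a synthetic scan with a part-solid nodule (70% ground-glass)
ph  <- make_lung_phantom(phantom_spec(shape = c(64, 64, 64), rng_seed = 11))
imp <- implant_nodule(ph$volume, ph$lung,
                      nodule_spec(center = c(45, 32, 32), radius_mm = 6,
                                  lepidic_fraction = 0.7), rng_seed = 2)

# learn the nine exemplars from ROI patches spanning the HU spectrum
set.seed(1)
rois <- list()
for (hu in seq(-950, -100, length.out = 9)) for (r in 1:6) {
  v <- ct_volume(array(rnorm(18 * 18, hu, 8), c(18, 18, 1)))
  m <- voxel_mask(array(FALSE, c(18, 18, 1))); m$data[9, 9, 1] <- TRUE
  rois <- c(rois, extract_rois(v, m))
}
model <- fit_exemplar_model(rois)
model
#> <exemplar_model> 9 exemplars from 54 ROIs
#>   mean HU by color: V=-418 I=-313 B=-950 G=-739 Y=-631 O=-101 R=-204 C=-845 P=-525

# segment, classify, and score one nodule end to end
rec <- run_nodule(imp$volume, seed_point = c(45, 32, 32), model)
round(rec[, c("VIRO_pct", "YP_pct", "BCG_pct", "YplusG_pct",
              "nodule_volume_cc", "fibrosis")], 2)
#>   VIRO_pct YP_pct BCG_pct YplusG_pct nodule_volume_cc fibrosis
#> 1    27.96  59.89   12.15      45.38             0.93        0
rec$flag_VIRO_le_71
#> [1] TRUE
```

The mostly ground-glass nodule shows a small invasive composite
(V-I-R-O ≈ 28% of tumor volume, well under the 71% screening cutoff, so the
nodule is flagged as a likely EGFR-mutant candidate), a ~0.93 cc truth
volume, and no fibrosis in its 10 mm peritumoral shell.

```r
# cohort-level statistics on a simulated feature cohort
coh <- simulate_feature_cohort(cohort_gen_params(n = 400, rng_seed = 7))
run_cohort(coh)
#> <cohort_report> n = 400
#>   smoking vs EGFR Fisher p = 4.66e-15
#>   stepwise EGFR predictors: never_smoker, G_pct, Y_pct, fibrosis
#>   VIRO AUC = 0.732, Y+G AUC = 0.771
#>   OR per 10-point VIRO decrease = 1.84
```

Stepwise selection recovers the generative predictors (never-smoking, the
Y and G exemplars, peritumoral fibrosis); the Y+G model AUC and the
odds-ratio per 10-point V-I-R-O decrease move in the directions the
underlying biology dictates.

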