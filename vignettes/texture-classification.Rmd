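---
title: "Texture-based tumor recognition in label-free multiphoton images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based tumor recognition in label-free multiphoton images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptexture)
```

## The problem

Label-free multiphoton microscopy produces co-registered CARS (lipid/protein
contrast), TPEF (endogenous fluorescence) and SHG (fibrillar collagen) images
of brain tissue without stains or injected markers. Brain tumors alter the
*spatial organization* of these signals more reliably than their absolute
intensity: nontumor cortex and white matter show ordered axon-like strands,
regularly spaced cells and punctate fluorescence, while tumors are spatially
inhomogeneous, densely and irregularly cellular, with diffuse fluorescence
and (variably) collagenous ECM. `mptexture` turns that qualitative contrast
into an observer-independent diagnostic rating:

1. split each channel image into fields of view (FoVs) of 104 × 208 pixels at
   a nominal 1 µm/pixel;
2. min–max normalize each FoV and compute 13 texture parameters per channel;
3. classify each FoV with a two-class linear discriminant, yielding a
   posterior probability of class assignment (0 = nontumor, 1 = tumor);
4. aggregate FoVs into a per-sample rating via the median probability, and
   render tiled probability maps for border delineation.

## The texture parameters

Per channel and FoV, after min–max normalization to [0, 1]:

* **First order (5):** mean gray value, standard deviation (N−1 denominator),
  kurtosis and skewness (population central moments, non-excess — a Gaussian
  texture has kurtosis 3), and Shannon entropy in bits over a 256-bin
  histogram with 0·log 0 := 0.
* **Second order (8):** gray-level co-occurrence matrices (GLCM) at two
  physical distances, 6 µm and 40 µm, in the four standard orientations
  (0°, 45°, 90°, 135°). From each normalized GLCM `p(i, j)`:
  contrast `Σ p·(i−j)²`, correlation
  `Σ p·(i−µ_r)(j−µ_c)/(σ_r σ_c)`, energy `Σ p²`, and homogeneity
  `Σ p/(1+|i−j|)`; the four orientations are averaged per distance.

The two distances probe complementary scales: 6 µm is the cell/puncta scale,
40 µm the scale of tumor intensity patches. Distances are specified in
micrometres and converted to pixels through the pixel size (rounded to the
nearest integer ≥ 1), so analyses at different magnifications probe matched
physical scales.

Conventions that the literature leaves open were fixed once and are recorded
in every model file via a configuration hash: 8 gray levels for quantization,
asymmetric pair counting (each ordered pair counted once in the offset
direction, out-of-bounds partners skipped), normalization of counts to joint
probabilities before property evaluation, and 256-bin base-2 entropy. All are
arguments of `texture_config()`; a model trained under one convention refuses
feature tables extracted under another.

### Degenerate fields of view

Nontumor parenchyma often lacks SHG-active structures entirely; after min–max
normalization such FoVs are pure amplified noise, and a truly constant FoV
would make several features 0/0. Constant FoVs therefore normalize to an
all-zero grid with a `degenerate` flag; sd, skewness, kurtosis and entropy
are defined as 0, and the correlation of a zero-variance GLCM is defined as 1
(a constant texture is perfectly predictable) with a flag preserved for
audit. This keeps every feature vector finite and classifier-safe without
discarding the — diagnostically meaningful — SHG-dark fields.

## The classifier

A two-class linear discriminant with pooled covariance: class means are
per-class feature means, the pooled covariance is the within-class scatter
divided by N−K, and the posterior follows from Bayes' rule with linear
discriminant scores. Three choices were genuinely open:

* **Priors.** Default empirical (class-frequency) priors with a `uniform`
  option; cohorts here are strongly unbalanced (many more tumor than
  nontumor patients), so the choice is material and is stored in the model.
* **Regularization.** A ridge λ·I with default `λ = 1e-6·trace(Σ)/p` keeps
  the covariance invertible in the presence of near-constant features
  (e.g. SHG texture in nontumor fields); `λ = 0` reproduces the strict
  classical estimator and errors informatively on singularity, naming the
  most deficient feature direction.
* **Ties.** A FoV posterior or sample median of exactly 0.5 is surfaced as
  `indeterminate` and counted as misclassified in evaluation — intermediate
  probabilities can technically fall to either class, but silently resolving
  them would overstate clinical confidence.

The split into training and test data is **by patient**, never by FoV: FoVs
of one patient are strongly correlated, and a FoV-level split leaks patient
identity into the test set. `train_classifier()` refuses leaked splits, and
the test suite demonstrates the inflation a FoV-level split produces on a
null cohort with strong interpatient variability.

## Aggregation and evaluation

The per-sample rating is the median FoV probability (mean of the middle two
for even n), thresholded at 0.5. Sensitivity is the percentage of tumor
samples rated tumor, specificity the percentage of nontumor samples rated
nontumor, and the correct rate the pooled percentage; report percentages are
rounded half-up to integers while machine-readable output keeps full
precision. Probability maps place each FoV's probability at its tile position
with a fixed diverging color code — blue (0) through gray (0.5) to red (1) —
so borders read as a blue-to-red transition with ambiguity rendered gray.

The package bundles the per-type correct-classification counts of a
218-biopsy test cohort (204 tumors of ten types, 14 nontumor samples) as a
plain-text fixture; `evaluate_counts()` reproduces the associated
sensitivity/specificity/correct-rate block from those counts alone, which
pins down the evaluation arithmetic (pooling, indeterminate handling,
rounding) against published integer rates.

## The synthetic generator

No patient images are distributed, so the pipeline's discrimination power is
demonstrated on synthetic three-channel images. The recipes are
*phenomenological*: they target the qualitative contrasts described above,
not optical image formation.

Both classes are drawn from one parametric family per channel; only the
parameter vectors differ. CARS: oriented sinusoidal strands with smooth phase
wobble plus Gaussian cell blobs placed on a density-matched lattice with
positional jitter (small jitter → regular nontumor spacing, large jitter →
irregular tumor packing) plus a low-frequency random intensity patch field
(correlation length 40 µm); TPEF: punctate blobs on the same
lattice-plus-jitter scheme plus a diffuse patch field; SHG: mostly dark, with
a class-dependent probability of containing either a fiber-bundle texture
(tumor-like ECM) or a single elliptical arc (corpus-amylaceum/vessel-like),
plus detector noise. Intensities are in arbitrary units by design — min–max
normalization downstream makes absolute scale irrelevant.

**Effect size.** Class parameter vectors are blended toward their common
midpoint: with class weight w (0 = nontumor, 1 = tumor), the effective weight
is `0.5 + effect_size·(w − 0.5)`. At `effect_size = 0` both classes sample
the *same* distribution (including a 50/50 fiber-vs-arc draw in SHG), giving
an exact null for calibration; `effect_size = 1` is the nominal contrast.

**Interpatient variability.** Each patient's parameter vector receives
multiplicative lognormal jitter (default sd 0.06 on the log scale, chosen as
a moderate-but-visible biological variability). This makes the patient-level
split load-bearing: with jitter, a FoV-level split can memorize patients.

**Determinism.** Every draw funnels through one seeded generator;
spec + seed reproduce each pixel bit-identically, and cohorts derive
per-patient sub-seeds from the cohort seed.

**Border sections** blend the two parameter vectors tile by tile across a
transition band, with per-tile truth labels by majority class — the
testbed for probability-map delineation.

### What passing tests do and do not show

The generator reproduces the *texture orderings* that motivate the method
(e.g. tumor CARS has higher long-range GLCM contrast) and realistic cohort
structure, so end-to-end recovery demonstrates that the feature/classifier
chain detects this class of spatial reorganization at realistic noise and
interpatient variability. It does not demonstrate performance on real
tissue: real morphology, optical artifacts, staining-free intensity
distributions and the true interpatient covariance structure are all richer
than the recipes. Accuracies on synthetic cohorts are an analogue of, not an
estimate of, clinical performance.

## Simulation sizes used in the checks

Chosen to exercise each property at the scale it needs while keeping a
complete run desk-sized:

* **Recovery:** 20 tumor + 10 nontumor patients × 100 FoVs (the default
  cohort shape), patient-level 50/50 split → ~1500 held-out FoVs.
* **Null calibration:** the patient, not the FoV, is the unit of variance
  under the null, so the null run allocates many patients with few FoVs:
  200 + 200 patients × 10 FoVs → 2000 held-out FoVs, which brings the
  patient-level standard error of accuracy under 2 percentage points.
* **Border mapping:** a 10 × 4-tile section with a 6-tile transition band at
  effect size 0.3, classifier trained on a matching 6 + 4 × 20 cohort. The
  moderate effect size models a margin where tumor-induced change is
  partial; at the full effect the discriminant separates so sharply that
  posteriors saturate at 0/1 and the map degenerates to a step.
  Monotonicity is summarized by the Spearman correlation of tile-column
  median probability with column index.
* **Resolution:** a 12 + 8 × 25 cohort generated at 0.5 µm/pixel
  (208 × 416-pixel FoVs), analysed natively and after 2 × 2 block averaging
  to 1 µm/pixel at matched physical distances.

## Worked example

```{r example, eval = FALSE}
library(mptexture)

cohort <- gen_cohort(n_tumor = 20, n_nontumor = 10,
                     fovs_per_sample = 100, seed = 1)
result <- run_pipeline(cohort)
result$fov_accuracy          # held-out FoV-level accuracy
glance(result$sample_eval)   # sensitivity / specificity / correct rate
tidy(result$model)           # per-feature discriminant weights

# border delineation
model <- result$model
sec <- gen_border_section(width_tiles = 10, height_tiles = 3,
                          transition_width = 3, seed = 2)
tiles <- lapply(sec$images, tile, fov_rows = 104, fov_cols = 208,
                sample_id = "border")
fovsets <- lapply(seq_along(tiles[[1]]), function(k) lapply(tiles, `[[`, k))
preds <- predict(model, compute_features(fovsets, texture_config()))
autoplot(prob_map(preds))
```

## Known limitations

* The LDA is the only classifier; no feature selection, cross-validation
  beyond the single patient-level split, or probability calibration.
* Tiling assumes abutting, non-overlapping tiles; overlapping acquisitions
  would need registration upstream.
* Synthetic SHG models presence/absence of two structure archetypes only;
  the real channel's interpatient variability is far broader.
* Multi-page TIFFs (z-stacks) and RGB inputs are rejected rather than
  interpreted.
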