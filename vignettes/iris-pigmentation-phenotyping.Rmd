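---
title: "Quantitative iris pigmentation phenotyping: methods and design"
author: "IrisPheno authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative iris pigmentation phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IrisPheno)
```

## The phenotyping model

Human iris colour is produced by two melanins — eumelanin (dark brown,
densely packed) and pheomelanin (sparser, yellow-to-red) — against the
blue-grey of unpigmented stroma, where Tyndall scattering dominates.
Classical quantitative eye-colour measures average colour over the whole
iris (mean hue/saturation, mean luminosity, Lab means, T-index) or reduce
it to a two-way blue/brown ratio (PIE score). Averaging obscures the
*mixture* of pigment types. IrisPheno instead classifies every iris pixel
into one of three classes — `non_pigmented`, `pheomelanin`, `eumelanin` —
and reports the three areal proportions `(p_non, p_pheo, p_eu)`, which by
construction are each in `[0, 1]` and sum to one. The legacy quantifiers
are computed on the same masked pixel set so all measures can be compared
on equal footing.

The pipeline is:

1. **Segmentation.** The image is converted to relative luminance
   (Rec. 601 weights) and edges are found with a Canny detector: Gaussian
   smoothing (`sigma = 2` px), Sobel gradients, non-maximum suppression,
   and hysteresis thresholds placed at the 0.70/0.90 quantiles of the
   positive gradient magnitudes. A circular Hough transform accumulates
   votes over integer radii; because the imagery this method targets has
   the pupil centred in the frame, candidate centres are restricted to a
   disc of radius 0.05 x `min(H, W)` around the image centre. The limbus
   is the top-scoring circle in the band 0.20-0.48 x `min(H, W)`; ties
   favour the larger radius so internal texture rings never beat the
   limbus. A second Hough pass around the limbus centre searches for the
   pupil in the band from 0.05 x `min(H, W)` up to 0.60 of the limbus
   radius; a pupil candidate is accepted only if its votes cover at least
   25% of its circumference, otherwise a concentric fallback pupil of
   0.30 x limbus radius is used. The iris mask is the annulus between the
   pupil and limbus radii about the limbus centre. Segmentations that
   fail (no limbus candidate) raise a typed condition carrying the sample
   id; `overrideSegmentation()` is the manual-curation hook.

2. **Pixel classification.** Each masked pixel's RGB triplet is mapped to
   HSV (hue as a fraction of the circle in `[0, 1)`, hue of achromatic
   pixels defined 0) and min-max scaled with ranges stored at training
   time. A one-vs-one soft-margin SVM with quadratic kernel
   `K(x, y) = (gamma * x.y + coef0)^2` (defaults `gamma = coef0 = cost =
   1`) assigns one class per pixel. Because hue wraps at red, a circular
   encoding (`cos 2*pi*H, sin 2*pi*H, S, V`) is available via
   `encoding = "circular"`; the default stays with raw H/S/V, which is
   adequate because iris hues cluster far from the wrap point. The class
   proportions over the mask are the phenotype.

3. **Legacy quantifiers.** These are interpretations of the cited prior
   measures, not reproductions (their original formulas are
   under-specified); each is oriented so that melanin-type measures rise
   with eumelanin:
   * `mean_h`, `mean_s` — circular mean hue (angle of the mean unit
     vector) and arithmetic mean saturation;
   * `lum_l` — melanin index: one minus mean relative luminance;
   * `colour_c` — mean CIE chroma `sqrt(a*^2 + b*^2)`;
   * `l_star`, `a_star`, `b_star` — mean CIELAB components (sRGB/D65;
     camera colour profiles are not modelled);
   * `pie` — fraction of "brown" pixels from 2-means clustering in Lab
     space (fixed internal seed, 10 restarts; the cluster with lower mean
     L* is brown; a degenerate single-colour iris scores 1 when its mean
     L* is below 50);
   * `t_index` — `1 - (mean(B) + mean(G)) / 510`.

## Statistical genetics

Genotypes are minor-allele dosages (0/1/2). The module provides:

* **QC:** minor-allele frequency, call rate, an exact conditional HWE
  test (summing the probabilities of all heterozygote configurations no
  more probable than the observed one, given the allele counts), and
  Rosenberg's informativeness for assignment `In` (nats) across
  populations.
* **Association:** partial correlation of dosage and phenotype after
  residualising both on the covariate design (intercept, age, sex,
  population dummies with the alphabetically first level as reference).
  Reported as `r2 = 100 r^2` with a t-based p-value at `n - 2 - k`
  degrees of freedom. This equals the full-regression t-statistic
  relation `r^2 = t^2 / (t^2 + df)` to machine precision (asserted in the
  tests). A combined all-SNP regression with adjusted R-squared is also
  available; exactly collinear SNPs are dropped with a warning.
* **Epistasis:** for each SNP pair, nested OLS models with and without
  the product term `X3 = X1 * X2` are compared by a one-degree F-test.
  Pairs in strong LD (dosage r-squared above 0.8 by default) are excluded
  before testing; pairs whose product term is collinear with the main
  effects are flagged untestable. The Bonferroni family size defaults to
  the number of tests actually performed but is configurable, because
  conventions for counting the family differ between studies.
* **Prediction:** OLS of a phenotype on SNP dosages, optional product
  terms and covariates, evaluated by repeated randomized train/holdout
  splits (default 100 repeats, 2/3 training fraction) with holdout
  `R^2 = 100 (1 - SS_res / SS_tot)`; the mean and 5%/95% quantiles over
  repeats are reported. Holdout R-squared — not squared correlation — is
  used so that miscalibrated predictions are penalised.

## What the synthetic generators emulate

No public imagery or genotype data accompany this method, so the package
carries ground-truthed generators used by every test.

`renderSyntheticEye()` builds an image of sclera, a dark pupil disc and
an iris annulus. Iris pixels get classes by rank-thresholding a smoothed
Gaussian field at cut points matching the requested proportions, giving
contiguous pigment patches (texture scale 6 px by default) rather than
i.i.d. speckle, so segmentation and classification face spatially
coherent structure. Class colours default to blue-grey (148,168,200),
yellow-brown (182,148,80) and dark brown (72,48,34) with channel spreads
of 10-12 — separated by several spreads in at least one HSV axis, the
regime in which per-pixel classification is well-posed and which the
method assumes. What the renderer does **not** emulate: crypts and
furrows, limbal ring gradients, specular glints, eyelid/eyelash
occlusion, off-centre gaze. Passing tests therefore demonstrate the
correctness of the algorithms under the stated model, not robustness to
all real-world image pathology.

`simulateCohort()` draws individuals from K populations (default 7,
equal weights), per-population allele frequencies from the
Balding-Nichols beta model (`fst = 0.02` by default) around ancestral
frequencies spanning 0.10-0.45, and genotypes Binomial(2, freq) — in HWE
within populations, with the pooled-sample Wahlund deviation emerging
naturally, which is exactly the HWE signature expected of a multi-centre
European cohort. Phenotypes are a genetic linear predictor (additive
betas, optional product terms) plus covariate effects plus Gaussian
noise; the noise SD is set from the realised genetic variance so that
`var(genetic) / (var(genetic) + var(noise))` equals the target fraction
(default 0.5, the scale of variance explained reported for
non-pigmented area by strongly associated SNP panels). The default
architecture uses one large-effect SNP (beta 2) and eleven smaller ones,
mirroring a HERC2-dominated panel. Age is uniform on 65-85 years (an
elderly study population); sex is Bernoulli(0.5). LD between SNPs is not
simulated; collinearity handling is exercised with duplicated columns.

## Numerical choices and edge cases

* **Determinism.** Every generator is a pure function of (spec, seed);
  RNG state is saved and restored around internal seeding, so calling
  package functions never perturbs the caller's stream. `pieScore()`
  seeds its k-means internally (10 restarts), making the whole
  quantification row bit-reproducible.
* **Hellinger distance** uses a shared-grid histogram estimator (64 bins
  in 1-D, 32 per dimension in 2-D, range = pooled min-max): simple,
  deterministic, and exact at the two limit cases (0 for identical
  samples, 1 for grid-disjoint supports). The estimator has a positive
  sparse-bin bias when cell counts are low — with `n` points spread over
  `k` occupied cells the expected distance between identical
  distributions grows like `sqrt(k / 8n)` — so comparisons between
  subspaces should use a common grid and sample size, as
  `categorySeparationTable()` does.
* **Circle accumulator ties** break toward the larger radius; candidate
  de-duplication suppresses circles within 2 px of a better-scoring one.
* **Degenerate inputs.** Constant images yield empty edge maps (not
  errors); blank images fail segmentation with a typed condition;
  monomorphic SNPs return HWE p = 1; constant variables yield NA
  correlations with warnings; k-means degeneracies in `pieScore()` fall
  back to a mean-lightness rule.
* **Classifier serialization** stores hyper-parameters plus the raw
  training pixels in versioned JSON and refits on load. The SVM fit is
  deterministic given identical inputs, so the restored model reproduces
  the original's labels exactly; this keeps the model file plain-text,
  diffable and independent of library binary formats.
* **Missing data** are handled by pairwise-complete deletion throughout
  the genetics module; no imputation is attempted.

## Problem sizes used by the test-suite

The packaged checks run at deliberately modest scale chosen to exercise
every claim: 50 rendered eyes (128 x 128 px) for segmentation recovery,
cohorts of n = 3000 with 12 SNPs for association/prediction recovery,
2000 null simulations (n = 1000) for F-test calibration and 200
replicates (n = 3000) for power, and 100,000 draws for the Hellinger
closed-form comparison. At these sizes the end-to-end properties hold
with comfortable margins: segmentation succeeds on all 50 eyes within a
3% radius tolerance, recovered proportions sit within 0.026 of truth,
and cross-validated R-squared lands within 2 points of the planned 50%.

## Known limitations

* The Hough transform assumes near-circular, near-centred irides; oblique
  gaze or strongly elliptical limbi defeat it (by design — out of scope).
* The classifier is only as good as its training distributions; the
  shipped default model is trained on the synthetic reference colours
  and should be retrained via `cmdTrain()` for real camera imagery.
* Legacy quantifier formulas are orientation-calibrated interpretations;
  absolute values are not comparable to other implementations of the
  same-named measures.
* Holdout R-squared can be negative for badly overfit models; quantile
  summaries retain this information rather than truncating at zero.
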