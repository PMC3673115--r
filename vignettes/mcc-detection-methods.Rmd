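---
title: "Detecting microcalcification clusters: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microcalcification clusters: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The detection problem

Clustered microcalcifications (MCCs) — groups of three or more tiny bright
calcium deposits within about a square centimetre — are among the earliest
mammographic signs of breast cancer. Individually an MC is a spot of a few
hundred micrometres with low contrast against dense tissue, so computer-aided
detection (CADe) pipelines face two coupled problems: finding spot-like
candidates without drowning in false positives from film grain, fibres and
skin markers, and then classifying each candidate as calcification or noise.
`mccdetect` implements a complete pipeline of this kind and a synthetic
phantom generator so every stage can be exercised and validated without
clinical data.

The stages are:

1. **Display transform and masking.** Raw 14-bit detector images are passed
   through an inverted logarithmic transform (ILT) onto a 12-bit display
   scale, `t = round(4095 (1 - ln(1+r)/ln(1+16383)))`, which inverts (tissue
   bright) and log-compresses. The reference curve for this transform is not
   publicly specified; the implementation pins the simplest mapping with the
   three required properties — monotone inversion, logarithmic compression,
   14-to-12-bit reduction — and keeps it behind one function. The breast
   region is the largest 8-connected component above the Otsu threshold of
   the ILT image; all later computation is restricted to it.
2. **Filter bank.** Eighteen "feature images" per mammogram: the ILT image;
   its white top-hat transform (disk radius 7 px), which removes smooth
   background and keeps narrow peaks; a two-level Daubechies-4 wavelet
   decomposition reconstructed with the level-2 approximation band zeroed,
   which removes the low-frequency background; and the 15 Laws
   texture-energy images (5x5 outer-product masks of the L/E/S/W/R kernels).
3. **Candidate detection.** On the top-hat and wavelet images separately:
   shift the gray scale down by a threshold `T` (clipping at zero), run Sobel
   and Canny edge detection, fill closed contours, open with a 3x3 cross to
   break bridges, and OR the two binary maps. `T` is adjusted iteratively
   until the number of 8-connected components falls inside a configured
   range — `[450, 550]` for the top-hat branch and `[350, 400]` for the
   wavelet branch — and the two branch masks are ORed into the candidate
   mask.
4. **Knowledge rules.** Candidates larger than 100 px (markers), line-like
   candidates (elongation > 3.5 or bounding-box compactness < 0.38), and
   isolated candidates (fewer than 3 candidates inside the centred
   1 cm x 1 cm window) are removed.
5. **Texture features.** For each candidate and each of the 18 feature
   images, a 16x16 window centred on the candidate is quantized to 64 gray
   levels and four gray-level co-occurrence matrices (d = 1; 0, 45, 90,
   135 degrees; symmetric counting, normalized) are reduced to 14 statistics
   each — 56 features per image, 18x56 per candidate.
6. **Automated feature selection.** Per feature image, a wrapper search over
   feature subsets scored by stratified 5-fold cross-validated mean squared
   label error (equal to the misclassification rate for binary labels) of an
   RBF-SVM: sequential forward selection, sequential backward selection, and
   prefixes of the descending F-score ranking; the subset with the minimum
   CV error wins (ties: higher ROC area, then fewer features).
7. **Ensemble training.** One RBF-SVM per feature image, trained on all
   MC-present candidates plus a seeded 5:1 sample of MC-absent candidates,
   with `(C, sigma)` grid-searched over `log2 C in {-5,-3,...,15}` and
   `log2 sigma in {-15,-13,...,3}` (110 pairs) by 5-fold CV. A candidate is
   accepted when at least `N` of the 18 SVMs vote for it; `N` is chosen from
   the training free-response ROC as the largest sensitivity with fewer than
   one false positive per image.
8. **Cluster scoring.** Accepted candidates are grouped by single-linkage
   clustering with a 10 mm link distance; groups of at least three members
   become cluster detections. A detection is a true positive when its
   rectangle covers more than 50% of a ground-truth rectangle and is at most
   four times its area (Kallergi's criteria); sensitivity and FP/image are
   reported, and the fROC is traced by sweeping `N` from 1 to 18.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pixel_spacing_mm` | 0.1 (config), 0.2 (phantoms) | mm/px | converts the 1 cm rules to pixels; mammograms carry no standard tag for it, so it is explicit configuration |
| `tophat_radius_px` | 7 | px | disk radius; peaks narrower than the disk survive |
| `candidate_range_tophat` | [450, 550] | count | empirical target for the top-hat branch |
| `candidate_range_wavelet` | [350, 400] | count | empirical target for the wavelet branch |
| size rule | 100 | px | strict upper candidate area |
| shape rule | 3.5 / 0.38 | — | strict elongation / compactness boundaries |
| `glcm_levels` | 64 | levels | window quantization: 256 pixels per window keep a 64x64 GLCM usably dense; configurable |
| `window_size` | 16 | px | texture window side |
| `normal_to_mc_ratio` | 5 | — | MC-absent to MC-present training ratio |
| `voting_threshold_N` | `"auto"` | votes | picked from the training fROC (largest sensitivity with FP/image < 1) |

## Numerical and design choices

**Wavelet boundary handling.** An orthogonal DAUB4 filter bank with plain
symmetric extension does not reconstruct perfectly. The implementation
reflect-pads the image to a multiple of four, applies the *periodized*
orthogonal pyramid transform (exact perfect reconstruction), and crops. The
reflected pad keeps wrap-around content away from the cropped region, and
the perfect-reconstruction property holds to float precision — both are
asserted by tests.

**Sobel binarization.** The edge maps must be binarized before filling. The
gradient histograms of mammographic images are strongly long-tailed: a few
marker/MC edges sit an order of magnitude above the faint spot edges that
must be kept, so a two-class Otsu split chases the extreme tail and starves
the wavelet branch of candidates. The implementation uses the standard
automatic Sobel threshold — four times the mean gradient magnitude — which
adapts to the sparsity of the threshold-shifted input. Canny uses sigma = 1
with hysteresis at 0.1/0.2 of the maximum magnitude.

**Shape rule combination.** Read literally, removing a candidate only when
it is *both* elongated and sparse would keep axis-aligned lines (compact but
elongated) and diagonal lines (sparse but not elongated), contradicting the
rule's purpose of removing line-like structures. The default mode therefore
removes a candidate when *either* test fails; the literal conjunctive
reading remains available (`shape_rule_mode = "and"`). All three rule
boundaries are strict inequalities.

**Count-control dynamics.** The threshold walk uses multiplicative steps
(x1.05 toward the range, widened to x1.4 while the count is more than twice
outside it) with a bisection fallback once two thresholds bracket the range,
a 200-evaluation cap, and an explicit zero-threshold probe to recognize
ranges unattainable from below. When the range cannot be met the
closest-count mask is returned with a warning flag rather than an error.

**GLCM definitions.** The 14 statistics are pinned to the classical
co-occurrence definitions (cluster shade and prominence for the third and
fourth moments; homogeneity `sum P/(1+|i-j|)`; inverse difference moment
`sum P/(1+(i-j)^2)`; intensity = GLCM mean; sum/difference statistics over
the diagonal-sum and absolute-difference marginals; natural logs with
`0 log 0 = 0`). Every statistic is unit-tested against an independent
double-sum oracle, so the pinned table is the single point of change. Each
window is quantized by its own min-max range; a constant window maps to
level 0 and yields finite features. The production extractor is compiled
(Rcpp) because a benchmark image asks for roughly 10^5 GLCMs; a pure-R
reference path is kept and the two are asserted equal.

**Feature standardization.** Features are z-scored with means/SDs fitted on
the training rows of each fold (or the final training set), since RBF
kernels on raw mixed-scale GLCM features would be dominated by the
large-magnitude moments. The kernel keeps the printed parameterization
`K(x,z) = exp(-sigma ||x-z||^2)`, mapping directly onto libsvm's gamma.

**Selection/grid-search interaction.** The `(C, sigma)` search runs once per
feature image on the full candidate feature set before subset search, and
once more inside ensemble training on the winning subset. Ties in the grid
go to smaller `C`, then smaller `sigma`; ties in selection to higher Az,
then fewer features; within a greedy step, to the lowest feature index.

**Tractability caps.** Subset evaluation and grid search inside the
end-to-end pipeline operate on a stratified subsample of at most
`max_eval_patterns = 400` candidates (class ratio preserved); the final
member SVMs are always fitted on the full 5:1 samples. The pipeline's
default selection method is the F-score prefix search; SFS and SBS are
implemented and tested, and `selection_method = "best"` runs all of them,
but a full SFS+SBS wrapper pass over all 18 feature images costs roughly
150,000 SVM fits, which is out of proportion for the benchmark.
Cross-validation screening fits (grid search, subset evaluation) run the
SVM optimizer at a stopping tolerance of 0.01; final member fits use the
default 0.001. These are engineering caps, not statements about the
methods.

## What the synthetic phantoms emulate — and what they do not

`synthetic_spec()` describes a 384x384 raster at 0.2 mm/px (a 7.7 cm field,
the working resolution after the downsampling customary in mammography CAD):
a half-elliptical breast support against one image edge; a smooth uneven
background (broad Gaussian blobs plus a ramp); clusters of `>= 3` bright MC
spots within a 4 mm radius, so every generated cluster satisfies the 1 cm
nearest-neighbour criterion by construction; isolated MCs; 1-px line
artifacts; marker blobs larger than 100 px; abundant spot-like speckle
(2,200 faint Gaussian bumps per image) standing in for film-grain/quantum
mottle clumps; and white noise. MC spots use a super-Gaussian (flat-top,
steep-edge) profile — the textural signature of a calcium deposit — while
speckle bumps stay smooth; spot scales sit above the pixel pitch, as a
detector point-spread function would place them. The designed display-domain
scene is encoded through the inverse ILT curve to 14-bit raw values so the
pipeline runs from its true entry point.

The defaults were fixed once, as the package's benchmark condition: the
speckle density and amplitude are set so that both detection branches
present abundant distinct peaks and the configured candidate-count ranges
are meaningful, and the default benchmark is 20 training plus 20 held-out
phantoms with 2 clusters per image.

What passing the synthetic benchmark shows: every stage composes correctly,
the ensemble learns a real texture difference at realistic candidate counts,
the voting threshold chosen on training data transfers to held-out images,
and the scoring machinery behaves. What it does not show: performance on
clinical mammograms. The phantoms have no anatomy (ducts, vasculature,
pectoral muscle), no compression or scatter physics, a single noise model,
and an MC/noise texture contrast that is cleaner than dense-breast reality.
Clinical figures require clinical data.

## Known limitations

- DICOM input is not supported (no reader among the package's dependencies);
  16-bit TIFF/PNG cover the raster path.
- The ILT curve is pinned by its qualitative properties, not a vendor
  reference.
- The cluster-level fROC need not be exactly monotone in `N` on adversarial
  inputs: acceptance is nested, but single-linkage clusters can merge into
  rectangles that fail the 4x area cap. On the benchmark phantoms the chosen
  operating region behaves monotonically.
- The iterative candidate search assumes the component count is eventually
  decreasing in the threshold; on inputs where the count collapses by
  percolation at low thresholds, the search reports the closest attainable
  count instead of failing.
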