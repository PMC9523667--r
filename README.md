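# nodiomics

Radiomic classification of mesorectal lymph nodes on high-resolution
T2-weighted MR slices — as a fully testable analysis workflow on synthetic
node phantoms.

## The problem

Whether a mesorectal lymph node is metastatic decides nodal stage and
therapy in rectal cancer, but benign and malignant nodes overlap badly in
size (most are under 6 mm short diameter), and the subjective cues readers
fall back on — border morphology, internal signal — agree only moderately
between readers. This package implements the radiomics alternative and its
benchmarks end to end:

1. **Synthetic cohort** — labelled 2D node chips with configurable class
   sizes, truncated-normal short-diameter distributions (defaults: benign
   4.83 ± 1.09 mm on 3–9.42, malignant 5.45 ± 2.17 mm on 3–14), four border
   morphologies (smooth / lobulated / spiculated / indistinct),
   class-dependent internal heterogeneity, distractor vessels, and 0.5625
   mm/pixel spacing.
2. **Four ROI geometries** per node: the contour, the contour expanded
   2.5 mm, a ±1 mm annular rim, and an inscribed circle — all in physical
   millimetres via exact distance transforms.
3. **A 1,409-feature bank**: 14 shape + 18 first-order + 75 texture
   features (GLCM 24, GLDM 14, GLRLM 16, GLSZM 16, NGTDM 5) on the original
   image, plus the 93 intensity/texture features on each of 14 filtered
   images (8 stationary-wavelet sub-bands, 2 Laplacian-of-Gaussian scales,
   gradient, square, square root, logarithm): 14 + 93 + 14 × 93 = 1,409.
4. **Screening**: an ICC stability gate (two-way mixed, consistency,
   single measures; retain iff intra- and inter-observer ICC > 0.75 against
   simulated re-segmentation), then variance threshold → SelectKBest
   (ANOVA F) → L1-penalized logistic selection with cross-validated
   penalty, reported as α and −log10(α).
5. **Modelling and evaluation**: stratified 7:3 split (floor rule:
   604 → 422/182), fivefold logistic cross-validation, Mann–Whitney/
   trapezoidal AUC with ACC/SE/SP at a 0.5 cutoff, Youden-optimal cutoffs
   for the size criterion, binary-reader metrics (AUC = (SE+SP)/2), and
   DeLong placement-value comparison of correlated AUCs.

## Worked example

```r
library(nodiomics)

co <- generate_cohort(cohort_config(n_benign = 15, n_malignant = 15,
                                    image_size = 64, seed = 7))
co
#> Synthetic node cohort: 30 nodes (15 malignant, 15 benign), spacing 0.5625 mm/px

roi <- derive_roi(co$masks[[1]], 2, co$spacing)   # contour + 2.5 mm
fv  <- extract_features(co$images[[1]], roi, co$spacing)
length(fv)
#> [1] 1409
round(fv[c("original_shape_Elongation", "original_firstorder_Mean",
           "original_glcm_Contrast", "wavelet.HH1_ngtdm_Busyness")], 3)
#>  original_shape_Elongation   original_firstorder_Mean
#>                      0.969                     68.495
#>     original_glcm_Contrast wavelet.HH1_ngtdm_Busyness
#>                     57.277                      0.067

# the size criterion is weak even in-sample on 30 nodes:
yd <- youden_threshold(co$records$short_diameter_mm, co$records$label)
sprintf("size criterion: AUC %.3f at threshold %.2f mm", yd$auc, yd$threshold)
#> [1] "size criterion: AUC 0.689 at threshold 3.74 mm"

# a binary reader scored from a diagnosis-vs-pathology 2x2 table:
round(rater_metrics(tp = 112, fp = 47, fn = 194, tn = 251), 3)
#>   auc   acc    se    sp
#> 0.604 0.601 0.366 0.842
```

The first node's elongation near 1 says the chip is nearly round; the GLCM
contrast and wavelet-band busyness are the kind of texture features the
Lasso signature typically retains; the reader row shows the characteristic
high-specificity / low-sensitivity pattern of subjective nodal calls.

## The analysis

Numbered drivers under `analysis/` run the whole study on a scaled-down
rendered cohort (75 + 75 chips) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohorts + manifest
Rscript analysis/02_derive_rois.R          # four ROI variants per node
Rscript analysis/03_extract_features.R     # 4 x (150 x 1409) feature tables
Rscript analysis/04_screen_features.R      # ICC gate + variance/KBest/Lasso
Rscript analysis/05_fit_models.R           # fivefold logistic + DeLong
Rscript analysis/06_reader_and_size_benchmarks.R
```

On this synthetic cohort the workflow reproduces the qualitative structure
of the clinical problem: the radiomic signatures dominate both benchmarks
(test AUCs 0.83–0.94 across the four ROI methods in the seed-1 run, with
the contour ROI best), while the size criterion sits near chance and the
three readers score AUC 0.604 / 0.634 / 0.671.

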