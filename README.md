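# sparsenuclei

Denoising and segmentation of cell nuclei in 3D fluorescence microscopy
stacks by dictionary-based sparse representation. The same sparse code
that reconstructs a denoised volume also yields, for free, a **detection
map** of likely nucleus positions; multiplying the two gives a
maximum-response image whose filtered local maxima seed a 3D
marker-controlled watershed that separates touching nuclei. The package
is aimed at quantitative microscopy users who need robust detection of
faint, noisy, densely packed nuclei where plain thresholding fails.

## Method in brief

Every overlapping `N×N×M` patch `y_i` of the volume is sparse-coded
against a dictionary `D` learned from the image itself:

```
min_α ||y_i − D α||₂   s.t.  ||α||₀ ≤ L        (orthogonal matching pursuit)
min_{D,α} ||Y − D α||_F  s.t.  ||α_i||₀ ≤ L    (K-SVD, atom-by-atom updates)
```

The initial atoms are random patches whose summed intensity exceeds the
patch average (so nuclei are represented from the start). The denoised
volume averages the overlapping reconstructions `D α_i`, optionally
blended with the raw data by a weight `λ` (default 0). Each voxel of the
detection map averages `Σ_k |α_i^k|` over the patches covering it,
normalized to `[0, 1]`. Segmentation: global Otsu or local adaptive
threshold `T = mean_local · (1 − sensitivity factor)` on the denoised
volume, minimum-volume filtering, marker detection on the
maximum-response image, seeded watershed flood. Evaluation: Hungarian
centroid matching with a distance gate, recall / precision / F-measure,
matched-pair Jaccard, and a coefficient-of-variation (CV) sweep that
quantifies parameter sensitivity.

A built-in synthetic benchmark (100×100×20 voxels, spheres of radii 7
and 9 including a touching pair, Poisson-Gaussian noise calibrated to
SNR 2 / −1 / −5 / −7 dB) exercises every stage with exact ground truth
and no external data.

## Worked example

```r
library(sparsenuclei)

suite <- make_benchmark_suite(seed = 1)        # four calibrated noise levels
lv <- suite[["snr_-5dB"]]

res <- segment_pipeline(lv$volume)             # patch 15x15x5, K=64, L=3,
                                               # 15 iterations, Otsu mask
ev <- evaluate_segmentation(res, lv$gt)
round(c(TP = ev$TP, FN = ev$FN, FP = ev$FP,
        F = ev$f_measure, Jaccard = ev$jaccard_mean), 2)
#>      TP      FN      FP       F Jaccard
#>    6.00    0.00    0.00  100.00    0.76
```

All six spheres — including the touching pair — are recovered with no
false positives at −5 dB (`F = 100`); the matched-pair Jaccard of 0.76
reflects boundary shrinkage under heavy noise, not lost objects.
`res$centroids` holds the per-object centroid table;
`denoise_volume()`, `detection_map()`, `max_response()`,
`detect_markers()` and `watershed_segment()` expose the individual
stages. A thin command-line wrapper with `simulate`, `denoise`,
`segment`, `evaluate`, `sweep-cv` and `run-full` subcommands lives in
`inst/cli/sparsenuclei`.

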