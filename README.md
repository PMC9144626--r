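# mpmtumor

Computer-aided differentiation of breast **fibroadenoma (FA)** from
**phyllodes tumor (PT)** on label-free multiphoton microscopy (MPM) images.

Both lesions are fibroepithelial tumors that are hard to tell apart on a
core-needle biopsy, yet they are managed differently: most FAs are observed,
PTs are excised. Two-channel MPM separates the informative tissue
compartments without staining: **second harmonic generation (SHG)** arises
from fibrillar collagen and is bright in stroma, while **autofluorescence
(AF)** (NADH, flavins) delineates epithelium. The package implements the
full analysis pipeline:

1. **Semantic segmentation** — a compact SegNet-style encoder–decoder
   (max-pooling indices reused by the decoder for unpooling) assigns every
   pixel to *Epithelial*, *Stroma* or *Outer*, trained by SGD with momentum
   (momentum 0.9, learning rate 0.01, L2 0.0005, mini-batch 4) with random
   flip/translation (≤ 20 px) augmentation.
2. **Per-image signatures** — the epithelial-to-stromal area ratio
   `r = #Epithelial / #Stroma` (elevated in PT) and the mean SHG intensity
   within stroma (elevated in FA, reflecting collagen organisation), both on
   the 8-bit analysis scale.
3. **Group statistics** — per-lesion mean ± SD and a two-sample
   Kolmogorov–Smirnov test (`D = sup |F̂_FA − F̂_PT|`; exact permutation p
   for small samples, asymptotic otherwise).
4. **Discrimination** — Fisher linear discriminant analysis
   `w = S⁻¹(μ_PT − μ_FA)` in the two-score feature space, on whole images
   and on 128-px blocks (4 × 4 subdivision, zero-stroma blocks excluded,
   500 blocks sampled per class), plus the orientation of the decision
   boundary relative to the SHG axis.

No patient images are distributed, so the package ships a **synthetic
cohort generator** that emulates the acquisition design — 5 FA + 5 PT
patients, 6–12 imaged regions each, 33 FA and 43 PT frames, 12-bit
two-channel rasters — and the qualitative FA/PT contrasts (round ducts vs
elongated leaf-like clefts, stronger vs weaker stromal SHG), with
per-patient random effects so frames from one patient are correlated.

## Worked example

```r
library(mpmtumor)

dir <- file.path(tempdir(), "demo")
man <- generate_cohort(cohort_spec(seed = 7),
                       optics_fa = optics_params(frame_size = 128),
                       optics_pt = pt_optics(frame_size = 128),
                       dir = dir)
table(man$lesion)
#> FA PT
#> 33 43

man <- split_dataset(man, 0.5, seed = 11)
model <- segnet(man, network_config(encoder_depth = 2, base_filters = 8),
                training_config(epochs = 60, seed = 5))
evaluate_split(model, man, "test")
#> Segmentation evaluation (test split, n = 38 images)
#>   total_accuracy  mean 0.9809  sd 0.0042
#>   weighted_iou    mean 0.9626  sd 0.0080
#>   pooled: accuracy 0.9809, weighted IoU 0.9625

scores <- score_dataset(man, "ground_truth")
scores$stats
#> area_ratio: FA 0.512 +/- 0.367, PT 1.587 +/- 1.164 (KS D = 0.625, p = 9.21e-07, *)
#> shg_stroma_mean: FA 117.340 +/- 14.697, PT 73.134 +/- 5.669 (KS D = 1.000, p = 1.21e-16, *)

pts <- build_block_features(man, "ground_truth", block_px = 32,
                            n_per_class = 500, seed = 3)
fit <- fit_lda(pts)
fit
#> Fisher LDA on (area ratio, stromal SHG) [standardized features]
#>   w = (0.1694, -9.0109), b = -0.0000
#>   boundary angle to SHG axis: 88.9 degrees
```

The per-image accuracy/weighted-IoU means quantify how well the network
reproduces the ground-truth masks on held-out images; the score table shows
the two lesion signatures separating with KS significance (`*` marks
p < 0.05); the LDA boundary lying almost perpendicular to the SHG axis
(88.9°) indicates that stromal SHG intensity carries most of the
discrimination, with the area ratio refining it.

The whole pipeline can also be run as one reproducible job
(`run_full(default_run_config("desk", seed = 1), "run1")`, or
`inst/cli/mpm-pipeline run-all --out run1 --seed 1` from a shell), which
writes every artifact with MD5 checksums and a collated `report.txt`.

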