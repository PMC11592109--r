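# evquant

Quantification of DiO-stained extracellular vesicles (EVs) in fluorescence
micrographs, and the downstream statistics used when plasma-EV cargo
(miRNAs, lncRNAs, metabolites) is evaluated as a relapse biomarker in
early-stage non-small-cell lung cancer (NSCLC).

Blood-based liquid biopsy studies of this kind chain together several
bespoke computations: counting sub-resolution fluorescent vesicles in
microscope images, relative expression of candidate miRNAs by RT-qPCR,
survival analysis of dichotomized expression groups, and a cross-omics
step that intersects miRNA-associated and metabolite-associated pathways
to nominate biomarkers. `evquant` implements each stage as a tested,
seeded, reusable component, together with synthetic-data generators with
known ground truth so that the whole pipeline is verifiable by parameter
recovery — no downloads, no patient data.

## What is inside

* **Synthetic data** (`simulate_ev_image()`, `simulate_image_dataset()`,
  `simulate_cq_table()`, `simulate_survival_table()`,
  `simulate_omics_fixture()`): seeded generators for fluorescence images
  with planted PSF-limited spots, long-format qPCR Cq tables with a
  planted fold change, exponential survival cohorts with a planted hazard
  ratio, and a cross-omics fixture with one planted pathway/miRNA/lncRNA
  chain among decoys.
* **Imaging** (`extract_green()`, `clahe()`, `denoise_channel()`,
  `auto_mask()`, `count_objects()`, `tile_image()`, `augment_tiles()`):
  classical preprocessing and automated intensity-distribution masks.
* **Multitask network** (`build_mtl()`, `train_mtl()`, `tune_mtl()`,
  `predict()`, `predict_image_count()`): a compact U-Net-style
  encoder/decoder for 128 x 128 tiles with two outputs — a per-pixel
  foreground probability map and a non-negative EV count from a
  regression head — trained jointly with
  `L = lambda_seg (Dice + BCE) + lambda_count MSE(log1p count)`
  on CPU, with seeded reproducibility. Implemented on compiled
  im2col+GEMM kernels; gradients verified against finite differences.
* **Metrics** (`dice()`, `iou()`, `count_errors()`, `rank_sum_test()`):
  segmentation overlap (`D = 2|A∩B|/(|A|+|B|)`,
  `J = |A∩B|/|A∪B|`), counting error summaries, and an exact/approximate
  Wilcoxon rank-sum test.
* **Expression & survival** (`delta_cq()`, `fold_change()`,
  `spikein_recovery()`, `dichotomize_median()`, `km_estimate()`,
  `logrank_test()`, `kappa_agreement()`): the 2^-ddCq method of relative
  quantification (`FC = 2^-(dCq_sample - dCq_calibrator)`), spike-in
  recovery QC, the Kaplan-Meier product-limit estimator, the two-group
  log-rank test, and Cohen's kappa. The published 32-patient cohort
  characteristics table ships as `nsclc_cohort()`.
* **Integration** (`filter_degs()`, `map_mirnas()`, `link_lncrnas()`,
  `ora()`, `adjust_p()`, `norm_metabolites()`, `annotate_mz()`,
  `metabolite_ora()`, `top_features()`, `intersect_nominate()`,
  `run_integration()`): DEG filtering at p-adj < 0.05 and FC > |2|,
  typed regulatory networks, hypergeometric over-representation
  `P(X >= k)` with BH/Bonferroni adjustment, median/log10/Pareto
  metabolomics normalization, 3-ppm accurate-mass annotation, and
  pathway-intersection biomarker nomination.

## Worked example

```r
library(evquant)

## 1. Simulate a micrograph with planted vesicles and recover the count
cfg <- image_sim_config(n_spots_range = c(10, 30))
sim <- simulate_ev_image(cfg, seed = 1)
mask <- auto_mask(denoise_channel(extract_green(sim$image)))
mask
#> <mask_image> 256x256, 13 object(s) at 8-connectivity
sim$gt$true_count
#> [1] 13

## 2. Relative expression of a planted 4-fold down-regulated miRNA
qcfg <- cohort_sim_config(n_patients = 31, n_controls = 10,
                          planted_fold_change = 0.25)
tab <- simulate_cq_table(qcfg, seed = 1)
dcq <- delta_cq(tab)
groups <- unique(tab[, c("sample_id", "group")])
fc <- fold_change(dcq, dcq[groups$sample_id[groups$group == "control"]])
mean(fc[groups$sample_id[groups$group == "case"]])
#> [1] 0.2676899

## 3. Survival analysis of the published cohort table
t1 <- nsclc_cohort()
km_estimate(t1$os_months, t1$death)
#> <km_fit> n = 32, 11 event time(s)
#>    time n_risk n_event survival
#> 1  11.7     32       1   0.9688
#> 2  14.8     31       1   0.9375
#> ...
#> 11 40.4     13       1   0.6244
logrank_test(t1$os_months, t1$death,
             ifelse(t1$histology == "SCC", "SCC", "non-SCC"))$p
#> [1] 0.7441769
```

The masked object count equals the planted count; the mean recovered fold
change (0.268) sits at the planted 0.25 within qPCR noise; the
Kaplan-Meier curve and log-rank statistic agree with
`survival::survfit()`/`survdiff()` to numerical precision (a property the
test suite asserts at every event time).

Training the multitask network end to end:

```r
cfg <- image_sim_config(height = 128, width = 128, n_spots_range = c(3, 12))
train <- simulate_image_dataset(cfg, 40, seed = 42)
val <- simulate_image_dataset(cfg, 10, seed = 43)
fit <- train_mtl(build_mtl(arch_config(), seed = 42),
                 augment_tiles(tile_dataset(train), n_aug = 10, seed = 42),
                 tile_dataset(val),
                 train_config(max_epochs = 12, seed = 42))
fit
#> <mtl_fit> 12 epochs (best 11): val Dice 0.976, val count MAE 0.84
```

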