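# sonostate

Resting-state functional connectivity analysis for functional ultrasound
(fUS) imaging: CCA denoising of Power-Doppler pixel time series against an
extracerebral noise region, followed by phase-based dynamic functional
connectivity (dFC) brain-state analysis with occupancy / dwell-time /
transition biomarkers, group statistics, and a biomarker classifier.

It is written for imaging groups analysing rodent (or neonatal) fUS
resting-state recordings who need preprocessing that removes physiological
and motion confounds **without** discarding epochs — preserving the
continuous time course that dynamic connectivity analysis requires — and
for methodologists who want a fully simulatable testbed for such pipelines.

## The method

Let `Xf` and `Xn` be time × pixel matrices of CBV-proportional signals from
the functional brain region and a designated noise region. Each is centered
and whitened through its SVD (`X = USVᵀ`, whitened form `UVᵀ`), and the
concatenation is decomposed again:

```
[X̃f X̃n] = U S Vᵀ,    canonical correlation of component i = Sᵢ² − 1.
```

The leading columns of `U` are the temporal components common to brain and
non-brain tissue — physiological noise and motion artifacts. Denoising is
the orthogonal projection of `Xf` off the first `th_CCA` components, with
`th_CCA` chosen as the smallest value for which the cohort-mean correlation
between the denoised signal and the tissue-motion magnitude trace falls
below 0.1 (one-tailed p < 0.001 via Fisher's z).

Denoised signals are bandpassed (zero-phase Butterworth, 0.01–0.1 Hz),
standardized, and averaged over seven regions (S1, M1, Ins, Str, HPC, TH,
CC). Instantaneous phases `φᵢ(t)` from the Hilbert analytic signal give a
synchronicity matrix per time point,

```
c_t(i, j) = cos(φᵢ(t) − φⱼ(t)),
```

whose vectorized stack is clustered with L1-norm k-means (K = 4, 100
iterations × 100 repetitions, median centroids) into recurring brain
states. Per animal and state, the package computes fractional occupancy
(FO), mean dwell time (MDT, s) and transition probabilities (TP), compares
them between groups (t-tests for FO and TP, Mann–Whitney for MDT, with
Bonferroni factors K−1, K and (K−1)K), and combines selected biomarkers in
a logistic-regression classifier summarized by ROC/AUC and the Youden
operating point. A synthetic-cohort generator with latent Markov state
sequences and planted noise provides ground truth for every stage.

## Worked example

Simulate a 16-animal cohort under the reference study conditions (15-minute
acquisitions at 2.5 Hz; the treated group spends less time in the globally
synchronous state), denoise, cluster, and test:

```r
library(sonostate)

cfg <- generator_config()
sim <- simulate_cohort(cfg, c(control = 8, treated = 8), seed = 1)

den <- denoise_cohort(sim$cohort, method = "cca", th = "auto")
den$report
#> <fus_denoising_report> selected th = 1 (cutoff 0.1); mean motion correlation at th: 0.0295

dfc <- dfc_analysis(den$cohort, repetitions = 20, seed = 2)
dfc$model
#> <fus_cluster_model> K = 4, 33600 points, total L1 cost 46853.87
#>   occurrences: 6571, 7177, 9865, 9987

compare_fo(dfc$biomarkers)
#>   biomarker mean1    sd1 mean2    sd2   p_raw p_corrected significant
#> 1      FO_1 0.184 0.0873 0.207 0.0607 0.53787      1.0000       FALSE
#> 2      FO_2 0.185 0.0762 0.242 0.0729 0.14721      0.4416       FALSE
#> 3      FO_3 0.370 0.1273 0.217 0.0477 0.00682      0.0205        TRUE
#> 4      FO_4 0.262 0.0904 0.333 0.0930 0.14202      0.4261       FALSE

clf <- fit_classifier(dfc$biomarkers[, c("FO_1", "FO_2", "FO_3")],
                      factor(dfc$biomarkers$group))
clf
#> <fus_classifier> features: FO_1, FO_2, FO_3
#>   LRT vs constant model: p = 0.0272
#>   AUC = 0.859
```

Reading the output: one common component suffices to push the
motion–signal correlation below the 0.1 significance cutoff for this
cohort. States are sorted by increasing occurrence; here state 3 is the
globally synchronous configuration, occupied 37.0% of the time in controls
versus 21.7% in the treated group — significant after Bonferroni
correction (p = 0.021) — and the FO biomarkers separate the groups with an
in-sample AUC of 0.86.

The same analysis runs as one orchestrated, manifest-writing pipeline:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
```

or from a shell via the bundled CLI
(`Rscript inst/cli/sonostate.R run --config pipeline.json`), with
subcommands `simulate | denoise | staticfc | dfc | stats | classify`.

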