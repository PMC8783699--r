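# bpcluster

Continuous, cuff-less blood pressure estimation from paired ECG/PPG
waveforms, built around a **cluster-then-regress** strategy.

Beat-to-beat feature data pooled across subjects and physiological
states is highly dispersed and multitrend: the same region of feature
space can sit on differently sloped blood-pressure responses. A single
regression model spreads its capacity across all of those trends at
once. `bpcluster` instead partitions the feature space first and fits a
dedicated model per partition:

1. **Extract** per-cardiac-cycle features from synchronized ECG/PPG/ABP
   records: pulse transit time *PTT* (R-peak to SDPPG-peak lag, s), PPG
   intensity ratio *PIR* = IH/IL (peak over valley intensity, ≥ 1),
   heart rate *HR* = 60·fs/RR (bpm), and the targets *SBP* = max(ABP),
   *DBP* = min(ABP) per cycle (mmHg).
2. **Cluster** the z-scored (PTT, PIR, HR) space with k-means (Lloyd,
   k-means++ init), selecting k by the mean silhouette
   s(i) = (b−a)/max(a,b) over k = 2…10.
3. **Fit one regressor per cluster** and per target — gradient boosting,
   random forest, or a multilayer perceptron — and route new samples to
   the Euclidean-nearest centroid.
4. **Aggregate** per-cluster metrics by the weighted arithmetic mean
   Σnᵢvᵢ/Σnᵢ, and grade the estimates against the BHS protocol
   (cumulative % of |error| ≤ 5/10/15 mmHg → grade A/B/C/D), the AAMI
   criterion (|ME| ≤ 5, SD ≤ 8 mmHg, ≥ 85 subjects) and Bland–Altman
   limits of agreement (bias ± 1.96·SD).

A beat-synchronized synthetic ECG/PPG/ABP simulator with exact per-beat
ground truth (`generate_population()`, `default_regimes()`) supports
end-to-end validation: on its five-regime, high-dispersion reference
population, feature extraction recovers the ground truth at sample
resolution, silhouette selection recovers k = 5, and the per-cluster
ensemble consistently beats a same-family global model.

## Worked example

```r
library(bpcluster)

cfg <- pipeline_config(regimes = default_regimes(n_beats = 400L),
                       k = "auto", learner = "gradient_boosting", seed = 42L)
res <- run_pipeline(cfg)
#> extract: 1995 cycles retained, 0 dropped
#> cluster: k = 5 (mean silhouette 0.556)

print(res$report)
#> Blood-pressure estimation report [clustered, test split] (n = 398 cycles)
#>   SBP: MAE 3.032  RMSE 3.835 (pooled 3.850)  r 0.895 mmHg
#>        BHS 82.2/98.2/100.0% -> grade A;  AAMI ME 0.24 SD 3.85 -> fail
#>   DBP: MAE 2.866  RMSE 3.561 (pooled 3.580)  r 0.848 mmHg
#>        BHS 82.9/99.2/100.0% -> grade A;  AAMI ME -0.06 SD 3.58 -> fail

print(res$comparison, digits = 3)
#>             learner estimator sbp_mae sbp_rmse sbp_r dbp_mae dbp_rmse dbp_r
#> 1 gradient_boosting    global    3.46     5.08 0.820    3.06     4.15 0.790
#> 2 gradient_boosting clustered    3.03     3.84 0.895    2.87     3.56 0.848
```

Reading the output: the pipeline simulated five waveform regimes
(2,000 beats → 1,995 complete cycles), extracted the per-cycle feature
table, chose k = 5 by silhouette, and fitted per-cluster gradient
boosting models on a cluster-stratified 80% training split. On the
held-out cycles the clustered estimator's weighted-total MAE (3.03 /
2.87 mmHg for SBP/DBP) undercuts the global model fitted on the same
training rows (3.46 / 3.06 mmHg), with both estimators BHS grade A on
this synthetic population. The AAMI line reports *fail* solely because
the simulated population contains 5 records, below the standard's
85-subject floor — the error bounds themselves are met.

The same stages are scriptable from the shell via the thin CLI:

```sh
Rscript inst/cli/bp-pipeline.R simulate --config inst/extdata/regimes_example.yaml \
        --seed 3 --out-dir work/
Rscript inst/cli/bp-pipeline.R extract --in work/regime1.csv --out work/features.csv
Rscript inst/cli/bp-pipeline.R cluster --features work/features.csv --k auto \
        --seed 3 --out work/model.json
```

(subcommands: `simulate`, `extract`, `cluster`, `train`, `predict`,
`evaluate`, `run`, `compare`).

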