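# uqscreen

Uncertainty-aware compound-activity prediction for virtual screening in R.

Ligand-based QSAR models are trained on public bioactivity records that are
doubly unreliable: known ligands cover a narrow slice of chemical space, so
predictions on novel chemotypes are extrapolations, and the records
themselves (Ki/IC50 values from heterogeneous assays) are sometimes plain
wrong. `uqscreen` is for computational chemists who want their regression
models to say *how sure* they are — and to use that information. It
provides:

* **Curation** of ChEMBL-style activity tables (parameter whitelist Ki,
  log(Ki), pKi, IC50, log(IC50), pIC50; strict `=` or extended relation
  sets; units M…fM) onto a common log10(Ki in nM) scale, with Ki = IC50/2
  for the IC50 family and per-compound aggregation (label = mean log
  activity, population SD over repeated measurements).
* **Fingerprints & similarity**: Morgan radius-2 and MACCS keys through an
  RDKit backend, synthetic fingerprints for backend-free work, and
  Tanimoto similarity |A∩B|/|A∪B| with max-similarity-to-training-set as
  the applicability-domain measure.
* **Splits**: random 5-fold CV and balanced agglomerative clustering (BAC),
  which clusters compounds by structure and assigns whole clusters to
  folds — the honest, harder evaluation regime.
* **MC-dropout MLP regressor**: a 500/500/200 ReLU network with dropout
  0.5 after every hidden layer, Adam (lr 0.001), 200 epochs, batches of
  100. Keeping dropout active at inference and running T = 50 passes gives
  a per-compound prediction ŷᵢ (mean over passes) and uncertainty uᵢ
  (standard deviation over passes).
* **Uncertainty-augmented ranking**: six hit-list scoring strategies —
  R = ŷᵢ (baseline), ŷᵢ+uᵢ, ũᵢ·ŷᵢ, ũᵢ+ŷᵢ, ũᵢ+ỹᵢ, and λŷᵢ+(1−λ)uᵢ (lower R
  = higher rank; ũ, ỹ min-max normalised) — evaluated by precision at the
  top 10%.
* **Suspect-record detection**: flags test compounds whose squared error
  is at/above the 95th percentile while uncertainty satisfies a
  directional 5th-percentile criterion, with the 10 most similar training
  compounds attached as curator context.
* **A synthetic generator** (clustered bit patterns, smooth bilinear
  activity landscape, repeated noisy measurements, injected label
  corruption) so the entire pipeline is testable end-to-end offline.

See `vignettes/uncertainty-aware-screening.Rmd` for the full model
description and design rationale.

## Worked example

Curate the bundled toy activity table (20 records exercising every filter
stage), then run a small synthetic benchmark:

```r
library(uqscreen)

recs <- readActivityRecords(system.file("extdata",
          "toy_activity_records.csv", package = "uqscreen"))
prep <- prepareActivityData(recs, relation_mode = "strict")
prep$report
#>              stage records_in records_out
#> 1  organism_filter         20          19
#> 2 parameter_filter         19          17
#> 3  relation_filter         17          14
#> 4      unit_filter         14          13
#> 5  standardization         13          11
```

One rat-assay record, two non-binding parameters (Kd, EC50), three
non-`=` relations, one bogus unit and two unstandardizable values drop,
leaving 11 measurements on 8 compounds:

```r
head(prep$compounds[, c("compound_id", "n_values", "mean_log_activity",
                        "std_log_activity", "label")], 4)
#>    compound_id n_values mean_log_activity std_log_activity  label
#> 1 CHEMBL139089        2             1.701           0.1328  1.701
#> 2 CHEMBL317433        1            -0.699           0.0000 -0.699
#> 3       TOY003        1             1.699           0.0000  1.699
#> 4       TOY004        1             3.000           0.0000  3.000
```

(37 and 68.2 nM average to log10 Ki = 1.701; a single 0.2 nM measurement
gives label −0.699 with spread exactly 0; 100 nM IC50 halves to 50 nM Ki,
log10 = 1.699; 1 µM = 3.0.)

Synthetic benchmark — train on four folds, predict the fifth with 50 MC
passes:

```r
ds    <- genDataset(synthConfig(n_compounds = 600, n_bits = 128,
                                n_clusters = 8, seed = 7))
cv    <- randomCvFolds(compoundIds(ds$fps), k = 5, seed = 7)
ix    <- foldIndices(cv, 0)
model <- mlpTrain(ds$fps[ix$train], ds$labels[ix$train],
                  mlpConfig(epochs = 50, seed = 7))
pred  <- predictMc(model, ds$fps[ix$test], seed = 8)
evaluatePredictions(pred, ds$labels[ix$test])
#> EvalSummary (n = 120)
#>   MSE (deterministic): 0.95615
#>   MSE (MC dropout):    0.27440
#>   mean uncertainty:    0.46009
```

The MC committee average beats the deterministic pass, as expected for
stacked 0.5-dropout layers. Ranking the held-out fold:

```r
rankingSweep(yMc(pred), uncertainty(pred), ds$labels[compoundIds(pred)])[1:5, ]
#>     strategy lambda precision_at_top delta_vs_baseline
#> 1   baseline     NA            0.667            0.0000
#> 2        add     NA            0.583           -0.0833
#> 3      scale     NA            0.667            0.0000
#> 4 add_scaled     NA            0.583           -0.0833
#> 5 sum_scaled     NA            0.667            0.0000
```

i.e. the predicted top decile recovers two-thirds of the truly most
active compounds here; whether uncertainty helps the ranking is
target-dependent, which is exactly why the sweep table exists.

`runPipeline(pipelineConfig(...), out_dir)` chains all stages
(simulate/ingest → prepare → featurize → split → per-fold train/predict →
rank → detect → analyze) with a manifest and per-stage resume; a thin CLI
wrapper with one subcommand per stage lives at
`system.file("cli", "uqscreen.R", package = "uqscreen")`.

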