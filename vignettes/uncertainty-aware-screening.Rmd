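---
title: "Uncertainty-aware activity prediction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware activity prediction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ligand-based activity models are trained on public bioactivity records
(Ki, IC50 and their logarithmic forms against a protein target) that are
noisy in two distinct ways: the chemistry covered by known ligands is narrow,
so a model asked about a structurally novel compound is extrapolating; and
the records themselves are sometimes wrong — unit mix-ups, assay
incompatibilities, transcription errors. `uqscreen` implements a regression
pipeline that carries a per-compound *uncertainty* alongside every
prediction and puts that uncertainty to work twice: to re-rank screening
hit lists, and to flag activity records that look like database errors.

# The model and its uncertainty

The regressor is a multi-layer perceptron from binary molecular
fingerprints to log10(Ki in nM): three ReLU hidden layers of 500, 500 and
200 units, a linear single-output head, and a dropout layer (drop
probability 0.5) after every hidden layer. Training minimises mean squared
error with Adam (learning rate 0.001) for 200 epochs in mini-batches of
100, with no additional regularisation penalty — dropout is the only
regulariser. These defaults are all exposed through `mlpConfig()`.

Uncertainty comes from Monte-Carlo dropout: dropout is kept active at
inference and each compound is pushed through the network T times (default
`mc_passes = 50`) with independent masks. The mean over passes is the MC
prediction `y_mc` — an implicit committee average — and the standard
deviation over passes is the uncertainty `u_i`. We report the standard
deviation rather than the variance so that `u_i` shares the units of the
prediction (log10 Ki); `uncertainty_stat = "var"` switches conventions. T
defaults to 50 as a compromise between the stability of a standard
deviation over passes and desk-scale cost; the committee property (the
run-to-run spread of `y_mc` shrinks as T grows) is asserted in the test
suite.

Dropout uses inverted scaling (activations divided by the keep probability
whenever a mask is applied), so the no-dropout deterministic pass `y_det`
is the first-order approximation of the mask average. With stacked p = 0.5
dropout layers and ReLU that approximation is visibly biased — the
deterministic test MSE is consistently *higher* than the MC-mean MSE, which
is the expected committee effect, and the reason `y_mc` is the pipeline's
canonical prediction. At `dropout_rate = 0` the two coincide exactly and
all uncertainties are exactly zero; this degenerate case is pinned in the
tests.

Why a hand-rolled network: the model is the methodological core of the
package, small enough (three dense layers, square loss) that a vectorised
implementation over the BLAS is both transparent and fast, and its
gradients are verified against numerical differentiation in the test
suite.

# Curation conventions

`prepareActivityData()` applies, in order: an optional organism filter, the
binding-parameter whitelist {Ki, log(Ki), pKi, IC50, log(IC50), pIC50}, the
relation filter (`strict` keeps only `=`; `extended` also keeps `<`, `>`,
`<=`, `>=`, `~`), and the unit filter {M, mM, µM, nM, pM, fM} for
concentration parameters. Every stage reports in/out counts, so drops are
auditable and counts are conserved.

Standardisation choices worth stating explicitly:

* **Scale.** Everything becomes log10 of Ki in nM (1 nM maps to 0);
  `log_convention = "pKi"` gives −log10 M instead. The nM log scale keeps
  worked values in the single digits for typical nM–µM chemistry.
* **IC50 to Ki.** IC50-family values are halved before logging — the
  conventional factor-of-two relation for competitive binding at substrate
  concentration near Km.
* **p-forms** are interpreted as −log10 of the molar value. **Plain
  log-forms** (`log(Ki)`, `log(IC50)`) are *rejected* unless the caller
  declares their base and unit via `log_form =` — exports do not define
  them, and silently guessing is worse than dropping with a counted reason.
* **Aggregation.** A compound's label is the mean of its log-scale
  measurements; the spread is the *population* standard deviation
  (divide-by-n), so a single measurement has spread exactly 0 without
  special-casing. The nM-scale mean is also emitted (`mean_ki_nm`) because
  assay reports usually quote it; the regression label stays on the log
  scale (`label_scale = "nM"` switches). Duplicate identical values count
  as separate measurements.

# Splitting

`randomCvFolds()` deals compounds into k = 5 folds differing in size by at
most one. `bacFolds()` implements balanced agglomerative clustering:
average-linkage clustering on Tanimoto distance (1 − Tanimoto), the
dendrogram cut into `min(3k, n)` clusters (three clusters per fold gives
the packer room to balance), then whole clusters packed greedily — largest
first, always onto the currently smallest fold, ties to the lowest fold
index. Clusters exceeding the fold capacity `ceiling(n/k)` are split, only
as a last resort, into capacity-sized chunks. The linkage and cut height
are documented defaults (`clusters_per_fold =`), not canonical: the
procedure family is standard but under-specified in the literature, and
the package treats them as tunable.

The point of BAC is that test compounds become structurally dissimilar
from the training set; `betweenFoldSimilarity()` measures exactly that, and
the benchmark below quantifies how much harder the regression task gets.

# Ranking strategies

With `y_hat` the predicted log-activity (lower = more active) and `u` the
uncertainty, `rankCompounds()` scores compounds so that lower R ranks
higher:

| strategy     | R                          |
|--------------|----------------------------|
| `baseline`   | `y_hat`                    |
| `add`        | `y_hat + u`                |
| `scale`      | `norm(u) * y_hat`          |
| `add_scaled` | `norm(u) + y_hat`          |
| `sum_scaled` | `norm(u) + norm(y_hat)`    |
| `comb`       | `λ·y_hat + (1−λ)·u`        |

Two min-max conventions exist for `norm()`: `(v−min)/(max−min)` maps
exactly onto [0, 1] and is the default (`minmax_range`); `(v−min)/max`
(`minmax_over_max`) is provided verbatim for comparability with the
alternative printed form, though its range depends on the sign of the
scores. Both agree on orderings whenever scores are non-negative and
min = 0. The `scale` strategy applied to signed log-activities multiplies
negatives by a [0, 1] factor, which *rewards* uncertain negatives; the
package warns rather than silently repairing the formula. Ties in R are
broken by compound id, making every ordering deterministic.

`precisionAtTop()` takes the `ceiling(fraction·n)` truly most-active
compounds and the same number of top-ranked compounds and reports their
overlap fraction; it is invariant to monotone transforms of R and uses the
same id tie-break. `rankingSweep()` tabulates all strategies plus a λ grid
of 0, 0.1, …, 1 (λ = 1 reproduces the baseline exactly).

# Suspect-record detection

`flagSuspects()` flags test compounds whose squared error (of `y_mc`
against the label) is at or above the `error_pctl` percentile while the
uncertainty satisfies a directional criterion at `unc_pctl`. Percentile
rank is defined as `100 · (#strictly smaller)/n`: deterministic under
ties, and on n distinct values "rank ≥ 95" selects exactly the top 5%.
With all values tied, no compound reaches the 95th percentile (and every
compound reaches the 0th) — the degenerate case is pinned in tests.

The uncertainty direction is a real analysis choice: `at_least` (the
default) keeps the criterion permissive — almost every compound passes an
"uncertainty at or above the 5th percentile" test, so flagging is driven by
error; `at_most` expresses the sharper "confident but wrong" reading, where
the model contradicts the record *and* is sure of itself. Both are
implemented; the direction is mandatory in the report so downstream readers
see which was used. `neighborContext()` attaches the N = 10 most similar
training compounds with their labels, which is the evidence a curator
actually inspects.

# The synthetic generator: what it emulates, what it does not

`synthConfig()` defaults are the package's reference study conditions,
chosen once: 2000 compounds, 256 bits, 20 scaffold-like clusters
(prototype bit density 0.3, member bits flipped at 0.05), a bilinear
landscape over 64 informative bits (linear weights plus pairwise bit
interactions, standardised to unit spread, centred at log10 Ki = 2, i.e.
100 nM), landscape noise 0.3 log units, a geometric number of measurements
per compound with mean 2, measurement noise 0.2 log units. These sizes mimic
a mid-sized ChEMBL target export (a few thousand curated compounds spread
over tens of chemotypes with sub-log-unit replicate scatter) while staying
desk-computable. Corruption — an additive offset of 2 log units (100× in
Ki) applied to all of a compound's measurements with probability
`corruption_fraction` — models gross record errors such as unit mix-ups,
with ground-truth flags returned for evaluation.

Measurements are emitted through randomized parameter forms (Ki, IC50 at
exactly twice the Ki, pKi, pIC50) and all six concentration units, so the
curation module's every branch is exercised and, with noise off, curation
inverts generation exactly (asserted to float tolerance).

What the generator does *not* emulate: real substructure-activity cliffs,
fingerprint bit collisions from hashing, assay-to-assay systematic shifts,
censored measurements (relations other than `=` carry no distributional
meaning here), or class-imbalanced activity distributions. Tests passing
on this generator therefore show the machinery is correct and the
qualitative mechanisms (cluster splits are harder; corrupted labels
surface as confident large errors) operate — they do not certify
real-ChEMBL error rates.

# Benchmark protocol and problem sizes

The package's benchmark tests and the acceptance script use the reference
conditions with training shortened to 50 epochs and one held-out fold per
seed (the fold index rotating with the seed) rather than all five folds —
per-seed comparisons (BAC vs CV, enrichment vs base rate) are unchanged by
this choice, and it keeps each experiment around a minute of single-core
time. The full five-fold protocol is what `runPipeline()` executes by
default. At these sizes the observed behaviour is unambiguous: BAC test
MSE exceeds random-CV MSE by a factor of 2–4, and compounds flagged at the
95th error percentile are corrupted at 10× or more the 5% base rate.

# Numerical and degenerate-input choices

* Tanimoto of two all-zero fingerprints is defined as 0 (no shared
  features), with a warning.
* "Similarity to the training set" is the *maximum* Tanimoto over training
  compounds (standard applicability-domain practice); mean is an option.
* Constant vectors normalise to all-zeros in both min-max modes.
* Quartiles in `groupByCount()` use linear interpolation (R's default
  type 7); single-member groups are flagged instead of drawing a
  degenerate box.
* Correlations on zero-variance columns raise a typed
  `uqscreen_undefined_correlation` condition instead of propagating `NaN`.
* Training aborts with a diagnostic on non-finite loss; weights use He
  initialisation; batch shuffling, mask draws and initialisation all hang
  off one integer seed, and reruns with the same seed reproduce rankings
  exactly (BLAS-level floating-point nondeterminism is tolerated in tests
  by comparing at tolerance, not bit equality).
* Morgan fingerprints default to 2048 bits (hashed length is a free
  parameter; 2048 is the common choice); MACCS keys are fixed at 167.

# Known limitations

* The chemistry backend is an external RDKit process; without it only
  precomputed or synthetic fingerprints are available (the error says so
  explicitly).
* MC-dropout uncertainty is epistemic only: it cannot see aleatoric
  measurement noise, which is why the diagnostics module treats
  "uncertainty vs measurement count/spread" as an empirical question and
  asserts nothing about the sign of those correlations.
* The BAC cut/linkage defaults are reasonable, not canonical; different
  choices move the hardness gap quantitatively.
* Percentile flagging on small test sets (n < 20) is unstable and warned
  against.
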