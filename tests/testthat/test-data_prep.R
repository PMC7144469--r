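test_that("relation filtering distinguishes strict from extended mode", {
  recs <- activityRecords(paste0("c", 1:5), "Ki",
                          c("=", "=", "<", "=", "="), c(1, 2, 3, 4, 5), "nM")
  strict <- filterRecords(recs, "strict")
  expect_equal(nrow(strict$records), 4)
  rel_row <- strict$report[strict$report$stage == "relation_filter", ]
  expect_equal(c(rel_row$records_in, rel_row$records_out), c(5, 4))

  ext <- filterRecords(recs, "extended")
  expect_equal(nrow(ext$records), 5)
})

test_that("records with unknown units or parameters are dropped, not fatal", {
  recs <- activityRecords(c("a", "b", "c"), c("Ki", "Ki", "Kd"), "=",
                          c(1, 2, 3), c("nM", "µg/mL", "nM"))
  out <- filterRecords(recs, "strict")
  expect_equal(out$records$compound_id, "a")
  expect_equal(out$report$records_out[out$report$stage == "parameter_filter"], 2)
  expect_equal(out$report$records_out[out$report$stage == "unit_filter"], 1)
})

test_that("filtering is idempotent and drop counts are conserved", {
  cfg <- tinySynth(n = 40, measurement_sd = 0.1)
  recs <- genActivities(genFingerprints(cfg), cfg, strict_relations = FALSE)$records
  once <- filterRecords(recs, "strict")
  twice <- filterRecords(once$records, "strict")
  expect_identical(twice$records, once$records)

  rep <- once$report
  dropped <- sum(rep$records_in - rep$records_out)
  expect_equal(dropped + nrow(once$records), nrow(recs))
})

test_that("standardization converts every parameter form to log10 Ki in nM", {
  expect_equal(standardizeValue("IC50", "=", 100, "nM"), log10(50))
  expect_equal(standardizeValue("Ki", "=", 1, "µM"), 3)
  expect_equal(standardizeValue("Ki", "=", 0.2, "nM"), log10(0.2))
  expect_equal(standardizeValue("pKi", "=", 9, NA), 0)
  expect_equal(standardizeValue("pIC50", "=", 7, NA), 2 - log10(2))
  ## pKi output convention: -log10(M)
  expect_equal(standardizeValue("Ki", "=", 1, "nM", log_convention = "pKi"), 9)
})

test_that("non-positive concentrations and undeclared log forms are rejected", {
  expect_error(standardizeValue("Ki", "=", -5, "nM"), "non-positive")
  expect_error(standardizeValue("Ki", "=", 0, "nM"), "non-positive")
  expect_error(standardizeValue("logKi", "=", 1.5, NA), "log_form")
  ## declared log form is accepted
  expect_equal(standardizeValue("logKi", "=", 1.5, NA,
                                log_form = list(base = 10, unit = "nM")), 1.5)
})

test_that("unit conversion round-trips exactly for all six units", {
  for (u in c("M", "mM", "µM", "nM", "pM", "fM")) {
    x <- c(0.037, 1, 260.5)
    back <- nmToUnit(unitToNm(x, u), u)
    expect_true(all(abs(back - x) / x < 1e-12), info = u)
  }
})

test_that("per-compound aggregation matches hand arithmetic", {
  recs <- activityRecords(rep("CHEMBL139089", 2), "Ki", "=", c(37, 68.2), "nM")
  std <- standardizeRecords(recs)$records
  agg <- aggregateCompounds(std)
  expect_equal(agg$n_values, 2)
  expect_equal(agg$mean_log_activity, (log10(37) + log10(68.2)) / 2,
               tolerance = 1e-12)
  expect_equal(agg$mean_ki_nm, (37 + 68.2) / 2, tolerance = 1e-12)
  expect_equal(agg$label, agg$mean_log_activity)

  one <- aggregateCompounds(standardizeRecords(
    activityRecords("CHEMBL317433", "Ki", "=", 0.2, "nM"))$records)
  expect_identical(one$std_log_activity, 0)
  expect_equal(one$n_values, 1)
})

test_that("aggregation is deterministic, bounded and rejects SMILES conflicts", {
  cfg <- tinySynth(n = 30, measurement_sd = 0.3)
  ds <- genDataset(cfg)
  agg <- ds$compounds
  expect_identical(agg$compound_id, sort(agg$compound_id))
  per <- split(ds$records$compound_id, ds$records$compound_id)
  ## label bounded by the compound's own measurements
  std <- standardizeRecords(filterRecords(ds$records, "strict")$records)$records
  for (id in agg$compound_id) {
    la <- std$log_activity[std$compound_id == id]
    expect_true(min(la) <= agg$label[agg$compound_id == id] + 1e-12)
    expect_true(max(la) >= agg$label[agg$compound_id == id] - 1e-12)
  }

  bad <- data.frame(record_id = c("x1", "x2"), compound_id = "dup",
                    smiles = c("CC", "CCC"), log_activity = c(1, 2))
  expect_error(aggregateCompounds(bad), "dup")
})

test_that("toy table filter counts match hand-computed values in both modes", {
  recs <- readActivityRecords(toyRecordsPath())
  expect_equal(nrow(recs), 20)

  strict <- prepareActivityData(recs, relation_mode = "strict")
  expect_equal(strict$report$records_out,
               c(19, 17, 14, 13, 11))
  expect_equal(strict$report$stage,
               c("organism_filter", "parameter_filter", "relation_filter",
                 "unit_filter", "standardization"))

  ext <- prepareActivityData(recs, relation_mode = "extended")
  expect_equal(ext$report$records_out, c(19, 17, 17, 16, 14))

  ## spot-check curated values against hand arithmetic
  cc <- strict$compounds
  get <- function(id, col) cc[cc$compound_id == id, col]
  expect_equal(get("CHEMBL139089", "mean_log_activity"),
               (log10(37) + log10(68.2)) / 2, tolerance = 1e-12)
  expect_equal(get("CHEMBL317433", "std_log_activity"), 0)
  expect_equal(get("TOY003", "label"), log10(50))
  expect_equal(get("TOY004", "label"), 3)
  expect_equal(get("TOY005", "label"), 0)
  expect_equal(get("TOY009", "label"), mean(c(log10(5e-3), log10(2e-6))))
  expect_equal(get("TOY010", "label"), mean(c(log10(3e6), log10(4e9))))
})

test_that("empty outputs raise an explicit empty-dataset signal", {
  recs <- activityRecords("a", "Kd", "=", 1, "nM")
  expect_warning(filterRecords(recs, "strict"), "empty")
  expect_error(suppressWarnings(prepareActivityData(recs)), "empty dataset")
})
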