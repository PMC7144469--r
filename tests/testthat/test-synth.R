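test_that("generator outputs are fully deterministic under a fixed seed", {
  cfg <- tinySynth(seed = 7)
  a <- genFingerprints(cfg)
  b <- genFingerprints(cfg)
  expect_identical(fpBits(a$fps), fpBits(b$fps))
  expect_identical(a$clusters, b$clusters)
  act_a <- genActivities(a, cfg)
  act_b <- genActivities(b, cfg)
  expect_identical(act_a$latent, act_b$latent)
  expect_identical(act_a$records, act_b$records)
  expect_identical(act_a$corrupted, act_b$corrupted)

  other <- genFingerprints(tinySynth(seed = 8))
  expect_false(identical(fpBits(other$fps), fpBits(a$fps)))
})

test_that("zero flip probability clones the cluster prototypes", {
  cfg <- tinySynth(n = 20, n_clusters = 4, within_cluster_flip_prob = 0,
                   seed = 9)
  fp <- genFingerprints(cfg)
  b <- fpBits(fp$fps)
  for (cl in unique(fp$clusters)) {
    rows <- which(fp$clusters == cl)
    for (r in rows[-1]) expect_identical(b[r, ], b[rows[1], ])
  }
})

test_that("within-cluster similarity exceeds between-cluster similarity", {
  cfg <- synthConfig(n_compounds = 120, n_bits = 128, n_clusters = 6,
                     within_cluster_flip_prob = 0.05, seed = 11)
  fp <- genFingerprints(cfg)
  sim <- tanimotoMatrix(fp$fps)
  same <- outer(fp$clusters, fp$clusters, "==")
  diag(same) <- NA
  within <- mean(sim[which(same)])          # > 1000 within-cluster pairs
  between <- mean(sim[which(!same)])
  expect_gt(within, between)
})

test_that("the no-noise dataset round-trips through curation exactly", {
  cfg <- tinySynth(n = 40, noise_sd = 0, measurement_sd = 0,
                   measurements_per_compound = 3, corruption_fraction = 0,
                   seed = 13)
  ds <- genDataset(cfg)
  expect_equal(unname(ds$labels), unname(ds$latent), tolerance = 1e-9)
  ## fixed 3 measurements of identical value -> std 0
  expect_true(all(ds$compounds$n_values == 3))
  expect_true(all(abs(ds$compounds$std_log_activity) < 1e-9))
})

test_that("single-measurement compounds aggregate with zero spread", {
  cfg <- tinySynth(n = 30, measurements_per_compound = 1,
                   measurement_sd = 0.4, seed = 17)
  ds <- genDataset(cfg)
  expect_true(all(ds$compounds$n_values == 1))
  expect_identical(unique(ds$compounds$std_log_activity), 0)
})

test_that("strict-mode records pass curation with zero unexpected drops", {
  cfg <- tinySynth(n = 50, seed = 19)
  recs <- genActivities(genFingerprints(cfg), cfg, strict_relations = TRUE)$records
  prep <- prepareActivityData(recs, relation_mode = "strict")
  expect_equal(prep$report$records_out[nrow(prep$report)], nrow(recs))
  expect_equal(nrow(prep$rejected), 0)
  ## every parameter form and unit branch gets exercised at this size
  expect_setequal(unique(recs$parameter), c("Ki", "IC50", "pKi", "pIC50"))
})

test_that("corruption flags follow the configured binomial rate", {
  cfg <- synthConfig(n_compounds = 1000, n_bits = 64, n_clusters = 10,
                     corruption_fraction = 0.05, corruption_offset = 2,
                     seed = 23)
  fp <- genFingerprints(cfg)
  act <- genActivities(fp, cfg)
  n_corr <- sum(act$corrupted)
  ## binomial(1000, 0.05): mean 50, sd ~6.9; allow 4 sd
  expect_gt(n_corr, 50 - 28)
  expect_lt(n_corr, 50 + 28)

  ## corrupted compounds sit ~offset above their latent activity
  cfg0 <- synthConfig(n_compounds = 200, n_bits = 64, n_clusters = 5,
                      corruption_fraction = 0.3, corruption_offset = 2,
                      measurement_sd = 0, measurements_per_compound = 1,
                      noise_sd = 0, seed = 29)
  fp0 <- genFingerprints(cfg0)
  act0 <- genActivities(fp0, cfg0)
  prep <- prepareActivityData(act0$records)
  lab <- setNames(prep$compounds$label, prep$compounds$compound_id)
  delta <- lab[names(act0$latent)] - act0$latent
  expect_equal(unname(delta[act0$corrupted]),
               rep(2, sum(act0$corrupted)), tolerance = 1e-9)
  expect_equal(unname(delta[!act0$corrupted]),
               rep(0, sum(!act0$corrupted)), tolerance = 1e-9)
})

test_that("measurement counts follow the configured distribution spec", {
  cfg <- tinySynth(n = 400, seed = 31,
                   measurements_per_compound = list(dist = "geometric",
                                                    mean = 2))
  fp <- genFingerprints(cfg)
  act <- genActivities(fp, cfg)
  m <- act$n_measurements
  expect_true(all(m >= 1))
  expect_gt(mean(m), 1.5)  # mean 2 within sampling noise at n=400
  expect_lt(mean(m), 2.5)
  expect_equal(nrow(act$records), sum(m))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthConfig(n_compounds = 5, n_clusters = 10), "n_clusters")
  expect_error(synthConfig(corruption_fraction = 1.5), "corruption_fraction")
  expect_error(synthConfig(informative_bits = 300, n_bits = 256),
               "informative_bits")
})
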