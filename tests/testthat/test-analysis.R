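mkDiagInputs <- function(seed = 301, n_test = 15, n_train = 25) {
  withr::with_seed(seed, {
    train <- randomFps(n_train, 32, seed = seed + 1, prefix = "train")
    test <- randomFps(n_test, 32, seed = seed + 2, prefix = "test")
    ids <- compoundIds(test)
    pred <- new("PredictionSet", compoundIds = ids, yDet = rnorm(n_test),
                yMc = rnorm(n_test), uncertainty = abs(rnorm(n_test)),
                samples = matrix(0, 0, n_test))
    curated <- data.frame(
      compound_id = c(ids, compoundIds(train)),
      label = rnorm(n_test + n_train),
      n_values = sample(1:5, n_test + n_train, replace = TRUE),
      std_log_activity = c(abs(rnorm(n_test + n_train - 3)), 0, 0, 0))
    y <- setNames(curated$label[1:n_test], ids)
    list(pred = pred, y = y, test = test, train = train, curated = curated)
  })
}

test_that("diagnostics columns equal independently recomputed values", {
  d <- mkDiagInputs()
  tab <- buildDiagnostics(d$pred, d$y, d$test, d$train, d$curated)
  expect_equal(nrow(tab), 15)
  expect_false(anyNA(tab))
  expect_true(all(tab$max_train_similarity >= 0 &
                  tab$max_train_similarity <= 1))

  ## recompute each column by brute force
  expect_equal(tab$squared_error, unname((yMc(d$pred) - d$y)^2))
  for (i in c(1, 8, 15)) {
    q <- fpBits(d$test)[i, ]
    sims <- sapply(seq_len(25), function(j) tanimotoRef(q, fpBits(d$train)[j, ]))
    expect_equal(tab$max_train_similarity[i], max(sims))
  }
  cc <- match(tab$compound_id, d$curated$compound_id)
  expect_equal(tab$n_values, d$curated$n_values[cc])
})

test_that("a memorised test compound shows similarity 1 and near-zero error", {
  train <- randomFps(10, 24, seed = 311)
  dup <- train[3]
  lab <- 1.25
  pred <- new("PredictionSet", compoundIds = compoundIds(dup),
              yDet = lab, yMc = lab + 1e-9, uncertainty = 0.01,
              samples = matrix(0, 0, 1))
  curated <- data.frame(compound_id = c(compoundIds(train)),
                        label = rep(lab, 10), n_values = 1L,
                        std_log_activity = 0)
  tab <- buildDiagnostics(pred, setNames(lab, compoundIds(dup)), dup, train,
                          curated)
  expect_equal(tab$max_train_similarity, 1)
  expect_lt(tab$squared_error, 1e-12)
  expect_equal(tab$std_log_activity, 0)  # single-measurement compound
})

test_that("missing fingerprints or curated rows are reported by name", {
  d <- mkDiagInputs()
  expect_error(buildDiagnostics(d$pred, d$y, d$test[1:5], d$train, d$curated),
               "missing a fingerprint")
  cur2 <- d$curated[-1, ]
  expect_error(buildDiagnostics(d$pred, d$y, d$test, d$train, cur2),
               d$curated$compound_id[1], fixed = TRUE)
})

test_that("correlations hit the textbook anchor cases", {
  tab <- data.frame(compound_id = letters[1:10], x = 1:10)
  tab$same <- tab$x
  tab$neg <- -tab$x
  tab$cubic <- tab$x^3
  expect_equal(correlateDiagnostics(tab, "x", "same")$coefficient, 1)
  expect_equal(correlateDiagnostics(tab, "x", "neg")$coefficient, -1)
  sp <- correlateDiagnostics(tab, "x", "cubic", "spearman")
  expect_equal(sp$coefficient, 1)  # monotone nonlinear: perfect rank corr
  pe <- correlateDiagnostics(tab, "x", "cubic", "pearson")
  expect_lt(pe$coefficient, 1)
  expect_equal(sp$n, 10)
})

test_that("zero-variance columns raise an explicit undefined-correlation signal", {
  tab <- data.frame(x = 1:5, flat = rep(2, 5))
  expect_error(correlateDiagnostics(tab, "x", "flat"),
               class = "uqscreen_undefined_correlation")
  expect_error(correlateDiagnostics(tab[1:2, ], "x", "x"), "at least 3")
})

test_that("per-count grouping partitions rows and flags singletons", {
  tab <- data.frame(compound_id = sprintf("c%02d", 1:11),
                    n_values = c(rep(1L, 5), rep(2L, 5), 7L),
                    uncertainty = c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10, 0.5))
  g <- groupByCount(tab)
  expect_equal(sum(g$group_size), nrow(tab))            # partition
  expect_equal(g$n_values, c(1L, 2L, 7L))

  r1 <- g[g$n_values == 1L, ]
  expect_equal(r1$median, 3)
  expect_equal(c(r1$q1, r1$q3), unname(quantile(1:5, c(.25, .75))))
  expect_false(r1$single_member)

  r7 <- g[g$n_values == 7L, ]
  expect_true(r7$single_member)
  expect_equal(r7$median, 0.5)  # median of one value is the value
  expect_equal(c(r7$min, r7$max), c(0.5, 0.5))
})

test_that("diagnostics are invariant to input row order", {
  d <- mkDiagInputs(seed = 321)
  tab1 <- buildDiagnostics(d$pred, d$y, d$test, d$train, d$curated)
  perm <- withr::with_seed(5, sample(nrow(d$curated)))
  tab2 <- buildDiagnostics(d$pred, d$y, d$test, d$train, d$curated[perm, ])
  expect_equal(tab2, tab1)
})

test_that("the standard correlation summary is bounded, sign left free", {
  d <- mkDiagInputs(seed = 331)
  tab <- buildDiagnostics(d$pred, d$y, d$test, d$train, d$curated)
  cors <- diagnosticCorrelations(tab)
  expect_equal(nrow(cors), 10)  # 5 pairs x 2 methods
  ok <- cors$defined
  expect_true(all(abs(cors$coefficient[ok]) <= 1))
})
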