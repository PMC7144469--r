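## Small architectures keep these tests fast; the full-size protocol is
## exercised by the end-to-end benchmarks.

tinyCfg <- function(...) mlpConfig(hidden_sizes = c(16L, 8L), epochs = 30L,
                                   batch_size = 32L, mc_passes = 25L, ...)

learnableData <- function(n = 200, nb = 24, seed = 41) {
  withr::with_seed(seed, {
    X <- matrix(as.integer(runif(n * nb) < 0.4), n, nb)
    w <- rnorm(nb)
    list(X = X, y = drop(X %*% w) / sqrt(nb))
  })
}

test_that("training reduces the loss on learnable data and is seeded", {
  d <- learnableData()
  m <- mlpTrain(d$X, d$y, tinyCfg(seed = 1))
  expect_lt(m@lossHistory[30], m@lossHistory[1])

  m2 <- mlpTrain(d$X, d$y, tinyCfg(seed = 1))
  expect_equal(m2@weights, m@weights, tolerance = 1e-12)
})

test_that("feature/label mismatch and config misuse raise errors", {
  d <- learnableData()
  expect_error(mlpTrain(d$X, d$y[-1], tinyCfg()), "differ in length")
  expect_error(mlpConfig(dropout_rate = 1), "dropout_rate")
  expect_error(mlpConfig(mc_passes = 1), "mc_passes")
  expect_error(mlpConfig(hidden_sizes = integer(0)), "non-empty")
})

test_that("gradients match numerical differentiation on a micro network", {
  ## independent check of the backprop arithmetic: train one step with
  ## dropout off and compare the analytic gradient against central
  ## differences of the loss.
  withr::with_seed(7, {
    X <- matrix(as.integer(runif(5 * 3) < 0.5), 5, 3)
    y <- rnorm(5)
  })
  cfg <- mlpConfig(hidden_sizes = 4L, dropout_rate = 0, epochs = 1L,
                   batch_size = 5L, learning_rate = 0, seed = 7)
  m <- mlpTrain(X, y, cfg)  # lr 0: weights equal the seeded initialisation
  W <- m@weights
  loss_at <- function(W) mean((uqscreen:::.mlpForward(W, X)$yhat - y)^2)

  ## analytic gradient for W$hidden[[1]]$W[1, 2]
  eps <- 1e-6
  for (probe in list(c(1, 2), c(3, 4))) {
    Wp <- W; Wm <- W
    Wp$hidden[[1]]$W[probe[1], probe[2]] <-
      Wp$hidden[[1]]$W[probe[1], probe[2]] + eps
    Wm$hidden[[1]]$W[probe[1], probe[2]] <-
      Wm$hidden[[1]]$W[probe[1], probe[2]] - eps
    num <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)

    fw <- uqscreen:::.mlpForward(W, X, keep_hidden = TRUE)
    dy <- matrix(2 * (fw$yhat - y) / 5, 5, 1)
    dH <- dy %*% t(W$out$W)
    dA <- dH * (fw$A[[1]] > 0)
    ana <- crossprod(X, dA)[probe[1], probe[2]]
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("zero dropout collapses MC prediction onto the deterministic pass", {
  d <- learnableData()
  m <- mlpTrain(d$X, d$y, tinyCfg(dropout_rate = 0, seed = 2))
  p <- predictMc(m, d$X[1:40, ], T = 10, seed = 5)
  expect_identical(unname(uncertainty(p)), rep(0, 40))
  expect_identical(unname(yMc(p)), unname(yDet(p)))
  ev <- evaluatePredictions(p, d$y[1:40])
  expect_identical(ev$mse, ev$dropout_mse)
})

test_that("MC prediction is reproducible and u_i equals the sample std", {
  d <- learnableData()
  m <- mlpTrain(d$X, d$y, tinyCfg(seed = 3))
  p1 <- predictMc(m, d$X[1:30, ], T = 20, seed = 9)
  p2 <- predictMc(m, d$X[1:30, ], T = 20, seed = 9)
  expect_equal(yMc(p2), yMc(p1), tolerance = 1e-15)
  expect_equal(uncertainty(p2), uncertainty(p1), tolerance = 1e-15)

  s <- mcSamples(p1)
  expect_equal(dim(s), c(20L, 30L))
  expect_equal(unname(yMc(p1)), colMeans(s))
  expect_equal(unname(uncertainty(p1)), apply(s, 2, sd))
  expect_true(all(uncertainty(p1) >= 0))

  expect_error(predictMc(m, d$X[1:5, ], T = 1, seed = 1), "at least 2")
})

test_that("variance option reports squared uncertainty", {
  d <- learnableData()
  m_sd <- mlpTrain(d$X, d$y, tinyCfg(seed = 4))
  m_var <- mlpTrain(d$X, d$y, tinyCfg(uncertainty_stat = "var", seed = 4))
  p_sd <- predictMc(m_sd, d$X[1:10, ], T = 15, seed = 2)
  p_var <- predictMc(m_var, d$X[1:10, ], T = 15, seed = 2)
  expect_equal(unname(uncertainty(p_var)), unname(uncertainty(p_sd))^2)
})

test_that("averaging more MC passes stabilises the committee prediction", {
  ## run-to-run spread of the MC mean across reseeded calls shrinks with T
  d <- learnableData(n = 150)
  m <- mlpTrain(d$X, d$y, tinyCfg(seed = 6))
  Xq <- d$X[1:20, ]
  spread <- function(T) {
    reps <- sapply(1:8, function(s) yMc(predictMc(m, Xq, T = T, seed = 100 + s)))
    mean(apply(reps, 1, sd))
  }
  expect_lt(spread(200), spread(10))
})

test_that("evaluatePredictions computes the advertised arithmetic", {
  p <- new("PredictionSet", compoundIds = c("a", "b"), yDet = c(1, 2),
           yMc = c(1, 2), uncertainty = c(0.1, 0.2),
           samples = matrix(0, 0, 2))
  ev <- evaluatePredictions(p, c(a = 1, b = 2))
  expect_equal(ev$mse, 0)
  ev2 <- evaluatePredictions(p, c(a = 0, b = 1))
  expect_equal(ev2$mse, 1)  # constant offset of 1
  expect_error(evaluatePredictions(p, c(a = 1, z = 2)), "missing")
})

test_that("models round-trip through the JSON checkpoint", {
  d <- learnableData(n = 60)
  m <- mlpTrain(d$X, d$y, tinyCfg(seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_equal(m2@weights, m@weights, tolerance = 1e-12)
  p1 <- predictMc(m, d$X[1:10, ], T = 5, seed = 3)
  p2 <- predictMc(m2, d$X[1:10, ], T = 5, seed = 3)
  expect_equal(yMc(p2), yMc(p1), tolerance = 1e-10)
})
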