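## Dropout multi-layer perceptron regressor with Monte-Carlo-dropout
## uncertainty estimation.
##
## Architecture: three ReLU hidden layers (500, 500, 200 by default), a
## single-neuron linear output, and a dropout layer after every hidden
## layer. Training minimises mean squared error with Adam. Uncertainty is
## obtained by keeping dropout active at inference: each test compound is
## passed through the network T times with independent dropout masks; the
## mean over passes is the MC prediction and the spread across passes is the
## model (epistemic) uncertainty. Inverted-dropout scaling (activations
## divided by the keep probability whenever a mask is applied) makes the
## deterministic no-dropout pass the expectation of the stochastic ones.

#' Configuration for the dropout MLP
#'
#' Defaults are the reference training protocol: hidden sizes 500/500/200,
#' dropout probability 0.5 after each hidden layer, Adam with learning rate
#' 0.001, 200 epochs, mini-batches of 100, and 50 MC passes.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param dropout_rate probability of dropping a hidden unit, in \[0, 1).
#' @param learning_rate Adam step size.
#' @param epochs number of training epochs (no early stopping).
#' @param batch_size mini-batch size (a partial final batch is allowed).
#' @param mc_passes default number of stochastic forward passes T (>= 2).
#' @param uncertainty_stat `"sd"` (default; same units as the prediction) or
#'   `"var"`.
#' @param seed integer seed controlling weight initialisation, batch
#'   shuffling and training dropout masks.
#' @return validated list of class `MLPConfig`.
#' @export
mlpConfig <- function(hidden_sizes = c(500L, 500L, 200L), dropout_rate = 0.5,
                      learning_rate = 0.001, epochs = 200L, batch_size = 100L,
                      mc_passes = 50L, uncertainty_stat = c("sd", "var"),
                      seed = 1L) {
  uncertainty_stat <- match.arg(uncertainty_stat)
  stopIfNot(length(hidden_sizes) >= 1L, "hidden_sizes must be non-empty")
  stopIfNot(dropout_rate >= 0 && dropout_rate < 1,
            "dropout_rate must lie in [0, 1)")
  stopIfNot(batch_size >= 1L, "batch_size must be at least 1")
  stopIfNot(mc_passes >= 2L, "mc_passes must be at least 2 for uncertainty")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 mc_passes = as.integer(mc_passes),
                 uncertainty_stat = uncertainty_stat,
                 seed = as.integer(seed)),
            class = "MLPConfig")
}

relu <- function(x) (x > 0) * x

## Forward pass. masks: NULL for deterministic, or list of 0/keep^-1
## matrices per hidden layer (inverted dropout).
.mlpForward <- function(W, X, masks = NULL, keep_hidden = FALSE) {
  L <- length(W$hidden)
  H <- X
  hs <- if (keep_hidden) vector("list", L) else NULL
  as <- if (keep_hidden) vector("list", L) else NULL
  for (l in seq_len(L)) {
    A <- sweep(H %*% W$hidden[[l]]$W, 2, W$hidden[[l]]$b, "+")
    Z <- relu(A)
    if (!is.null(masks)) Z <- Z * masks[[l]]
    if (keep_hidden) { as[[l]] <- A; hs[[l]] <- Z }
    H <- Z
  }
  yhat <- drop(H %*% W$out$W) + W$out$b
  list(yhat = yhat, H = hs, A = as)
}

.dropoutMasks <- function(batch, sizes, rate) {
  if (rate == 0) return(NULL)
  keep <- 1 - rate
  lapply(sizes, function(h) {
    matrix((stats::runif(batch * h) < keep) / keep, batch, h)
  })
}

#' Train the dropout MLP regressor
#'
#' Minimises mean squared error with Adam under the configuration's training
#' protocol. Dropout is active after every hidden layer during training.
#' Training is deterministic given the configuration seed (up to the
#' floating-point reproducibility of the BLAS in use).
#'
#' @param features a [FingerprintMatrix-class] or plain numeric matrix
#'   (compounds in rows).
#' @param labels numeric vector of regression targets (log-activities),
#'   aligned to the feature rows.
#' @param config an [mlpConfig()].
#' @return An [MCDropoutModel-class].
#' @export
mlpTrain <- function(features, labels, config = mlpConfig()) {
  stopIfNot(inherits(config, "MLPConfig"), "config must come from mlpConfig()")
  X <- if (methods::is(features, "FingerprintMatrix")) fpBits(features)
       else as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopIfNot(n == length(labels),
            sprintf("feature rows (%d) and labels (%d) differ in length",
                    n, length(labels)))
  y <- as.numeric(labels)
  d <- ncol(X)
  sizes <- config$hidden_sizes
  L <- length(sizes)

  withSeed(config$seed, {
    ## He initialisation for ReLU layers
    dims <- c(d, sizes)
    W <- list(hidden = lapply(seq_len(L), function(l) {
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1],
                                   sd = sqrt(2 / dims[l])),
                      dims[l], dims[l + 1]),
           b = numeric(dims[l + 1]))
    }), out = list(W = matrix(stats::rnorm(sizes[L], sd = sqrt(2 / sizes[L])),
                              sizes[L], 1),
                   b = 0))

    ## Adam state mirrors the weight structure
    zeros_like <- function(w) list(
      hidden = lapply(w$hidden, function(x) list(W = x$W * 0, b = x$b * 0)),
      out = list(W = w$out$W * 0, b = 0))
    m <- zeros_like(W); v <- zeros_like(W)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    t_step <- 0L
    loss_hist <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        B <- length(idx)
        masks <- .dropoutMasks(B, sizes, config$dropout_rate)
        fw <- .mlpForward(W, Xb, masks, keep_hidden = TRUE)
        err <- fw$yhat - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (consider a lower learning rate)")
        ep_loss <- ep_loss + loss * B

        ## backprop
        g <- zeros_like(W)
        dy <- matrix(2 * err / B, B, 1)
        Hlast <- if (L >= 1L) fw$H[[L]] else Xb
        g$out$W <- crossprod(Hlast, dy)
        g$out$b <- sum(dy)
        dH <- dy %*% t(W$out$W)
        for (l in rev(seq_len(L))) {
          if (!is.null(masks)) dH <- dH * masks[[l]]
          dA <- dH * (fw$A[[l]] > 0)
          Hprev <- if (l > 1L) fw$H[[l - 1L]] else Xb
          g$hidden[[l]]$W <- crossprod(Hprev, dA)
          g$hidden[[l]]$b <- colSums(dA)
          if (l > 1L) dH <- dA %*% t(W$hidden[[l]]$W)
        }

        ## Adam update
        t_step <- t_step + 1L
        c1 <- 1 - b1^t_step; c2 <- 1 - b2^t_step
        upd <- function(w, mm, vv, gg) {
          mm <- b1 * mm + (1 - b1) * gg
          vv <- b2 * vv + (1 - b2) * gg^2
          w <- w - lr * (mm / c1) / (sqrt(vv / c2) + eps)
          list(w = w, m = mm, v = vv)
        }
        for (l in seq_len(L)) {
          r <- upd(W$hidden[[l]]$W, m$hidden[[l]]$W, v$hidden[[l]]$W,
                   g$hidden[[l]]$W)
          W$hidden[[l]]$W <- r$w; m$hidden[[l]]$W <- r$m; v$hidden[[l]]$W <- r$v
          r <- upd(W$hidden[[l]]$b, m$hidden[[l]]$b, v$hidden[[l]]$b,
                   g$hidden[[l]]$b)
          W$hidden[[l]]$b <- r$w; m$hidden[[l]]$b <- r$m; v$hidden[[l]]$b <- r$v
        }
        r <- upd(W$out$W, m$out$W, v$out$W, g$out$W)
        W$out$W <- r$w; m$out$W <- r$m; v$out$W <- r$v
        r <- upd(W$out$b, m$out$b, v$out$b, g$out$b)
        W$out$b <- r$w; m$out$b <- r$m; v$out$b <- r$v
      }
      loss_hist[epoch] <- ep_loss / n
    }

    methods::new("MCDropoutModel", weights = W, config = unclass(config),
                 lossHistory = loss_hist, nBits = as.integer(d))
  })
}

#' Monte-Carlo-dropout prediction
#'
#' Runs `T` stochastic forward passes with independent dropout masks (and
#' one deterministic pass with dropout off). Per compound: `y_det` is the
#' deterministic prediction, `y_mc` the mean over passes, `uncertainty` the
#' standard deviation (or variance) over passes. With `dropout_rate = 0` the
#' passes are identical, so uncertainty is exactly 0 and `y_mc == y_det`.
#'
#' @param model an [MCDropoutModel-class].
#' @param features [FingerprintMatrix-class] or numeric matrix to predict on.
#' @param T number of MC passes (>= 2); defaults to the model's configured
#'   `mc_passes`.
#' @param seed integer seed for the inference dropout masks.
#' @param keep_samples retain the T x n matrix of per-pass predictions
#'   (default `TRUE`).
#' @return A [PredictionSet-class].
#' @export
predictMc <- function(model, features, T = NULL, seed = 1L,
                      keep_samples = TRUE) {
  stopIfNot(methods::is(model, "MCDropoutModel"), "not a trained model")
  if (is.null(T)) T <- model@config$mc_passes
  stopIfNot(T >= 2L, "T must be at least 2 (standard deviation undefined)")
  X <- if (methods::is(features, "FingerprintMatrix")) fpBits(features)
       else as.matrix(features)
  ids <- if (methods::is(features, "FingerprintMatrix")) compoundIds(features)
         else rownames(X) %||% sprintf("cmpd_%04d", seq_len(nrow(X)))
  storage.mode(X) <- "double"
  stopIfNot(ncol(X) == model@nBits,
            sprintf("model expects %d input bits, got %d", model@nBits, ncol(X)))
  n <- nrow(X)
  rate <- model@config$dropout_rate
  sizes <- model@config$hidden_sizes

  y_det <- .mlpForward(model@weights, X)$yhat
  samples <- withSeed(seed, {
    out <- matrix(0, T, n)
    for (t in seq_len(T)) {
      masks <- .dropoutMasks(n, sizes, rate)
      out[t, ] <- .mlpForward(model@weights, X, masks)$yhat
    }
    out
  })
  ## with dropout off every pass is the deterministic forward, so the MC
  ## mean and the spread are pinned exactly rather than left to summation
  ## rounding
  y_mc <- if (rate == 0) y_det else colMeans(samples)
  u <- if (rate == 0) rep(0, n) else apply(samples, 2, stats::sd)
  if (model@config$uncertainty_stat == "var") u <- u^2
  methods::new("PredictionSet", compoundIds = as.character(ids),
               yDet = as.numeric(y_det), yMc = y_mc,
               uncertainty = as.numeric(u),
               samples = if (keep_samples) samples else matrix(0, 0, n))
}

#' Evaluate predictions against labels
#'
#' @param pred a [PredictionSet-class].
#' @param labels numeric vector named by compound id, or aligned to the
#'   prediction order when unnamed.
#' @return list of class `EvalSummary` with `mse` (deterministic
#'   predictions), `dropout_mse` (MC-mean predictions) and
#'   `mean_uncertainty`.
#' @export
evaluatePredictions <- function(pred, labels) {
  stopIfNot(methods::is(pred, "PredictionSet"), "not a PredictionSet")
  ids <- compoundIds(pred)
  if (!is.null(names(labels))) {
    stopIfNot(all(ids %in% names(labels)),
              "labels are missing some predicted compound ids")
    labels <- labels[ids]
  } else {
    stopIfNot(length(labels) == length(ids),
              "unnamed labels must align with predictions")
  }
  structure(list(mse = mean((pred@yDet - labels)^2),
                 dropout_mse = mean((pred@yMc - labels)^2),
                 mean_uncertainty = mean(pred@uncertainty),
                 n = length(ids)),
            class = "EvalSummary")
}

#' @export
print.EvalSummary <- function(x, ...) {
  cat(sprintf("EvalSummary (n = %d)\n  MSE (deterministic): %.5f\n  MSE (MC dropout):    %.5f\n  mean uncertainty:    %.5f\n",
              x$n, x$mse, x$dropout_mse, x$mean_uncertainty))
  invisible(x)
}

#' Save / load a trained model
#'
#' Serialises the weights and configuration to a single JSON file (text
#' format, portable across platforms).
#'
#' @param model an [MCDropoutModel-class].
#' @param path file path.
#' @return `loadModel` returns the model; `saveModel` returns `path`
#'   invisibly.
#' @export
saveModel <- function(model, path) {
  payload <- list(
    config = model@config, nBits = model@nBits,
    lossHistory = model@lossHistory,
    hidden = lapply(model@weights$hidden, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)),
    out = list(W = as.vector(model@weights$out$W),
               dim = dim(model@weights$out$W), b = model@weights$out$b))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- list(hidden = lapply(seq_along(p$hidden$b), function(l)
    list(W = matrix(p$hidden$W[[l]], p$hidden$dim[[l]][1], p$hidden$dim[[l]][2]),
         b = p$hidden$b[[l]])),
    out = list(W = matrix(p$out$W, p$out$dim[1], p$out$dim[2]), b = p$out$b))
  cfg <- p$config
  cfg$hidden_sizes <- as.integer(cfg$hidden_sizes)
  methods::new("MCDropoutModel", weights = W, config = cfg,
               lossHistory = as.numeric(p$lossHistory),
               nBits = as.integer(p$nBits))
}
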