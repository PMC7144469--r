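## End-to-end orchestration: simulate/ingest -> curate -> featurize -> split
## -> per-fold train/predict -> rank -> detect -> analyze, with per-stage
## artifacts, a manifest recording the configuration hash and seed, and
## per-stage resumability.

#' Default pipeline configuration
#'
#' Returns the full nested run configuration with the reference defaults:
#' the training protocol (hidden sizes 500/500/200, dropout 0.5, Adam lr
#' 0.001, 200 epochs, batches of 100), k = 5 folds, 50 MC passes, ranking
#' and detection defaults, and the synthetic-data study conditions.
#' Supplied values override defaults by name.
#'
#' @param ... named overrides for any block (`synth`, `prepare`, `split`,
#'   `model`, `ranking`, `detect`), or top-level `seed`, `input_records`,
#'   `input_fps`, `folds_to_run`.
#' @return nested configuration list of class `RunConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    input_records = NULL,   # path to a raw records CSV; NULL -> synthetic
    input_fps = NULL,       # path to a fingerprint CSV; NULL -> synthetic
    folds_to_run = NULL,    # NULL -> all k folds
    synth = list(),         # overrides for synthConfig()
    prepare = list(relation_mode = "strict"),
    split = list(method = "random_cv", k = 5L),
    model = list(),         # overrides for mlpConfig()
    ranking = list(strategy = "sum_scaled", fraction = 0.1,
                   normalization = "minmax_range"),
    detect = list(error_pctl = 95, unc_pctl = 5, unc_direction = "at_least"))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipelineConfig()].
#' @return a `RunConfig`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

.stageDone <- function(dir, name) file.exists(file.path(dir, paste0(".done_", name)))
.markDone <- function(dir, name) {
  file.create(file.path(dir, paste0(".done_", name)))
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes every stage into `out_dir`, writing CSV/JSON artifacts plus a
#' `manifest.json` recording the configuration, its hash, the seed and the
#' artifact list. With `resume = TRUE`, stages whose done-marker exists are
#' skipped. Any stage failure is re-raised with the stage name attached.
#'
#' @param config a `RunConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param out_dir output directory (created if needed).
#' @param resume skip stages already completed in `out_dir`.
#' @param verbose log stage progress to stderr.
#' @return invisibly, a list with the main in-memory results (`compounds`,
#'   `split`, `evals`, `predictions`, `ranking`, `suspects`, `diagnostics`,
#'   `correlations`).
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir, resume = FALSE,
                        verbose = TRUE) {
  stopIfNot(inherits(config, "RunConfig"), "config must come from pipelineConfig()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[uqscreen] ", sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed

  ## --- simulate / ingest -------------------------------------------------
  say("stage simulate/ingest")
  if (is.null(config$input_records)) {
    scfg <- do.call(synthConfig, utils::modifyList(list(seed = seed),
                                                   config$synth))
    ds <- run_stage("simulate", genDataset(
      scfg, strict_relations = identical(config$prepare$relation_mode,
                                         "strict")))
    records <- ds$records; fps_all <- ds$fps
    ground_truth <- list(latent = ds$latent, corrupted = ds$corrupted,
                         clusters = ds$clusters)
    if (!.stageDone(out_dir, "simulate") || !resume) {
      utils::write.csv(records, file.path(out_dir, "records.csv"),
                       row.names = FALSE)
      writeFingerprints(fps_all, file.path(out_dir, "fingerprints.csv"))
      jsonlite::write_json(
        list(corrupted = names(ds$corrupted)[ds$corrupted],
             clusters = as.list(ds$clusters)),
        file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
      .markDone(out_dir, "simulate")
    }
  } else {
    if (!file.exists(config$input_records))
      stop("stage 'ingest' failed: input path not found: ",
           config$input_records, call. = FALSE)
    records <- run_stage("ingest", readActivityRecords(config$input_records))
    fps_all <- NULL
    ground_truth <- NULL
  }

  ## --- prepare -----------------------------------------------------------
  say("stage prepare")
  prep <- run_stage("prepare", do.call(prepareActivityData,
    c(list(records = records), config$prepare)))
  compounds <- prep$compounds
  utils::write.csv(compounds, file.path(out_dir, "curated.csv"),
                   row.names = FALSE)
  jsonlite::write_json(prep$report, file.path(out_dir, "filter_report.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  .markDone(out_dir, "prepare")

  ## --- featurize ---------------------------------------------------------
  say("stage featurize")
  fps <- run_stage("featurize", {
    if (!is.null(config$input_fps)) readFingerprints(config$input_fps)
    else if (!is.null(fps_all)) fps_all
    else fingerprintSmiles(stats::setNames(compounds$smiles,
                                           compounds$compound_id))
  })
  fps <- fps[intersect(compoundIds(fps), compounds$compound_id)]
  compounds <- compounds[match(compoundIds(fps), compounds$compound_id), ]
  labels <- stats::setNames(compounds$label, compounds$compound_id)

  ## --- split -------------------------------------------------------------
  say("stage split (%s, k = %d)", config$split$method, config$split$k)
  split <- run_stage("split", {
    if (config$split$method == "random_cv")
      randomCvFolds(compoundIds(fps), k = config$split$k, seed = seed)
    else bacFolds(fps, k = config$split$k, seed = seed)
  })
  utils::write.csv(as.data.frame(split), file.path(out_dir, "folds.csv"),
                   row.names = FALSE)
  .markDone(out_dir, "split")

  ## --- per-fold train/predict --------------------------------------------
  folds <- config$folds_to_run
  if (is.null(folds)) folds <- seq_len(split@k) - 1L
  mcfg_base <- utils::modifyList(list(seed = seed), config$model)
  evals <- list(); pred_rows <- list(); preds <- list()
  pred_path <- file.path(out_dir, "predictions.csv")
  if (resume && .stageDone(out_dir, "train_predict") &&
      file.exists(pred_path)) {
    say("stage train/predict: resuming from %s", pred_path)
    prev <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
    for (f in folds) {
      df <- prev[prev$fold == f, , drop = FALSE]
      ix <- foldIndices(split, f)
      pred <- methods::new("PredictionSet", compoundIds = df$compound_id,
                           yDet = df$y_det, yMc = df$y_mc,
                           uncertainty = df$uncertainty,
                           samples = matrix(0, 0, nrow(df)))
      preds[[as.character(f)]] <- list(pred = pred, train = ix$train,
                                       test = ix$test)
      evals[[as.character(f)]] <- evaluatePredictions(pred, labels)
      pred_rows[[as.character(f)]] <- df
    }
    folds <- integer(0)
  }
  for (f in folds) {
    say("stage train/predict, fold %d", f)
    fold_res <- run_stage(sprintf("train_fold_%d", f), {
      ix <- foldIndices(split, f)
      mcfg <- do.call(mlpConfig, utils::modifyList(
        mcfg_base, list(seed = childSeed(seed, 100L + f))))
      model <- mlpTrain(fps[ix$train], labels[ix$train], mcfg)
      pred <- predictMc(model, fps[ix$test], seed = childSeed(seed, 200L + f))
      list(pred = pred, ix = ix)
    })
    preds[[as.character(f)]] <- list(pred = fold_res$pred,
                                     train = fold_res$ix$train,
                                     test = fold_res$ix$test)
    evals[[as.character(f)]] <- evaluatePredictions(fold_res$pred, labels)
    df <- as.data.frame(fold_res$pred); df$fold <- f
    pred_rows[[as.character(f)]] <- df
  }
  pred_df <- do.call(rbind, pred_rows)
  utils::write.csv(pred_df, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  fold_metrics <- data.frame(
    fold = as.integer(names(evals)),
    mse = vapply(evals, `[[`, numeric(1), "mse"),
    dropout_mse = vapply(evals, `[[`, numeric(1), "dropout_mse"),
    mean_uncertainty = vapply(evals, `[[`, numeric(1), "mean_uncertainty"))
  fold_metrics <- rbind(fold_metrics,
                        data.frame(fold = NA_integer_,
                                   mse = mean(fold_metrics$mse),
                                   dropout_mse = mean(fold_metrics$dropout_mse),
                                   mean_uncertainty =
                                     mean(fold_metrics$mean_uncertainty)))
  utils::write.csv(fold_metrics, file.path(out_dir, "fold_metrics.csv"),
                   row.names = FALSE)
  .markDone(out_dir, "train_predict")

  ## --- rank / detect / analyze over pooled test predictions ---------------
  say("stage rank")
  rk <- config$ranking
  y_hat <- stats::setNames(pred_df$y_mc, pred_df$compound_id)
  u <- stats::setNames(pred_df$uncertainty, pred_df$compound_id)
  y_true <- labels[names(y_hat)]
  ranking <- run_stage("rank", rankCompounds(
    y_hat, u, rk$strategy,
    lambda = rk$lambda, normalization = rk$normalization))
  sweep_tab <- run_stage("rank", rankingSweep(
    y_hat, u, y_true, fraction = rk$fraction,
    normalization = rk$normalization))
  utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep_tab, file.path(out_dir, "ranking_sweep.csv"),
                   row.names = FALSE)
  .markDone(out_dir, "rank")

  say("stage detect")
  dt <- config$detect
  pset <- methods::new("PredictionSet", compoundIds = names(y_hat),
                       yDet = pred_df$y_det, yMc = pred_df$y_mc,
                       uncertainty = pred_df$uncertainty,
                       samples = matrix(0, 0, length(y_hat)))
  suspects <- run_stage("detect", flagSuspects(
    pset, y_true, error_pctl = dt$error_pctl, unc_pctl = dt$unc_pctl,
    unc_direction = dt$unc_direction))
  writeSuspectReport(suspects, file.path(out_dir, "suspects.json"))
  .markDone(out_dir, "detect")

  say("stage analyze")
  diagnostics <- run_stage("analyze", {
    rows <- lapply(preds, function(p)
      buildDiagnostics(p$pred, labels, fps, fps[p$train], compounds))
    do.call(rbind, rows)
  })
  correlations <- diagnosticCorrelations(diagnostics)
  utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(correlations, file.path(out_dir, "correlations.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  .markDone(out_dir, "analyze")

  manifest <- list(package = "uqscreen",
                   version = as.character(utils::packageVersion("uqscreen")),
                   seed = seed, config = unclass(config),
                   config_hash = .configHash(unclass(config)),
                   artifacts = list.files(out_dir),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: %s", out_dir)

  invisible(list(compounds = compounds, split = split, evals = evals,
                 fold_metrics = fold_metrics, predictions = pred_df,
                 ranking = ranking, ranking_sweep = sweep_tab,
                 suspects = suspects, diagnostics = diagnostics,
                 correlations = correlations, ground_truth = ground_truth))
}
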