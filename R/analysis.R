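## Uncertainty diagnostics: how prediction error, similarity to the training
## set, MC-dropout uncertainty and the measurement record (count and spread
## of reported activity values) relate to each other on a test set.

#' Build the per-compound diagnostics table
#'
#' One row per test compound with: squared prediction error (MC-mean vs.
#' label), maximum Tanimoto similarity to the training set, MC-dropout
#' uncertainty, and the number and population standard deviation of the
#' activity measurements behind the compound's label.
#'
#' @param pred a [PredictionSet-class] for the test compounds.
#' @param y_true numeric labels named by compound id (or aligned).
#' @param fps_test [FingerprintMatrix-class] covering the test compounds.
#' @param fps_train [FingerprintMatrix-class] of the training set.
#' @param curated curated-compound data.frame covering the test compounds
#'   (source of `n_values` and `std_log_activity`).
#' @return data.frame with columns `compound_id`, `squared_error`,
#'   `max_train_similarity`, `uncertainty`, `n_values`, `std_log_activity`.
#' @export
buildDiagnostics <- function(pred, y_true, fps_test, fps_train, curated) {
  ids <- compoundIds(pred)
  miss <- setdiff(ids, compoundIds(fps_test))
  if (length(miss))
    stop("compound(s) missing a fingerprint: ", paste(miss, collapse = ", "))
  if (!is.null(names(y_true))) {
    stopIfNot(all(ids %in% names(y_true)), "labels missing for some compounds")
    y_true <- y_true[ids]
  } else stopIfNot(length(y_true) == length(ids), "labels misaligned")
  cc <- match(ids, curated$compound_id)
  if (anyNA(cc))
    stop("compound(s) missing from the curated table: ",
         paste(ids[is.na(cc)], collapse = ", "))

  sim <- tanimotoMatrix(fps_test[ids], fps_train)
  data.frame(compound_id = ids,
             squared_error = (pred@yMc - y_true)^2,
             max_train_similarity = apply(sim, 1, max),
             uncertainty = pred@uncertainty,
             n_values = curated$n_values[cc],
             std_log_activity = curated$std_log_activity[cc],
             stringsAsFactors = FALSE)
}

#' Correlate two diagnostics columns
#'
#' Pearson or Spearman correlation between two columns of the diagnostics
#' table. A zero-variance column yields an explicit undefined-correlation
#' condition (class `uqscreen_undefined_correlation`) rather than silently
#' propagating `NA`.
#'
#' @param table diagnostics data.frame from [buildDiagnostics()].
#' @param x,y column names.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `coefficient` (in \[-1, 1\]), `n` and `method`.
#' @export
correlateDiagnostics <- function(table, x, y,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNot(nrow(table) >= 3L, "need at least 3 rows to correlate")
  stopIfNot(x %in% names(table) && y %in% names(table), "unknown column")
  vx <- table[[x]]; vy <- table[[y]]
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    stop(structure(class = c("uqscreen_undefined_correlation", "error",
                             "condition"),
                   list(message = sprintf(
                     "correlation between '%s' and '%s' undefined: zero variance",
                     x, y), call = sys.call())))
  list(coefficient = stats::cor(vx, vy, method = method), n = nrow(table),
       method = method)
}

#' Distribution of a diagnostic per measurement count
#'
#' Groups test compounds by `n_values` (the number of activity measurements
#' behind their label) and summarises the chosen column per group: median,
#' first/third quartile (linear-interpolation convention), range, and a
#' single-member flag for groups where no box can be drawn.
#'
#' @param table diagnostics data.frame.
#' @param value column to summarise (default `"uncertainty"`).
#' @return data.frame with one row per distinct `n_values`: `n_values`,
#'   `group_size`, `median`, `q1`, `q3`, `min`, `max`, `single_member`.
#' @export
groupByCount <- function(table, value = "uncertainty") {
  stopIfNot(nrow(table) > 0, "empty diagnostics table")
  stopIfNot(value %in% names(table), "unknown column")
  counts <- sort(unique(table$n_values))
  rows <- lapply(counts, function(nv) {
    v <- table[[value]][table$n_values == nv]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n_values = nv, group_size = length(v), median = q[2],
               q1 = q[1], q3 = q[3], min = min(v), max = max(v),
               single_member = length(v) == 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation summary across the standard diagnostic pairs
#'
#' Convenience wrapper computing the correlations the diagnostics are
#' usually read for: uncertainty vs. measurement count, uncertainty vs.
#' measurement spread, error vs. similarity, uncertainty vs. similarity,
#' and error vs. uncertainty — each with Pearson and Spearman coefficients.
#' Pairs whose correlation is undefined (zero variance) are reported as
#' `NA` with a `defined = FALSE` marker.
#'
#' @param table diagnostics data.frame from [buildDiagnostics()].
#' @return data.frame with columns `x`, `y`, `method`, `coefficient`,
#'   `defined`, `n`.
#' @export
diagnosticCorrelations <- function(table) {
  pairs <- list(c("uncertainty", "n_values"),
                c("uncertainty", "std_log_activity"),
                c("squared_error", "max_train_similarity"),
                c("uncertainty", "max_train_similarity"),
                c("squared_error", "uncertainty"))
  rows <- list()
  for (p in pairs) for (m in c("pearson", "spearman")) {
    res <- tryCatch(correlateDiagnostics(table, p[1], p[2], m),
                    uqscreen_undefined_correlation = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      x = p[1], y = p[2], method = m,
      coefficient = if (is.null(res)) NA_real_ else res$coefficient,
      defined = !is.null(res), n = nrow(table), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
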