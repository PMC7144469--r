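## Detection of suspect activity records by joint error/uncertainty
## percentile criteria.
##
## A test compound is flagged when its squared prediction error sits at or
## above the error percentile threshold while its uncertainty satisfies the
## directional uncertainty criterion. The motivating pattern: a compound the
## model gets badly wrong (because structurally similar training compounds
## say otherwise) is a candidate database error — especially when the model
## is simultaneously confident (low uncertainty) about its prediction.

#' Flag suspect activity records
#'
#' Per-compound percentile ranks are computed as
#' `100 * (number of strictly smaller values) / n` — a convention that is
#' deterministic under ties and makes "at or above the 95th percentile" on n
#' distinct values select exactly the top 5\%. A compound is flagged iff its
#' squared error (MC-mean prediction vs. label) has percentile rank
#' `>= error_pctl` and its uncertainty rank is `>= unc_pctl`
#' (`unc_direction = "at_least"`, the literal criterion) or `<= unc_pctl`
#' (`"at_most"`, the confident-but-wrong reading). The direction is a
#' mandatory, recorded analysis choice.
#'
#' @param pred a [PredictionSet-class] (or data.frame with `compound_id`,
#'   `y_mc`, `uncertainty`).
#' @param y_true numeric labels, named by compound id or aligned.
#' @param error_pctl error percentile threshold in \[0, 100\] (default 95).
#' @param unc_pctl uncertainty percentile threshold (default 5).
#' @param unc_direction `"at_least"` or `"at_most"`.
#' @return list of class `SuspectReport`: `flagged` (data.frame with
#'   compound_id, squared_error, uncertainty, error_percentile,
#'   uncertainty_percentile), `all` (same columns for every compound, plus
#'   `flagged`), and the settings used.
#' @export
flagSuspects <- function(pred, y_true, error_pctl = 95, unc_pctl = 5,
                         unc_direction = c("at_least", "at_most")) {
  unc_direction <- match.arg(unc_direction)
  stopIfNot(error_pctl >= 0 && error_pctl <= 100, "error_pctl out of [0,100]")
  stopIfNot(unc_pctl >= 0 && unc_pctl <= 100, "unc_pctl out of [0,100]")
  if (methods::is(pred, "PredictionSet")) {
    ids <- compoundIds(pred); ymc <- pred@yMc; u <- pred@uncertainty
  } else {
    ids <- pred$compound_id; ymc <- pred$y_mc; u <- pred$uncertainty
  }
  if (!is.null(names(y_true))) {
    stopIfNot(all(ids %in% names(y_true)), "labels missing for some compounds")
    y_true <- y_true[ids]
  } else stopIfNot(length(y_true) == length(ids), "labels misaligned")
  n <- length(ids)
  if (n < 20L)
    warning("fewer than 20 compounds: percentile thresholds are unstable")

  se <- (ymc - y_true)^2
  err_rank <- percentileRank(se)
  unc_rank <- percentileRank(u)
  unc_ok <- if (unc_direction == "at_least") unc_rank >= unc_pctl
            else unc_rank <= unc_pctl
  flagged <- err_rank >= error_pctl & unc_ok

  tab <- data.frame(compound_id = ids, squared_error = se, uncertainty = u,
                    error_percentile = err_rank,
                    uncertainty_percentile = unc_rank, flagged = flagged,
                    stringsAsFactors = FALSE)
  structure(list(flagged = tab[flagged, setdiff(names(tab), "flagged"),
                               drop = FALSE],
                 all = tab, error_pctl = error_pctl, unc_pctl = unc_pctl,
                 unc_direction = unc_direction, n = n),
            class = "SuspectReport")
}

#' @export
print.SuspectReport <- function(x, ...) {
  cat(sprintf(
    "SuspectReport: %d of %d compounds flagged (error >= P%s, uncertainty %s P%s)\n",
    nrow(x$flagged), x$n, format(x$error_pctl),
    if (x$unc_direction == "at_least") ">=" else "<=", format(x$unc_pctl)))
  invisible(x)
}

#' Nearest-training-neighbour context for flagged compounds
#'
#' For each flagged compound, lists the `N` structurally most similar
#' training compounds (descending Tanimoto) with their labels and reported
#' measurement summaries — the context a curator needs to judge whether a
#' flagged record is plausible.
#'
#' @param flagged_ids character vector of flagged compound ids.
#' @param fps_query [FingerprintMatrix-class] containing the flagged
#'   compounds.
#' @param fps_train [FingerprintMatrix-class] of the training set.
#' @param curated curated-compound data.frame (from
#'   [aggregateCompounds()]) covering the training compounds.
#' @param N neighbours per flagged compound (default 10). When `N` exceeds
#'   the training-set size, all training compounds are returned with a
#'   warning.
#' @return data.frame with columns `compound_id`, `neighbor_id`,
#'   `similarity`, `neighbor_label`, `neighbor_n_values`, ordered by
#'   flagged compound then descending similarity.
#' @export
neighborContext <- function(flagged_ids, fps_query, fps_train, curated,
                            N = 10L) {
  stopIfNot(all(flagged_ids %in% compoundIds(fps_query)),
            "some flagged compounds have no fingerprint")
  if (N > length(fps_train)) {
    warning("N exceeds training-set size; returning all training compounds")
    N <- length(fps_train)
  }
  sim <- tanimotoMatrix(fps_query[flagged_ids], fps_train)
  train_ids <- compoundIds(fps_train)
  lab <- curated$label[match(train_ids, curated$compound_id)]
  nv <- curated$n_values[match(train_ids, curated$compound_id)]
  rows <- lapply(seq_along(flagged_ids), function(i) {
    ord <- order(-sim[i, ], train_ids)[seq_len(N)]
    data.frame(compound_id = flagged_ids[i], neighbor_id = train_ids[ord],
               similarity = sim[i, ord], neighbor_label = lab[ord],
               neighbor_n_values = nv[ord], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a SuspectReport to JSON
#'
#' @param report a `SuspectReport` from [flagSuspects()].
#' @param path output path.
#' @param neighbors optional neighbour table from [neighborContext()] to
#'   embed.
#' @return `path`, invisibly.
#' @export
writeSuspectReport <- function(report, path, neighbors = NULL) {
  payload <- list(settings = list(error_pctl = report$error_pctl,
                                  unc_pctl = report$unc_pctl,
                                  unc_direction = report$unc_direction,
                                  n = report$n),
                  flagged = report$flagged)
  if (!is.null(neighbors)) payload$neighbors <- neighbors
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
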