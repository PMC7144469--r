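## Uncertainty-augmented compound ranking for virtual screening.
##
## Compounds are ranked by a score R(yhat_i, u_i); the lower the score, the
## higher the compound sits in the hit list. yhat is predicted log-activity
## (lower = more active) and u is the MC-dropout uncertainty. Six strategies
## are supported:
##   baseline    R = yhat
##   add         R = yhat + u
##   scale       R = u~ * yhat          (u~ = normalized uncertainty)
##   add_scaled  R = u~ + yhat
##   sum_scaled  R = u~ + y~            (both normalized)
##   comb        R = lambda * yhat + (1 - lambda) * u

.STRATEGIES <- c("baseline", "add", "scale", "add_scaled", "sum_scaled", "comb")

#' Min-max normalization of a score vector
#'
#' Two conventions are provided. `"minmax_range"` is the usual
#' `(v - min) / (max - min)`, mapping the vector exactly onto \[0, 1\].
#' `"minmax_over_max"` is `(v - min) / max`, an alternative sometimes seen in
#' print whose range depends on the sign and spread of `v`; it is kept for
#' strict comparability. A constant vector maps to all zeros in both modes.
#'
#' @param v numeric vector (length >= 1).
#' @param mode `"minmax_range"` (default) or `"minmax_over_max"`.
#' @return numeric vector of the same length.
#' @examples
#' normalizeVector(c(2, 4, 6))                        # 0, 0.5, 1
#' normalizeVector(c(2, 4, 6), "minmax_over_max")     # 0, 1/3, 2/3
#' @export
normalizeVector <- function(v, mode = c("minmax_range", "minmax_over_max")) {
  mode <- match.arg(mode)
  stopIfNot(length(v) >= 1L, "cannot normalize an empty vector")
  rng <- max(v) - min(v)
  if (rng == 0) return(rep(0, length(v)))
  if (mode == "minmax_range") return((v - min(v)) / rng)
  if (max(v) == 0) {
    warning("max of vector is 0; minmax_over_max normalization returns zeros")
    return(rep(0, length(v)))
  }
  (v - min(v)) / max(v)
}

#' Rank compounds by prediction and uncertainty
#'
#' Computes the ranking score R per compound under the chosen strategy and
#' returns scores with the resulting ascending order (rank 1 = top of the
#' hit list). Ties in R are broken by compound id for determinism.
#'
#' @param y_hat numeric vector of predicted log-activities (lower = more
#'   active).
#' @param u numeric vector of non-negative uncertainties, aligned to
#'   `y_hat`.
#' @param strategy one of `"baseline"`, `"add"`, `"scale"`, `"add_scaled"`,
#'   `"sum_scaled"`, `"comb"`.
#' @param lambda weight in \[0, 1\] for `comb`: `R = lambda*y_hat +
#'   (1-lambda)*u`. Required iff `strategy == "comb"`.
#' @param normalization min-max convention for the normalized strategies,
#'   see [normalizeVector()].
#' @param compound_ids optional ids (default from names or generated).
#' @return data.frame with columns `compound_id`, `R`, `rank`, ordered by
#'   rank.
#' @examples
#' rankCompounds(c(1, 2), c(0.5, 0.1), "add")
#' @export
rankCompounds <- function(y_hat, u, strategy = .STRATEGIES, lambda = NULL,
                          normalization = "minmax_range",
                          compound_ids = names(y_hat)) {
  strategy <- match.arg(strategy)
  n <- length(y_hat)
  stopIfNot(length(u) == n, "y_hat and u must be aligned")
  stopIfNot(all(u >= 0), "uncertainties must be non-negative")
  if (strategy == "comb") {
    stopIfNot(!is.null(lambda) && lambda >= 0 && lambda <= 1,
              "strategy 'comb' requires lambda in [0, 1]")
  } else if (!is.null(lambda)) {
    warning("lambda is only used by strategy 'comb'; ignored")
  }
  if (is.null(compound_ids)) compound_ids <- sprintf("cmpd_%04d", seq_len(n))

  if (strategy == "scale" && any(y_hat < 0))
    warning("strategy 'scale' with negative predictions: the product ",
            "ordering rewards uncertain negatives; interpret with care")

  u_t <- function() normalizeVector(u, normalization)
  R <- switch(strategy,
    baseline = y_hat,
    add = y_hat + u,
    scale = u_t() * y_hat,
    add_scaled = u_t() + y_hat,
    sum_scaled = u_t() + normalizeVector(y_hat, normalization),
    comb = lambda * y_hat + (1 - lambda) * u)

  ord <- order(R, compound_ids)
  out <- data.frame(compound_id = compound_ids, R = R,
                    stringsAsFactors = FALSE)
  out$rank <- integer(n)
  out$rank[ord] <- seq_len(n)
  out[order(out$rank), , drop = FALSE]
}

#' Precision at the top fraction of a ranking
#'
#' The fraction of the truly most-active top-m compounds recovered inside
#' the predicted top-m, with `m = ceiling(fraction * n)`. "Most active"
#' means lowest true log-activity; the predicted list is the m lowest
#' ranking scores. Ties on either side are broken by compound id.
#'
#' @param y_true numeric vector of true log-activities.
#' @param R numeric vector of ranking scores (lower = higher rank), aligned.
#' @param fraction top fraction in (0, 1\]; default 0.1.
#' @param compound_ids optional ids used for deterministic tie-breaks.
#' @return single numeric in \[0, 1\].
#' @export
precisionAtTop <- function(y_true, R, fraction = 0.1,
                           compound_ids = names(y_true)) {
  n <- length(y_true)
  stopIfNot(n > 0, "empty input")
  stopIfNot(length(R) == n, "y_true and R must be aligned")
  stopIfNot(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  if (is.null(compound_ids)) compound_ids <- sprintf("cmpd_%04d", seq_len(n))
  m <- ceiling(fraction * n)
  top_true <- order(y_true, compound_ids)[seq_len(m)]
  top_pred <- order(R, compound_ids)[seq_len(m)]
  length(intersect(compound_ids[top_true], compound_ids[top_pred])) / m
}

#' Compare all ranking strategies on one prediction set
#'
#' Computes precision-at-top for the baseline, the four fixed
#' uncertainty-augmented strategies and a lambda sweep of the linear
#' combination — the tabular form of the strategy-comparison heat maps.
#'
#' @param y_hat,u,y_true aligned numeric vectors (predicted log-activity,
#'   uncertainty, true log-activity).
#' @param fraction top fraction for the precision metric (default 0.1).
#' @param lambdas grid for the `comb` strategy (default `seq(0, 1, 0.1)`).
#' @param normalization see [normalizeVector()].
#' @param compound_ids optional ids.
#' @return data.frame with columns `strategy`, `lambda` (`NA` except for
#'   comb rows), `precision_at_top`, and `delta_vs_baseline`.
#' @export
rankingSweep <- function(y_hat, u, y_true, fraction = 0.1,
                         lambdas = seq(0, 1, by = 0.1),
                         normalization = "minmax_range",
                         compound_ids = names(y_hat)) {
  if (is.null(compound_ids))
    compound_ids <- sprintf("cmpd_%04d", seq_along(y_hat))
  one <- function(strategy, lambda = NULL) {
    r <- suppressWarnings(
      rankCompounds(y_hat, u, strategy, lambda, normalization, compound_ids))
    r <- r[match(compound_ids, r$compound_id), ]
    precisionAtTop(y_true, r$R, fraction, compound_ids)
  }
  base <- one("baseline")
  rows <- data.frame(strategy = c("baseline", "add", "scale", "add_scaled",
                                  "sum_scaled"),
                     lambda = NA_real_, stringsAsFactors = FALSE)
  rows$precision_at_top <- vapply(rows$strategy, one, numeric(1))
  comb <- data.frame(strategy = "comb", lambda = lambdas,
                     stringsAsFactors = FALSE)
  comb$precision_at_top <- vapply(lambdas, function(l) one("comb", l),
                                  numeric(1))
  out <- rbind(rows, comb)
  out$delta_vs_baseline <- out$precision_at_top - base
  out
}
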