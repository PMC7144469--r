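#' FingerprintMatrix: binary fingerprints for a set of compounds
#'
#' Container for a compounds-by-bits binary matrix together with the compound
#' identifiers and the fingerprinting scheme. Rows are compounds; entries are
#' 0/1.
#'
#' @slot bits integer matrix (compounds x n_bits) of 0/1 entries.
#' @slot compoundIds character vector, one id per row of `bits`.
#' @slot scheme single string, one of `"morgan_r2"`, `"maccs"`, `"synthetic"`.
#'
#' @aliases FingerprintMatrix-class
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
  representation(bits = "matrix", compoundIds = "character", scheme = "character"))

setValidity("FingerprintMatrix", function(object) {
  msgs <- character(0)
  b <- object@bits
  if (!is.numeric(b) && !is.integer(b))
    msgs <- c(msgs, "bits must be a numeric/integer matrix")
  if (nrow(b) != length(object@compoundIds))
    msgs <- c(msgs, "number of rows must equal length(compoundIds)")
  if (length(b) && !all(b %in% c(0L, 1L)))
    msgs <- c(msgs, "all fingerprint entries must be 0 or 1")
  if (length(object@scheme) != 1L ||
      !object@scheme %in% c("morgan_r2", "maccs", "synthetic"))
    msgs <- c(msgs, "scheme must be one of 'morgan_r2', 'maccs', 'synthetic'")
  if (anyDuplicated(object@compoundIds))
    msgs <- c(msgs, "compoundIds must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FingerprintMatrix
#'
#' @param bits matrix of 0/1 entries, compounds in rows.
#' @param compoundIds character vector of compound identifiers (defaults to
#'   rownames of `bits`).
#' @param scheme fingerprinting scheme: `"morgan_r2"`, `"maccs"` or
#'   `"synthetic"`.
#' @return A [FingerprintMatrix-class] object.
#' @examples
#' fps <- FingerprintMatrix(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 2, 4,
#'                                 byrow = TRUE),
#'                          compoundIds = c("a", "b"), scheme = "synthetic")
#' tanimoto(fps["a"], fps["b"])
#' @export
FingerprintMatrix <- function(bits, compoundIds = rownames(bits),
                              scheme = "synthetic") {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (is.null(compoundIds))
    compoundIds <- sprintf("cmpd_%04d", seq_len(nrow(bits)))
  rownames(bits) <- compoundIds
  methods::new("FingerprintMatrix", bits = bits,
               compoundIds = as.character(compoundIds), scheme = scheme)
}

#' SplitAssignment: fold membership for cross-validation
#'
#' @slot compoundIds character vector of compound ids.
#' @slot fold integer vector of 0-based fold indices, aligned to
#'   `compoundIds`.
#' @slot k integer, number of folds.
#' @slot method `"random_cv"` or `"bac"`.
#' @slot seed integer seed the assignment was generated under.
#'
#' @aliases SplitAssignment-class
#' @exportClass SplitAssignment
setClass("SplitAssignment",
  representation(compoundIds = "character", fold = "integer", k = "integer",
                 method = "character", seed = "integer"))

setValidity("SplitAssignment", function(object) {
  msgs <- character(0)
  if (length(object@fold) != length(object@compoundIds))
    msgs <- c(msgs, "fold and compoundIds must be aligned")
  if (length(object@fold) && (min(object@fold) < 0L ||
                              max(object@fold) >= object@k))
    msgs <- c(msgs, "fold indices must lie in [0, k)")
  if (!object@method %in% c("random_cv", "bac"))
    msgs <- c(msgs, "method must be 'random_cv' or 'bac'")
  if (length(object@fold) >= object@k &&
      length(unique(object@fold)) < object@k)
    msgs <- c(msgs, "all k folds must be non-empty when n >= k")
  if (length(msgs)) msgs else TRUE
})

#' PredictionSet: deterministic and MC-dropout predictions
#'
#' Holds, per compound, the deterministic prediction (dropout off), the
#' Monte-Carlo mean prediction over T stochastic passes, the prediction
#' uncertainty (standard deviation over passes by default) and optionally the
#' raw T x n sample matrix.
#'
#' @slot compoundIds character vector.
#' @slot yDet numeric, deterministic predictions.
#' @slot yMc numeric, MC-dropout mean predictions.
#' @slot uncertainty numeric, non-negative per-compound uncertainty.
#' @slot samples T x n numeric matrix of per-pass predictions (possibly
#'   0-row when not retained).
#'
#' @aliases PredictionSet-class
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(compoundIds = "character", yDet = "numeric", yMc = "numeric",
                 uncertainty = "numeric", samples = "matrix"))

setValidity("PredictionSet", function(object) {
  msgs <- character(0)
  n <- length(object@compoundIds)
  if (length(object@yDet) != n || length(object@yMc) != n ||
      length(object@uncertainty) != n)
    msgs <- c(msgs, "yDet, yMc and uncertainty must be aligned to compoundIds")
  if (length(object@uncertainty) && any(object@uncertainty < 0))
    msgs <- c(msgs, "uncertainty must be non-negative")
  if (nrow(object@samples) > 0L && ncol(object@samples) != n)
    msgs <- c(msgs, "samples must have one column per compound")
  if (length(msgs)) msgs else TRUE
})

#' MCDropoutModel: a trained dropout MLP regressor
#'
#' @slot weights list of weight matrices and bias vectors per layer.
#' @slot config the `mlpConfig()` list the model was trained under.
#' @slot lossHistory numeric, mean training loss per epoch.
#' @slot nBits integer, expected input width.
#'
#' @aliases MCDropoutModel-class
#' @exportClass MCDropoutModel
setClass("MCDropoutModel",
  representation(weights = "list", config = "list", lossHistory = "numeric",
                 nBits = "integer"))
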