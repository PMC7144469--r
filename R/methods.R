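#' @describeIn FingerprintMatrix compound ids
#' @param x,object a FingerprintMatrix.
#' @export
setMethod("compoundIds", "FingerprintMatrix", function(x) x@compoundIds)

#' @describeIn FingerprintMatrix the 0/1 bit matrix
#' @export
setMethod("fpBits", "FingerprintMatrix", function(x) x@bits)

#' @describeIn FingerprintMatrix the fingerprinting scheme
#' @export
setMethod("fpScheme", "FingerprintMatrix", function(x) x@scheme)

#' @describeIn FingerprintMatrix number of bits per fingerprint
#' @export
setMethod("nBits", "FingerprintMatrix", function(x) ncol(x@bits))

#' @describeIn FingerprintMatrix number of compounds
#' @export
setMethod("length", "FingerprintMatrix", function(x) nrow(x@bits))

#' @describeIn FingerprintMatrix subset by index or compound id
#' @param i index, logical or character vector of compound ids.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "FingerprintMatrix", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, x@compoundIds)
    if (length(miss))
      stop("unknown compound ids: ", paste(miss, collapse = ", "))
    i <- match(i, x@compoundIds)
  }
  FingerprintMatrix(x@bits[i, , drop = FALSE], x@compoundIds[i], x@scheme)
})

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d compounds x %d bits (scheme: %s)\n",
              nrow(object@bits), ncol(object@bits), object@scheme))
  cat(sprintf("  mean bit density: %.3f\n",
              if (length(object@bits)) mean(object@bits) else NA_real_))
})

#' @describeIn SplitAssignment compound ids
#' @param x,object a SplitAssignment.
#' @export
setMethod("compoundIds", "SplitAssignment", function(x) x@compoundIds)

#' @describeIn SplitAssignment named 0-based fold indices
#' @export
setMethod("foldIds", "SplitAssignment", function(x) {
  stats::setNames(x@fold, x@compoundIds)
})

setMethod("show", "SplitAssignment", function(object) {
  cat(sprintf("SplitAssignment: %d compounds, k = %d, method = %s, seed = %d\n",
              length(object@compoundIds), object@k, object@method, object@seed))
  print(table(fold = object@fold))
})

#' Coerce a SplitAssignment to a data.frame
#' @param x a SplitAssignment.
#' @param ... ignored.
#' @return data.frame with columns `compound_id`, `fold`.
#' @export
as.data.frame.SplitAssignment <- function(x, ...) {
  data.frame(compound_id = x@compoundIds, fold = x@fold,
             stringsAsFactors = FALSE)
}

#' @describeIn PredictionSet compound ids
#' @param x,object a PredictionSet.
#' @export
setMethod("compoundIds", "PredictionSet", function(x) x@compoundIds)

#' @describeIn PredictionSet deterministic predictions
#' @export
setMethod("yDet", "PredictionSet", function(x) {
  stats::setNames(x@yDet, x@compoundIds)
})

#' @describeIn PredictionSet MC mean predictions
#' @export
setMethod("yMc", "PredictionSet", function(x) {
  stats::setNames(x@yMc, x@compoundIds)
})

#' @describeIn PredictionSet per-compound uncertainty
#' @export
setMethod("uncertainty", "PredictionSet", function(x) {
  stats::setNames(x@uncertainty, x@compoundIds)
})

#' @describeIn PredictionSet per-pass sample matrix
#' @export
setMethod("mcSamples", "PredictionSet", function(x) x@samples)

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d compounds, %d MC passes retained\n",
              length(object@compoundIds), nrow(object@samples)))
  cat(sprintf("  mean uncertainty: %.4f\n", mean(object@uncertainty)))
})

#' Coerce a PredictionSet to a data.frame
#' @param x a PredictionSet.
#' @param ... ignored.
#' @return data.frame with columns `compound_id`, `y_det`, `y_mc`,
#'   `uncertainty`.
#' @export
as.data.frame.PredictionSet <- function(x, ...) {
  data.frame(compound_id = x@compoundIds, y_det = x@yDet, y_mc = x@yMc,
             uncertainty = x@uncertainty, stringsAsFactors = FALSE)
}

setMethod("show", "MCDropoutModel", function(object) {
  hs <- paste(object@config$hidden_sizes, collapse = "-")
  cat(sprintf("MCDropoutModel: %d -> %s -> 1, dropout %.2f\n",
              object@nBits, hs, object@config$dropout_rate))
  if (length(object@lossHistory))
    cat(sprintf("  trained %d epochs, final loss %.5f\n",
                length(object@lossHistory),
                object@lossHistory[length(object@lossHistory)]))
})
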