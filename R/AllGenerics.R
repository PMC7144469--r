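#' Compound identifiers of an object
#' @param x a FingerprintMatrix, SplitAssignment or PredictionSet.
#' @return character vector of compound ids.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Fingerprint bit matrix
#' @param x a FingerprintMatrix.
#' @return integer matrix of 0/1 entries, compounds in rows.
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' Fingerprinting scheme
#' @param x a FingerprintMatrix.
#' @return single string.
#' @export
setGeneric("fpScheme", function(x) standardGeneric("fpScheme"))

#' Number of fingerprint bits
#' @param x a FingerprintMatrix.
#' @return integer.
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' Fold indices of a split assignment
#' @param x a SplitAssignment.
#' @return integer vector of 0-based fold indices, named by compound id.
#' @export
setGeneric("foldIds", function(x) standardGeneric("foldIds"))

#' Deterministic predictions (dropout off)
#' @param x a PredictionSet.
#' @return numeric vector named by compound id.
#' @export
setGeneric("yDet", function(x) standardGeneric("yDet"))

#' Monte-Carlo mean predictions
#' @param x a PredictionSet.
#' @return numeric vector named by compound id.
#' @export
setGeneric("yMc", function(x) standardGeneric("yMc"))

#' Per-compound prediction uncertainty
#' @param x a PredictionSet.
#' @return numeric vector named by compound id.
#' @export
setGeneric("uncertainty", function(x) standardGeneric("uncertainty"))

#' Per-pass MC prediction samples
#' @param x a PredictionSet.
#' @return T x n numeric matrix (0 rows if samples were not retained).
#' @export
setGeneric("mcSamples", function(x) standardGeneric("mcSamples"))
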