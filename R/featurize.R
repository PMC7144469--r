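## Binary fingerprint computation and Tanimoto similarity.
##
## Chemistry-backed schemes (Morgan radius 2, MACCS keys) are delegated to an
## RDKit helper invoked through the system `python`; similarity arithmetic is
## done in R with matrix operations so it works identically for synthetic and
## chemistry-backed fingerprints.

.MACCS_NBITS <- 167L

findChemistryBackend <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) return(NULL)
  ok <- tryCatch(
    system2(py, c("-c", shQuote("import rdkit")), stdout = FALSE,
            stderr = FALSE) == 0L,
    warning = function(w) FALSE, error = function(e) FALSE)
  if (ok) py else NULL
}

#' Compute chemistry-backed fingerprints for SMILES strings
#'
#' Computes Morgan (radius 2, hashed to `n_bits`) or MACCS-key fingerprints
#' through the RDKit backend. Deterministic: the same SMILES always yields
#' the same bit vector.
#'
#' @param smiles character vector of SMILES strings.
#' @param scheme `"morgan_r2"` (default, 2048 bits) or `"maccs"` (167 keys;
#'   `n_bits` is ignored).
#' @param n_bits hashed length for Morgan fingerprints.
#' @param compound_ids identifiers for the rows; defaults to names of
#'   `smiles` or generated ids.
#' @return A [FingerprintMatrix-class].
#' @export
fingerprintSmiles <- function(smiles, scheme = c("morgan_r2", "maccs"),
                              n_bits = 2048L, compound_ids = names(smiles)) {
  scheme <- match.arg(scheme)
  stopIfNot(length(smiles) > 0, "no SMILES supplied")
  py <- findChemistryBackend()
  if (is.null(py))
    stop("chemistry backend (python + rdkit) not available; ",
         "use precomputed fingerprints (readFingerprints) or synthetic ",
         "fingerprints (genFingerprints) instead")
  helper <- system.file("python", "fingerprints.py", package = "uqscreen")
  stopIfNot(nzchar(helper), "bundled fingerprint helper not found")
  if (scheme == "maccs") n_bits <- .MACCS_NBITS
  out <- system2(py, c(helper, scheme, as.character(n_bits)),
                 input = as.character(smiles), stdout = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("fingerprint backend failed (exit ", status, ")")
  bad <- grepl("^ERROR\t", out)
  if (any(bad)) {
    idx <- which(bad)[1]
    stop("fingerprinting failed for record ", idx, ": ",
         sub("^ERROR\t", "", out[idx]))
  }
  bits <- matrix(0L, length(out), n_bits)
  for (i in seq_along(out)) {
    v <- as.integer(strsplit(out[i], "")[[1]])
    if (length(v) != n_bits)
      stop("backend returned fingerprint of unexpected length for record ", i)
    bits[i, ] <- v
  }
  if (is.null(compound_ids))
    compound_ids <- sprintf("cmpd_%04d", seq_along(smiles))
  FingerprintMatrix(bits, compound_ids, scheme)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over set bits. The undefined all-zero/all-zero
#' case (0/0) is defined as 0 with a warning: no shared features.
#'
#' @param a,b fingerprints — [FingerprintMatrix-class] objects with a single
#'   row, or plain 0/1 vectors of equal length.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- .asBitVector(a); b <- .asBitVector(b)
  stopIfNot(length(a) == length(b),
            "fingerprints must have the same number of bits")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0")
    return(0)
  }
  inter / uni
}

.asBitVector <- function(x) {
  if (methods::is(x, "FingerprintMatrix")) {
    stopIfNot(nrow(fpBits(x)) == 1L, "expected a single-compound fingerprint")
    x <- fpBits(x)[1, ]
  }
  x <- as.integer(x)
  stopIfNot(all(x %in% c(0L, 1L)), "fingerprint bits must be 0/1")
  x
}

#' Pairwise Tanimoto similarity matrix
#'
#' All-pairs Tanimoto between the rows of two fingerprint matrices, computed
#' by matrix multiplication (intersections) and popcount sums (unions).
#' All-zero vs all-zero pairs yield 0.
#'
#' @param x a [FingerprintMatrix-class] (queries, rows of the result).
#' @param y a [FingerprintMatrix-class] (references, columns); defaults to `x`.
#' @return numeric matrix `length(x)` x `length(y)` with dimnames set to
#'   compound ids.
#' @export
tanimotoMatrix <- function(x, y = x) {
  stopIfNot(fpScheme(x) == fpScheme(y) && nBits(x) == nBits(y),
            "fingerprint schemes/lengths differ")
  a <- fpBits(x); b <- fpBits(y)
  inter <- a %*% t(b)
  pa <- rowSums(a); pb <- rowSums(b)
  uni <- outer(pa, pb, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  dimnames(sim) <- list(compoundIds(x), compoundIds(y))
  sim
}

#' Maximum Tanimoto similarity of a query to a training set
#'
#' The standard applicability-domain measure: the highest Tanimoto between a
#' query fingerprint and any member of a training fingerprint set. `mean`
#' aggregation is available as an option.
#'
#' @param query a single-row [FingerprintMatrix-class] or 0/1 vector.
#' @param train a non-empty [FingerprintMatrix-class].
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return single numeric similarity in \[0, 1\].
#' @export
maxSimilarityToSet <- function(query, train, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopIfNot(methods::is(train, "FingerprintMatrix") && length(train) > 0,
            "training fingerprint set is empty")
  q <- .asBitVector(query)
  stopIfNot(length(q) == nBits(train),
            "query and training fingerprints have different lengths")
  qm <- FingerprintMatrix(matrix(q, 1), "query", fpScheme(train))
  sims <- tanimotoMatrix(qm, train)[1, ]
  if (aggregate == "max") max(sims) else mean(sims)
}

#' Read / write fingerprint matrices as CSV
#'
#' The on-disk format is one row per compound: `compound_id` followed by the
#' 0/1 bit columns; the scheme is recorded in a header comment line.
#'
#' @param fps a [FingerprintMatrix-class].
#' @param path file path.
#' @return `readFingerprints` returns a [FingerprintMatrix-class];
#'   `writeFingerprints` returns `path` invisibly.
#' @export
writeFingerprints <- function(fps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s n_bits=%d", fpScheme(fps), nBits(fps)), con)
  df <- data.frame(compound_id = compoundIds(fps), fpBits(fps),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("compound_id", sprintf("bit_%04d", seq_len(nBits(fps))))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFingerprints
#' @export
readFingerprints <- function(path) {
  first <- readLines(path, n = 1L)
  scheme <- "synthetic"
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("scheme=(\\S+)", first))[[1]]
    if (length(m) == 2L) scheme <- m[2]
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = FALSE)
  bits <- as.matrix(df[, -1, drop = FALSE])
  FingerprintMatrix(bits, df$compound_id, scheme)
}
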