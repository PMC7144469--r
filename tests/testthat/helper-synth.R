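## Shared fixtures for the test suite: small synthetic datasets and a
## brute-force Tanimoto reference.

tinySynth <- function(n = 60, n_bits = 48, n_clusters = 4, seed = 101, ...) {
  synthConfig(n_compounds = n, n_bits = n_bits, n_clusters = n_clusters,
              seed = seed, ...)
}

## independent reference: per-pair loop over bits
tanimotoRef <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 0 else inter / uni
}

randomFps <- function(n, nb, seed, density = 0.3, prefix = "cmpd") {
  withr::with_seed(seed,
    FingerprintMatrix(matrix(as.integer(runif(n * nb) < density), n, nb),
                      compoundIds = sprintf("%s_%04d", prefix, seq_len(n))))
}

toyRecordsPath <- function() {
  system.file("extdata", "toy_activity_records.csv", package = "uqscreen")
}

## Brute-force ranking references: explicit formula + stable sort,
## independent of the package's vectorised implementation.
refScore <- function(y, u, strategy, lambda = NULL, mode = "minmax_range") {
  norm <- function(v) {
    if (max(v) == min(v)) return(rep(0, length(v)))
    if (mode == "minmax_range") (v - min(v)) / (max(v) - min(v))
    else (v - min(v)) / max(v)
  }
  switch(strategy,
         baseline = y,
         add = y + u,
         scale = norm(u) * y,
         add_scaled = norm(u) + y,
         sum_scaled = norm(u) + norm(y),
         comb = lambda * y + (1 - lambda) * u)
}

refOrder <- function(R, ids) ids[order(R, ids)]

refPrecision <- function(y, R, frac, ids) {
  m <- ceiling(frac * length(y))
  tt <- ids[order(y, ids)][1:m]
  tp <- ids[order(R, ids)][1:m]
  length(intersect(tt, tp)) / m
}
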