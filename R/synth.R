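## Synthetic fingerprint/activity generator.
##
## Emulates the structure of curated bioactivity datasets without any
## database download: clustered chemical space (scaffold-like prototype bit
## patterns with per-member bit flips), a smooth activity landscape over the
## bits (linear or with pairwise bit interactions), heteroscedastic repeated
## measurements per compound emitted in randomized parameter/unit forms that
## standardize back to the latent scale exactly, and optional label
## corruption with ground-truth flags.

#' Synthetic-data configuration
#'
#' Defaults are the package's reference study conditions: 2000 compounds in
#' 20 structural clusters over 256 bits (flip probability 0.05), a bilinear
#' activity landscape over 64 informative bits with landscape noise 0.3 log
#' units, and a geometric number of measurements per compound (mean 2) with
#' measurement noise 0.2 log units. Corruption is off by default.
#'
#' @param n_compounds number of compounds.
#' @param n_bits fingerprint length.
#' @param n_clusters number of scaffold-like clusters (<= n_compounds).
#' @param within_cluster_flip_prob per-bit flip probability applied to each
#'   cluster member's prototype.
#' @param activity_model `"bilinear"` (linear plus pairwise bit
#'   interactions) or `"linear"`.
#' @param informative_bits number of bits carrying activity signal.
#' @param noise_sd landscape noise sd (log-activity units) added to the
#'   latent activity itself.
#' @param measurements_per_compound either a fixed integer or
#'   `list(dist = "geometric", mean = m)` for `1 + Geometric` counts with
#'   the given mean.
#' @param measurement_sd per-measurement noise sd (log units).
#' @param corruption_fraction probability that a compound's measurements are
#'   all offset by `corruption_offset` (ground truth is returned).
#' @param corruption_offset offset in log units (default 2, i.e. 100x in
#'   Ki).
#' @param activity_center latent mean in log10(Ki nM) units (default 2, a
#'   100 nM-centred landscape).
#' @param seed integer seed; every generator output is deterministic in it.
#' @return validated list of class `SynthConfig`.
#' @export
synthConfig <- function(n_compounds = 2000L, n_bits = 256L, n_clusters = 20L,
                        within_cluster_flip_prob = 0.05,
                        activity_model = c("bilinear", "linear"),
                        informative_bits = min(64L, n_bits), noise_sd = 0.3,
                        measurements_per_compound = list(dist = "geometric",
                                                         mean = 2),
                        measurement_sd = 0.2, corruption_fraction = 0,
                        corruption_offset = 2, activity_center = 2,
                        seed = 1L) {
  activity_model <- match.arg(activity_model)
  stopIfNot(n_clusters <= n_compounds, "n_clusters must not exceed n_compounds")
  stopIfNot(within_cluster_flip_prob >= 0 && within_cluster_flip_prob <= 1,
            "flip probability must lie in [0, 1]")
  stopIfNot(corruption_fraction >= 0 && corruption_fraction <= 1,
            "corruption_fraction must lie in [0, 1]")
  stopIfNot(informative_bits <= n_bits,
            "informative_bits must not exceed n_bits")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_bits = as.integer(n_bits),
                 n_clusters = as.integer(n_clusters),
                 within_cluster_flip_prob = within_cluster_flip_prob,
                 activity_model = activity_model,
                 informative_bits = as.integer(informative_bits),
                 noise_sd = noise_sd,
                 measurements_per_compound = measurements_per_compound,
                 measurement_sd = measurement_sd,
                 corruption_fraction = corruption_fraction,
                 corruption_offset = corruption_offset,
                 activity_center = activity_center,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Generate clustered synthetic fingerprints
#'
#' Each cluster has a random prototype bit pattern (bit density 0.3);
#' members are the prototype with bits flipped independently at the
#' configured probability. Compounds are dealt to clusters near-equally.
#'
#' @param config a [synthConfig()].
#' @return list with `fps` (a [FingerprintMatrix-class], scheme
#'   `"synthetic"`) and `clusters` (integer cluster label per compound).
#' @export
genFingerprints <- function(config) {
  stopIfNot(inherits(config, "SynthConfig"), "config must come from synthConfig()")
  withSeed(childSeed(config$seed, 1L), {
    n <- config$n_compounds; nb <- config$n_bits; nc <- config$n_clusters
    proto <- matrix(as.integer(stats::runif(nc * nb) < 0.3), nc, nb)
    clusters <- sample(rep_len(seq_len(nc), n))
    flips <- matrix(stats::runif(n * nb) < config$within_cluster_flip_prob,
                    n, nb)
    bits <- abs(proto[clusters, , drop = FALSE] - flips)
    ids <- sprintf("SYN%05d", seq_len(n))
    list(fps = FingerprintMatrix(bits, ids, "synthetic"),
         clusters = stats::setNames(clusters, ids))
  })
}

.measurementCounts <- function(spec, n) {
  if (is.numeric(spec) && length(spec) == 1L)
    return(rep(as.integer(spec), n))
  stopIfNot(is.list(spec) && identical(spec$dist, "geometric"),
            "measurements_per_compound must be an integer or a geometric spec")
  stopIfNot(spec$mean >= 1, "geometric measurement mean must be >= 1")
  1L + stats::rgeom(n, prob = 1 / spec$mean)
}

#' Generate activities and a raw measurement table over fingerprints
#'
#' The latent activity is a weighted sum over a fixed random subset of
#' informative bits (`linear`), optionally plus pairwise products of
#' informative bits (`bilinear`), standardized to unit spread, centred at
#' `activity_center`, plus landscape noise. Each compound receives one or
#' more measurements (latent + measurement noise, plus the corruption offset
#' for corrupted compounds), emitted as activity records in randomized
#' parameter forms (Ki, IC50 at twice the Ki, pKi, pIC50) and concentration
#' units covering all six — every form standardizes back to the latent
#' scale exactly.
#'
#' @param fps output of [genFingerprints()] (the list, or a
#'   [FingerprintMatrix-class]).
#' @param config the same [synthConfig()].
#' @param strict_relations emit only `=` relations (default `TRUE`); when
#'   `FALSE`, a small fraction of records get relations from the extended
#'   set.
#' @return list with `latent` (named true log-activities), `records` (raw
#'   activity table, one row per measurement), `corrupted` (named logical
#'   ground truth), `n_measurements` (named integer).
#' @export
genActivities <- function(fps, config, strict_relations = TRUE) {
  stopIfNot(inherits(config, "SynthConfig"), "config must come from synthConfig()")
  if (is.list(fps) && !methods::is(fps, "FingerprintMatrix")) fps <- fps$fps
  B <- fpBits(fps)
  ids <- compoundIds(fps)
  n <- nrow(B)

  withSeed(childSeed(config$seed, 2L), {
    S <- sample.int(ncol(B), config$informative_bits)
    w <- stats::rnorm(config$informative_bits)
    z <- drop(B[, S, drop = FALSE] %*% w)
    if (config$activity_model == "bilinear") {
      n_pairs <- config$informative_bits
      p1 <- sample(S, n_pairs, replace = TRUE)
      p2 <- sample(S, n_pairs, replace = TRUE)
      v <- stats::rnorm(n_pairs)
      z2 <- drop((B[, p1, drop = FALSE] * B[, p2, drop = FALSE]) %*% v)
      zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
      z <- zs(z) + zs(z2)
    }
    if (stats::sd(z) > 0) z <- (z - mean(z)) / stats::sd(z)
    latent <- config$activity_center + z +
      stats::rnorm(n, sd = config$noise_sd)
    names(latent) <- ids

    corrupted <- stats::runif(n) < config$corruption_fraction
    names(corrupted) <- ids
    m <- .measurementCounts(config$measurements_per_compound, n)
    names(m) <- ids

    cid <- rep(ids, m)
    v_log <- rep(latent, m) + stats::rnorm(sum(m), sd = config$measurement_sd) +
      rep(ifelse(corrupted, config$corruption_offset, 0), m)

    nrec <- length(v_log)
    forms <- sample(c("Ki", "IC50", "pKi", "pIC50"), nrec, replace = TRUE)
    units <- sample(c("M", "mM", "uM", "nM", "pM", "fM"), nrec, replace = TRUE)
    value <- numeric(nrec); unit <- rep(NA_character_, nrec)
    ki_nm <- 10^v_log
    is_ki <- forms == "Ki"; is_ic <- forms == "IC50"
    value[is_ki] <- nmToUnit(ki_nm[is_ki], units[is_ki])
    unit[is_ki] <- units[is_ki]
    value[is_ic] <- nmToUnit(2 * ki_nm[is_ic], units[is_ic])
    unit[is_ic] <- units[is_ic]
    value[forms == "pKi"] <- 9 - v_log[forms == "pKi"]
    value[forms == "pIC50"] <- 9 - v_log[forms == "pIC50"] - log10(2)

    relation <- rep("=", nrec)
    if (!strict_relations) {
      alt <- stats::runif(nrec) < 0.1
      relation[alt] <- sample(c("<", ">", "<=", ">=", "~"), sum(alt),
                              replace = TRUE)
    }

    records <- activityRecords(compound_id = cid, parameter = forms,
                               relation = relation, value = value,
                               unit = unit, organism = "Homo sapiens")
    list(latent = latent, records = records, corrupted = corrupted,
         n_measurements = m)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [genFingerprints()], [genActivities()] and
#' the curation pipeline, returning everything the downstream stages need.
#'
#' @param config a [synthConfig()].
#' @param strict_relations see [genActivities()].
#' @return list with `fps`, `clusters`, `latent`, `records`, `corrupted`,
#'   `compounds` (curated table), `labels` (named label vector).
#' @export
genDataset <- function(config, strict_relations = TRUE) {
  fp <- genFingerprints(config)
  act <- genActivities(fp$fps, config, strict_relations)
  prep <- prepareActivityData(act$records,
                              relation_mode = if (strict_relations) "strict"
                                              else "extended")
  cc <- prep$compounds
  list(fps = fp$fps[cc$compound_id], clusters = fp$clusters[cc$compound_id],
       latent = act$latent[cc$compound_id],
       records = act$records, corrupted = act$corrupted[cc$compound_id],
       compounds = cc,
       labels = stats::setNames(cc$label, cc$compound_id))
}
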