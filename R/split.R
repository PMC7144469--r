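## Fold assignment: random k-fold CV and balanced agglomerative clustering
## (BAC). BAC places whole structural clusters into folds so that test
## compounds are dissimilar to the training set — the harder, more honest
## evaluation regime for activity models.

#' Random k-fold cross-validation assignment
#'
#' Shuffles compounds under the seed and deals them into k folds whose sizes
#' differ by at most one.
#'
#' @param compound_ids character vector of compound ids (or a single integer
#'   n, in which case ids `cmpd_0001..` are generated).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A [SplitAssignment-class].
#' @export
randomCvFolds <- function(compound_ids, k = 5L, seed = 1L) {
  if (is.numeric(compound_ids) && length(compound_ids) == 1L)
    compound_ids <- sprintf("cmpd_%04d", seq_len(compound_ids))
  n <- length(compound_ids)
  stopIfNot(k >= 2L, "k must be at least 2")
  stopIfNot(n >= k, sprintf("cannot split %d compounds into %d folds", n, k))
  fold <- withSeed(seed, {
    idx <- sample.int(n)
    f <- integer(n)
    f[idx] <- (seq_len(n) - 1L) %% k
    f
  })
  methods::new("SplitAssignment", compoundIds = as.character(compound_ids),
               fold = as.integer(fold), k = as.integer(k),
               method = "random_cv", seed = as.integer(seed))
}

#' Balanced agglomerative clustering (BAC) fold assignment
#'
#' Clusters compounds by average-linkage agglomerative clustering on
#' Tanimoto distance (1 - Tanimoto), cuts the dendrogram into
#' `min(clusters_per_fold * k, n)` clusters, then packs whole clusters onto
#' folds greedily, largest cluster first, always onto the currently smallest
#' fold (ties to the lowest fold index). Clusters larger than the fold
#' capacity `ceiling(n / k)` are split — only as a last resort — into
#' capacity-sized chunks (member order shuffled under the seed) before
#' packing.
#'
#' @param fps a [FingerprintMatrix-class].
#' @param k number of folds (default 5).
#' @param seed integer seed (used only where cluster structure forces a
#'   split; clustering itself is deterministic).
#' @param clusters_per_fold dendrogram is cut into `clusters_per_fold * k`
#'   clusters (default 3, giving the packer room to balance).
#' @return A [SplitAssignment-class].
#' @export
bacFolds <- function(fps, k = 5L, seed = 1L, clusters_per_fold = 3L) {
  stopIfNot(methods::is(fps, "FingerprintMatrix"), "fps must be a FingerprintMatrix")
  n <- length(fps)
  stopIfNot(k >= 2L, "k must be at least 2")
  stopIfNot(n >= k, sprintf("cannot split %d compounds into %d folds", n, k))

  d <- stats::as.dist(1 - tanimotoMatrix(fps))
  hc <- stats::hclust(d, method = "average")
  n_clusters <- min(as.integer(clusters_per_fold) * as.integer(k), n)
  cl <- stats::cutree(hc, k = n_clusters)

  capacity <- ceiling(n / k)
  members <- split(seq_len(n), cl)
  ## last-resort split of oversized clusters into capacity-sized chunks
  chunks <- withSeed(seed, {
    out <- list()
    for (m in members) {
      if (length(m) > capacity) {
        m <- sample(m)
        out <- c(out, split(m, ceiling(seq_along(m) / capacity)))
      } else out <- c(out, list(m))
    }
    out
  })

  ## greedy largest-first packing onto the currently smallest fold;
  ## ties by insertion order of chunks, then lowest fold index
  ord <- order(-vapply(chunks, length, integer(1)), seq_along(chunks))
  fold_sizes <- integer(k)
  fold <- integer(n)
  for (ci in ord) {
    target <- which.min(fold_sizes)  # lowest index wins ties
    fold[chunks[[ci]]] <- target - 1L
    fold_sizes[target] <- fold_sizes[target] + length(chunks[[ci]])
  }

  methods::new("SplitAssignment", compoundIds = compoundIds(fps),
               fold = as.integer(fold), k = as.integer(k), method = "bac",
               seed = as.integer(seed))
}

#' Per-fold train/test index helper
#'
#' @param split a [SplitAssignment-class].
#' @param test_fold 0-based index of the fold used as test set.
#' @return list with integer vectors `train` and `test` (row indices into
#'   the split's compound order).
#' @export
foldIndices <- function(split, test_fold) {
  stopIfNot(test_fold >= 0L && test_fold < split@k, "test_fold out of range")
  test <- which(split@fold == test_fold)
  list(train = setdiff(seq_along(split@fold), test), test = test)
}

#' Mean between-fold maximum similarity
#'
#' Diagnostic for split hardness: for each compound, the maximum Tanimoto to
#' any compound in a different fold, averaged over compounds. Lower values
#' mean folds are structurally better separated (the BAC mechanism).
#'
#' @param fps a [FingerprintMatrix-class].
#' @param split a [SplitAssignment-class] over the same compounds.
#' @return single numeric in \[0, 1\].
#' @export
betweenFoldSimilarity <- function(fps, split) {
  stopIfNot(identical(compoundIds(fps), split@compoundIds),
            "fps and split cover different compounds")
  sim <- tanimotoMatrix(fps)
  diag(sim) <- 0
  same <- outer(split@fold, split@fold, "==")
  sim[same] <- -Inf
  mean(apply(sim, 1, max))
}
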