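# Isolation forest for feature-table outlier exclusion.
#
# The classic construction: fully random binary trees on subsamples of the
# data; anomalous points isolate in few splits. Score for a point is
# 2^(-E[h] / c(psi)) with E[h] the mean path length over trees and c(psi) the
# expected path length of an unsuccessful BST search. Implemented here
# directly because no isolation-forest package ships with the analysis stack;
# the algorithm is small and fully deterministic given the seed.

iforest_cn <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

iforest_grow <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1L || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  ranges <- apply(x, 2, range)
  usable <- which(ranges[2, ] > ranges[1, ])
  if (!length(usable)) return(list(leaf = TRUE, size = n))
  j <- if (length(usable) == 1L) usable else sample(usable, 1L)
  split <- stats::runif(1, ranges[1, j], ranges[2, j])
  left <- x[, j] < split
  list(
    leaf = FALSE, var = j, split = split,
    left = iforest_grow(x[left, , drop = FALSE], depth + 1L, max_depth),
    right = iforest_grow(x[!left, , drop = FALSE], depth + 1L, max_depth)
  )
}

iforest_path <- function(tree, row, depth = 0) {
  if (tree$leaf) return(depth + iforest_cn(tree$size))
  if (row[tree$var] < tree$split) {
    iforest_path(tree$left, row, depth + 1)
  } else {
    iforest_path(tree$right, row, depth + 1)
  }
}

#' Flag outlying subjects with an isolation forest
#'
#' Fits an isolation forest to the numeric feature columns and flags the
#' `contamination` fraction of subjects with the highest anomaly scores for
#' exclusion from model training.
#'
#' @param features feature table (data.frame; non-numeric columns such as
#'   `subject_id` are ignored for scoring)
#' @param contamination fraction of subjects to flag, in (0, 0.5)
#' @param seed integer seed
#' @param n_trees number of isolation trees
#' @param subsample per-tree subsample size
#' @return logical vector, `TRUE` = flagged outlier, with the anomaly scores
#'   as attribute `"score"`
#' @export
#' @examples
#' x <- data.frame(a = c(rnorm(20), 50), b = c(rnorm(20), -40))
#' detect_outliers(x, contamination = 0.04, seed = 1)
detect_outliers <- function(features, contamination = 0.02, seed = 1L,
                            n_trees = 100L, subsample = 256L) {
  if (contamination <= 0 || contamination >= 0.5) {
    stopf("contamination must be in (0, 0.5)")
  }
  x <- as.matrix(features[vapply(features, is.numeric, logical(1))])
  if (!all(is.finite(x))) stopf("features must be finite for outlier detection")
  n <- nrow(x)
  psi <- min(subsample, n)
  max_depth <- ceiling(log2(psi))
  set.seed(child_seed(seed, 13L))
  trees <- lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(n, psi)
    iforest_grow(x[idx, , drop = FALSE], 0L, max_depth)
  })
  mean_path <- vapply(seq_len(n), function(i) {
    mean(vapply(trees, iforest_path, numeric(1), row = x[i, ]))
  }, numeric(1))
  score <- 2^(-mean_path / iforest_cn(psi))
  k <- as.integer(ceiling(contamination * n))
  flags <- rank(-score, ties.method = "first") <= k
  attr(flags, "score") <- score
  flags
}
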