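#' Specification of a synthetic classification dataset
#'
#' Describes the structure wrapper feature selection assumes: a small
#' number of class-informative columns, optional redundant columns
#' (noisy linear mixes of the informative ones) and label-independent
#' noise columns, so that a small subset attains low classification
#' error while the full set carries a size penalty.
#'
#' @param n_samples Number of rows; at least `10 * n_classes`.
#' @param n_informative Number of class-informative columns (>= 1).
#' @param n_noise Number of pure-noise columns.
#' @param n_redundant Number of redundant columns.
#' @param n_classes Number of classes (>= 2).
#' @param class_separation Euclidean distance between adjacent
#'   class-conditional means in the informative subspace, in units of
#'   the within-class standard deviation (which is 1).  The spacing per
#'   informative dimension is therefore
#'   `class_separation / sqrt(n_informative)`, so informative features
#'   are individually weak but jointly separate the classes — the
#'   structure wrapper feature selection is designed to exploit.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples,
                           n_informative,
                           n_noise = 0L,
                           n_redundant = 0L,
                           n_classes = 2L,
                           class_separation = 2,
                           seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_informative <- as.integer(n_informative)
  n_noise <- as.integer(n_noise)
  n_redundant <- as.integer(n_redundant)
  n_classes <- as.integer(n_classes)
  stopifnot(
    n_informative >= 1L, n_noise >= 0L, n_redundant >= 0L,
    n_classes >= 2L, n_samples >= 10L * n_classes,
    is.finite(class_separation), class_separation > 0
  )
  structure(
    list(n_samples = n_samples, n_informative = n_informative,
         n_noise = n_noise, n_redundant = n_redundant,
         n_classes = n_classes, class_separation = class_separation,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic feature-selection dataset
#'
#' Informative columns are drawn from class-conditional Gaussians with
#' unit within-class standard deviation; adjacent class means are
#' `class_separation / sqrt(n_informative)` apart per informative
#' dimension, i.e. `class_separation` apart in the informative subspace
#' jointly.  Redundant columns are random linear
#' combinations of the informative block plus 10% relative Gaussian
#' noise; noise columns are standard normal and independent of the
#' label.  Columns are shuffled with a recorded permutation and the
#' ground-truth informative positions are stored in `informative_mask`.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `fs_dataset`: `features` (matrix),
#'   `labels` (factor), `feature_names`, `informative_mask` (0/1 vector,
#'   1 marking informative columns), and the column `permutation`.
#' @examples
#' d <- generate_dataset(synthetic_spec(100, 3, n_noise = 5, seed = 7))
#' dim(d$features)
#' sum(d$informative_mask)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ni <- spec$n_informative
  d <- ni + spec$n_redundant + spec$n_noise
  labels <- factor(rep_len(paste0("class", seq_len(spec$n_classes)), n))
  class_idx <- as.integer(labels)

  per_dim <- spec$class_separation / sqrt(ni)
  informative <- matrix(stats::rnorm(n * ni), n, ni) +
    matrix((class_idx - 1) * per_dim, n, ni)

  blocks <- list(informative)
  if (spec$n_redundant > 0L) {
    redundant <- matrix(0, n, spec$n_redundant)
    for (j in seq_len(spec$n_redundant)) {
      w <- stats::runif(ni, 0.5, 1.5) * sample(c(-1, 1), ni, replace = TRUE)
      base <- drop(informative %*% w)
      redundant[, j] <- base + stats::rnorm(n, sd = 0.1 * stats::sd(base))
    }
    blocks <- c(blocks, list(redundant))
  }
  if (spec$n_noise > 0L) {
    blocks <- c(blocks, list(matrix(stats::rnorm(n * spec$n_noise), n, spec$n_noise)))
  }
  features <- do.call(cbind, blocks)
  truth <- c(rep(1L, ni), rep(0L, d - ni))

  permutation <- sample.int(d)
  features <- features[, permutation, drop = FALSE]
  truth <- truth[permutation]
  feature_names <- sprintf("f%02d", seq_len(d))
  colnames(features) <- feature_names

  structure(
    list(features = features,
         labels = labels,
         feature_names = feature_names,
         informative_mask = truth,
         permutation = permutation,
         spec = spec),
    class = "fs_dataset"
  )
}

#' Construct a feature-selection dataset from components
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Class labels, coerced to factor.
#' @param feature_names Optional column names.
#' @param informative_mask Optional ground-truth 0/1 vector.
#' @return An `fs_dataset`.
#' @export
fs_dataset <- function(features, labels, feature_names = colnames(features),
                       informative_mask = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- droplevels(as.factor(labels))
  if (anyNA(features) || anyNA(labels)) stop("missing values are not allowed")
  if (nrow(features) != length(labels)) {
    stop("`features` rows and `labels` length differ")
  }
  if (nlevels(labels) < 2L) stop("need at least 2 distinct labels")
  if (nrow(features) < 10L) stop("need at least 10 samples")
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%02d", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names,
         informative_mask = informative_mask),
    class = "fs_dataset"
  )
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat(sprintf("Feature-selection dataset: %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), nlevels(x$labels)))
  if (!is.null(x$informative_mask)) {
    cat("  ground truth:", sum(x$informative_mask), "informative features\n")
  }
  invisible(x)
}

#' Exhaustive-search oracle over all non-empty subsets
#'
#' Enumerates every non-empty feature mask (up to `D = 16`, i.e. 65535
#' subsets) and scores each with exactly the same split, scaling and
#' KNN evaluation as the optimizer, returning the global minimum of the
#' wrapper fitness.  Ties keep the lowest mask index (masks enumerated
#' with feature 1 as the least-significant bit).
#'
#' @inheritParams subset_error
#' @param weight_alpha,weight_beta Fitness weights.
#' @return List with `mask`, `fitness`, `error`, `size`.
#' @export
exhaustive_best_subset <- function(dataset, k = 5L, split = split_spec(),
                                   weight_alpha = 0.99, weight_beta = 0.01) {
  d <- ncol(dataset$features)
  if (d > 16L) stop("exhaustive search refused for D > 16 (got ", d, ")")
  problem <- fs_problem(dataset, k, split, weight_alpha, weight_beta)
  best <- NULL
  for (code in seq_len(2^d - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, 0:(d - 1L)), 1L))
    res <- problem(mask)
    if (is.null(best) || res$fitness < best$fitness) {
      best <- list(mask = mask, fitness = res$fitness,
                   error = res$error, size = res$size)
    }
  }
  best
}
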