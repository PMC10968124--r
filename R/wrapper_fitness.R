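#' Train/evaluation split specification
#'
#' Two schemes are supported: a stratified `"holdout"` split (default
#' 80% train / 20% evaluation) and the `"three-way"` 50/30/20
#' train/validation/test convention, where the validation part scores
#' subsets during the search and the test part is reserved for final
#' reporting.
#'
#' @param scheme `"holdout"` or `"three-way"`.
#' @param train_fraction,validation_fraction,test_fraction Proportions
#'   summing to 1; `validation_fraction` must be 0 for holdout and
#'   positive for three-way.
#' @param stratified Draw the split per class (default) or globally.
#' @param seed Integer seed the split is drawn from.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(scheme = c("holdout", "three-way"),
                       train_fraction = NULL,
                       validation_fraction = NULL,
                       test_fraction = NULL,
                       stratified = TRUE,
                       seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "holdout") {
    if (is.null(train_fraction)) train_fraction <- 0.8
    if (is.null(validation_fraction)) validation_fraction <- 0
    if (is.null(test_fraction)) test_fraction <- 1 - train_fraction
    if (validation_fraction != 0) stop("holdout scheme has no validation part")
  } else {
    if (is.null(train_fraction)) train_fraction <- 0.5
    if (is.null(validation_fraction)) validation_fraction <- 0.3
    if (is.null(test_fraction)) test_fraction <- 1 - train_fraction - validation_fraction
    if (validation_fraction <= 0) stop("three-way scheme needs a validation part")
  }
  fr <- c(train_fraction, validation_fraction, test_fraction)
  if (abs(sum(fr) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (train_fraction <= 0 || test_fraction <= 0) {
    stop("train and test fractions must be positive")
  }
  structure(
    list(scheme = scheme,
         train_fraction = train_fraction,
         validation_fraction = validation_fraction,
         test_fraction = test_fraction,
         stratified = isTRUE(stratified),
         seed = as.integer(seed)),
    class = "split_spec"
  )
}

# Allocate n items to parts proportionally, largest-remainder rounding,
# guaranteeing >= 1 in every positive-fraction part when n allows.
.allocate <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  active <- which(fractions > 0)
  for (p in active) {
    if (base[p] == 0 && any(base[active] > 1)) {
      donor <- active[which.max(base[active])]
      base[donor] <- base[donor] - 1
      base[p] <- base[p] + 1
    }
  }
  base
}

#' Draw split indices for a label vector
#'
#' @param labels Factor (or coercible) class labels.
#' @param split A [split_spec()].
#' @return List of integer index vectors `train`, `validation` (possibly
#'   empty), `test`.
#' @export
draw_split <- function(labels, split) {
  labels <- as.factor(labels)
  n <- length(labels)
  fr <- c(split$train_fraction, split$validation_fraction, split$test_fraction)
  assign_part <- integer(n)
  # local RNG so drawing a split never disturbs the optimizer's stream
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(split$seed)
  groups <- if (split$stratified) split(seq_len(n), labels) else list(seq_len(n))
  for (idx in groups) {
    counts <- .allocate(length(idx), fr)
    shuffled <- idx[sample.int(length(idx))]
    assign_part[shuffled] <- rep.int(1:3, counts)
  }
  list(train = which(assign_part == 1L),
       validation = which(assign_part == 2L),
       test = which(assign_part == 3L))
}

# Min-max scaling fitted on the training rows only; zero-range columns
# collapse to 0 so they carry no distance information.
.minmax_fit <- function(train_x) {
  lo <- apply(train_x, 2L, min)
  hi <- apply(train_x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

.minmax_apply <- function(x, fit) {
  sweep(sweep(x, 2L, fit$lo, "-"), 2L, fit$rng, "/")
}

# Pure-R reference implementation of the deterministic
# k-nearest-neighbour rule: Euclidean distance, majority vote, distance
# ties resolved by training-row order, vote ties by the label of the
# nearest neighbour among the tied classes.  The hot path uses the
# compiled kernel in src/knn.cpp with identical semantics; this version
# is retained as an independent cross-check.
.knn_predict <- function(train_x, train_y, test_x, k) {
  n_train <- nrow(train_x)
  n_test <- nrow(test_x)
  stopifnot(k >= 1L, k < n_train)
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  # k passes of row-wise argmin give neighbours in increasing-distance
  # order with "first index wins" tie-breaking
  nb <- matrix(0L, n_test, k)
  for (j in seq_len(k)) {
    idx <- max.col(-d2, ties.method = "first")
    nb[, j] <- idx
    d2[cbind(seq_len(n_test), idx)] <- Inf
  }
  y <- as.integer(train_y)
  nlev <- nlevels(train_y)
  votes <- matrix(0L, n_test, nlev)
  for (j in seq_len(k)) {
    hit <- cbind(seq_len(n_test), y[nb[, j]])
    votes[hit] <- votes[hit] + 1L
  }
  top <- max.col(votes, ties.method = "first")
  best <- votes[cbind(seq_len(n_test), top)]
  n_winner <- rowSums(votes == best)
  for (i in which(n_winner > 1L)) {
    winners <- which(votes[i, ] == best[i])
    lab <- y[nb[i, ]]
    top[i] <- lab[match(TRUE, lab %in% winners)]
  }
  factor(levels(train_y)[top], levels = levels(train_y))
}

#' Hold-out error of a KNN classifier on a feature subset
#'
#' Splits the dataset per `split`, min-max scales features using training
#' statistics only, restricts to the columns selected by `mask`, fits a
#' deterministic k-nearest-neighbour classifier on the training part and
#' returns the misclassification fraction on the evaluation part (the
#' hold-out set for `"holdout"`, the validation set for `"three-way"`,
#' or the test set when `part = "test"`).
#'
#' @param dataset An `fs_dataset` (see [generate_dataset()] or
#'   [read_csv_dataset()]).
#' @param mask Integer 0/1 vector over the features; at least one 1.
#' @param k Neighbour count, `1 <= k <` training-set size.
#' @param split A [split_spec()]; its `seed` fixes the split.
#' @param part Which part to score: `"eval"` (default, the search-time
#'   part) or `"test"` (three-way scheme only).
#' @return Misclassification fraction in \[0, 1\].
#' @export
subset_error <- function(dataset, mask, k = 5L, split = split_spec(),
                         part = c("eval", "test")) {
  part <- match.arg(part)
  prep <- .prepare_eval(dataset, k, split)
  .masked_error(prep, mask, part)
}

# Split + scale once; reused by subset_error, fs_problem and the
# exhaustive oracle so all three score a mask identically.
.prepare_eval <- function(dataset, k, split) {
  stopifnot(inherits(dataset, "fs_dataset"))
  parts <- draw_split(dataset$labels, split)
  eval_idx <- if (split$scheme == "three-way") parts$validation else parts$test
  fit <- .minmax_fit(dataset$features[parts$train, , drop = FALSE])
  if (k >= length(parts$train)) {
    stop("`k` must be smaller than the training-set size (",
         length(parts$train), ")")
  }
  train_x <- .minmax_apply(dataset$features[parts$train, , drop = FALSE], fit)
  eval_x <- .minmax_apply(dataset$features[eval_idx, , drop = FALSE], fit)
  test_x <- .minmax_apply(dataset$features[parts$test, , drop = FALSE], fit)
  train_y <- droplevels(as.factor(dataset$labels[parts$train]))
  eval_y <- as.factor(dataset$labels[eval_idx])
  test_y <- as.factor(dataset$labels[parts$test])
  # features-as-rows copies keep the compiled kernel's inner loop
  # contiguous; labels are pre-coded against the training levels (an
  # unseen evaluation label maps to NA and always counts as an error)
  list(
    train_x = train_x, train_xt = t(train_x),
    train_y = train_y, train_codes = as.integer(train_y),
    eval_x = eval_x, eval_xt = t(eval_x),
    eval_y = eval_y,
    eval_codes = match(as.character(eval_y), levels(train_y)),
    test_x = test_x, test_xt = t(test_x),
    test_y = test_y,
    test_codes = match(as.character(test_y), levels(train_y)),
    nlev = nlevels(train_y),
    k = as.integer(k)
  )
}

.masked_error <- function(prep, mask, part = "eval") {
  mask <- as.integer(mask)
  if (length(mask) != ncol(prep$train_x)) {
    stop("`mask` length must equal the feature count")
  }
  if (!all(mask %in% c(0L, 1L))) stop("`mask` must be a 0/1 vector")
  cols <- which(mask == 1L)
  if (length(cols) == 0L) stop("`mask` selects no features; repair it first")
  xst <- if (part == "test") prep$test_xt else prep$eval_xt
  ys <- if (part == "test") prep$test_codes else prep$eval_codes
  codes <- .knn_predict_codes(prep$train_xt[cols, , drop = FALSE],
                              prep$train_codes,
                              xst[cols, , drop = FALSE],
                              prep$k, prep$nlev)
  mean(is.na(ys) | codes != ys)
}

#' Wrapper fitness of a feature subset
#'
#' `weight_alpha * error + weight_beta * subset_size / total_features`:
#' a convex combination of the classification error and the fraction of
#' features kept, so among equally accurate subsets the smaller wins.
#'
#' @param error Classification error in \[0, 1\].
#' @param subset_size Number of selected features.
#' @param total_features Total feature count `D`.
#' @param weight_alpha,weight_beta Weights with
#'   `weight_alpha = 1 - weight_beta`.
#' @return Fitness value in \[0, 1\] (smaller is better).
#' @examples
#' fitness_value(0.1, 5, 10)  # 0.99 * 0.1 + 0.01 * 0.5 = 0.104
#' @export
fitness_value <- function(error, subset_size, total_features,
                          weight_alpha = 0.99, weight_beta = 0.01) {
  stopifnot(error >= 0, error <= 1,
            subset_size >= 0, subset_size <= total_features)
  if (abs(weight_alpha + weight_beta - 1) > 1e-9) {
    stop("`weight_alpha` must equal 1 - `weight_beta`")
  }
  weight_alpha * error + weight_beta * subset_size / total_features
}

#' Build the wrapper-fitness callable for a dataset
#'
#' Fixes the split and the scaled feature matrices once, then returns a
#' function that maps a 0/1 mask to `list(fitness, error, size)`.  This
#' is the objective handed to [bgoa_optimize()] and to
#' [exhaustive_best_subset()], guaranteeing both score any mask
#' identically.
#'
#' @inheritParams subset_error
#' @param weight_alpha,weight_beta Fitness weights.
#' @return A function of class `fs_problem` with attributes `n_features`
#'   and `prep`.
#' @export
fs_problem <- function(dataset, k = 5L, split = split_spec(),
                       weight_alpha = 0.99, weight_beta = 0.01) {
  prep <- .prepare_eval(dataset, k, split)
  d <- ncol(dataset$features)
  fn <- function(mask) {
    err <- .masked_error(prep, mask)
    list(fitness = fitness_value(err, sum(mask), d, weight_alpha, weight_beta),
         error = err,
         size = sum(mask))
  }
  class(fn) <- c("fs_problem", "function")
  attr(fn, "n_features") <- d
  attr(fn, "prep") <- prep
  fn
}
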