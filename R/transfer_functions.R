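#' Catalog of transfer-function variants
#'
#' @return Character vector of the recognised variant names: the four
#'   S-shaped and four V-shaped baselines plus the time-varying
#'   sine+Gaussian variant `"tvg"`.
#' @export
transfer_variants <- function() {
  c("s1", "s2", "s3", "s4", "v1", "v2", "v3", "v4", "tvg")
}

.match_variant <- function(variant) {
  v <- tolower(as.character(variant))
  if (length(v) != 1L || !(v %in% transfer_variants())) {
    stop("unknown transfer variant: ", variant,
         " (expected one of ", paste(transfer_variants(), collapse = ", "), ")")
  }
  v
}

#' S-shaped transfer functions
#'
#' The four classic sigmoid transfer maps used to turn a continuous
#' coordinate into the probability of setting a bit to 1:
#' S1 `1/(1+e^-x)`, S2 `1/(1+e^-2x)`, S3 `1/(1+e^-x/2)`,
#' S4 `1/(1+e^-x/3)`.  All are strictly increasing with range (0, 1).
#'
#' @param variant One of `"s1"`, `"s2"`, `"s3"`, `"s4"`.
#' @param x Finite numeric input (vectorized).
#' @return Probabilities in (0, 1).
#' @export
s_shaped <- function(variant, x) {
  v <- .match_variant(variant)
  if (!all(is.finite(x))) stop("`x` must be finite")
  slope <- switch(v,
    s1 = 1, s2 = 2, s3 = 1 / 2, s4 = 1 / 3,
    stop("not an S-shaped variant: ", variant)
  )
  1 / (1 + exp(-slope * x))
}

#' V-shaped transfer functions
#'
#' The four classic symmetric transfer maps used as bit-flip
#' probabilities: V1 `|erf(sqrt(pi)/2 * x)|`, V2 `|tanh(x)|`,
#' V3 `|x / sqrt(1 + x^2)|`, V4 `|2/pi * atan(pi/2 * x)|`.  All are even,
#' zero at the origin, nondecreasing on `[0, Inf)` and bounded in
#' `[0, 1)`.
#'
#' @param variant One of `"v1"`, `"v2"`, `"v3"`, `"v4"`.
#' @param x Finite numeric input (vectorized).
#' @return Probabilities in `[0, 1)`.
#' @export
v_shaped <- function(variant, x) {
  v <- .match_variant(variant)
  if (!all(is.finite(x))) stop("`x` must be finite")
  switch(v,
    # erf(z) = 2 * pnorm(z * sqrt(2)) - 1
    v1 = abs(2 * stats::pnorm(sqrt(pi) / 2 * x * sqrt(2)) - 1),
    v2 = abs(tanh(x)),
    v3 = abs(x / sqrt(1 + x^2)),
    v4 = abs(2 / pi * atan(pi / 2 * x)),
    stop("not a V-shaped variant: ", variant)
  )
}

#' Scheduled transfer parameters at a given iteration
#'
#' Evaluates the three linear schedules: `alpha` increases from
#' `alpha_min` to `alpha_max` (the sine transfer widens, moving from
#' exploration to exploitation), while `beta` and `sigma` decrease from
#' their maxima to their minima (the V-shape steepens and the Gaussian
#' mutation fades out).
#'
#' @param iteration Iteration index in `[0, max_iterations]`.
#' @param schedule A [transfer_schedule()].
#' @return List with components `alpha`, `beta`, `sigma`.
#' @export
schedule_values <- function(iteration, schedule) {
  L <- schedule$max_iterations
  if (any(iteration < 0) || any(iteration > L)) {
    stop("`iteration` must lie in [0, max_iterations]")
  }
  list(
    alpha = schedule$alpha_min + iteration * (schedule$alpha_max - schedule$alpha_min) / L,
    beta = schedule$beta_max - iteration * (schedule$beta_max - schedule$beta_min) / L,
    sigma = schedule$sigma_max - iteration * (schedule$sigma_max - schedule$sigma_min) / L
  )
}

#' Time-varying sine transfer probability
#'
#' `|sin(position / alpha)|`.  The absolute value keeps the result a
#' valid probability; small `alpha` makes the map oscillate rapidly
#' (high diversity), large `alpha` flattens it toward zero near the
#' origin (exploitation).
#'
#' @param position Continuous coordinate(s).
#' @param alpha Positive scale from the schedule.
#' @return Probabilities in \[0, 1\].
#' @export
sine_probability <- function(position, alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0)) stop("`alpha` must be positive")
  abs(sin(position / alpha))
}

#' Set bits from the sine transfer
#'
#' Bit `d` is set to 1 when `uniform_draws[d] <
#' sine_probability(positions[d], alpha)`, else 0 (a set-rule: the
#' previous bit is not consulted).
#'
#' @param positions Continuous coordinates.
#' @param alpha Sine-transfer scale.
#' @param uniform_draws One draw in `[0, 1)` per coordinate.
#' @return Integer bit vector.
#' @export
binarize_sine <- function(positions, alpha, uniform_draws) {
  if (length(uniform_draws) != length(positions)) {
    stop("`uniform_draws` must match `positions` in length")
  }
  as.integer(uniform_draws < sine_probability(positions, alpha))
}

#' Time-varying V-shaped + Gaussian transfer probability
#'
#' `|2/pi * atan(pi/2 * position / beta)| + sigma * gaussian_draw`,
#' clipped into \[0, 1\].  The Gaussian term is a mutation: early in the
#' run (`sigma` large) it randomizes flip probabilities to escape local
#' optima; by the last iterations it is negligible and the pure V-shape
#' remains.  With `beta = 1` and `sigma = 0` this is exactly the V4
#' baseline.
#'
#' @param position Continuous coordinate(s).
#' @param beta Positive steepness from the schedule.
#' @param sigma Non-negative mutation standard deviation.
#' @param gaussian_draw Standard-normal draw(s), one per coordinate.
#' @return Probabilities in \[0, 1\].
#' @export
tvg_probability <- function(position, beta, sigma, gaussian_draw) {
  if (!is.numeric(beta) || any(beta <= 0)) stop("`beta` must be positive")
  if (any(sigma < 0)) stop("`sigma` must be non-negative")
  raw <- abs(2 / pi * atan(pi / 2 * position / beta)) + sigma * gaussian_draw
  pmin(pmax(raw, 0), 1)
}

#' Flip bits by the time-varying Gaussian transfer
#'
#' Bit `d` is complemented when `uniform_draws[d]` falls below
#' [tvg_probability()] at that coordinate, and kept otherwise
#' (a flip-rule).
#'
#' @param bits Current integer bit vector.
#' @param positions Continuous coordinates, same length.
#' @param beta,sigma Schedule values.
#' @param uniform_draws One uniform draw per coordinate.
#' @param gaussian_draws One standard-normal draw per coordinate.
#' @return Integer bit vector.
#' @export
tvg_flip <- function(bits, positions, beta, sigma, uniform_draws, gaussian_draws) {
  n <- length(bits)
  if (length(positions) != n || length(uniform_draws) != n ||
      length(gaussian_draws) != n) {
    stop("all vectors must share one length")
  }
  p <- tvg_probability(positions, beta, sigma, gaussian_draws)
  flip <- uniform_draws < p
  out <- as.integer(bits)
  out[flip] <- 1L - out[flip]
  out
}

#' Generic binarization under a set- or flip-rule
#'
#' Harness shared by the static baselines: S-shaped probabilities use the
#' set-rule (bit becomes 1 with probability `p`), V-shaped probabilities
#' use the flip-rule (bit is complemented with probability `p`).
#'
#' @param probabilities Probabilities in \[0, 1\], one per bit.
#' @param rule `"set"` or `"flip"`.
#' @param current_bits Required for the flip-rule: the bits to perturb.
#' @param uniform_draws One uniform draw per bit.
#' @return Integer bit vector.
#' @export
binarize_static <- function(probabilities, rule = c("set", "flip"),
                            current_bits = NULL, uniform_draws) {
  rule <- match.arg(rule)
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("`probabilities` must lie in [0, 1]")
  }
  if (length(uniform_draws) != length(probabilities)) {
    stop("`uniform_draws` must match `probabilities` in length")
  }
  hit <- uniform_draws < probabilities
  if (rule == "set") {
    as.integer(hit)
  } else {
    if (is.null(current_bits) || length(current_bits) != length(probabilities)) {
      stop("flip-rule needs `current_bits` of matching length")
    }
    out <- as.integer(current_bits)
    out[hit] <- 1L - out[hit]
    out
  }
}
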