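#' Grasshopper social-force function
#'
#' The pairwise interaction kernel `S(r) = f * exp(-r / l) - exp(-r)`:
#' negative values are repulsion (short range), positive values
#' attraction (long range), and the zero crossing is the comfort-zone
#' boundary where neither dominates.  With the defaults `f = 0.5`,
#' `l = 1.5` the boundary sits at `3 * log(2)`, approximately 2.079, which
#' is why inter-grasshopper distances are normalized into \[1, 4\]: the
#' swarm then always contains both attracting and repelling pairs.
#'
#' @param r Non-negative distance(s), typically on the normalized scale.
#' @param f Attraction intensity (> 0).
#' @param l Attraction length scale (> 0).
#' @return Numeric vector of force values, same length as `r`.
#' @examples
#' social_force(c(1, 2.079, 4))
#' @export
social_force <- function(r, f = 0.5, l = 1.5) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0)) {
    stop("`r` must be finite and non-negative")
  }
  stopifnot(is.finite(f), f > 0, is.finite(l), l > 0)
  f * exp(-r / l) - exp(-r)
}

#' Comfort-zone boundary of the social force
#'
#' Locates the sign change of [social_force()] by bisection: the distance
#' at which repulsion turns into attraction.
#'
#' @param f,l Social-force parameters.
#' @param lower,upper Bracket for the root; the force must change sign
#'   across it.
#' @param tol Bracket width at which bisection stops.
#' @return The root as a single numeric value.
#' @examples
#' comfort_zone_distance()  # ~ 2.0794 = 3 * log(2)
#' @export
comfort_zone_distance <- function(f = 0.5, l = 1.5,
                                  lower = 0.1, upper = 4, tol = 1e-4) {
  flo <- social_force(lower, f, l)
  fhi <- social_force(upper, f, l)
  if (sign(flo) == sign(fhi)) {
    stop("social force does not change sign on [", lower, ", ", upper, "]")
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    fm <- social_force(mid, f, l)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lower <- mid
      flo <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

#' Linearly shrinking comfort coefficient
#'
#' `c(l) = c_max - l * (c_max - c_min) / L`: starts at `c_max` and decays
#' linearly to `c_min` at the final iteration, contracting both the
#' comfort zone and the step size so the swarm moves from exploration to
#' exploitation.
#'
#' @param iteration Current iteration index `l`, `0 <= l <= L`
#'   (vectorized).
#' @param max_iterations Iteration budget `L`.
#' @param c_max,c_min Schedule endpoints.
#' @return Coefficient value(s) in `[c_min, c_max]`.
#' @export
comfort_coefficient <- function(iteration, max_iterations,
                                c_max = 1.0, c_min = 1e-5) {
  stopifnot(max_iterations >= 1, c_min > 0, c_min < c_max)
  if (any(iteration < 0) || any(iteration > max_iterations)) {
    stop("`iteration` must lie in [0, max_iterations]")
  }
  c_max - iteration * (c_max - c_min) / max_iterations
}

#' Normalize pairwise distances into [1, 4]
#'
#' Affinely maps the off-diagonal entries of a symmetric distance matrix
#' so the smallest becomes 1 and the largest 4, keeping the social force
#' in its mixed attraction/repulsion regime.  The diagonal stays 0 (it is
#' never used).  If all off-diagonal distances are equal the map is
#' undefined, so every pair is assigned the interval midpoint 2.5; with
#' fewer than two points the input is returned unchanged.
#'
#' @param pairwise Symmetric N x N matrix of Euclidean distances with a
#'   zero diagonal.
#' @return Matrix of the same shape with off-diagonal entries in \[1, 4\].
#' @export
normalize_distances <- function(pairwise) {
  stopifnot(is.matrix(pairwise), nrow(pairwise) == ncol(pairwise))
  n <- nrow(pairwise)
  if (n < 2L) return(pairwise)
  off <- pairwise[row(pairwise) != col(pairwise)]
  if (any(!is.finite(off)) || any(off < 0)) {
    stop("pairwise distances must be finite and non-negative")
  }
  dmin <- min(off)
  dmax <- max(off)
  out <- pairwise
  if (dmax - dmin <= 0) {
    out[row(out) != col(out)] <- 2.5
  } else {
    idx <- row(out) != col(out)
    out[idx] <- 1 + 3 * (pairwise[idx] - dmin) / (dmax - dmin)
  }
  out
}

#' One step of the continuous grasshopper dynamics
#'
#' Computes, for every grasshopper, the social step
#' `DX[i, ] = c * sum_{j != i} c * ((ub - lb) / 2) * S(d_ij) *
#' (x_j - x_i) / d_ij` with `d_ij` the pairwise distance normalized into
#' \[1, 4\] (both the social-force argument and the unit-vector
#' denominator use the normalized scalar), and proposes the new position
#' `DX[i, ] + target_position`, clipped to the box bounds.  Both
#' multiplicative coefficients are the same comfort coefficient `c`.
#'
#' @param positions N x D matrix of continuous coordinates.
#' @param target_position Length-D coordinates of the incumbent best
#'   solution the swarm is attracted to.
#' @param config A [goa_config()].
#' @param c Comfort coefficient for this iteration.
#' @return List with `step` (N x D matrix of increments) and `proposed`
#'   (N x D matrix of clipped new positions).
#' @export
goa_step <- function(positions, target_position, config, c) {
  stopifnot(is.matrix(positions), all(is.finite(positions)),
            length(target_position) == ncol(positions),
            c >= config$c_min - 1e-15, c <= config$c_max + 1e-15)
  n <- nrow(positions)
  d <- ncol(positions)
  half_range <- (config$upper_bound - config$lower_bound) / 2
  if (n == 1L) {
    step <- matrix(0, 1L, d)
  } else {
    dn <- normalize_distances(as.matrix(stats::dist(positions)))
    w <- c * half_range * social_force(dn, config$f, config$l) / dn
    diag(w) <- 0
    # sum_j w_ij * (x_j - x_i) = (W %*% X)[i,] - rowSums(W)[i] * X[i,]
    step <- c * (w %*% positions - rowSums(w) * positions)
  }
  if (any(!is.finite(step))) stop("non-finite step encountered")
  dimnames(step) <- NULL
  proposed <- sweep(step, 2L, target_position, "+")
  proposed <- pmin(pmax(proposed, config$lower_bound), config$upper_bound)
  list(step = step, proposed = proposed)
}
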