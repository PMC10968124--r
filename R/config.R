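#' Optimizer configuration
#'
#' Bundles every constant of the grasshopper dynamics and of the wrapper
#' objective into a validated list.  Defaults follow the standard settings
#' for binary grasshopper feature selection: attraction intensity
#' `f = 0.5` and length scale `l = 1.5` (which place the comfort-zone
#' boundary near 2.079 on the normalized \[1, 4\] distance scale), comfort
#' coefficient shrinking linearly from 1 to 1e-5, a population of 40
#' grasshoppers run for 100 iterations, continuous coordinates boxed in
#' \[0, 1\], and fitness weights 0.99 (classification error) / 0.01
#' (subset-size ratio).
#'
#' @param dim Number of binary decision variables (features), `D >= 1`.
#' @param population_size Number of grasshoppers `N`.
#' @param max_iterations Iteration budget `L`.
#' @param f Attraction intensity of the social-force function.
#' @param l Attraction length scale of the social-force function.
#' @param c_max,c_min Endpoints of the linearly shrinking comfort
#'   coefficient; `0 < c_min < c_max`.
#' @param lower_bound,upper_bound Box bounds of the continuous positions
#'   (scalar, applied to every dimension).
#' @param weight_beta Weight of the subset-size ratio in the fitness;
#'   `weight_alpha` defaults to its complement.
#' @param weight_alpha Weight of the classification error; must equal
#'   `1 - weight_beta`.
#' @return An object of class `goa_config`.
#' @seealso [transfer_schedule()], [bgoa_optimize()]
#' @examples
#' goa_config(dim = 10, population_size = 20, max_iterations = 50)
#' @export
goa_config <- function(dim,
                       population_size = 40L,
                       max_iterations = 100L,
                       f = 0.5,
                       l = 1.5,
                       c_max = 1.0,
                       c_min = 1e-5,
                       lower_bound = 0.0,
                       upper_bound = 1.0,
                       weight_beta = 0.01,
                       weight_alpha = 1 - weight_beta) {
  dim <- as.integer(dim)
  population_size <- as.integer(population_size)
  max_iterations <- as.integer(max_iterations)
  stopifnot(
    length(dim) == 1L, dim >= 1L,
    length(population_size) == 1L, population_size >= 1L,
    length(max_iterations) == 1L, max_iterations >= 1L,
    is.finite(f), f > 0, is.finite(l), l > 0,
    is.finite(c_min), is.finite(c_max), c_min > 0, c_min < c_max,
    is.finite(lower_bound), is.finite(upper_bound),
    upper_bound > lower_bound
  )
  if (abs(weight_alpha + weight_beta - 1) > 1e-12) {
    stop("`weight_alpha` + `weight_beta` must equal 1 (got ",
         weight_alpha + weight_beta, ")")
  }
  structure(
    list(
      dim = dim,
      population_size = population_size,
      max_iterations = max_iterations,
      f = f, l = l,
      c_max = c_max, c_min = c_min,
      lower_bound = lower_bound, upper_bound = upper_bound,
      weight_alpha = weight_alpha, weight_beta = weight_beta
    ),
    class = "goa_config"
  )
}

#' @export
print.goa_config <- function(x, ...) {
  cat("Grasshopper optimizer configuration\n")
  cat(sprintf("  dimensions: %d, population: %d, iterations: %d\n",
              x$dim, x$population_size, x$max_iterations))
  cat(sprintf("  social force: f = %g, l = %g; comfort c: %g -> %g\n",
              x$f, x$l, x$c_max, x$c_min))
  cat(sprintf("  bounds: [%g, %g]; fitness weights: %g error + %g size\n",
              x$lower_bound, x$upper_bound, x$weight_alpha, x$weight_beta))
  invisible(x)
}

#' Time-varying transfer-function schedule
#'
#' Holds the ranges of the three linearly scheduled transfer parameters:
#' the sine-transfer scale `alpha` (increasing, default 0.05 to 5), the
#' V-shape steepness `beta` (decreasing, default 10 to 0.05) and the
#' Gaussian-mutation standard deviation `sigma` (decreasing, default 10
#' to 0.01).  `alpha_min` uses a small positive floor rather than zero,
#' since the sine transfer divides the coordinate by `alpha`.
#'
#' @param max_iterations Iteration budget `L` the schedule spans.
#' @param alpha_min,alpha_max Range of the sine-transfer scale.
#' @param beta_min,beta_max Range of the V-shape steepness.
#' @param sigma_min,sigma_max Range of the mutation standard deviation.
#' @return An object of class `transfer_schedule`.
#' @seealso [schedule_values()]
#' @export
transfer_schedule <- function(max_iterations,
                              alpha_min = 0.05, alpha_max = 5,
                              beta_min = 0.05, beta_max = 10,
                              sigma_min = 0.01, sigma_max = 10) {
  max_iterations <- as.integer(max_iterations)
  stopifnot(
    max_iterations >= 1L,
    alpha_min > 0, alpha_min < alpha_max,
    beta_min > 0, beta_min < beta_max,
    sigma_min > 0, sigma_min < sigma_max
  )
  structure(
    list(
      max_iterations = max_iterations,
      alpha_min = alpha_min, alpha_max = alpha_max,
      beta_min = beta_min, beta_max = beta_max,
      sigma_min = sigma_min, sigma_max = sigma_max
    ),
    class = "transfer_schedule"
  )
}

#' @export
print.transfer_schedule <- function(x, ...) {
  cat("Transfer-function schedule over", x$max_iterations, "iterations\n")
  cat(sprintf("  alpha: %g -> %g (increasing)\n", x$alpha_min, x$alpha_max))
  cat(sprintf("  beta:  %g -> %g (decreasing)\n", x$beta_max, x$beta_min))
  cat(sprintf("  sigma: %g -> %g (decreasing)\n", x$sigma_max, x$sigma_min))
  invisible(x)
}
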