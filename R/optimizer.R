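#' Repair an empty feature mask
#'
#' The wrapper objective needs at least one feature, so an all-zero mask
#' is repaired by setting the bit whose continuous coordinate has the
#' largest absolute value (ties: the first such dimension).
#'
#' @param mask Integer 0/1 vector.
#' @param positions Continuous coordinates of the same length.
#' @return The mask, with exactly one bit forced on if it was empty.
#' @export
repair_mask <- function(mask, positions) {
  if (length(mask) != length(positions)) {
    stop("`mask` and `positions` must share one length")
  }
  mask <- as.integer(mask)
  if (sum(mask) >= 1L) return(mask)
  mask[which.max(abs(positions))] <- 1L
  mask
}

.eval_problem <- function(problem, mask) {
  res <- problem(mask)
  if (is.list(res)) {
    fit <- res$fitness
    err <- if (!is.null(res$error)) res$error else NA_real_
  } else {
    fit <- res
    err <- NA_real_
  }
  if (!is.numeric(fit) || length(fit) != 1L || !is.finite(fit)) {
    stop("fitness callable returned a non-finite value")
  }
  list(fitness = fit, error = err)
}

#' Run the binary grasshopper optimizer
#'
#' Executes the full search loop: continuous positions are initialized
#' uniformly in the box and thresholded at the box midpoint into initial
#' masks; each iteration updates the comfort coefficient and the
#' transfer-parameter schedules, normalizes pairwise distances into
#' \[1, 4\], moves the swarm by the social step plus target attraction,
#' and binarizes the new positions.  The `"tvg"` variant first sets bits
#' through the time-varying sine transfer and then perturbs them through
#' the time-varying V-shaped + Gaussian flip; the `"s1"`–`"s4"` baselines
#' use the set-rule and `"v1"`–`"v4"` the flip-rule on the previous
#' masks.  Empty masks are repaired, every individual is re-evaluated,
#' and the incumbent target is replaced only on strict improvement, so
#' the best-fitness trace is nonincreasing.
#'
#' Randomness is consumed from R's generator seeded once with `seed`, in
#' a fixed order (initial positions, then per iteration the binarization
#' draws, individual-major and dimension-minor; for `"tvg"` the sine
#' uniforms, then the flip uniforms, then the Gaussians), so identical
#' seeds replay bit-for-bit.
#'
#' @param problem Objective callable: takes a length-D 0/1 vector,
#'   returns either a finite numeric fitness or a list with elements
#'   `fitness` and `error` (as built by [fs_problem()]).  Smaller is
#'   better.
#' @param config A [goa_config()]; `config$dim` must match the problem.
#' @param schedule A [transfer_schedule()]; defaults to the standard
#'   ranges over `config$max_iterations`.
#' @param variant Transfer variant name, see [transfer_variants()].
#' @param seed Integer seed for the run.
#' @return An object of class `bgoa_result`: `best_mask`,
#'   `best_fitness`, `best_error` (NA for a bare-numeric problem),
#'   `subset_size`, `trace` (length `max_iterations`, nonincreasing),
#'   `seed`, `evaluations`, `variant`.
#' @examples
#' prob <- function(mask) sum(mask) / length(mask)  # smallest subset wins
#' cfg <- goa_config(dim = 6, population_size = 8, max_iterations = 10)
#' bgoa_optimize(prob, cfg, seed = 1)
#' @export
bgoa_optimize <- function(problem, config,
                          schedule = transfer_schedule(config$max_iterations),
                          variant = "tvg",
                          seed = 1L) {
  variant <- .match_variant(variant)
  stopifnot(inherits(config, "goa_config"),
            inherits(schedule, "transfer_schedule"))
  if (config$dim < 1L) stop("`dim` must be at least 1")
  n <- config$population_size
  d <- config$dim
  L <- config$max_iterations
  lb <- config$lower_bound
  ub <- config$upper_bound

  set.seed(as.integer(seed))
  positions <- matrix(stats::runif(n * d, lb, ub), nrow = n, byrow = TRUE)
  midpoint <- lb + 0.5 * (ub - lb)
  masks <- matrix(as.integer(positions > midpoint), nrow = n)
  evaluations <- 0L

  evaluate_all <- function(masks, positions) {
    fitness <- numeric(n)
    errors <- numeric(n)
    for (i in seq_len(n)) {
      masks[i, ] <- repair_mask(masks[i, ], positions[i, ])
      res <- .eval_problem(problem, masks[i, ])
      fitness[i] <- res$fitness
      errors[i] <- res$error
    }
    evaluations <<- evaluations + n
    list(masks = masks, fitness = fitness, errors = errors)
  }

  ev <- evaluate_all(masks, positions)
  masks <- ev$masks
  best_i <- which.min(ev$fitness)
  target_fitness <- ev$fitness[best_i]
  target_error <- ev$errors[best_i]
  target_mask <- masks[best_i, ]
  target_position <- positions[best_i, ]

  trace <- numeric(L)
  sfamily <- variant %in% c("s1", "s2", "s3", "s4")
  vfamily <- variant %in% c("v1", "v2", "v3", "v4")

  for (iter in seq_len(L)) {
    c_iter <- comfort_coefficient(iter, L, config$c_max, config$c_min)
    sv <- schedule_values(iter, schedule)
    st <- goa_step(positions, target_position, config, c_iter)
    positions <- st$proposed

    if (variant == "tvg") {
      u_sine <- matrix(stats::runif(n * d), nrow = n, byrow = TRUE)
      u_flip <- matrix(stats::runif(n * d), nrow = n, byrow = TRUE)
      g_flip <- matrix(stats::rnorm(n * d), nrow = n, byrow = TRUE)
      new_masks <- masks
      for (i in seq_len(n)) {
        bits <- binarize_sine(positions[i, ], sv$alpha, u_sine[i, ])
        new_masks[i, ] <- tvg_flip(bits, positions[i, ], sv$beta, sv$sigma,
                                   u_flip[i, ], g_flip[i, ])
      }
    } else {
      u <- matrix(stats::runif(n * d), nrow = n, byrow = TRUE)
      new_masks <- masks
      for (i in seq_len(n)) {
        if (sfamily) {
          p <- s_shaped(variant, positions[i, ])
          new_masks[i, ] <- binarize_static(p, "set", uniform_draws = u[i, ])
        } else if (vfamily) {
          p <- v_shaped(variant, positions[i, ])
          new_masks[i, ] <- binarize_static(p, "flip",
                                            current_bits = masks[i, ],
                                            uniform_draws = u[i, ])
        }
      }
    }

    ev <- evaluate_all(new_masks, positions)
    masks <- ev$masks
    best_i <- which.min(ev$fitness)
    if (ev$fitness[best_i] < target_fitness) {
      target_fitness <- ev$fitness[best_i]
      target_error <- ev$errors[best_i]
      target_mask <- masks[best_i, ]
      target_position <- positions[best_i, ]
    }
    trace[iter] <- target_fitness
  }

  structure(
    list(
      best_mask = as.integer(target_mask),
      best_fitness = target_fitness,
      best_error = target_error,
      subset_size = sum(target_mask),
      trace = trace,
      seed = as.integer(seed),
      evaluations = evaluations,
      variant = variant
    ),
    class = "bgoa_result"
  )
}

#' @export
print.bgoa_result <- function(x, ...) {
  cat("Binary grasshopper optimization result (", x$variant, ")\n", sep = "")
  cat(sprintf("  best fitness: %.6f", x$best_fitness))
  if (is.finite(x$best_error)) cat(sprintf("  (error %.4f)", x$best_error))
  cat("\n")
  cat(sprintf("  subset size: %d of %d; %d evaluations; seed %d\n",
              x$subset_size, length(x$best_mask), x$evaluations, x$seed))
  invisible(x)
}
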