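# Shared fixtures, all generated in code.

# Two well-separated classes where feature 1 alone classifies perfectly
# (margin >> noise); remaining columns are pure noise.
separable_dataset <- function(n = 40, n_noise = 2, seed = 1) {
  set.seed(seed)
  labels <- rep(c("a", "b"), length.out = n)
  x1 <- ifelse(labels == "a", 0, 10) + stats::rnorm(n, sd = 0.1)
  noise <- matrix(stats::rnorm(n * n_noise), n)
  fs_dataset(cbind(x1, noise), labels,
             feature_names = c("sep", paste0("noise", seq_len(n_noise))))
}

# Balanced two-class dataset whose features carry no class signal.
noise_only_dataset <- function(n = 60, d = 4, seed = 1) {
  set.seed(seed)
  fs_dataset(matrix(stats::rnorm(n * d), n), rep(c("a", "b"), length.out = n))
}

# Wrap a problem so fitness calls are counted.
counting_problem <- function(problem) {
  calls <- 0L
  fn <- function(mask) {
    calls <<- calls + 1L
    problem(mask)
  }
  list(problem = fn, calls = function() calls)
}

# Small standard config for fast optimizer tests.
tiny_config <- function(dim, pop = 8L, iters = 15L) {
  goa_config(dim = dim, population_size = pop, max_iterations = iters)
}
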