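grid <- seq(-10, 10, length.out = 2001)

test_that("S-shaped family: closed-form values, monotone, bounded", {
  expect_equal(s_shaped("s1", 0), 0.5)
  expect_equal(s_shaped("s2", 1), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(s_shaped("s2", 1), 0.8807971, tolerance = 1e-6)
  expect_equal(s_shaped("s3", 2), 1 / (1 + exp(-1)), tolerance = 1e-12)
  for (v in c("s1", "s2", "s3", "s4")) {
    y <- s_shaped(v, grid)
    expect_true(all(y > 0 & y < 1), info = v)
    expect_true(all(diff(y) > 0), info = v)
    # antisymmetry about 0.5
    expect_equal(s_shaped(v, -grid), 1 - s_shaped(v, grid), tolerance = 1e-12)
  }
  expect_error(s_shaped("s9", 0), "unknown transfer variant")
  expect_error(s_shaped("v1", 0), "not an S-shaped")
})

test_that("V-shaped family: closed-form values, even, zero at origin", {
  expect_equal(v_shaped("v2", 0), 0)
  expect_equal(v_shaped("v3", 1), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(v_shaped("v4", 1), 2 / pi * atan(pi / 2), tolerance = 1e-12)
  # V1 against an independent erf via pracma-free identity erf(x) = 2*pnorm(x*sqrt(2)) - 1,
  # sampled numerically through integrate() of the Gaussian kernel
  erf_num <- function(z) {
    2 / sqrt(pi) * stats::integrate(function(t) exp(-t^2), 0, z)$value
  }
  for (x in c(0.3, 1, 2)) {
    expect_equal(v_shaped("v1", x), abs(erf_num(sqrt(pi) / 2 * x)),
                 tolerance = 1e-8)
  }
  for (v in c("v1", "v2", "v3", "v4")) {
    y <- v_shaped(v, grid)
    # V1 saturates to 1 within double precision for |x| >~ 6
    expect_true(all(y >= 0 & y <= 1), info = v)
    expect_true(all(v_shaped(v, seq(-3, 3, by = 0.01)) < 1), info = v)
    expect_equal(v_shaped(v, -grid), y, tolerance = 1e-12, info = v)
    pos <- v_shaped(v, seq(0, 10, length.out = 500))
    expect_true(all(diff(pos) >= 0), info = v)
    expect_equal(v_shaped(v, 0), 0, info = v)
  }
})

test_that("schedules are linear with exact endpoints", {
  sch <- transfer_schedule(100)
  s0 <- schedule_values(0, sch)
  expect_identical(s0$alpha, 0.05)
  expect_identical(s0$beta, 10)
  expect_identical(s0$sigma, 10)
  sL <- schedule_values(100, sch)
  expect_equal(sL$alpha, 5)
  expect_equal(sL$beta, 0.05)
  expect_equal(sL$sigma, 0.01)
  smid <- schedule_values(50, sch)
  expect_equal(smid$alpha, (0.05 + 5) / 2, tolerance = 1e-12)
  expect_equal(smid$beta, (10 + 0.05) / 2, tolerance = 1e-12)
  expect_equal(smid$sigma, (10 + 0.01) / 2, tolerance = 1e-12)
  # monotone directions over the whole budget
  a <- sapply(0:100, function(i) schedule_values(i, sch)$alpha)
  b <- sapply(0:100, function(i) schedule_values(i, sch)$beta)
  expect_true(all(diff(a) > 0) && all(diff(b) < 0))
  expect_error(schedule_values(101, sch), "iteration")
})

test_that("sine transfer probabilities and set-rule binarization", {
  expect_equal(sine_probability(0, 1), 0)
  expect_equal(sine_probability(2 * pi / 2, 2), 1, tolerance = 1e-12)
  expect_equal(sine_probability(3 * pi / 6, 3), 0.5, tolerance = 1e-12)
  expect_true(all(sine_probability(grid, 0.37) >= 0 &
                    sine_probability(grid, 0.37) <= 1))
  expect_error(sine_probability(1, 0), "positive")

  # probability 0 never sets, probability 1 always sets
  expect_identical(binarize_sine(c(0, pi / 2), 1, c(0.99, 0.99)), c(0L, 1L))
  # direct comparison oracle under fixed draws
  expect_identical(
    binarize_sine(c(pi / 6, pi / 6), 1, c(0.3, 0.7)), c(1L, 0L)
  )
  expect_error(binarize_sine(c(1, 2), 1, 0.5), "length")
})

test_that("TVG probability: closed form, clipping, V4 reduction", {
  expect_equal(tvg_probability(0, 1, 0, 0), 0)
  expect_equal(tvg_probability(1e9, 1, 0, 0), 1, tolerance = 1e-8)
  expect_equal(tvg_probability(2, 2, 0, 0), 2 / pi * atan(pi / 2),
               tolerance = 1e-12)
  expect_equal(tvg_probability(2, 2, 0, 0), 0.639, tolerance = 1e-3)
  # sigma = 0, beta = 1 reduces pointwise to the V4 baseline
  expect_equal(tvg_probability(grid, 1, 0, rep(0, length(grid))),
               v_shaped("v4", grid), tolerance = 1e-12)
  # Gaussian term shifts then clips into [0, 1]
  expect_equal(tvg_probability(0, 1, 2, 10), 1)
  expect_equal(tvg_probability(0, 1, 2, -10), 0)
  set.seed(5)
  p <- tvg_probability(runif(500, -10, 10), 0.5, 3, rnorm(500))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(tvg_probability(1, 0, 1, 0), "beta")
})

test_that("TVG flip-rule complements exactly the hit bits", {
  bits <- c(1L, 0L, 1L, 0L)
  pos <- c(0, 0, 0, 0)
  # probability 0 everywhere -> unchanged
  expect_identical(tvg_flip(bits, pos, 1, 0, runif(4), rnorm(4)), bits)
  # probability 1 (clipped) -> all complemented; applying twice restores
  once <- tvg_flip(bits, pos, 1, 10, rep(0.5, 4), rep(10, 4))
  expect_identical(once, 1L - bits)
  twice <- tvg_flip(once, pos, 1, 10, rep(0.5, 4), rep(10, 4))
  expect_identical(twice, bits)
  expect_error(tvg_flip(bits, pos[1:3], 1, 0, runif(4), rnorm(4)), "length")
})

test_that("static binarization rules reproduce direct comparisons", {
  expect_identical(binarize_static(c(0, 0), "set", uniform_draws = c(0.1, 0.9)),
                   c(0L, 0L))
  expect_identical(
    binarize_static(c(1, 1), "flip", current_bits = c(1L, 0L),
                    uniform_draws = c(0.5, 0.5)),
    c(0L, 1L)
  )
  expect_identical(
    binarize_static(c(0.2, 0.8), "set", uniform_draws = c(0.5, 0.5)),
    c(0L, 1L)
  )
  # independent re-implementation of both rules on a recorded draw sequence
  set.seed(9)
  p <- runif(50)
  u <- runif(50)
  bits <- sample(0:1, 50, replace = TRUE)
  expect_identical(binarize_static(p, "set", uniform_draws = u),
                   as.integer(u < p))
  expect_identical(
    binarize_static(p, "flip", current_bits = bits, uniform_draws = u),
    as.integer(ifelse(u < p, 1L - bits, bits))
  )
  expect_error(binarize_static(c(0.5), "flip", uniform_draws = 0.1),
               "current_bits")
  expect_error(binarize_static(1.5, "set", uniform_draws = 0.1), "0, 1")
})

test_that("schedule construction rejects inverted or non-positive ranges", {
  expect_error(transfer_schedule(10, alpha_min = 0), "alpha_min")
  expect_error(transfer_schedule(10, beta_min = 5, beta_max = 1))
  expect_error(transfer_schedule(0))
})
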