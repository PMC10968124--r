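test_that("social force matches closed-form evaluation and sign structure", {
  # independent evaluations of 0.5*exp(-r/1.5) - exp(-r)
  expect_equal(social_force(1.0), -0.11117088165514633, tolerance = 1e-12)
  expect_equal(social_force(4.0), 0.016426086722666593, tolerance = 1e-12)
  # comfort-zone boundary: repulsion below, ~0 at 2.079, attraction above
  expect_lt(abs(social_force(2.079)), 1e-3)
  expect_lt(social_force(1.5), 0)
  expect_gt(social_force(3), 0)
  # vanishes at long range
  expect_lt(abs(social_force(50)), 1e-14)
  expect_true(all(abs(social_force(seq(0, 10, by = 0.01))) <= max(0.5, 1)))
  expect_error(social_force(-1), "non-negative")
  expect_error(social_force(NaN), "finite")
})

test_that("social force has exactly one sign change on (0, 4), near 2.079", {
  r <- seq(0.01, 4, by = 1e-3)
  s <- sign(social_force(r))
  changes <- which(diff(s) != 0)
  expect_length(changes, 1L)
  # stats::uniroot as an independent root-finding oracle
  oracle <- stats::uniroot(function(x) social_force(x), c(0.1, 4),
                           tol = 1e-10)$root
  expect_equal(oracle, 3 * log(2), tolerance = 1e-8)
  expect_equal(comfort_zone_distance(), oracle, tolerance = 1e-3)
  expect_lt(abs(comfort_zone_distance() - 2.079), 1e-3)
})

test_that("comfort coefficient follows the linear schedule", {
  expect_identical(comfort_coefficient(0, 100), 1.0)
  expect_equal(comfort_coefficient(100, 100), 1e-5)
  expect_equal(comfort_coefficient(50, 100), 0.500005, tolerance = 1e-12)
  # generic endpoints
  expect_equal(comfort_coefficient(37, 37, c_max = 0.7, c_min = 0.2), 0.2)
  # linearity: c(a) + c(b) = 2 c((a+b)/2)
  set.seed(1)
  for (i in 1:20) {
    ab <- sort(sample(0:200, 2))
    expect_equal(
      comfort_coefficient(ab[1], 200) + comfort_coefficient(ab[2], 200),
      2 * comfort_coefficient(mean(ab), 200),
      tolerance = 1e-12
    )
  }
  # strictly decreasing
  expect_true(all(diff(comfort_coefficient(0:100, 100)) < 0))
  expect_error(comfort_coefficient(101, 100), "iteration")
})

test_that("distance normalization maps off-diagonal entries onto [1, 4]", {
  m <- matrix(c(0, 2, 6,
                2, 0, 2,
                6, 2, 0), 3, 3)
  out <- normalize_distances(m)
  expect_equal(out[1, 2], 1.0)
  expect_equal(out[1, 3], 4.0)
  expect_equal(diag(out), rep(0, 3))

  # endpoints fixed, midpoint preserved by linearity
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 1
  m2[2, 3] <- m2[3, 2] <- 2.5
  m2[1, 3] <- m2[3, 1] <- 4
  out2 <- normalize_distances(m2)
  expect_equal(out2[2, 3], 2.5)

  # degenerate: all points coincide -> midpoint policy
  z <- matrix(0, 4, 4)
  outz <- normalize_distances(z)
  expect_true(all(outz[row(outz) != col(outz)] == 2.5))

  # single point: unchanged (no pairs)
  expect_identical(normalize_distances(matrix(0, 1, 1)), matrix(0, 1, 1))

  # property: outputs in [1,4] and order preserved
  set.seed(7)
  for (i in 1:10) {
    pts <- matrix(runif(12), 6)
    dm <- as.matrix(dist(pts))
    nd <- normalize_distances(dm)
    off <- upper.tri(dm)
    expect_true(all(nd[off] >= 1 - 1e-12 & nd[off] <= 4 + 1e-12))
    expect_equal(order(dm[off]), order(nd[off]))
  }
})

test_that("goa_step matches a literal term-by-term transcription", {
  positions <- matrix(c(0.1, 0.8,
                        0.5, 0.2,
                        0.9, 0.6), nrow = 3, byrow = TRUE)
  target <- c(0.4, 0.5)
  cfg <- goa_config(dim = 2, population_size = 3, max_iterations = 10)
  cc <- 0.5

  # independent brute-force oracle over the double sum
  dm <- as.matrix(dist(positions))
  off <- dm[row(dm) != col(dm)]
  dn <- 1 + 3 * (dm - min(off)) / (max(off) - min(off))
  s_fun <- function(r) 0.5 * exp(-r / 1.5) - exp(-r)
  expected <- matrix(0, 3, 2)
  for (i in 1:3) {
    for (d in 1:2) {
      acc <- 0
      for (j in 1:3) {
        if (j == i) next
        acc <- acc + cc * ((1 - 0) / 2) * s_fun(dn[i, j]) *
          (positions[j, d] - positions[i, d]) / dn[i, j]
      }
      expected[i, d] <- cc * acc
    }
  }
  st <- goa_step(positions, target, cfg, cc)
  expect_equal(st$step, expected, tolerance = 1e-12)
  expect_equal(st$proposed,
               pmin(pmax(sweep(expected, 2, target, "+"), 0), 1),
               tolerance = 1e-12)
})

test_that("goa_step limits: lone grasshopper, symmetry, swarm collapse", {
  cfg <- goa_config(dim = 3, population_size = 1, max_iterations = 5)
  st <- goa_step(matrix(0.2, 1, 3), c(0.7, 0.1, 0.9), cfg, 0.5)
  expect_equal(st$step, matrix(0, 1, 3))
  expect_equal(drop(st$proposed), c(0.7, 0.1, 0.9))

  # symmetric pair about the target: equal and opposite steps
  cfg2 <- goa_config(dim = 2, population_size = 2, max_iterations = 5)
  pos <- rbind(c(0.3, 0.3), c(0.7, 0.7))
  st2 <- goa_step(pos, c(0.5, 0.5), cfg2, 0.4)
  expect_equal(st2$step[1, ], -st2$step[2, ], tolerance = 1e-12)

  # c = 0 is the collapse limit: everyone moves to the target
  cfg3 <- goa_config(dim = 2, population_size = 4, max_iterations = 5,
                     c_min = 1e-30)
  set.seed(3)
  pos3 <- matrix(runif(8), 4)
  st3 <- goa_step(pos3, c(0.42, 0.58), cfg3, 0)
  expect_true(all(abs(sweep(st3$proposed, 2, c(0.42, 0.58), "-")) < 1e-12))
})

test_that("goa_step is equivariant under permutation of grasshoppers", {
  set.seed(11)
  pos <- matrix(runif(10), 5, 2)
  target <- runif(2)
  cfg <- goa_config(dim = 2, population_size = 5, max_iterations = 5)
  st <- goa_step(pos, target, cfg, 0.3)
  perm <- c(3, 1, 5, 2, 4)
  st_p <- goa_step(pos[perm, ], target, cfg, 0.3)
  expect_equal(st_p$step, st$step[perm, ], tolerance = 1e-12)
})

test_that("configuration invariants are enforced", {
  expect_error(goa_config(dim = 0), "dim")
  expect_error(goa_config(dim = 3, c_min = 0), "c_min")
  expect_error(goa_config(dim = 3, lower_bound = 1, upper_bound = 0))
  expect_error(goa_config(dim = 3, weight_alpha = 0.5, weight_beta = 0.01),
               "must equal 1")
  cfg <- goa_config(dim = 3)
  expect_equal(cfg$weight_alpha + cfg$weight_beta, 1)
})
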