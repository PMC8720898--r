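test_that("NB pmf matches hand-evaluated values and normalizes", {
  # (theta/(theta+mu))^theta at y = 0, mu = theta = 1 -> 1/2
  expect_equal(nb_pmf(0, mu = 1, theta = 1), 0.5)
  # normalization over a tail-truncated support, across a parameter grid
  for (mu in c(0.5, 2, 10)) {
    for (theta in c(0.5, 1, 5)) {
      ymax <- qnbinom(1e-13, size = theta, mu = mu, lower.tail = FALSE) + 10
      expect_equal(sum(nb_pmf(0:ymax, mu, theta)), 1, tolerance = 1e-10)
    }
  }
})

test_that("NB pmf approaches the Poisson limit for large theta", {
  y <- 0:25
  expect_lt(max(abs(nb_pmf(y, mu = 3, theta = 1e6) - dpois(y, 3))), 1e-4)
})

test_that("NB pmf rejects invalid arguments", {
  expect_error(nb_pmf(-1, 1, 1), "nonnegative")
  expect_error(nb_pmf(1.5, 1, 1), "nonnegative integer")
  expect_error(nb_pmf(1, 1, theta = 0), "theta")
})

test_that("ZINB pmf has the correct piecewise form", {
  # degenerate all-zero mixture
  expect_equal(zinb_pmf(0, pi = 1, mu = 5, theta = 2), 1)
  # hand evaluation: 0.3 + 0.7 * (1/3)
  expect_equal(zinb_pmf(0, pi = 0.3, mu = 2, theta = 1), 0.3 + 0.7 / 3)
  # pi = 0 reduces to NB everywhere
  y <- 0:40
  expect_equal(zinb_pmf(y, pi = 0, mu = 4, theta = 2), nb_pmf(y, 4, 2))
  # normalization across a grid including zero inflation
  for (pi in c(0, 0.3, 0.7)) {
    for (mu in c(0.5, 10)) {
      ymax <- qnbinom(1e-13, size = 2, mu = mu, lower.tail = FALSE) + 10
      expect_equal(sum(zinb_pmf(0:ymax, pi, mu, 2)), 1, tolerance = 1e-10)
    }
  }
})

test_that("log-space ZINB evaluation matches direct evaluation", {
  y <- 0:30
  for (pi in c(0, 0.25, 0.9)) {
    direct <- pi * (y == 0) + (1 - pi) * dnbinom(y, size = 2, mu = 3)
    expect_equal(zinb_pmf(y, pi, 3, 2, log = TRUE), log(direct),
                 tolerance = 1e-12)
  }
})

test_that("zinb_params validates and derives phi and mu_prime", {
  p <- zinb_params(pi = 0.3, mu = 2, theta = 4, p = 0.5)
  expect_equal(p$phi * p$theta, 1)
  expect_equal(p$mu_prime, 1)
  expect_lte(p$mu_prime, p$mu)
  q <- zinb_params(pi = 0.3, mu = 2, phi = 0.25)
  expect_equal(q$theta, 4)
  expect_error(zinb_params(pi = 1.2, mu = 1, theta = 1), "pi")
  expect_error(zinb_params(pi = 0.5, mu = -1, theta = 1), "mu")
  expect_error(zinb_params(pi = 0.5, mu = 1, theta = 2, phi = 2),
               "inconsistent")
})

test_that("ZINB sampler matches its pmf and moments", {
  x <- zinb_sample(1e5, pi = 0.4, mu = 3, theta = 2, seed = 1)
  p0 <- zinb_pmf(0, pi = 0.4, mu = 3, theta = 2)
  se0 <- sqrt(p0 * (1 - p0) / 1e5)
  expect_lt(abs(mean(x == 0) - p0), 3 * se0)
  expect_lt(abs(mean(x) - (1 - 0.4) * 3), 3 * mc_se(x))
  # degenerate pi = 1
  expect_true(all(zinb_sample(100, pi = 1, mu = 5, theta = 1, seed = 2) == 0))
  # seed reproducibility
  expect_identical(zinb_sample(50, 0.2, 4, 1, seed = 9),
                   zinb_sample(50, 0.2, 4, 1, seed = 9))
})

test_that("observed moments follow the thinned-ZINB formulas", {
  m <- observed_moments(pi = 0.2, mu = 5, theta = 2, p = 0.5)
  expect_equal(m$mean, 2)
  expect_equal(m$variance, 5.5)
  # pi = 0, p = 1 reduces to the NB variance mu + mu^2 phi
  m2 <- observed_moments(pi = 0, mu = 4, theta = 2, p = 1)
  expect_equal(m2$variance, 4 + 16 / 2)
  # V = E (1 + mu p (pi + phi)) identity, and overdispersion V >= E
  for (pi in c(0, 0.3)) {
    for (p in c(0.2, 1)) {
      mm <- observed_moments(pi, mu = 6, theta = 3, p = p)
      expect_equal(mm$variance, mm$mean * (1 + 6 * p * (pi + 1 / 3)),
                   tolerance = 1e-12)
      expect_gte(mm$variance, mm$mean)
    }
  }
  # mean is monotone in p
  expect_gte(observed_moments(0.2, 5, 2, p = 1)$mean,
             observed_moments(0.2, 5, 2, p = 0.6)$mean)
})
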