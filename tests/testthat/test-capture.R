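test_that("binomial thinning obeys its limits and stays below the truth", {
  set.seed(5)
  Z <- matrix(rnbinom(200, size = 2, mu = 8), 20, 10)
  expect_identical(thin_counts(Z, p = 1, seed = 1), Z)
  expect_true(all(thin_counts(Z, p = 0, seed = 1) == 0))
  Y <- thin_counts(Z, p = rep(0.4, 10), seed = 3)
  expect_true(all(Y <= Z))
  expect_identical(Y, thin_counts(Z, p = rep(0.4, 10), seed = 3))
  expect_error(thin_counts(Z, p = c(0.5, 0.5)), "per cell")
})

test_that("thinned sample mean matches the observed-moment formula", {
  n <- 1e5
  z <- zinb_sample(n, pi = 0.3, mu = 8, theta = 2, seed = 11)
  y <- thin_counts(matrix(z, 1), p = rep(0.25, n), seed = 12)
  expect_lt(abs(mean(y) - (1 - 0.3) * 8 * 0.25), 4 * mc_se(as.numeric(y)))
})

test_that("brute-force thinning marginal equals the closed-form ZINB", {
  # worked zero-probability case: 0.3 + 0.7 * (1 / (1 + 1)) with mu' = 1
  expect_equal(thinned_pmf_oracle(0, pi = 0.3, mu = 2, theta = 1, p = 0.5),
               zinb_pmf(0, 0.3, 1, 1), tolerance = 1e-12)
  expect_equal(thinned_pmf_oracle(0, 0.3, 2, 1, 0.5), 0.65,
               tolerance = 1e-10)
  # identity thinning
  for (y in c(0, 3, 17)) {
    expect_equal(thinned_pmf_oracle(y, 0.2, 6, 2, p = 1),
                 zinb_pmf(y, 0.2, 6, 2), tolerance = 1e-12)
  }
  # a (small) parameter grid; the full grid runs in the acceptance suite
  for (pi in c(0, 0.5)) {
    for (p in c(0.1, 0.9)) {
      err <- max(vapply(0:30, function(y) {
        abs(thinned_pmf_oracle(y, pi, 5, 1.5, p) -
              zinb_pmf(y, pi, 5 * p, 1.5))
      }, 0))
      expect_lt(err, 1e-10)
    }
  }
  expect_error(thinned_pmf_oracle(0, 0.3, 50, 2, 0.5, z_max = 10),
               "tail mass")
})

test_that("thinned draws are distributed as ZINB with mean mu * p", {
  n <- 5e4
  z <- zinb_sample(n, pi = 0.3, mu = 8, theta = 2, seed = 21)
  y <- as.numeric(thin_counts(matrix(z, 1), p = rep(0.4, n), seed = 22))
  # one-sample goodness of fit against the closed-form thinned pmf
  kmax <- max(y)
  probs <- zinb_pmf(0:kmax, 0.3, 8 * 0.4, 2)
  bins <- c(probs[1:10], 1 - sum(probs[1:10]))   # counts 0..9 and 10+
  obs <- c(tabulate(factor(pmin(y, 10), levels = 0:10)))
  gof <- suppressWarnings(chisq.test(obs, p = bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero probability decreases with capture and mu' stays below mu", {
  p_grid <- c(0.1, 0.4, 0.7, 1)
  zeros <- vapply(p_grid, function(p) zinb_pmf(0, 0.3, 5 * p, 2), 0)
  expect_true(all(diff(zeros) < 0))
  expect_true(all(5 * p_grid[-4] < 5))
})

test_that("spike-in regression recovers per-cell slopes", {
  # exact proportionality
  C <- c(1, 2, 4, 8, 16)
  sp <- spikein_set(C, matrix(0.5 * C, nrow = 1, byrow = TRUE))
  est <- estimate_capture_spikeins(sp)
  expect_equal(est$p_hat, 0.5, tolerance = 1e-12)
  # identity line
  est2 <- estimate_capture_spikeins(spikein_set(c(1, 2, 4),
                                                matrix(c(1, 2, 4), 1)))
  expect_equal(est2$p_hat, 1, tolerance = 1e-12)
  expect_equal(est2$intercepts, 0, tolerance = 1e-12)
  # three-point table, against the lm() oracle
  est3 <- estimate_capture_spikeins(spikein_set(c(1, 2, 3),
                                                matrix(c(1, 1, 2), 1)))
  ref <- coef(lm(c(1, 1, 2) ~ c(1, 2, 3)))
  expect_equal(est3$p_hat, unname(ref[2]), tolerance = 1e-12)
  expect_equal(est3$p_raw, unname(ref[2]), tolerance = 1e-12)
  expect_equal(est3$intercepts, unname(ref[1]), tolerance = 1e-12)
  # multi-cell fixture against lm per cell
  set.seed(31)
  Cm <- 2^(0:9)
  R <- t(vapply(c(0.2, 0.6), function(p) rpois(10, p * Cm), numeric(10)))
  estm <- estimate_capture_spikeins(spikein_set(Cm, R))
  for (i in 1:2) {
    expect_equal(estm$p_hat[i], unname(coef(lm(R[i, ] ~ Cm))[2]),
                 tolerance = 1e-10)
  }
})

test_that("spike-in regression handles degenerate inputs", {
  expect_error(estimate_capture_spikeins(
    spikein_set(c(2, 2, 2), matrix(c(1, 2, 3), 1))), "constant")
  # slope > 1 is clamped, raw value preserved
  est <- estimate_capture_spikeins(spikein_set(c(1, 2, 4),
                                               matrix(c(2, 4, 8), 1)))
  expect_equal(est$p_hat, 1)
  expect_equal(est$p_raw, 2, tolerance = 1e-12)
})

test_that("library-size capture estimator interpolates log10 sizes", {
  est <- estimate_capture_librarysize(c(10, 100, 1000), 0.1, 0.9)
  expect_equal(est$p_hat, c(0.1, 0.5, 0.9), tolerance = 1e-12)
  # extremes map to rho1 / rho2 for arbitrary sizes
  set.seed(7)
  S <- round(runif(50, 500, 50000))
  est2 <- estimate_capture_librarysize(S, 0.2, 0.8)
  expect_equal(est2$p_hat[which.min(S)], 0.2)
  expect_equal(est2$p_hat[which.max(S)], 0.8)
  expect_true(all(est2$p_hat >= 0.2 & est2$p_hat <= 0.8))
  expect_warning(out <- estimate_capture_librarysize(rep(100, 4)), "equal")
  expect_equal(out$p_hat, rep(0.5, 4))
  expect_error(estimate_capture_librarysize(c(0, 10)), "positive")
  expect_error(estimate_capture_librarysize(c(10, 20), 0.9, 0.1), "rho")
})

test_that("capture summaries satisfy their moment inequalities", {
  est <- capture_estimate(c(0.1, 0.5, 0.9), method = "fixed")
  expect_gte(est$p2_bar, est$p_bar^2 - 1e-12)
  expect_gte(est$var_p, 0)
  expect_equal(est$var_p, est$p2_bar - est$p_bar^2)
})
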