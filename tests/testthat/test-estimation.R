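test_that("E-step weights follow the posterior formula", {
  # positive counts always belong to the count component
  expect_equal(e_step_weights(5, pi = 0.4, mu_prime = 2, theta = 1), 1)
  # hand case: f_NB(0) = 1/(1 + mu') = 0.25 at theta = 1, mu' = 3
  expect_equal(e_step_weights(0, pi = 0.5, mu_prime = 3, theta = 1), 0.2,
               tolerance = 1e-12)
  # no zero component
  expect_equal(e_step_weights(c(0, 2, 0), pi = 0, mu_prime = 2, theta = 1),
               rep(1, 3))
  # pi = 1 with a positive count: degenerate, weight 1 with warning
  expect_warning(w <- e_step_weights(c(0, 3), pi = 1, mu_prime = 2,
                                     theta = 1), "pi = 1")
  expect_equal(w, c(0, 1))
})

test_that("EM recovers intercept-only ZINB parameters", {
  y <- zinb_sample(1000, pi = 0.3, mu = 5, theta = 2, seed = 41)
  fit <- em_fit_gene(y, intercept_design(1000))
  expect_lt(abs(mean(fit$fitted_pi) - 0.3), 0.05)
  expect_lt(abs(mean(fit$fitted_mu) - 5) / 5, 0.1)
  expect_lt(abs(fit$theta - 2) / 2, 0.25)
  expect_true(fit$converged)
  # EM ascent: incomplete-data log-likelihood is non-decreasing
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  # weights are exactly 1 off zero
  expect_true(all(fit$weights[y > 0] == 1))
})

test_that("EM drives pi to zero when the data have no zeros", {
  set.seed(42)
  y <- rnbinom(800, size = 5, mu = 30) + 1L   # strictly positive
  fit <- em_fit_gene(y, intercept_design(800))
  expect_lt(mean(fit$fitted_pi), 1e-3)
  # mean matches a plain NB fit when the zero component is empty
  ref <- MASS::glm.nb(y ~ 1)
  expect_equal(mean(fit$fitted_mu), unname(exp(coef(ref)[1])),
               tolerance = 0.01)
})

test_that("EM input contracts are enforced", {
  d <- intercept_design(10)
  expect_error(em_fit_gene(rep(0L, 10), d), "non-zero")
  expect_error(em_fit_gene(c(-1L, rep(1L, 9)), d), "nonnegative")
  expect_error(em_fit_gene(rep(1L, 5), d), "length")
})

test_that("direct simplex fallback agrees with EM at the optimum", {
  y <- zinb_sample(400, pi = 0.25, mu = 6, theta = 2, seed = 43)
  d <- intercept_design(400)
  em <- em_fit_gene(y, d)
  nm_cold <- direct_mle_fallback(y, d)
  expect_lt(abs(nm_cold$loglik - em$loglik), 1e-3)
  expect_identical(nm_cold$method, "direct")
  # warm start from the EM fit takes fewer simplex evaluations
  nm_warm <- direct_mle_fallback(y, d, init = em)
  expect_lte(nm_warm$n_iter, nm_cold$n_iter)
  # degenerate input: a single non-zero count still yields finite estimates
  y0 <- c(rep(0L, 49), 3L)
  f0 <- direct_mle_fallback(y0, intercept_design(50))
  expect_true(all(is.finite(f0$coef_mu)))
  expect_true(is.finite(f0$loglik))
})

test_that("capture offsets recover the true mean from thinned counts", {
  set.seed(44)
  n <- 600
  Z <- matrix(zinb_sample(5 * n, pi = 0.3, mu = 10, theta = 2), 5)
  Y <- thin_counts(Z, rep(0.25, n), seed = 45)
  d <- intercept_design(n)
  with_p <- fit_all_genes(Y, d, capture = fixed_capture(0.25, n))
  without <- fit_all_genes(Y, d)
  expect_lt(abs(mean(with_p$summary$mu_hat) - 10) / 10, 0.15)
  expect_lt(abs(mean(without$summary$mu_hat) - 2.5) / 2.5, 0.15)
  # p = 1 offset is a no-op
  d1 <- intercept_design(n)
  a <- fit_all_genes(Y[1:2, ], d1, capture = fixed_capture(1, n))
  b <- fit_all_genes(Y[1:2, ], d1)
  expect_equal(a$summary$mu_hat, b$summary$mu_hat, tolerance = 1e-8)
})

test_that("zero-inflation estimates are invariant to the capture rate", {
  # Corollary-2 behavior: pi is unaffected by thinning
  set.seed(46)
  n <- 500
  n_genes <- 30
  pis <- runif(n_genes, 0.1, 0.5)
  Z <- t(vapply(seq_len(n_genes), function(j)
    zinb_sample(n, pis[j], mu = 20, theta = 2), numeric(n)))
  d <- intercept_design(n)
  pi_at <- function(p) {
    Y <- thin_counts(Z, rep(p, n), seed = 47)
    fit_all_genes(Y, d, capture = fixed_capture(p, n))$summary$pi_hat
  }
  expect_lt(median(abs(pi_at(0.8) - pi_at(0.3))), 0.05)
})

test_that("a two-group log fold change is estimated without bias", {
  set.seed(48)
  n_rep <- 40
  gamma1 <- log(2)
  d <- two_group_design(150)
  est <- vapply(seq_len(n_rep), function(r) {
    y <- c(zinb_sample(150, 0.2, 5, 2), zinb_sample(150, 0.2, 5 * exp(gamma1), 2))
    unname(em_fit_gene(y, d)$coef_mu[2])
  }, 0)
  expect_lt(abs(mean(est) - gamma1), 3 * mc_se(est))
})

test_that("fitting a simulator fixture converges for nearly all genes", {
  sim <- simulate_dataset(simulation_config(n_genes = 50, n_cells = 300,
                                            seed = 49))
  d <- design_spec(sim$cell_meta$group)
  fits <- fit_all_genes(sim$observed, d,
                        capture = fixed_capture(sim$cell_meta$p))
  expect_true(all(fits$summary$ok))
  expect_gte(mean(fits$summary$converged), 0.95)
})

test_that("design matrices are validated and de-aliased", {
  d <- design_spec(rep(c("a", "b"), each = 4),
                   clusters = rep(c("c1", "c2"), 4))
  expect_equal(ncol(d$M), 3)
  expect_equal(d$group_cols, 2L)
  # cluster perfectly confounded with group: aliased column dropped
  expect_warning(
    d2 <- design_spec(rep(c("a", "b"), each = 4),
                      clusters = rep(c("k1", "k2"), each = 4)),
    "aliased")
  expect_equal(ncol(d2$M), 2)
  expect_error(design_spec(rep("a", 4), clusters = rep("c", 3)), "length")
})
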