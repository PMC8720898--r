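#' ZINB parameter set
#'
#' Bundles the parameters of a zero-inflated negative binomial (ZINB)
#' observation model for UMI counts: zero-inflation probability `pi`, mean of
#' the count (NB) component `mu`, size parameter `theta` (dispersion
#' `phi = 1/theta`), and the capture-adjusted mean `mu_prime = mu * p`, where
#' `p` is the per-cell molecular capture rate. Under binomial capture of a
#' ZINB-distributed true count, the observed count is again ZINB with mean
#' `mu_prime` and unchanged `pi` and `theta`.
#'
#' @param pi Zero-inflation probability in `[0, 1]`.
#' @param mu Mean of the NB count component, `>= 0`.
#' @param theta NB size parameter, `> 0`. Exactly one of `theta` or `phi`
#'   must be supplied.
#' @param phi Dispersion `1/theta`, `> 0`.
#' @param p Capture rate in `[0, 1]` used to derive `mu_prime`; default 1
#'   (perfect capture, `mu_prime == mu`).
#' @return An object of class `"zinb_params"`: a list with elements `pi`,
#'   `mu`, `theta`, `phi`, `p`, `mu_prime`.
#' @examples
#' zinb_params(pi = 0.3, mu = 2, theta = 1, p = 0.5)
#' @export
zinb_params <- function(pi, mu, theta = NULL, phi = NULL, p = 1) {
  if (is.null(theta) && is.null(phi)) {
    stop("supply one of `theta` or `phi`")
  }
  if (!is.null(theta) && !is.null(phi) && abs(theta * phi - 1) > 1e-8) {
    stop("`theta` and `phi` are inconsistent: need phi = 1/theta")
  }
  if (is.null(theta)) theta <- 1 / phi
  .check_prob(pi, "pi")
  .check_prob(p, "p")
  if (any(mu < 0)) stop("`mu` must be >= 0")
  if (any(theta <= 0)) stop("`theta` must be > 0")
  structure(
    list(pi = pi, mu = mu, theta = theta, phi = 1 / theta,
         p = p, mu_prime = mu * p),
    class = "zinb_params"
  )
}

#' @export
print.zinb_params <- function(x, ...) {
  cat("ZINB parameters: pi =", x$pi, " mu =", x$mu, " theta =", x$theta,
      " (phi =", format(x$phi, digits = 4), ")\n")
  if (any(x$p != 1)) {
    cat("  capture p =", x$p, " -> mu' =", x$mu_prime, "\n")
  }
  invisible(x)
}

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must lie in [0, 1]")
  }
}

.check_counts <- function(y) {
  if (any(y < 0) || any(y != floor(y))) {
    stop("`y` must contain nonnegative integers")
  }
}

#' Negative binomial probability mass function
#'
#' NB pmf in the (mu, theta) parameterization used throughout:
#' `P(Y = y) = G(y + theta) / (G(y + 1) G(theta)) *
#'   (theta / (theta + mu))^theta * (mu / (theta + mu))^y`.
#' Evaluated in log space (via [stats::dnbinom()]) for stability; the
#' distribution tends to Poisson(mu) as `theta -> Inf`.
#'
#' @param y Vector of nonnegative integers.
#' @param mu NB mean, `>= 0`.
#' @param theta NB size, `> 0`.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) of `y`.
#' @examples
#' nb_pmf(0, mu = 1, theta = 1) # 0.5
#' @export
nb_pmf <- function(y, mu, theta, log = FALSE) {
  .check_counts(y)
  if (any(theta <= 0)) stop("`theta` must be > 0")
  if (any(mu < 0)) stop("`mu` must be >= 0")
  dnbinom(y, size = theta, mu = mu, log = log)
}

#' Zero-inflated negative binomial probability mass function
#'
#' `P(Y = 0) = pi + (1 - pi) (theta/(theta + mu))^theta` and
#' `P(Y = y) = (1 - pi) f_NB(y; mu, theta)` for `y > 0`. With `pi = 0` this
#' reduces to the NB pmf. When evaluating the observed-count model under
#' capture rate `p`, pass `mu = mu_true * p` (or use a [zinb_params()] object
#' and its `mu_prime`).
#'
#' @param y Vector of nonnegative integers.
#' @param pi Zero-inflation probability in `[0, 1]`. Alternatively a
#'   `"zinb_params"` object, in which case `mu`/`theta` are taken from it
#'   (using `mu_prime`, i.e. the observed-count model).
#' @param mu,theta NB component parameters (ignored when `pi` is a
#'   `"zinb_params"` object).
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) of `y`.
#' @examples
#' zinb_pmf(0, pi = 0.3, mu = 2, theta = 1) # 0.3 + 0.7/3
#' @export
zinb_pmf <- function(y, pi, mu = NULL, theta = NULL, log = FALSE) {
  if (inherits(pi, "zinb_params")) {
    pp <- pi
    pi <- pp$pi; mu <- pp$mu_prime; theta <- pp$theta
  }
  .check_counts(y)
  .check_prob(pi, "pi")
  lnb <- nb_pmf(y, mu, theta, log = TRUE)
  lp <- ifelse(y == 0,
               .log_mix_zero(pi, lnb),
               log1p(-pi) + lnb)
  if (log) lp else exp(lp)
}

# log(pi + (1 - pi) * exp(lnb0)), stable for pi in {0, 1} and tiny exp(lnb0)
.log_mix_zero <- function(pi, lnb0) {
  n <- max(length(pi), length(lnb0))
  pi <- rep_len(pi, n)
  lnb0 <- rep_len(lnb0, n)
  a <- rep(-Inf, length(pi))
  pos <- pi > 0
  a[pos] <- log(pi[pos])
  b <- rep(-Inf, length(pi))
  lt1 <- pi < 1
  b[lt1] <- log1p(-pi[lt1]) + lnb0[lt1]
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

#' Sample from a ZINB distribution
#'
#' With probability `pi` emits 0, otherwise draws from NB(`mu`, `theta`).
#'
#' @param n Number of draws, `>= 1`.
#' @param pi,mu,theta ZINB parameters; `pi` may be a `"zinb_params"` object
#'   (its `mu_prime` is used).
#' @param seed Optional integer seed set before drawing, for reproducibility.
#' @return Integer vector of length `n`.
#' @examples
#' zinb_sample(5, pi = 0.4, mu = 3, theta = 2, seed = 1)
#' @export
zinb_sample <- function(n, pi, mu = NULL, theta = NULL, seed = NULL) {
  if (inherits(pi, "zinb_params")) {
    pp <- pi
    pi <- pp$pi; mu <- pp$mu_prime; theta <- pp$theta
  }
  if (n < 1) stop("`n` must be >= 1")
  .check_prob(pi, "pi")
  if (any(theta <= 0)) stop("`theta` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  drop0 <- runif(n) < pi
  x <- rnbinom(n, size = theta, mu = mu)
  x[drop0] <- 0L
  x
}

#' Mean and variance of the observed (capture-thinned) count
#'
#' For a true count following ZINB(`pi`, `mu`, `theta`) thinned by binomial
#' capture at rate `p`, the observed count has
#' `E(Y) = (1 - pi) mu p` and
#' `V(Y) = (1 - pi) mu p (1 + pi mu p + mu p phi)`, `phi = 1/theta`,
#' equivalently `V = E * (1 + mu p (pi + phi))`.
#'
#' @param pi,mu,theta ZINB parameters of the true count; `pi` may be a
#'   `"zinb_params"` object (its `p` is then the default capture rate).
#' @param p Capture rate in `[0, 1]`.
#' @return List with elements `mean` and `variance`.
#' @examples
#' observed_moments(pi = 0.2, mu = 5, theta = 2, p = 0.5) # mean 2, var 5.5
#' @export
observed_moments <- function(pi, mu = NULL, theta = NULL, p = NULL) {
  if (inherits(pi, "zinb_params")) {
    pp <- pi
    if (is.null(p)) p <- pp$p
    pi <- pp$pi; mu <- pp$mu; theta <- pp$theta
  }
  if (is.null(p)) p <- 1
  .check_prob(pi, "pi")
  .check_prob(p, "p")
  if (any(mu < 0)) stop("`mu` must be >= 0")
  if (any(theta <= 0)) stop("`theta` must be > 0")
  phi <- 1 / theta
  m <- (1 - pi) * mu * p
  v <- m * (1 + pi * mu * p + mu * p * phi)
  list(mean = m, variance = v)
}
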