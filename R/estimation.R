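#' Design specification for gene-wise ZINB GLMs
#'
#' Builds the cells x coefficients model matrix shared by the log-mean and
#' logit-zero-inflation submodels: an intercept plus group contrasts (`X`),
#' optional cell-cluster contrasts (`R`, first cluster as reference) and
#' optional cell-level covariates (`C`, e.g. cell cycle/phase), together with
#' per-cell offsets for the two linear predictors. Aliased (collinear)
#' columns are dropped with a warning.
#'
#' @param groups Factor (or coercible) of cell group/type labels; the first
#'   level is the reference.
#' @param clusters Optional factor of cell-cluster labels.
#' @param covariates Optional numeric matrix / data.frame of cell-level
#'   covariates (one row per cell).
#' @param offset_mu Per-cell offset for the log-mean model (default 0). The
#'   capture adjustment `log(p_hat)` is added by [fit_all_genes()] when a
#'   capture estimate is supplied.
#' @param offset_pi Per-cell offset for the logit-zero-inflation model
#'   (default 0).
#' @return Object of class `"design_spec"` with the combined model matrix
#'   `M`, indices of the group-contrast columns `group_cols`, offsets, and
#'   bookkeeping fields.
#' @export
design_spec <- function(groups, clusters = NULL, covariates = NULL,
                        offset_mu = NULL, offset_pi = NULL) {
  groups <- as.factor(groups)
  I <- length(groups)
  if (nlevels(groups) > 1) {
    X <- model.matrix(~groups)
    colnames(X) <- c("(Intercept)",
                     paste0("group_", levels(groups)[-1]))
  } else {
    X <- matrix(1, I, 1, dimnames = list(NULL, "(Intercept)"))
  }
  M <- X
  if (!is.null(clusters)) {
    clusters <- as.factor(clusters)
    if (length(clusters) != I) stop("`clusters` length must match `groups`")
    if (nlevels(clusters) > 1) {
      R <- model.matrix(~clusters)[, -1, drop = FALSE]
      colnames(R) <- paste0("cluster_", levels(clusters)[-1])
      M <- cbind(M, R)
    }
  }
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    if (nrow(C) != I) stop("`covariates` must have one row per cell")
    if (is.null(colnames(C))) colnames(C) <- paste0("cov_", seq_len(ncol(C)))
    M <- cbind(M, C)
  }
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    keep <- sort(qrM$pivot[seq_len(qrM$rank)])
    dropped <- colnames(M)[setdiff(seq_len(ncol(M)), keep)]
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
    M <- M[, keep, drop = FALSE]
  }
  group_cols <- which(colnames(M) %in% colnames(X)[-1])
  if (is.null(offset_mu)) offset_mu <- rep(0, I)
  if (is.null(offset_pi)) offset_pi <- rep(0, I)
  if (length(offset_mu) == 1) offset_mu <- rep(offset_mu, I)
  if (length(offset_pi) == 1) offset_pi <- rep(offset_pi, I)
  stopifnot(length(offset_mu) == I, length(offset_pi) == I)
  structure(
    list(M = M, group_cols = group_cols, groups = groups,
         n_groups = nlevels(groups), clusters = clusters,
         offset_mu = offset_mu, offset_pi = offset_pi),
    class = "design_spec"
  )
}

#' EM control settings
#'
#' @param tol Convergence tolerance on the change of the incomplete-data
#'   log-likelihood (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 100).
#' @param theta_range Admissible range for the NB size parameter during the
#'   profile update (default `c(0.01, 1000)`).
#' @param stall_tol EM iterations gaining less than this in log-likelihood
#'   (after the first 10) are treated as stalled in the slow linear-
#'   convergence tail; the fit is then finished by the gradient polish
#'   (default `1e-3`).
#' @param polish Finish every fit with a quasi-Newton (BFGS, analytic
#'   gradient) maximization of the incomplete-data log-likelihood from the
#'   EM endpoint, so the returned optimum is exact regardless of where the
#'   EM stopped (default `TRUE`).
#' @param fallback Invoke the derivative-free Nelder-Mead maximizer when EM
#'   (plus polish) fails to converge or the log-likelihood decreases
#'   (default `TRUE`).
#' @return List of class `"em_control"`.
#' @export
em_control <- function(tol = 1e-6, max_iter = 100L,
                       theta_range = c(0.01, 1000), stall_tol = 1e-3,
                       polish = TRUE, fallback = TRUE) {
  stopifnot(tol > 0, max_iter >= 1, theta_range[1] > 0,
            theta_range[2] > theta_range[1], stall_tol >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 theta_range = theta_range, stall_tol = stall_tol,
                 polish = polish, fallback = fallback),
            class = "em_control")
}

#' E-step posterior weights of the count component
#'
#' Posterior probability that each observation arises from the NB count
#' component rather than the structural-zero component:
#' `w_i = (1 - pi_i) f_NB(y_i) / (pi_i d0(y_i) + (1 - pi_i) f_NB(y_i))`.
#' For `y_i > 0` the Dirac mass vanishes and `w_i = 1` exactly.
#'
#' @param y Gene count vector.
#' @param pi Per-cell zero-inflation probabilities.
#' @param mu_prime Per-cell NB means on the observed (capture-adjusted) scale.
#' @param theta NB size parameter (scalar).
#' @return Vector of weights in `[0, 1]`.
#' @export
e_step_weights <- function(y, pi, mu_prime, theta) {
  .check_counts(y)
  n <- length(y)
  if (length(pi) == 1) pi <- rep(pi, n)
  if (length(mu_prime) == 1) mu_prime <- rep(mu_prime, n)
  w <- rep(1, n)
  z <- y == 0
  if (any(z)) {
    f0 <- dnbinom(0, size = theta, mu = mu_prime[z])
    num <- (1 - pi[z]) * f0
    den <- pi[z] + num
    wz <- ifelse(den > 0, num / den, 0)
    w[z] <- wz
  }
  bad <- !z & pi == 1
  if (any(bad)) {
    warning("pi = 1 with positive count: weight set to 1")
    w[bad] <- 1
  }
  w
}

# incomplete-data ZINB log-likelihood with per-cell pi and mu'
zinb_loglik <- function(y, pi, mu_prime, theta) {
  lnb <- dnbinom(y, size = theta, mu = mu_prime, log = TRUE)
  z <- y == 0
  ll <- numeric(length(y))
  ll[!z] <- log1p(-pi[!z]) + lnb[!z]
  if (any(z)) ll[z] <- .log_mix_zero(pi[z], lnb[z])
  sum(ll)
}

# starting coefficients per the standard ZINB recipe
.zinb_init <- function(y, Mmu, Mpi, off_mu, off_pi, theta_range) {
  m <- mean(y); v <- var(y)
  if (!is.finite(v) || v <= m) v <- m + m^2 / 2 + 1e-8
  theta0 <- min(max(m^2 / max(v - m, 1e-8), theta_range[1]), theta_range[2])
  mu0 <- if (any(y > 0)) mean(y[y > 0]) else m + 0.1
  zf <- mean(y == 0)
  pi0 <- min(max(zf - dnbinom(0, size = theta0, mu = mu0), 0.01), 0.95)
  coef_mu <- c(log(mu0) - mean(off_mu), rep(0, ncol(Mmu) - 1))
  coef_pi <- c(qlogis(pi0) - mean(off_pi), rep(0, ncol(Mpi) - 1))
  list(coef_mu = coef_mu, coef_pi = coef_pi, theta = theta0)
}

# profile update of theta on the weighted NB log-likelihood: bracketed
# search on log(theta) around the current value, expanding while the
# optimum sits at the bracket edge (the final theta is refined later by the
# gradient polish, so a coarse tolerance suffices here)
.update_theta <- function(y, mu_prime, w, theta_range, theta0 = 1) {
  obj <- function(lt) {
    -sum(w * dnbinom(y, size = exp(lt), mu = mu_prime, log = TRUE))
  }
  lo_all <- log(theta_range[1]); hi_all <- log(theta_range[2])
  lt0 <- min(max(log(theta0), lo_all), hi_all)
  half <- 2
  for (k in 1:4) {
    lo <- max(lt0 - half, lo_all); hi <- min(lt0 + half, hi_all)
    opt <- optimize(obj, interval = c(lo, hi), tol = 1e-3)
    at_edge <- (opt$minimum - lo < 0.05 && lo > lo_all) ||
      (hi - opt$minimum < 0.05 && hi < hi_all)
    if (!at_edge) break
    lt0 <- opt$minimum
    half <- half * 2
  }
  exp(opt$minimum)
}

# EM workhorse on explicit model matrices (Mmu may differ from Mpi for the
# constrained fits used by the likelihood-ratio tests)
.zinb_em <- function(y, Mmu, Mpi, off_mu, off_pi, control = em_control(),
                     init = NULL) {
  n <- length(y)
  if (is.null(init)) {
    init <- .zinb_init(y, Mmu, Mpi, off_mu, off_pi, control$theta_range)
  }
  coef_mu <- init$coef_mu; coef_pi <- init$coef_pi; theta <- init$theta
  eta_mu <- drop(Mmu %*% coef_mu) + off_mu
  eta_pi <- drop(Mpi %*% coef_pi) + off_pi
  mu_prime <- exp(eta_mu)
  pi_i <- plogis(eta_pi)
  ll <- zinb_loglik(y, pi_i, mu_prime, theta)
  ll_trace <- ll
  converged <- FALSE
  decreased <- FALSE
  stalled <- FALSE
  iter <- 0L
  w <- rep(1, n)
  while (iter < control$max_iter) {
    iter <- iter + 1L
    prev <- list(coef_mu = coef_mu, coef_pi = coef_pi, theta = theta,
                 pi_i = pi_i, mu_prime = mu_prime)
    w <- e_step_weights(y, pi_i, mu_prime, theta)
    # M-step, count component: weighted NB regression at current theta
    fit_mu <- tryCatch(
      suppressWarnings(glm.fit(x = Mmu, y = y, weights = w,
                               offset = off_mu,
                               family = negative.binomial(theta),
                               start = coef_mu,
                               control = list(maxit = 25))),
      error = function(e) NULL)
    if (is.null(fit_mu) || any(!is.finite(fit_mu$coefficients))) break
    coef_mu <- fit_mu$coefficients
    eta_mu <- drop(Mmu %*% coef_mu) + off_mu
    mu_prime <- exp(eta_mu)
    theta <- .update_theta(y, mu_prime, w, control$theta_range, theta)
    # M-step, zero component: weighted logistic regression on 1 - w
    fit_pi <- tryCatch(
      suppressWarnings(glm.fit(x = Mpi, y = 1 - w, offset = off_pi,
                               family = quasibinomial(),
                               start = coef_pi,
                               control = list(maxit = 25))),
      error = function(e) NULL)
    if (is.null(fit_pi) || any(!is.finite(fit_pi$coefficients))) break
    coef_pi <- fit_pi$coefficients
    eta_pi <- drop(Mpi %*% coef_pi) + off_pi
    pi_i <- plogis(eta_pi)
    ll_new <- zinb_loglik(y, pi_i, mu_prime, theta)
    if (ll_new < ll - 1e-9) {
      # reject the trial step (numerical M-step overshoot), keep the ascent
      coef_mu <- prev$coef_mu; coef_pi <- prev$coef_pi; theta <- prev$theta
      pi_i <- prev$pi_i; mu_prime <- prev$mu_prime
      decreased <- TRUE
      break
    }
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < control$tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    if (iter >= 10 && abs(ll_new - ll) < control$stall_tol) {
      # slow linear-convergence tail: hand over to the gradient polish
      ll <- ll_new
      stalled <- TRUE
      break
    }
    ll <- ll_new
  }
  if (length(ll_trace) > 1) ll <- max(ll, ll_trace[length(ll_trace)])
  names(coef_mu) <- colnames(Mmu)
  names(coef_pi) <- colnames(Mpi)
  fit <- structure(
    list(coef_mu = coef_mu, coef_pi = coef_pi,
         theta = theta, phi = 1 / theta, omega = log(theta),
         loglik = ll, ll_trace = ll_trace,
         weights = w, fitted_pi = pi_i, fitted_mu_prime = mu_prime,
         fitted_mu = exp(drop(Mmu %*% coef_mu)),
         converged = converged, decreased = decreased, stalled = stalled,
         n_iter = iter, method = "em"),
    class = "gene_fit"
  )
  if (control$polish) {
    pol <- tryCatch(
      .zinb_bfgs(y, Mmu, Mpi, off_mu, off_pi, control, init = fit),
      error = function(e) NULL)
    if (!is.null(pol) && pol$loglik >= fit$loglik) {
      em_conv <- fit$converged
      fit <- pol
      # EM reached the optimum itself when the polish barely moved it
      fit$converged <- TRUE
      fit$method <- if (em_conv || pol$loglik - ll < 1e-4) "em" else "direct"
      fit$ll_trace <- c(ll_trace, pol$loglik)
      fit$n_iter <- iter
      fit$decreased <- decreased
    }
  }
  fit
}

# analytic gradient of the incomplete-data log-likelihood wrt
# (coef_mu, coef_pi, log theta); par layout as in the direct optimizers
.zinb_grad <- function(par, y, Mmu, Mpi, off_mu, off_pi) {
  pmu <- ncol(Mmu); ppi <- ncol(Mpi)
  cm <- par[seq_len(pmu)]
  cp <- par[pmu + seq_len(ppi)]
  th <- exp(par[pmu + ppi + 1])
  mu <- exp(pmin(drop(Mmu %*% cm) + off_mu, 30))
  pi_i <- plogis(drop(Mpi %*% cp) + off_pi)
  z <- y == 0
  d_mu <- d_pi <- d_lt <- numeric(length(y))
  # positive counts: NB score, zero component vanishes
  yp <- y[!z]; mup <- mu[!z]; pip <- pi_i[!z]
  d_mu[!z] <- yp - mup * (yp + th) / (th + mup)
  d_pi[!z] <- -pip
  d_lt[!z] <- th * (digamma(yp + th) - digamma(th) + log(th) + 1 -
                      log(th + mup) - (yp + th) / (th + mup))
  # zeros: mixture of the point mass and the NB zero probability
  mu0 <- mu[z]; pi0 <- pi_i[z]
  lf0 <- th * (log(th) - log(th + mu0))
  f0 <- exp(lf0)
  D <- pi0 + (1 - pi0) * f0
  D <- pmax(D, 1e-300)
  d_mu[z] <- -(1 - pi0) * f0 * th * mu0 / (th + mu0) / D
  d_pi[z] <- pi0 * (1 - pi0) * (1 - f0) / D
  d_lt[z] <- (1 - pi0) * f0 * th *
    (log(th / (th + mu0)) + mu0 / (th + mu0)) / D
  c(drop(crossprod(Mmu, d_mu)), drop(crossprod(Mpi, d_pi)), sum(d_lt))
}

# quasi-Newton (BFGS, analytic gradient) maximization of the incomplete-data
# log-likelihood; polishes an EM endpoint to the exact optimum
.zinb_bfgs <- function(y, Mmu, Mpi, off_mu, off_pi, control = em_control(),
                       init = NULL) {
  if (is.null(init)) {
    init <- .zinb_init(y, Mmu, Mpi, off_mu, off_pi, control$theta_range)
  }
  pmu <- ncol(Mmu); ppi <- ncol(Mpi)
  par0 <- c(init$coef_mu, init$coef_pi,
            log(if (!is.null(init$theta)) init$theta else 1))
  negll <- function(par) {
    cm <- par[seq_len(pmu)]
    cp <- par[pmu + seq_len(ppi)]
    th <- exp(par[pmu + ppi + 1])
    if (!is.finite(th) || th <= 0) return(1e12)
    mu_prime <- exp(pmin(drop(Mmu %*% cm) + off_mu, 30))
    pi_i <- plogis(drop(Mpi %*% cp) + off_pi)
    ll <- zinb_loglik(y, pi_i, mu_prime, th)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  neggrad <- function(par) {
    -.zinb_grad(par, y, Mmu, Mpi, off_mu, off_pi)
  }
  opt <- optim(par0, negll, neggrad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  .pack_direct_fit(opt, Mmu, Mpi, off_mu, off_pi, y, method = "direct")
}

# assemble a gene_fit from an optim() result
.pack_direct_fit <- function(opt, Mmu, Mpi, off_mu, off_pi, y, method) {
  pmu <- ncol(Mmu); ppi <- ncol(Mpi)
  cm <- opt$par[seq_len(pmu)]
  cp <- opt$par[pmu + seq_len(ppi)]
  theta <- exp(opt$par[pmu + ppi + 1])
  eta_mu <- drop(Mmu %*% cm) + off_mu
  eta_pi <- drop(Mpi %*% cp) + off_pi
  mu_prime <- exp(eta_mu)
  pi_i <- plogis(eta_pi)
  names(cm) <- colnames(Mmu); names(cp) <- colnames(Mpi)
  structure(
    list(coef_mu = cm, coef_pi = cp,
         theta = theta, phi = 1 / theta, omega = log(theta),
         loglik = -opt$value, ll_trace = -opt$value,
         weights = e_step_weights(y, pi_i, mu_prime, theta),
         fitted_pi = pi_i, fitted_mu_prime = mu_prime,
         fitted_mu = exp(drop(Mmu %*% cm)),
         converged = opt$convergence == 0, decreased = FALSE,
         stalled = FALSE,
         n_iter = as.integer(opt$counts[1]), method = method),
    class = "gene_fit"
  )
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("ZINB gene fit (", x$method, "): loglik ",
      format(x$loglik, digits = 8), ", theta ",
      format(x$theta, digits = 4), ", ",
      x$n_iter, " iterations, converged = ", x$converged, "\n", sep = "")
  cat("  mean coef: ", paste(names(x$coef_mu), format(x$coef_mu, digits = 3),
                             collapse = ", "), "\n")
  cat("  zero coef: ", paste(names(x$coef_pi), format(x$coef_pi, digits = 3),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Fit a gene-wise ZINB GLM by expectation-maximization
#'
#' Alternates the E-step (posterior count-component weights) with two
#' weighted M-steps: an NB log-linear regression for the mean submodel (with
#' a profile-likelihood update of the size parameter `theta`) and a logistic
#' regression for the zero-inflation submodel, both on the design given by
#' [design_spec()], until the incomplete-data log-likelihood changes by less
#' than `control$tol` or `control$max_iter` is reached. On non-convergence
#' (or a log-likelihood decrease) the direct Nelder-Mead maximizer
#' [direct_mle_fallback()] is invoked when `control$fallback` is `TRUE`.
#'
#' @param y Gene count vector (one entry per cell), at least one non-zero.
#' @param design A [design_spec()].
#' @param control An [em_control()].
#' @return Object of class `"gene_fit"`: coefficient vectors `coef_mu`
#'   (log-mean model) and `coef_pi` (logit-zero model), `theta`, `loglik`,
#'   the log-likelihood trace, per-cell posterior `weights`, fitted `pi` and
#'   means, convergence status and the method used.
#' @export
em_fit_gene <- function(y, design, control = em_control()) {
  stopifnot(inherits(design, "design_spec"))
  .check_counts(y)
  if (length(y) != nrow(design$M)) {
    stop("`y` length must equal the number of cells in the design")
  }
  if (all(y == 0)) stop("`y` must have at least one non-zero entry")
  fit <- .zinb_em(y, design$M, design$M, design$offset_mu, design$offset_pi,
                  control)
  if ((!fit$converged || fit$decreased) && control$fallback) {
    fb <- .zinb_direct(y, design$M, design$M, design$offset_mu,
                       design$offset_pi, control, init = fit)
    if (fb$loglik >= fit$loglik) fit <- fb
  }
  fit
}

# direct Nelder-Mead maximization of the incomplete-data log-likelihood
.zinb_direct <- function(y, Mmu, Mpi, off_mu, off_pi, control = em_control(),
                         init = NULL) {
  if (is.null(init)) {
    init <- .zinb_init(y, Mmu, Mpi, off_mu, off_pi, control$theta_range)
  }
  pmu <- ncol(Mmu); ppi <- ncol(Mpi)
  par0 <- c(init$coef_mu, init$coef_pi,
            log(if (!is.null(init$theta)) init$theta else 1))
  negll <- function(par) {
    cm <- par[seq_len(pmu)]
    cp <- par[pmu + seq_len(ppi)]
    th <- exp(par[pmu + ppi + 1])
    if (!is.finite(th) || th <= 0) return(1e12)
    mu_prime <- exp(pmin(drop(Mmu %*% cm) + off_mu, 30))
    pi_i <- plogis(drop(Mpi %*% cp) + off_pi)
    ll <- zinb_loglik(y, pi_i, mu_prime, th)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  opt <- optim(par0, negll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  .pack_direct_fit(opt, Mmu, Mpi, off_mu, off_pi, y, method = "direct")
}

#' Direct maximum-likelihood fit by Nelder-Mead simplex search
#'
#' Maximizes the incomplete-data ZINB log-likelihood over all mean-model and
#' zero-model coefficients plus `log(theta)` with a derivative-free simplex
#' search. Used as a fallback when the EM iteration does not converge; can be
#' warm-started from a partial EM fit.
#'
#' @inheritParams em_fit_gene
#' @param init Optional `"gene_fit"` (e.g. a partial EM fit) used as the
#'   starting point.
#' @return A `"gene_fit"` with `method = "direct"`.
#' @export
direct_mle_fallback <- function(y, design, init = NULL,
                                control = em_control()) {
  stopifnot(inherits(design, "design_spec"))
  .check_counts(y)
  .zinb_direct(y, design$M, design$M, design$offset_mu, design$offset_pi,
               control, init = init)
}

#' Fit ZINB GLMs for every gene of a count matrix
#'
#' Runs [em_fit_gene()] for each gene (row). When a capture estimate is
#' supplied, `log(p_hat_i)` is added to the mean-model offset so that fitted
#' means estimate the true (pre-capture) expression `mu` rather than the
#' observed `mu' = mu p`; with `p_hat = 1` the two coincide. Individual gene
#' failures are recorded, not fatal.
#'
#' @param counts Genes x cells count matrix (rows named by gene).
#' @param design A [design_spec()].
#' @param capture Optional [capture_estimate()]; its `p_hat` enters the mean
#'   offset as `log(p_hat)`.
#' @param control An [em_control()].
#' @return Object of class `"gene_fits"`: list of per-gene `"gene_fit"`
#'   objects (`$fits`), a summary `data.frame` (`$summary`) with gene-level
#'   `mu_hat` (cell-average fitted true mean), `pi_hat` (cell-average fitted
#'   zero inflation), `theta_hat`, `loglik`, `converged`, `n_iter`, `method`,
#'   `ok`, and the design/capture used.
#' @export
fit_all_genes <- function(counts, design, capture = NULL,
                          control = em_control()) {
  counts <- as.matrix(counts)
  stopifnot(inherits(design, "design_spec"))
  if (ncol(counts) != nrow(design$M)) {
    stop("`counts` columns must match the design's cells")
  }
  design <- .with_capture_offset(design, capture, ncol(counts))
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  fits <- vector("list", nrow(counts))
  ok <- logical(nrow(counts))
  for (j in seq_len(nrow(counts))) {
    fits[[j]] <- tryCatch(em_fit_gene(counts[j, ], design, control),
                          error = function(e) e)
    ok[j] <- inherits(fits[[j]], "gene_fit")
  }
  summary <- data.frame(
    gene_id = gene_ids,
    mu_hat = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) mean(f$fitted_mu) else NA_real_, 0),
    pi_hat = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) mean(f$fitted_pi) else NA_real_, 0),
    theta_hat = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) f$theta else NA_real_, 0),
    loglik = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) f$loglik else NA_real_, 0),
    converged = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) f$converged else FALSE, TRUE),
    n_iter = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) f$n_iter else NA_integer_, 0L),
    method = vapply(fits, function(f)
      if (inherits(f, "gene_fit")) f$method else "failed", ""),
    ok = ok,
    row.names = NULL
  )
  structure(list(fits = setNames(fits, gene_ids), summary = summary,
                 design = design, capture = capture),
            class = "gene_fits")
}

#' @export
print.gene_fits <- function(x, ...) {
  cat("ZINB gene fits:", nrow(x$summary), "genes,",
      sum(x$summary$converged), "converged,",
      sum(!x$summary$ok), "failed\n")
  print(head(x$summary))
  invisible(x)
}

# add log(p_hat) to the mean-model offset
.with_capture_offset <- function(design, capture, n_cells) {
  if (is.null(capture)) return(design)
  stopifnot(inherits(capture, "capture_estimate"))
  p <- pmax(capture$p_hat, 1e-6)
  if (length(p) != n_cells) {
    stop("capture estimate covers ", length(p), " cells; counts have ",
         n_cells)
  }
  design$offset_mu <- design$offset_mu + log(p)
  design
}
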