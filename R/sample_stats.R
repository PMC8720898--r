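#' Cluster-balanced sample mean and variance of a gene
#'
#' Computes the cluster-balanced sample mean
#' `ybar = (1/K) sum_k (1/I_k) sum_i y_ik` and the pooled sample variance
#' `s2 = (1/K) sum_k (1/(I_k - 1)) sum_i (y_ik - ybar)^2`, where the inner
#' deviation uses the overall balanced mean `ybar` (not the cluster means).
#'
#' @param y Gene count vector.
#' @param clusters Optional per-cell cluster labels; `NULL` means a single
#'   cluster. Every cluster must contain at least two cells.
#' @return List with `ybar` and `s2`.
#' @export
observed_gene_stats <- function(y, clusters = NULL) {
  if (is.null(clusters)) clusters <- rep(1L, length(y))
  if (length(clusters) != length(y)) {
    stop("`clusters` length must match `y`")
  }
  clusters <- as.factor(clusters)
  sizes <- table(clusters)
  if (any(sizes < 2)) {
    stop("cluster(s) with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  K <- nlevels(clusters)
  cl_means <- tapply(y, clusters, mean)
  ybar <- mean(cl_means)
  dev2 <- (y - ybar)^2
  s2 <- mean(tapply(dev2, clusters, sum) / (sizes - 1))
  list(ybar = unname(ybar), s2 = unname(s2))
}

#' Model-implied moments of gene sample statistics
#'
#' Plug-in estimates of the sampling moments of a gene's sample mean and
#' sample variance under the capture-thinned ZINB model with gene-level
#' parameters `(pi, mu, theta)` and per-cell capture rates summarized by
#' `p_bar`, `p2_bar` and `var_p`:
#' \describe{
#'   \item{`E_ybar`}{`mu (1 - pi) p_bar`}
#'   \item{`V_ybar`}{`mu (1 - pi) / I * (2 p_bar + mu phi p2_bar) +
#'     (1 - pi)^2 mu^2 var_p` (published form)}
#'   \item{`E_s2`}{`mu p_bar + mu^2 phi p2_bar + mu^2 var_p` (published
#'     form, dispersion convention; set `theta_eq46 = TRUE` for the variant
#'     with `theta` in place of `phi`)}
#' }
#' The published `V_ybar`/`E_s2` forms do not follow from the observation
#' model's variance (they differ already in the `pi = 0` limit); exact
#' moments derived directly from the per-cell mean and variance of the
#' observed count are therefore also returned as `V_ybar_exact` and
#' `E_s2_exact` (single-cluster case, fixed per-cell capture rates):
#' `V_ybar_exact = [(1-pi) mu p_bar + (1-pi) mu^2 (pi + phi) p2_bar] / I`,
#' `E_s2_exact = (1-pi) mu p_bar + (1-pi) mu^2 (pi + phi) p2_bar +
#'   (1-pi)^2 mu^2 var_p * I/(I-1)`.
#' The derived columns `sd_ybar = sqrt(V_ybar)`, `se_ybar = sd_ybar /
#' sqrt(I)` and `cv_ybar = sd_ybar / E_ybar` use the published `V_ybar`.
#'
#' @param mu,pi,theta Gene-level ZINB parameter estimates (vectors allowed,
#'   one entry per gene).
#' @param capture A [capture_estimate()] providing `p_bar`, `p2_bar`,
#'   `var_p`.
#' @param I Total number of cells, `> 1`.
#' @param theta_eq46 Use the size parameter `theta` instead of the
#'   dispersion `phi` in the published `E_s2` formula (default `FALSE`).
#' @return `data.frame` with one row per gene: `E_ybar`, `V_ybar`, `E_s2`,
#'   `V_ybar_exact`, `E_s2_exact`, `sd_ybar`, `se_ybar`, `cv_ybar`.
#' @export
estimated_gene_stats <- function(mu, pi, theta, capture, I,
                                 theta_eq46 = FALSE) {
  stopifnot(inherits(capture, "capture_estimate"))
  if (I <= 1) stop("`I` must exceed 1")
  .check_prob(pi, "pi")
  if (any(theta <= 0)) stop("`theta` must be > 0")
  phi <- 1 / theta
  pb <- capture$p_bar; p2b <- capture$p2_bar; vp <- capture$var_p
  E_ybar <- mu * (1 - pi) * pb
  V_ybar <- mu * (1 - pi) / I * (2 * pb + mu * phi * p2b) +
    (1 - pi)^2 * mu^2 * vp
  disp <- if (theta_eq46) theta else phi
  E_s2 <- mu * pb + mu^2 * disp * p2b + mu^2 * vp
  V_ybar_exact <- ((1 - pi) * mu * pb +
                     (1 - pi) * mu^2 * (pi + phi) * p2b) / I
  E_s2_exact <- (1 - pi) * mu * pb +
    (1 - pi) * mu^2 * (pi + phi) * p2b +
    (1 - pi)^2 * mu^2 * vp * I / (I - 1)
  sd_ybar <- sqrt(V_ybar)
  data.frame(
    E_ybar = E_ybar, V_ybar = V_ybar, E_s2 = E_s2,
    V_ybar_exact = V_ybar_exact, E_s2_exact = E_s2_exact,
    sd_ybar = sd_ybar,
    se_ybar = sd_ybar / sqrt(I),
    cv_ybar = ifelse(E_ybar > 0, sd_ybar / E_ybar, NA_real_)
  )
}
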