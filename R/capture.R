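#' Spike-in data set
#'
#' Container for external RNA spike-in calibration data: per-transcript
#' molecular concentrations and the cells x transcripts matrix of observed
#' spike-in UMI counts.
#'
#' @param concentrations Numeric vector `C_u` of molecular concentrations for
#'   the `n` spike-in transcripts (molecules per lysate).
#' @param counts Cells x transcripts matrix of nonnegative integer spike-in
#'   UMI counts `R_iu`.
#' @param transcript_ids Optional transcript labels (default `spike_1..n`).
#' @return Object of class `"spikein_set"`.
#' @export
spikein_set <- function(concentrations, counts, transcript_ids = NULL) {
  counts <- as.matrix(counts)
  n <- length(concentrations)
  if (n < 2) stop("need >= 2 spike-in transcripts for regression")
  if (ncol(counts) != n) {
    stop("`counts` must have one column per spike-in transcript (",
         n, " concentrations, ", ncol(counts), " columns)")
  }
  if (any(counts < 0)) stop("spike-in counts must be nonnegative")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.null(transcript_ids)) {
    transcript_ids <- paste0("spike_", seq_len(n))
  }
  colnames(counts) <- transcript_ids
  structure(
    list(concentrations = as.numeric(concentrations), counts = counts,
         transcript_ids = transcript_ids),
    class = "spikein_set"
  )
}

#' Per-cell capture-rate estimate
#'
#' Holds per-cell capture rates `p_hat` with the summaries needed by the
#' sampling-moment formulas: mean `p_bar`, mean of squares `p2_bar`, and
#' population variance `var_p`.
#'
#' @param p_hat Per-cell capture rates in `[0, 1]`.
#' @param method One of `"spikein"`, `"librarysize"`, `"fixed"`.
#' @param range `(rho1, rho2)` when `method = "librarysize"`.
#' @param L_range `(L_min, L_max)` log10 library-size extremes, if relevant.
#' @param p_raw Unclamped slopes (spike-in method), kept for diagnostics.
#' @param intercepts Per-cell regression intercepts (spike-in method).
#' @return Object of class `"capture_estimate"`.
#' @export
capture_estimate <- function(p_hat, method = c("fixed", "spikein", "librarysize"),
                             range = NULL, L_range = NULL, p_raw = NULL,
                             intercepts = NULL) {
  method <- match.arg(method)
  .check_prob(p_hat, "p_hat")
  structure(
    list(p_hat = as.numeric(p_hat),
         p_bar = mean(p_hat),
         p2_bar = mean(p_hat^2),
         var_p = mean(p_hat^2) - mean(p_hat)^2,
         method = method, range = range, L_range = L_range,
         p_raw = p_raw, intercepts = intercepts),
    class = "capture_estimate"
  )
}

#' @export
print.capture_estimate <- function(x, ...) {
  cat("Capture-rate estimate (", x$method, "): ", length(x$p_hat),
      " cells\n  p_bar = ", format(x$p_bar, digits = 4),
      ", p2_bar = ", format(x$p2_bar, digits = 4),
      ", var(p) = ", format(x$var_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Binomial thinning of true counts by per-cell capture rates
#'
#' Each observed entry is drawn as `Y ~ Binomial(Z, p_i)` where `Z` is the
#' true count and `p_i` the capture rate of the entry's cell (capture is
#' gene-constant within a cell). `p = 1` returns `Z` unchanged (perfect deep
#' sequencing); `p = 0` gives all zeros.
#'
#' @param Z Genes x cells matrix of nonnegative integer true counts.
#' @param p Capture rate(s): scalar or one value per cell (column).
#' @param seed Optional integer seed.
#' @return Genes x cells integer matrix `Y <= Z` elementwise.
#' @export
thin_counts <- function(Z, p, seed = NULL) {
  Z <- as.matrix(Z)
  .check_counts(Z)
  if (length(p) == 1) p <- rep(p, ncol(Z))
  if (length(p) != ncol(Z)) {
    stop("`p` must have one capture rate per cell (", ncol(Z), " columns, ",
         length(p), " rates)")
  }
  .check_prob(p, "p")
  if (!is.null(seed)) set.seed(seed)
  Y <- matrix(rbinom(length(Z), size = as.vector(Z),
                     prob = rep(p, each = nrow(Z))),
              nrow = nrow(Z), dimnames = dimnames(Z))
  storage.mode(Y) <- storage.mode(Z)
  Y
}

#' Brute-force marginal pmf of the capture-thinned ZINB count
#'
#' Computes `P(Y = y) = sum_z Binomial(y | z, p) * ZINB(z; pi, mu, theta)` by
#' direct truncated summation. Serves as the independent oracle for the
#' marginalization theorem: the result equals the closed form
#' `ZINB(y; pi, mu * p, theta)` (checked to 1e-10 in the test suite).
#'
#' @param y Nonnegative integer (scalar).
#' @param pi,mu,theta ZINB parameters of the true count.
#' @param p Capture rate in `[0, 1]`.
#' @param z_max Truncation bound for the sum over true counts; chosen
#'   automatically (ZINB tail mass `< tol`) when `NULL`.
#' @param tol Maximum admissible truncated tail mass (default `1e-12`).
#' @return The marginal probability `P(Y = y)`.
#' @export
thinned_pmf_oracle <- function(y, pi, mu, theta, p, z_max = NULL, tol = 1e-12) {
  stopifnot(length(y) == 1)
  .check_counts(y)
  .check_prob(pi, "pi")
  .check_prob(p, "p")
  if (is.null(z_max)) {
    z_max <- max(y, qnbinom(tol / 10, size = theta, mu = mu,
                            lower.tail = FALSE) + 10L)
  }
  # NB-component tail mass beyond z_max (the point mass at 0 has no tail)
  tail_mass <- (1 - pi) * pnbinom(z_max, size = theta, mu = mu,
                                  lower.tail = FALSE)
  if (tail_mass > tol) {
    stop("`z_max` too small: truncated tail mass ", format(tail_mass),
         " exceeds tol ", format(tol))
  }
  z <- y:z_max
  sum(dbinom(y, size = z, prob = p) * zinb_pmf(z, pi, mu, theta))
}

#' Estimate per-cell capture rates from external RNA spike-ins
#'
#' For each cell, ordinary least squares of the observed spike-in UMI counts
#' `R_iu` on the known molecular concentrations `C_u`; the slope estimates
#' the cell's capture rate `p_i` and the intercept absorbs cell-specific
#' background. Slopes are clamped to `[0, 1]` (raw values kept in `p_raw`).
#'
#' @param spikes A [spikein_set()].
#' @return A [capture_estimate()] with `method = "spikein"`.
#' @export
estimate_capture_spikeins <- function(spikes) {
  stopifnot(inherits(spikes, "spikein_set"))
  C <- spikes$concentrations
  cc <- C - mean(C)
  ssq <- sum(cc^2)
  if (ssq < .Machine$double.eps * length(C)) {
    stop("spike-in concentrations are constant: regression is singular")
  }
  R <- spikes$counts                      # cells x transcripts
  slopes <- drop(R %*% cc) / ssq          # cov(C, R_i.) / var(C), per cell
  intercepts <- rowMeans(R) - slopes * mean(C)
  p_hat <- pmin(1, pmax(0, slopes))
  capture_estimate(p_hat, method = "spikein", p_raw = slopes,
                   intercepts = intercepts)
}

#' Estimate per-cell capture rates from library sizes
#'
#' Without spike-ins, capture rates are interpolated from log10 library
#' sizes: `L_i = log10(S_i)` and
#' `p_i = rho1 + (rho2 - rho1) (L_i - L_min) / (L_max - L_min)`, so the
#' smallest cell gets `rho1` and the largest `rho2`.
#'
#' @param library_sizes Per-cell positive totals `S_i`.
#' @param rho1,rho2 Capture-rate range, `0 <= rho1 < rho2 <= 1`; defaults
#'   `(0.1, 0.9)`.
#' @return A [capture_estimate()] with `method = "librarysize"`.
#' @export
estimate_capture_librarysize <- function(library_sizes, rho1 = 0.1, rho2 = 0.9) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (!(rho1 >= 0 && rho1 < rho2 && rho2 <= 1)) {
    stop("need 0 <= rho1 < rho2 <= 1")
  }
  L <- log10(library_sizes)
  L_min <- min(L); L_max <- max(L)
  if (L_max - L_min < .Machine$double.eps * 4) {
    warning("all library sizes equal; returning midpoint capture rate for all cells")
    p_hat <- rep((rho1 + rho2) / 2, length(L))
  } else {
    p_hat <- rho1 + (rho2 - rho1) * (L - L_min) / (L_max - L_min)
  }
  capture_estimate(p_hat, method = "librarysize", range = c(rho1, rho2),
                   L_range = c(L_min, L_max))
}

#' Fixed capture rates
#'
#' Wraps a known or assumed per-cell capture-rate vector (e.g. simulation
#' truth, or `p = 1` for no capture adjustment).
#'
#' @param p Scalar or per-cell capture rate(s) in `[0, 1]`.
#' @param n_cells Number of cells when `p` is scalar.
#' @return A [capture_estimate()] with `method = "fixed"`.
#' @export
fixed_capture <- function(p, n_cells = length(p)) {
  if (length(p) == 1) p <- rep(p, n_cells)
  capture_estimate(p, method = "fixed")
}
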