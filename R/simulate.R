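#' Simulation configuration
#'
#' Defines the generative model used by [simulate_dataset()]: per-gene true
#' counts are ZINB with gene-level `(pi, mu, theta)` drawn from the stated
#' ranges, group effects act multiplicatively on the mean (`de_lfc`, natural
#' log) and additively on the logit zero inflation (`dzi_effect`), optional
#' cell clusters carry disjoint marker-gene sets plus global scale shifts,
#' and observed counts arise by binomial capture thinning with per-cell
#' rates.
#'
#' @param n_genes,n_cells Dimensions of the simulated matrix.
#' @param n_groups Number of cell groups (default 2).
#' @param group_sizes Cells per group; equal split by default.
#' @param n_clusters Number of cell clusters (default 1 = no cluster
#'   structure).
#' @param cluster_marker_frac Fraction of genes acting as cluster markers,
#'   split evenly across clusters (default 0.6).
#' @param cluster_marker_lfc Natural-log fold change of a marker gene in its
#'   cluster (default `log(12)`).
#' @param cluster_scale_step Multiplicative global expression step between
#'   consecutive clusters (default 1.6), mimicking cell-size differences.
#' @param de_fraction,de_lfc Fraction of genes with a group effect on the
#'   mean and its magnitude `gamma_1` (natural log, default `log(3)`; signs
#'   alternate).
#' @param dzi_fraction,dzi_effect Fraction of genes with a group effect on
#'   the zero inflation and its logit-scale magnitude `beta_1` (default 2;
#'   signs alternate).
#' @param mu_range Log-uniform range of gene mean expression (default
#'   `c(0.5, 50)`).
#' @param theta_range Uniform range of the NB size (default `c(0.5, 10)`).
#' @param pi_range Uniform range of zero inflation (default `c(0.05, 0.6)`).
#' @param capture Capture model: `list(type = "fixed", p = ...)` (scalar or
#'   per-cell vector) or `list(type = "gradient", range = c(lo, hi))`
#'   (per-cell rates evenly spaced over the range and randomly assigned to
#'   cells, so capture is independent of group/cluster membership; the
#'   default, `c(0.1, 0.9)`).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 200L, n_cells = 200L,
                              n_groups = 2L, group_sizes = NULL,
                              n_clusters = 1L,
                              cluster_marker_frac = 0.6,
                              cluster_marker_lfc = log(12),
                              cluster_scale_step = 1.6,
                              de_fraction = 0.1, de_lfc = log(3),
                              dzi_fraction = 0.1, dzi_effect = 2,
                              mu_range = c(0.5, 50),
                              theta_range = c(0.5, 10),
                              pi_range = c(0.05, 0.6),
                              capture = list(type = "gradient",
                                             range = c(0.1, 0.9)),
                              seed = 1L) {
  if (is.null(group_sizes)) {
    base <- n_cells %/% n_groups
    group_sizes <- rep(base, n_groups)
    group_sizes[1] <- n_cells - sum(group_sizes[-1])
  }
  if (sum(group_sizes) != n_cells) stop("group sizes must sum to n_cells")
  if (n_clusters > n_cells) stop("more clusters than cells")
  stopifnot(de_fraction >= 0, de_fraction <= 1,
            dzi_fraction >= 0, dzi_fraction <= 1,
            pi_range[1] >= 0, pi_range[2] <= 1,
            mu_range[1] > 0, theta_range[1] > 0)
  if (!capture$type %in% c("fixed", "gradient")) {
    stop("capture$type must be 'fixed' or 'gradient'")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
         n_groups = as.integer(n_groups), group_sizes = group_sizes,
         n_clusters = as.integer(n_clusters),
         cluster_marker_frac = cluster_marker_frac,
         cluster_marker_lfc = cluster_marker_lfc,
         cluster_scale_step = cluster_scale_step,
         de_fraction = de_fraction, de_lfc = de_lfc,
         dzi_fraction = dzi_fraction, dzi_effect = dzi_effect,
         mu_range = mu_range, theta_range = theta_range,
         pi_range = pi_range, capture = capture, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a UMI data set with known ZINB truth
#'
#' Forward model: true counts `Z ~ ZINB(pi_ij, mu_ij, theta_j)` with group,
#' cluster-marker and cluster-scale effects on `mu` and group effects on the
#' logit of `pi`; observed counts `Y | Z ~ Binomial(Z, p_i)` with per-cell
#' capture rates from the configured capture model.
#'
#' @param config A [simulation_config()].
#' @return List with `observed` (genes x cells matrix), `true` (latent
#'   counts), `gene_truth` (`data.frame`: per-gene parameters, DE/DZI flags
#'   and effects, marker cluster), `cell_meta` (`data.frame`: `cell_id`,
#'   `group`, `cluster`, `p`, `library_size`) and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  J <- config$n_genes; I <- config$n_cells
  gene_ids <- sprintf("gene_%03d", seq_len(J))
  cell_ids <- sprintf("cell_%03d", seq_len(I))
  mu <- exp(runif(J, log(config$mu_range[1]), log(config$mu_range[2])))
  theta <- runif(J, config$theta_range[1], config$theta_range[2])
  pi <- runif(J, config$pi_range[1], config$pi_range[2])

  n_de <- round(config$de_fraction * J)
  is_de <- seq_len(J) %in% sample.int(J, n_de)
  gamma1 <- ifelse(is_de, config$de_lfc * rep_len(c(1, -1), J), 0)
  n_dzi <- round(config$dzi_fraction * J)
  is_dzi <- seq_len(J) %in% sample.int(J, n_dzi)
  beta1 <- ifelse(is_dzi, config$dzi_effect * rep_len(c(1, -1), J), 0)

  group <- factor(rep(paste0("g", seq_len(config$n_groups)),
                      times = config$group_sizes))
  cluster <- factor(rep_len(paste0("c", seq_len(config$n_clusters)), I))

  marker_cluster <- rep(NA_integer_, J)
  if (config$n_clusters > 1) {
    n_mark <- floor(config$cluster_marker_frac * J)
    mk <- sample.int(J, n_mark)
    marker_cluster[mk] <- rep_len(seq_len(config$n_clusters), n_mark)
  }

  in_g2 <- as.integer(group != levels(group)[1])  # contrast vs reference
  log_mu <- outer(log(mu), rep(1, I)) + outer(gamma1, in_g2)
  if (config$n_clusters > 1) {
    cl_idx <- as.integer(cluster)
    scale_k <- log(config$cluster_scale_step) * (cl_idx - 1)
    log_mu <- log_mu + outer(rep(1, J), scale_k)
    mark <- !is.na(marker_cluster)
    if (any(mark)) {
      boost <- outer(ifelse(mark, config$cluster_marker_lfc, 0), rep(1, I)) *
        (matrix(marker_cluster, J, I) == matrix(cl_idx, J, I, byrow = TRUE))
      boost[is.na(boost)] <- 0
      log_mu <- log_mu + boost
    }
  }
  logit_pi <- outer(qlogis(pi), rep(1, I)) + outer(beta1, in_g2)
  pi_mat <- plogis(logit_pi)

  Z <- matrix(rnbinom(J * I, size = rep(theta, I), mu = exp(log_mu)), J, I)
  Z[matrix(runif(J * I), J, I) < pi_mat] <- 0L
  storage.mode(Z) <- "integer"
  dimnames(Z) <- list(gene_ids, cell_ids)

  p <- switch(config$capture$type,
    fixed = {
      pp <- config$capture$p
      if (length(pp) == 1) rep(pp, I) else pp
    },
    gradient = sample(seq(config$capture$range[1], config$capture$range[2],
                          length.out = I)))
  if (length(p) != I) stop("capture rates must cover all cells")
  Y <- thin_counts(Z, p)

  list(
    observed = Y, true = Z,
    gene_truth = data.frame(
      gene_id = gene_ids, mu = mu, theta = theta, pi = pi,
      is_de = is_de, gamma1 = gamma1, is_dzi = is_dzi, beta1 = beta1,
      marker_cluster = marker_cluster, row.names = NULL),
    cell_meta = data.frame(
      cell_id = cell_ids, group = group, cluster = cluster, p = p,
      library_size = colSums(Y), row.names = NULL),
    config = config
  )
}

#' Simulate an external RNA spike-in set
#'
#' Spike-in counts `R_iu ~ NB(mean = p_i C_u, size = 1/noise)` for each cell
#' `i` and ladder point `u`; with `noise <= 0` the deterministic limit
#' `R = p C` is returned (exact slope recovery). The default ladder is an
#' ERCC-like 2-fold dilution series.
#'
#' @param n_transcripts Number of spike-in transcripts (default 23).
#' @param concentration_ladder Positive concentrations; defaults to
#'   `0.5 * 2^(0:(n_transcripts-1))`. Must span at least one order of
#'   magnitude.
#' @param p Per-cell capture rates.
#' @param noise NB dispersion of the spike-in counts (default 0.02, the near-Poisson technical noise typical of deduplicated UMI spike-in counts).
#' @param seed Optional integer seed.
#' @return A [spikein_set()].
#' @export
simulate_spikeins <- function(n_transcripts = 23L, concentration_ladder = NULL,
                              p, noise = 0.02, seed = NULL) {
  if (is.null(concentration_ladder)) {
    concentration_ladder <- 0.5 * 2^(seq_len(n_transcripts) - 1)
  }
  C <- as.numeric(concentration_ladder)
  if (max(C) / min(C) < 10) {
    stop("concentration ladder must span at least one order of magnitude")
  }
  .check_prob(p, "p")
  if (!is.null(seed)) set.seed(seed)
  m <- outer(p, C)                      # cells x transcripts
  R <- if (noise <= 0) m else {
    matrix(rnbinom(length(m), size = 1 / noise, mu = as.vector(m)),
           nrow = length(p))
  }
  spikein_set(C, R)
}
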