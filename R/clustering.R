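#' Within/between sum-of-squares cluster index
#'
#' For per-cell summary values `Y_i` (a scalar per cell, or a row per cell
#' for multivariate profiles) and a cluster assignment, computes
#' `WSS = sum_k sum_i ||Y_ik - Ybar_.k||^2`,
#' `BSS = sum_k I_k ||Ybar_.k - Ybar_..||^2`, their total `TSS = WSS + BSS`
#' (the ANOVA identity, which holds componentwise and hence for the sums),
#' and the index `r = WSS / BSS`. Small `r` means tight, well-separated
#' clusters.
#'
#' @param values Per-cell numeric values: a vector (one summary per cell)
#'   or a cells x features matrix (sums of squares are accumulated over
#'   features).
#' @param labels Cluster assignment with at least 2 nonempty clusters.
#' @return List with `wss`, `bss`, `tss`, `r`.
#' @export
cluster_index <- function(values, labels) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels)) {
    stop("`values` and `labels` lengths differ")
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need >= 2 nonempty clusters")
  gm <- colMeans(values)
  sizes <- as.numeric(table(labels))
  cl_means <- rowsum(values, labels) / sizes
  tss <- sum(sweep(values, 2, gm)^2)
  bss <- sum(sizes * rowSums(sweep(cl_means, 2, gm)^2))
  wss <- tss - bss
  if (bss <= .Machine$double.eps * max(1, tss)) {
    stop("BSS is zero (all cluster means equal): index undefined")
  }
  list(wss = wss, bss = bss, tss = tss, r = wss / bss)
}

#' Choose the number of cell clusters by the WSS/BSS index
#'
#' For each candidate cluster count `h`, runs k-means (multiple restarts,
#' seeded) on the cells of a normalized log-transformed count matrix and
#' evaluates the index `r_h = WSS/BSS` on the same normalized expression
#' profiles. `r_h` decreases as clusters tighten; the optimum is taken where
#' the curve flattens: the first `h` whose relative improvement
#' `(r_h - r_{h+1}) / r_{h+1}` falls below `elbow_frac`. The `h` maximizing
#' `r_h` is also reported for transparency.
#'
#' @param counts Genes x cells count matrix.
#' @param h_range Candidate cluster counts (each in `[2, cells - 1]`).
#' @param seed Integer seed; fixes the k-means restarts, hence the whole
#'   curve.
#' @param normalize Library-size scale (to the median library size) and
#'   `log1p`-transform counts before clustering (default `TRUE`).
#' @param elbow_frac Relative-improvement threshold below which the curve
#'   counts as flat (default 0.15).
#' @param nstart k-means restarts per `h` (default 10).
#' @param max_retry Retries on a degenerate k-means run (default 5).
#' @return Object of class `"cluster_index_curve"`: `h_values`, `r_h`,
#'   `wss`, `bss`, `tss`, `h_opt`, `h_argmax`, `labels_opt` (per-cell labels
#'   at `h_opt`), `labels` (per `h`), and `no_structure` flag.
#' @export
optimal_cluster_number <- function(counts, h_range = 2:10, seed = 1L,
                                   normalize = TRUE, elbow_frac = 0.15,
                                   nstart = 10L, max_retry = 5L) {
  counts <- as.matrix(counts)
  I <- ncol(counts)
  h_range <- sort(unique(as.integer(h_range)))
  if (any(h_range < 2) || any(h_range > I - 1)) {
    stop("`h_range` must lie in [2, cells - 1]")
  }
  if (length(h_range) < 2) stop("need at least two candidate cluster counts")
  expr <- counts
  if (normalize) {
    libs <- pmax(colSums(counts), 1)
    expr <- log1p(t(t(counts) / libs * median(libs)))
  }
  cells <- t(expr)                      # k-means observations: cells
  if (nrow(unique(cells)) < 2) {
    warning("index curve is flat from h = ", h_range[1],
            ": no cluster structure detected")
    return(structure(
      list(h_values = h_range, r_h = rep(NA_real_, length(h_range)),
           wss = rep(0, length(h_range)), bss = rep(0, length(h_range)),
           tss = rep(0, length(h_range)),
           h_opt = h_range[1], h_argmax = h_range[1],
           labels_opt = rep(1L, I), labels = NULL,
           elbow_frac = elbow_frac, no_structure = TRUE, seed = seed),
      class = "cluster_index_curve"))
  }
  set.seed(seed)
  n_h <- length(h_range)
  wss <- bss <- tss <- r_h <- rep(NA_real_, n_h)
  labels <- vector("list", n_h)
  for (ii in seq_len(n_h)) {
    h <- h_range[ii]
    km <- NULL
    for (try in seq_len(max_retry)) {
      km <- tryCatch(kmeans(cells, centers = h, nstart = nstart,
                            iter.max = 100),
                     error = function(e) NULL,
                     warning = function(w) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == h) break
      km <- NULL
    }
    if (is.null(km)) stop("k-means failed repeatedly at h = ", h)
    idx <- cluster_index(cells, km$cluster)
    wss[ii] <- idx$wss; bss[ii] <- idx$bss; tss[ii] <- idx$tss
    r_h[ii] <- idx$r
    labels[[ii]] <- km$cluster
  }
  rel_drop <- (r_h[-n_h] - r_h[-1]) / r_h[-1]
  no_structure <- FALSE
  if (all(rel_drop < elbow_frac)) {
    # curve flat from the start: no detectable structure
    h_opt <- h_range[1]
    no_structure <- TRUE
    warning("index curve is flat from h = ", h_range[1],
            ": no cluster structure detected")
  } else {
    flat <- which(rel_drop < elbow_frac)
    h_opt <- if (length(flat)) h_range[min(flat)] else h_range[n_h]
  }
  structure(
    list(h_values = h_range, r_h = r_h, wss = wss, bss = bss, tss = tss,
         h_opt = h_opt, h_argmax = h_range[which.max(r_h)],
         labels_opt = labels[[match(h_opt, h_range)]], labels = labels,
         elbow_frac = elbow_frac, no_structure = no_structure, seed = seed),
    class = "cluster_index_curve"
  )
}

#' @export
print.cluster_index_curve <- function(x, ...) {
  cat("Cluster-number selection: h_opt =", x$h_opt,
      "(argmax r_h at", x$h_argmax, ")\n")
  print(data.frame(h = x$h_values, wss = x$wss, bss = x$bss, r_h = x$r_h))
  invisible(x)
}
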