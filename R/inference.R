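#' Likelihood-ratio test for one gene
#'
#' Tests differential expression (`target = "DE"`, group contrasts in the
#' log-mean submodel) or differential zero inflation (`target = "DZI"`,
#' group contrasts in the logit-zero submodel) by comparing the full joint
#' ZINB fit against the fit with the targeted group contrasts removed; the
#' non-targeted submodel keeps its group terms in both fits, so each test
#' isolates one parameter block. The statistic `-2 (l_constrained - l_full)`
#' is referred to a chi-square distribution with `L - 1` degrees of freedom
#' (`1` for two groups).
#'
#' If the constrained log-likelihood exceeds the full one by more than a
#' small tolerance (optimizer noise), both models are refit with the direct
#' Nelder-Mead maximizer; a persisting negative statistic is clamped to 0
#' and flagged `unreliable`.
#'
#' @param y Gene count vector.
#' @param design A [design_spec()] with at least 2 groups (capture offsets
#'   already folded into `offset_mu` if desired; see [fit_all_genes()]).
#' @param target `"DE"` or `"DZI"`.
#' @param control An [em_control()].
#' @return List of class `"lrt_result"`: `target`, `lfc` (group coefficient,
#'   natural log / logit scale), `lfc_log2`, `stat`, `df`, `p_value`,
#'   `loglik_full`, `loglik_reduced`, `unreliable`.
#' @export
lrt_test <- function(y, design, target = c("DE", "DZI"),
                     control = em_control()) {
  target <- match.arg(target)
  stopifnot(inherits(design, "design_spec"))
  if (design$n_groups < 2) stop("need >= 2 groups to test")
  full <- .fit_joint(y, design, design$M, design$M, control)
  red <- .fit_reduced(y, design, target, control)
  out <- .lrt_from_fits(y, design, target, full, red, control)
  out
}

.fit_joint <- function(y, design, Mmu, Mpi, control, init = NULL) {
  fit <- .zinb_em(y, Mmu, Mpi, design$offset_mu, design$offset_pi, control,
                  init = init)
  if ((!fit$converged || fit$decreased) && control$fallback) {
    fb <- .zinb_direct(y, Mmu, Mpi, design$offset_mu, design$offset_pi,
                       control, init = fit)
    if (fb$loglik >= fit$loglik) fit <- fb
  }
  fit
}

# warm start for a reduced model: drop the removed columns' coefficients
.reduced_init <- function(full, keep_mu, keep_pi) {
  list(coef_mu = full$coef_mu[keep_mu], coef_pi = full$coef_pi[keep_pi],
       theta = full$theta)
}

.fit_reduced <- function(y, design, target, control) {
  Mred <- design$M[, -design$group_cols, drop = FALSE]
  if (target == "DE") {
    .fit_joint(y, design, Mred, design$M, control)
  } else {
    .fit_joint(y, design, design$M, Mred, control)
  }
}

.lrt_from_fits <- function(y, design, target, full, red, control) {
  df <- length(design$group_cols)
  stat <- 2 * (full$loglik - red$loglik)
  unreliable <- FALSE
  if (stat < -1e-6) {
    # refit both sides with the simplex maximizer
    Mred <- design$M[, -design$group_cols, drop = FALSE]
    full2 <- .zinb_direct(y, design$M, design$M, design$offset_mu,
                          design$offset_pi, control, init = full)
    red2 <- if (target == "DE") {
      .zinb_direct(y, Mred, design$M, design$offset_mu, design$offset_pi,
                   control, init = red)
    } else {
      .zinb_direct(y, design$M, Mred, design$offset_mu, design$offset_pi,
                   control, init = red)
    }
    if (full2$loglik > full$loglik) full <- full2
    if (red2$loglik > red$loglik) red <- red2
    stat <- 2 * (full$loglik - red$loglik)
    if (stat < -1e-6) unreliable <- TRUE
  }
  stat <- max(stat, 0)
  co <- if (target == "DE") full$coef_mu else full$coef_pi
  lfc <- unname(co[design$group_cols[1]])
  structure(
    list(target = target, lfc = lfc, lfc_log2 = lfc / log(2),
         stat = stat, df = df,
         p_value = pchisq(stat, df = df, lower.tail = FALSE),
         loglik_full = full$loglik, loglik_reduced = red$loglik,
         fit_full = full, unreliable = unreliable),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(x$target, "LRT: stat =", format(x$stat, digits = 5),
      "df =", x$df, "p =", format(x$p_value, digits = 4),
      "lfc(log2) =", format(x$lfc_log2, digits = 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone after rank restoration) and the
#' matching FDR estimates.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param method Adjustment procedure; only `"BH"` is provided.
#' @return List with `adjusted` and `fdr` (both equal to the BH step-up
#'   values, the standard FDR estimate).
#' @export
adjust_pvalues <- function(p_values, method = "BH") {
  method <- match.arg(method, "BH")
  if (!length(p_values)) return(list(adjusted = numeric(0), fdr = numeric(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, fdr = adj)
}

#' Run DE and DZI tests for every gene
#'
#' Fits, per gene, the full joint ZINB model plus the two constrained models
#' (group contrasts removed from the mean submodel, and from the zero
#' submodel), producing differential-expression and differential-zero-
#' inflation likelihood-ratio tests in a single pass, with BH-adjusted
#' p-values and the influential-gene classification at level `alpha`.
#'
#' @param counts Genes x cells count matrix.
#' @param design A [design_spec()] with at least 2 groups.
#' @param capture Optional [capture_estimate()] folded into the mean offset.
#' @param alpha Significance level applied to adjusted p-values (default
#'   0.05).
#' @param control An [em_control()].
#' @return Object of class `"influence_results"` with `de` and `dzi`
#'   `data.frame`s (`gene_id`, `target`, `lfc`, `lfc_log2`, `stat`, `df`,
#'   `p_value`, `p_adjusted`, `fdr`, `significant`, `unreliable`), the
#'   `classes` data.frame from [classify_genes()], and `alpha`.
#' @export
run_influence_tests <- function(counts, design, capture = NULL, alpha = 0.05,
                                control = em_control()) {
  counts <- as.matrix(counts)
  stopifnot(inherits(design, "design_spec"))
  design <- .with_capture_offset(design, capture, ncol(counts))
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  n <- nrow(counts)
  res_de <- res_dzi <- vector("list", n)
  Mred <- design$M[, -design$group_cols, drop = FALSE]
  keep <- setdiff(seq_len(ncol(design$M)), design$group_cols)
  all_cols <- seq_len(ncol(design$M))
  for (j in seq_len(n)) {
    y <- counts[j, ]
    full <- .fit_joint(y, design, design$M, design$M, control)
    red_mu <- .fit_joint(y, design, Mred, design$M, control,
                         init = .reduced_init(full, keep, all_cols))
    red_pi <- .fit_joint(y, design, design$M, Mred, control,
                         init = .reduced_init(full, all_cols, keep))
    res_de[[j]] <- .lrt_from_fits(y, design, "DE", full, red_mu, control)
    res_dzi[[j]] <- .lrt_from_fits(y, design, "DZI", full, red_pi, control)
  }
  de <- .lrt_table(gene_ids, res_de, alpha)
  dzi <- .lrt_table(gene_ids, res_dzi, alpha)
  classes <- classify_genes(de, dzi, alpha = alpha)
  structure(list(de = de, dzi = dzi, classes = classes, alpha = alpha),
            class = "influence_results")
}

.lrt_table <- function(gene_ids, res, alpha) {
  p <- vapply(res, function(r) r$p_value, 0)
  adj <- adjust_pvalues(p)
  data.frame(
    gene_id = gene_ids,
    target = vapply(res, function(r) r$target, ""),
    lfc = vapply(res, function(r) r$lfc, 0),
    lfc_log2 = vapply(res, function(r) r$lfc_log2, 0),
    stat = vapply(res, function(r) r$stat, 0),
    df = vapply(res, function(r) r$df, 0L),
    p_value = p,
    p_adjusted = adj$adjusted,
    fdr = adj$fdr,
    significant = adj$adjusted < alpha,
    unreliable = vapply(res, function(r) r$unreliable, TRUE),
    row.names = NULL
  )
}

#' @export
print.influence_results <- function(x, ...) {
  cat("DE/DZI likelihood-ratio tests on", nrow(x$de), "genes (alpha =",
      x$alpha, ")\n")
  print(table(x$classes$label))
  invisible(x)
}

#' Classify influential genes from DE and DZI significance
#'
#' Deterministic four-way classification: both tests significant -> `DEZI`;
#' only the DE null rejected -> `DE_only`; only the DZI null rejected ->
#' `DZI_only`; neither -> `non_influential`.
#'
#' @param de,dzi Result `data.frame`s covering the same genes, each with
#'   `gene_id` and either a logical `significant` column or `p_adjusted`
#'   (thresholded at `alpha`).
#' @param alpha Significance level used when thresholding `p_adjusted`.
#' @return `data.frame` with `gene_id`, `de_significant`, `dzi_significant`,
#'   `label`; the per-class counts are attached as attribute `"counts"`.
#' @export
classify_genes <- function(de, dzi, alpha = 0.05) {
  if (!setequal(de$gene_id, dzi$gene_id)) {
    only_de <- setdiff(de$gene_id, dzi$gene_id)
    only_dzi <- setdiff(dzi$gene_id, de$gene_id)
    stop("gene sets differ; only in DE: ",
         paste(head(only_de, 5), collapse = ", "),
         "; only in DZI: ", paste(head(only_dzi, 5), collapse = ", "))
  }
  dzi <- dzi[match(de$gene_id, dzi$gene_id), ]
  sig <- function(d) {
    if (!is.null(d$significant)) as.logical(d$significant)
    else d$p_adjusted < alpha
  }
  de_sig <- sig(de); dzi_sig <- sig(dzi)
  label <- ifelse(de_sig & dzi_sig, "DEZI",
                  ifelse(de_sig, "DE_only",
                         ifelse(dzi_sig, "DZI_only", "non_influential")))
  out <- data.frame(gene_id = de$gene_id, de_significant = de_sig,
                    dzi_significant = dzi_sig, label = label,
                    row.names = NULL)
  attr(out, "counts") <- table(factor(
    label, levels = c("DEZI", "DE_only", "DZI_only", "non_influential")))
  out
}
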