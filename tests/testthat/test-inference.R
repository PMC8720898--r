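test_that("BH adjustment matches the hand computation", {
  out <- adjust_pvalues(c(0.01, 0.02, 0.03))
  expect_equal(out$adjusted, rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(1, 5))$adjusted, rep(1, 5))
  expect_equal(adjust_pvalues(0.2)$adjusted, 0.2)
  expect_length(adjust_pvalues(numeric(0))$adjusted, 0)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # adjusted values never fall below the raw ones
  set.seed(81)
  p <- runif(50)
  expect_true(all(adjust_pvalues(p)$adjusted >= p))
})

test_that("the LRT is null on duplicated groups and invariant to relabeling", {
  y <- zinb_sample(150, pi = 0.25, mu = 6, theta = 2, seed = 82)
  # both groups are the same cells: no information in the contrast
  d <- two_group_design(150)
  res <- lrt_test(c(y, y), d, target = "DE")
  expect_lt(res$stat, 0.01)
  expect_gt(res$p_value, 0.9)
  expect_equal(res$df, 1)
  # swapping which group is the reference leaves the statistic unchanged
  set.seed(83)
  y2 <- c(zinb_sample(120, 0.2, 4, 2), zinb_sample(120, 0.2, 9, 2))
  d12 <- design_spec(rep(c("g1", "g2"), each = 120))
  d21 <- design_spec(rep(c("g2", "g1"), each = 120))
  r12 <- lrt_test(y2, d12, "DE")
  r21 <- lrt_test(y2, d21, "DE")
  expect_equal(r12$stat, r21$stat, tolerance = 1e-6)
  expect_equal(r12$lfc, -r21$lfc, tolerance = 1e-4)
  # DZI test runs on the same machinery
  rz <- lrt_test(y2, d12, "DZI")
  expect_gte(rz$stat, 0)
  expect_true(rz$p_value >= 0 && rz$p_value <= 1)
})

test_that("a strong planted mean shift is detected with high significance", {
  set.seed(84)
  y <- c(zinb_sample(200, 0.2, 4, 2), zinb_sample(200, 0.2, 12, 2))
  res <- lrt_test(y, two_group_design(200), "DE")
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$lfc_log2, 1)   # true log2 FC is log2(3) ~ 1.58
})

test_that("null p-values are approximately uniform", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 60, n_cells = 300, de_fraction = 0, dzi_fraction = 0,
    seed = 85))
  d <- design_spec(sim$cell_meta$group)
  res <- run_influence_tests(sim$observed, d,
                             capture = fixed_capture(sim$cell_meta$p))
  expect_gt(ks.test(res$de$p_value, "punif")$p.value, 0.01)
  expect_gt(ks.test(res$dzi$p_value, "punif")$p.value, 0.01)
  expect_true(all(res$de$p_adjusted >= res$de$p_value))
})

test_that("gene classification is the deterministic two-flag function", {
  de <- data.frame(gene_id = paste0("g", 1:4),
                   significant = c(TRUE, TRUE, FALSE, FALSE))
  dzi <- data.frame(gene_id = paste0("g", 1:4),
                    significant = c(TRUE, FALSE, TRUE, FALSE))
  cls <- classify_genes(de, dzi)
  expect_equal(cls$label,
               c("DEZI", "DE_only", "DZI_only", "non_influential"))
  # order-robust: shuffled dzi rows give the same labels
  cls2 <- classify_genes(de, dzi[c(3, 1, 4, 2), ])
  expect_equal(cls2$label, cls$label)
  # class sizes partition the gene set
  expect_equal(sum(attr(cls, "counts")), 4)
  expect_error(classify_genes(de, dzi[1:3, ]), "differ")
})

test_that("end-to-end influence testing classifies every gene exactly once", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 24, n_cells = 160, de_fraction = 0.25, de_lfc = log(6),
    dzi_fraction = 0.25, dzi_effect = 3, seed = 86))
  d <- design_spec(sim$cell_meta$group)
  res <- run_influence_tests(sim$observed, d,
                             capture = fixed_capture(sim$cell_meta$p))
  counts <- attr(res$classes, "counts")
  expect_equal(sum(counts), 24)
  expect_setequal(res$classes$gene_id, rownames(sim$observed))
  # labels agree with the two significance columns
  with(res$classes, {
    expect_true(all((label == "DEZI") == (de_significant & dzi_significant)))
    expect_true(all((label == "non_influential") ==
                      (!de_significant & !dzi_significant)))
  })
  # strong planted effects are found
  expect_gt(sum(res$classes$de_significant), 0)
})
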