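# zinbcapture

Zero-inflated negative binomial (ZINB) modeling of single-cell RNA-seq UMI
counts with an explicit molecular-capture layer.

Single-cell protocols recover only a fraction (often 1–10%) of the mRNA
molecules in each cell, so observed UMI counts are thinned versions of the
true transcript counts and many zeros are dropouts rather than silent
genes. `zinbcapture` is for analysts who want to model that process
directly: estimate gene-wise expression parameters corrected for per-cell
capture rates, test genes for differential expression (DE) and
differential zero inflation (DZI) between cell groups, pick the number of
cell clusters, and simulate data with known ground truth to validate any
of it.

## The model

True counts follow a zero-inflated negative binomial,

    Z_ij ~ ZINB(pi_ij, mu_ij, theta_j),

and observation is binomial capture with a per-cell rate p_i,

    Y_ij | Z_ij ~ Binomial(Z_ij, p_i).

The observed count is then again ZINB with only the mean rescaled:

    Y_ij ~ ZINB(pi_ij, mu_ij * p_i, theta_j),

so capture enters gene-wise generalized linear models as the offset
`log p_i` on the log-mean, while zero inflation `pi` and dispersion
`phi = 1/theta` are invariant to thinning. Both parameters carry covariate
structure,

    log mu'_ij   = x_i' gamma_j + r_i' w_j + c_i' s_j + O_mu,i
    logit pi_ij  = x_i' beta_j  + r_i' u_j + c_i' v_j + O_pi,i

(group contrasts `x`, cell-cluster contrasts `r`, cell-level covariates
`c`), fit per gene by an EM algorithm that treats component membership as
missing data, with a quasi-Newton polish to the exact maximum and a
Nelder–Mead fallback. DE tests the group block `gamma_1j`, DZI tests
`beta_1j`, each by a likelihood-ratio statistic against chi-square with
`L - 1` degrees of freedom, with Benjamini–Hochberg adjustment; genes are
classified as `DEZI`, `DE_only`, `DZI_only`, or `non_influential`.

Capture rates come either from external RNA spike-ins (per-cell OLS of
spike-in counts on known concentrations; the slope estimates `p_i`) or,
without spike-ins, by interpolating log10 library sizes over a range
`(rho1, rho2)`. A WSS/BSS index over k-means partitions selects the number
of cell clusters at the flattening point of its curve.

See the methods vignette (`vignettes/zinb-capture-model.Rmd`) for the
estimation details, the sampling-moment formulas (including a documented
discrepancy in the published variance formulas and the exact forms used
alongside them), and the design choices.

## Worked example

```r
library(zinbcapture)

# simulate 40 genes x 200 cells, two groups, known capture gradient
cfg <- simulation_config(n_genes = 40, n_cells = 200,
                         de_fraction = 0.2, dzi_fraction = 0.2, seed = 7)
sim <- simulate_dataset(cfg)

# estimate per-cell capture rates from library sizes
cap <- estimate_capture_librarysize(sim$cell_meta$library_size)

# gene-wise ZINB fits with capture offsets, then DE/DZI tests
design <- design_spec(sim$cell_meta$group)
res <- run_influence_tests(sim$observed, design, capture = cap)
print(res)
head(res$de[order(res$de$p_value),
            c("gene_id", "lfc_log2", "stat", "p_value", "p_adjusted")])
```

```
DE/DZI likelihood-ratio tests on 40 genes (alpha = 0.05 )

        DE_only            DEZI        DZI_only non_influential
              4               2               4              30

    gene_id  lfc_log2      stat      p_value   p_adjusted
8  gene_008 -1.415550 70.886348 3.784075e-17 1.513630e-15
36 gene_036 -1.359508 56.717971 5.030175e-14 1.006035e-12
11 gene_011  2.077673 20.490163 5.993851e-06 7.991801e-05
35 gene_035  1.923083 13.632490 2.223049e-04 2.223049e-03
9  gene_009  1.268249 11.343032 7.573158e-04 6.058526e-03
32 gene_032 -1.995091  8.239593 4.098632e-03 2.732421e-02
```

The simulation planted a two-fold-plus effect (`gamma_1 = log 3`, i.e.
|log2 FC| ≈ 1.58) in 20% of genes and a zero-inflation shift in another
20%. Six genes reach DE significance after BH adjustment (columns above:
estimated log2 fold change, LRT statistic, raw and adjusted p-value) —
their `lfc_log2` estimates scatter around ±1.6 as expected — and the four
class counts partition the 40 genes. With the true capture rates supplied
instead of the library-size estimate, the same pipeline recovers the same
leading genes; `sim$gene_truth` holds the planted truth for checking
either way.

The same pipeline is scriptable from a shell via the bundled CLI wrapper
(`inst/cli/zinbcapture.R`), with subcommands `simulate`, `capture`,
`cluster`, `fit`, `test`, `stats`.

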