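# shared fixtures: all data built in code, seeded

# intercept-only design for n cells
intercept_design <- function(n) design_spec(groups = rep("a", n))

# two balanced groups
two_group_design <- function(n_per_group) {
  design_spec(groups = rep(c("g1", "g2"), each = n_per_group))
}

# small seeded dataset shared by io/cli tests
tiny_sim <- function(n_genes = 20, n_cells = 60, seed = 101, ...) {
  simulate_dataset(simulation_config(n_genes = n_genes, n_cells = n_cells,
                                     seed = seed, ...))
}

# Monte-Carlo standard error of a mean
mc_se <- function(x) sd(x) / sqrt(length(x))
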