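# Small synthetic cohorts used across test files.

make_test_cohort <- function(n_nodes = 20, n_mdd = 10, n_hc = 10, seed = 1,
                             ...) {
  generate_cohort(simulation_config(n_nodes = n_nodes, n_mdd = n_mdd,
                                    n_hc = n_hc, seed = seed, ...))
}

# a short grid keeps multi-threshold tests fast
short_grid <- function() sparsity_grid(0.10, 0.30, 0.05)
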