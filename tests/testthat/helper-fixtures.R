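# Small shared fixtures, all generated in code.

# a compact abGC generator: fewer cells so per-cell fitting stays quick
small_abgc_config <- function(seed = 1L, cells = 4L) {
  generator_config("abGC", cells_per_condition = cells, seed = seed)
}

small_ca1_config <- function(seed = 1L, cells = 6L) {
  generator_config("CA1", cells_per_condition = cells, seed = seed)
}

# reference plasticity parameter vector used in closed-loop tests
theta_reference <- function() {
  c(stim_proportion = 0.5, mult_strength = 0.2, add_strength = 0.02,
    tau_stdp_ms = 0.5, pot_rate = 0.007, dep_rate_rel = 0.003)
}

# minimal-cost inference settings for structural (non-recovery) tests:
# 2 neurons x 50 inputs = 100 weights, a single noise step
tiny_settings <- function() {
  inference_settings(n_neurons = 2L, n_inputs = 50L, duration = 0.05,
                     dt_noise = 0.05, n_bins = 12L)
}
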