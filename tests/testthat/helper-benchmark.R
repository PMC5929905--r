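# The two-node benchmark: initial correlation 0.58, both SDs raised 20%
# (variances 1 -> 1.44, covariance unchanged at 0.58). The effective dof is
# taken from a 230-point weakly autocorrelated (AR(1) = 0.1) realization,
# the acquisition length the scenario emulates; the covariance summaries
# are the scenario's population values.
benchmark_summary <- function(seed) {
  sp <- two_node_scenario("none", n_timepoints = 230, autocorr = 0.1,
                          seed = seed)
  dof <- estimate_effective_dof(generate_state(sp, "A"))
  two_state_summary(
    state_covariance(1, 1, 0.58, 230, dof_eff = dof, state_label = "A"),
    state_covariance(1.44, 1.44, 0.58, 230, dof_eff = dof,
                     state_label = "B"))
}
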