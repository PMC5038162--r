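# Shared fixtures: coarse solver settings and small vascular beds keep the
# unit suite fast; the acceptance suite uses the full study conditions.

fast_settings <- function(n = 1024) solver_settings(n_per_period = n)

# beds terminating early so impedance spectra build in milliseconds
small_tree <- function(...) tree_params(r_min = 0.05, ...)

# a coarse coupled configuration on the three-segment network
coarse_coupled_config <- function(T0 = 30, n = 1024) {
  law <- tube_law_params(P0_mmHg = 40)
  net <- make_test_network("symmetric_bifurcation", law)
  lvsa_config(
    net = net, tree = small_tree(),
    lv = reduced_lv(actp = activation_params(T0 = T0)),
    solver = fast_settings(n),
    coupling = coupling_settings(init_periods = 2, max_cycles = 4),
    inflow = make_inflow(SV = 72.6, Q_peak = 532, t_ej = 0.22, period = 0.9))
}
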