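# Shared helpers: small purpose-built cells/networks and memoized scenario
# runs so that several test files can share one expensive simulation.

.run_cache <- new.env(parent = emptyenv())

cached_scenario_run <- function(name, seed) {
  key <- paste0(name, "_", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_scenario(name, seed = seed)
  .run_cache[[key]]
}

# parameter list with a single passive compartment in place of the basket
passive_soma_params <- function(leak = 0.1, e_leak = -65,
                                length = 39, diam = 20) {
  p <- cdg_parameters()
  p$channels$basket$default <- list(leak = leak)
  p$leak_reversal$basket <- e_leak
  p$fs_kinetics$basket <- FALSE
  p$geometry$basket <- list(list(name = "soma", length = length, diam = diam,
                                 parent = NULL, z_factor = 1.0))
  p
}

# passive three-compartment chain built on the basket slot
passive_chain_params <- function(leak = 0.1, e_leak = -65) {
  p <- passive_soma_params(leak, e_leak)
  p$geometry$basket <- list(
    list(name = "soma", length = 40, diam = 10, parent = NULL, z_factor = 1.0),
    list(name = "mid", length = 60, diam = 4, parent = "soma", z_factor = 1.0),
    list(name = "tip", length = 60, diam = 2, parent = "mid", z_factor = 1.0))
  p
}

# small, fast E-I network for structural and determinism tests
tiny_network <- function(g_ei = 9.1e-4, g_ie = 8e-2, g_ii = 7.5e-3,
                         n_pyr = 9, n_inh = 4, layer = "L5") {
  cfg <- network_config(layer, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
                        n_pyr = n_pyr, n_inh = n_inh, space_constant = 3.5)
  build_network(layer, cfg)
}
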