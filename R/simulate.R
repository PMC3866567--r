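#' Run a network simulation
#'
#' Integrates the configured simulation with the fixed-step scheme
#' (exponential Euler gating, implicit cable coupling) at the output time
#' step, detecting spikes online (0 mV upward somatic crossings, 1 ms
#' refractory) and delivering synaptic events through the network's
#' connections.  The per-layer current dipole and the aggregate somatic
#' GABA-A current are accumulated during integration.
#'
#' @param sim A `cdg_simulation` from [attach_drives()] (or a `cdg_network`,
#'   in which case no drives are attached).
#' @param duration Simulated time, ms.
#' @param dt Time step, ms.
#' @param seed Integer seed controlling all stochastic drives.
#' @param v_init Initial membrane voltage, mV (gating at steady state); by
#'   default each compartment starts at its settled resting potential.
#' @param record_soma Record somatic voltages of all cells.
#' @param record_nodes Optional integer vector of node indices (1-based rows
#'   of `network$nodes`) whose voltages are recorded in full.
#' @return A `cdg_run` bundle: `time` (ms), `dipole` (a `cdg_dipole` with
#'   per-layer and aggregate CD in nAm), `spikes` (list per cell), `cells`,
#'   `gaba_current` (nA per layer), `events` (exogenous events), `soma_v`,
#'   `seed`, and the simulation definition.
#' @export
simulate <- function(sim, duration = 550, dt = 0.025, seed = 1,
                     v_init = NULL, record_soma = TRUE, record_nodes = integer(0)) {
  if (inherits(sim, "cdg_network")) sim <- attach_drives(sim, list())
  stopifnot(inherits(sim, "cdg_simulation"))
  if (dt <= 0) stop("dt must be positive")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) stop("duration must be a multiple of dt")
  n_steps <- as.integer(round(n_steps))

  net <- sim$network
  nodes <- net$nodes
  cells <- net$cells
  syn <- net$syn
  layers <- net$layers
  layer_idx <- match(cells$layer, layers) - 1L

  dr <- .resolve_drives(sim, duration, dt, seed)
  ev <- dr$events
  ord <- order(ev$time)
  ev <- ev[ord, , drop = FALSE]

  conns <- net$connections
  engine_net <- list(
    parent = as.integer(nodes$parent), r_ax = .na0(nodes$r_ax),
    cap = nodes$cap, z = nodes$z,
    g = as.matrix(nodes[, .CHAN]), e_leak = nodes$e_leak,
    vshift = nodes$vshift, fs = nodes$fs,
    e_rev = .e_rev(net$params),
    ca_factor = nodes$ca_factor, ca_tau = net$params$calcium_pool$tau,
    ca0 = net$params$calcium_pool$ca0,
    cell = as.integer(nodes$cell - 1L), soma_node = as.integer(net$soma_node),
    cell_layer = layer_idx,
    cell_is_pyr = cells$type == "pyramidal",
    n_layers = length(layers), node_label = nodes$label,
    syn_tau_r = syn$rise, syn_tau_d = syn$decay, syn_e = syn$e,
    gaba_classes = which(syn$name == "gabaa") - 1L,
    conn_pre = as.integer(conns$pre - 1L),
    conn_node = as.integer(conns$post_node),
    conn_class = as.integer(match(conns$receptor, syn$name) - 1L),
    conn_w = conns$weight,
    conn_delay_steps = as.integer(round(conns$delay / dt)))
  engine_run <- list(
    exo_step = as.integer(round(ev$time / dt)), exo_node = as.integer(ev$node),
    exo_class = rep(0L, nrow(ev)), exo_w = ev$weight,
    iapp = dr$iapp, inj_node = integer(0), inj_I = matrix(0, n_steps + 1, 0),
    dt = dt, n_steps = n_steps,
    v_init = if (is.null(v_init)) nodes$v_rest else rep(v_init, nrow(nodes)),
    record_nodes = as.integer(record_nodes - 1L),
    record_soma = record_soma, record_gaba = TRUE,
    spike_threshold = 0, refractory = 1)

  out <- .engine_simulate(engine_net, engine_run)

  dip <- as.data.frame(out$dipole)
  names(dip) <- layers
  dipole <- dipole_ts(time = out$time, layer_cd = dip,
                      n_pyr = vapply(layers, function(l)
                        sum(cells$layer == l & cells$type == "pyramidal"), 0),
                      metadata = list(seed = seed, dt = dt))

  gaba <- as.data.frame(out$gaba_current)
  names(gaba) <- layers

  structure(list(time = out$time, dipole = dipole, spikes = out$spikes,
                 cells = cells, gaba_current = gaba,
                 soma_v = out$soma_v, v = out$v, events = ev,
                 duration = duration, dt = dt, seed = seed,
                 network = net, drives = sim$drives),
            class = "cdg_run")
}

#' @export
print.cdg_run <- function(x, ...) {
  nsp <- sum(lengths(x$spikes))
  cat("<cdg_run>", x$duration, "ms, dt", x$dt, "ms,",
      nrow(x$cells), "cells,", nsp, "spikes\n")
  invisible(x)
}

#' Per-cell firing rates
#'
#' @param run A `cdg_run`.
#' @param window Analysis window `c(start, end)` in ms.
#' @param type Cell type to include.
#' @param layer Optional layer filter.
#' @return Numeric vector of rates in Hz, one per cell.
#' @export
firing_rates <- function(run, window = c(50, 550), type = "pyramidal",
                         layer = NULL) {
  keep <- run$cells$type == type
  if (!is.null(layer)) keep <- keep & run$cells$layer == layer
  n <- vapply(run$spikes[keep], function(s)
    sum(s >= window[1] & s <= window[2]), 0)
  n / diff(window) * 1000
}
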