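#' Build a cell model
#'
#' Constructs one of the three cell types of the laminar column model: a
#' reduced-morphology layer 2/3 pyramidal cell, a layer 5 pyramidal cell, or a
#' single-compartment fast-spiking basket interneuron.  Pyramidal cells have a
#' soma, apical compartments oriented orthogonally to the laminae, one oblique
#' dendrite parallel to the laminae (which does not contribute to the current
#' dipole), and three basilar compartments; the L5 cell carries one additional
#' apical compartment and its summed apical-axis extent is exactly 2.21 times
#' that of the L2/3 cell (the L2/3 apical lengths are rescaled at build time to
#' enforce the ratio).
#'
#' Compartments longer than 100 um are discretized with one additional
#' internal point, so they are represented by two series segments in the cable
#' equation.
#'
#' @param kind One of `"l23_pyramidal"`, `"l5_pyramidal"`, `"basket"`.
#' @param params Parameter list from [cdg_parameters()].
#' @return An object of class `cdg_cell` with elements `kind`, `compartments`
#'   (geometry table with per-compartment `z_projection` in um and
#'   `axial_resistance` in MOhm), `nodes` (the discretized segment table used
#'   by the integrator) and `channels` (per-compartment conductance densities
#'   in mS/cm^2).
#' @export
build_cell <- function(kind = c("l23_pyramidal", "l5_pyramidal", "basket"),
                       params = cdg_parameters()) {
  if (length(kind) != 1L || !kind %in% c("l23_pyramidal", "l5_pyramidal", "basket"))
    stop("unknown cell kind '", paste(kind, collapse = ","),
         "'; must be one of l23_pyramidal, l5_pyramidal, basket")
  geo <- params$geometry[[kind]]
  comps <- do.call(rbind, lapply(geo, function(g)
    data.frame(name = g$name, length = g$length, diam = g$diam,
               parent = if (is.null(g$parent)) NA_character_ else g$parent,
               z_factor = g$z_factor, stringsAsFactors = FALSE)))

  if (kind == "l23_pyramidal") {
    # rescale apical compartments so the L5/L2 apical-axis extent ratio is exact
    l5 <- params$geometry$l5_pyramidal
    l5_extent <- sum(vapply(l5, function(g) g$length * max(g$z_factor, 0), 0))
    apical <- grepl("^apical", comps$name) & comps$z_factor > 0
    soma_l <- comps$length[comps$name == "soma"]
    target <- l5_extent / params$apical_extent_ratio_l5_l23
    scale <- (target - soma_l) / sum(comps$length[apical])
    comps$length[apical] <- comps$length[apical] * scale
  }
  comps$z_projection <- comps$length * comps$z_factor
  comps$n_internal_points <- ifelse(comps$length > params$extra_point_length, 2L, 1L)

  ra <- params$axial_resistivity # ohm cm
  # full-compartment axial resistance, MOhm
  comps$axial_resistance <- ra * (comps$length * 1e-4) /
    (pi * (comps$diam / 2 * 1e-4)^2) / 1e6

  chans <- params$channels[[kind]]
  chan_of <- function(nm) {
    d <- chans$default
    if (!is.null(chans[[nm]])) d <- utils::modifyList(d, chans[[nm]])
    d
  }
  channel_list <- lapply(comps$name, chan_of)
  names(channel_list) <- comps$name

  cm <- params$capacitance[[kind]]
  e_leak <- params$leak_reversal[[kind]]

  cell <- structure(list(kind = kind, compartments = comps,
                         channels = channel_list, cm = cm, e_leak = e_leak,
                         params = params),
                    class = "cdg_cell")
  cell$nodes <- .cell_nodes(cell)
  cell$nodes$v_rest <- .settle_rest(cell)
  cell
}

# Relax a drive-free cell to its stationary resting state and return the
# per-node voltages, used to initialize simulations without onset transients.
.settle_rest <- function(cell, duration = 600, dt = 0.05) {
  nodes <- cell$nodes
  N <- nrow(nodes)
  syn <- .syn_classes(cell$params)
  net <- list(
    parent = as.integer(nodes$parent), r_ax = .na0(nodes$r_ax),
    cap = nodes$cap, z = nodes$z,
    g = as.matrix(nodes[, .CHAN]), e_leak = nodes$e_leak,
    vshift = nodes$vshift, fs = nodes$fs,
    e_rev = .e_rev(cell$params),
    ca_factor = nodes$ca_factor, ca_tau = cell$params$calcium_pool$tau,
    ca0 = cell$params$calcium_pool$ca0,
    cell = rep(0L, N), soma_node = which(nodes$is_soma)[1] - 1L,
    cell_layer = 0L, cell_is_pyr = cell$kind != "basket", n_layers = 1L,
    node_label = nodes$label,
    syn_tau_r = syn$rise, syn_tau_d = syn$decay, syn_e = syn$e,
    gaba_classes = which(syn$name == "gabaa") - 1L,
    conn_pre = integer(0), conn_node = integer(0), conn_class = integer(0),
    conn_w = numeric(0), conn_delay_steps = integer(0))
  n_steps <- as.integer(duration / dt)
  run <- list(exo_step = integer(0), exo_node = integer(0),
              exo_class = integer(0), exo_w = numeric(0),
              iapp = rep(0, N), inj_node = integer(0),
              inj_I = matrix(0, n_steps + 1, 0),
              dt = dt, n_steps = n_steps, v_init = rep(-65, N),
              record_nodes = seq_len(N) - 1L, record_soma = FALSE,
              record_gaba = FALSE, spike_threshold = 0, refractory = 1)
  out <- .engine_simulate(net, run)
  as.numeric(out$v[n_steps + 1, ])
}

# Channel column order shared with the C++ engine
.CHAN <- c("na", "k", "leak", "kdr", "km", "ca", "h", "cat", "kca")

# Discretize a cell into cable segments ("nodes").  Each compartment becomes
# n_internal_points series segments; the parent of a compartment's first node
# is the last node of its parent compartment.  Returns a data.frame with
# 0-based `parent` indices, coupling resistances to the parent node (MOhm,
# half-segment + half-parent-segment), per-node membrane area (cm^2),
# capacitance (nF), signed z projection (um) and absolute channel conductances
# (uS).
.cell_nodes <- function(cell) {
  comps <- cell$compartments
  rows <- list()
  last_node_of <- integer(0)
  idx <- 0L
  seg_r_half <- numeric(0) # half-resistance of each node's segment
  for (ci in seq_len(nrow(comps))) {
    cp <- comps[ci, ]
    n <- cp$n_internal_points
    lseg <- cp$length / n
    area <- pi * cp$diam * lseg * 1e-8          # cm^2
    capn <- cell$cm * area * 1e3                # nF
    rseg <- cp$axial_resistance / n             # MOhm per segment
    dens <- cell$channels[[cp$name]]
    gabs <- vapply(.CHAN, function(ch) {
      d <- dens[[ch]]
      if (is.null(d)) 0 else d * area * 1e3     # uS
    }, 0)
    for (s in seq_len(n)) {
      idx <- idx + 1L
      if (s == 1L) {
        if (is.na(cp$parent)) {
          pn <- -1L; rcouple <- NA_real_
        } else {
          pn <- last_node_of[[cp$parent]]
          rcouple <- rseg / 2 + seg_r_half[pn + 1L]
        }
      } else {
        pn <- idx - 2L
        rcouple <- rseg
      }
      rows[[idx]] <- data.frame(
        comp = cp$name, seg = s,
        label = paste0(cp$name, if (n > 1L) paste0(".", s) else ""),
        parent = pn, r_ax = rcouple,
        area = area, cap = capn,
        z = cp$z_projection / n,
        is_soma = identical(cp$name, "soma") && s == 1L,
        stringsAsFactors = FALSE)
      rows[[idx]] <- cbind(rows[[idx]], as.data.frame(as.list(gabs)))
      seg_r_half <- c(seg_r_half, rseg / 2)
    }
    last_node_of[[cp$name]] <- idx - 1L
  }
  nodes <- do.call(rbind, rows)
  nodes$e_leak <- cell$e_leak
  vsh <- cell$params$kinetics_vshift[[cell$kind]]
  nodes$vshift <- if (is.null(vsh)) 0 else vsh
  fsk <- cell$params$fs_kinetics[[cell$kind]]
  nodes$fs <- if (isTRUE(fsk)) 1 else 0
  # calcium pool on compartments carrying Ca channels
  capar <- cell$params$calcium_pool
  nodes$ca_factor <- ifelse(nodes$ca > 0 | nodes$cat > 0,
                            capar$influx_scale / nodes$area, 0)
  rownames(nodes) <- NULL
  nodes
}

#' @export
print.cdg_cell <- function(x, ...) {
  cat("<cdg_cell>", x$kind, "-", nrow(x$compartments), "compartments,",
      nrow(x$nodes), "segments\n")
  invisible(x)
}

#' Apical-axis extent of a cell (um)
#'
#' Summed length projected on the apical (pia-directed) axis over the soma and
#' apical compartments.
#' @param cell A `cdg_cell`.
#' @return Extent in um.
#' @export
apical_extent <- function(cell) {
  comps <- cell$compartments
  sum(comps$z_projection[comps$z_projection > 0])
}

#' Integrate a single cell
#'
#' Runs the fixed-step integrator (exponential Euler gating, implicit cable
#' coupling) for one isolated cell with optional injected currents and
#' synaptic events.
#'
#' @param model A `cdg_cell` from [build_cell()].
#' @param inputs A list with optional elements `I` (named list mapping
#'   compartment name to a constant current in nA or a vector of length
#'   `duration/dt + 1`) and `events` (data.frame with columns `time` (ms),
#'   `comp`, `weight` (uS) and optionally `receptor`, `"ampa"` by default).
#' @param dt Time step, ms.
#' @param duration Total simulated time, ms; must be a multiple of `dt`.
#' @param v_init Initial voltage (mV) for all compartments; gating variables
#'   start at their steady state for this voltage.
#' @return A list with `time` (ms), `v` (matrix, time x segment, mV, columns
#'   labelled by segment), `spikes` (soma spike times, ms) and `dipole`
#'   (single-cell current dipole, nAm).
#' @export
integrate_cell <- function(model, inputs = list(), dt = 0.025, duration = 550,
                           v_init = NULL) {
  stopifnot(inherits(model, "cdg_cell"))
  if (dt <= 0) stop("dt must be positive")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration must be a multiple of dt")
  n_steps <- as.integer(round(n_steps))

  nodes <- model$nodes
  N <- nrow(nodes)
  syn <- .syn_classes(model$params)

  inj_node <- integer(0)
  inj_I <- matrix(0, n_steps + 1, 0)
  if (!is.null(inputs$I)) {
    for (nm in names(inputs$I)) {
      k <- which(nodes$comp == nm & nodes$seg == 1L)
      if (length(k) == 0) stop("no compartment named '", nm, "'")
      cur <- inputs$I[[nm]]
      if (length(cur) == 1L) cur <- rep(cur, n_steps + 1)
      if (length(cur) != n_steps + 1)
        stop("current trace for '", nm, "' must have length duration/dt + 1")
      inj_node <- c(inj_node, k - 1L)
      inj_I <- cbind(inj_I, cur)
    }
  }

  exo <- list(step = integer(0), node = integer(0), class = integer(0), w = numeric(0))
  if (!is.null(inputs$events) && nrow(inputs$events) > 0) {
    ev <- inputs$events
    if (is.null(ev$receptor)) ev$receptor <- "ampa"
    cls <- match(ev$receptor, syn$name) - 1L
    if (anyNA(cls)) stop("unknown receptor in events")
    nodei <- vapply(ev$comp, function(nm) {
      k <- which(nodes$comp == nm)
      if (length(k) == 0) stop("no compartment named '", nm, "'")
      k[ceiling(length(k) / 2)] - 1L
    }, 0L)
    exo <- list(step = as.integer(round(ev$time / dt)), node = as.integer(nodei),
                class = cls, w = ev$weight)
  }

  net <- list(
    parent = as.integer(nodes$parent), r_ax = .na0(nodes$r_ax),
    cap = nodes$cap, z = nodes$z,
    g = as.matrix(nodes[, .CHAN]), e_leak = nodes$e_leak,
    vshift = nodes$vshift, fs = nodes$fs,
    e_rev = .e_rev(model$params),
    ca_factor = nodes$ca_factor, ca_tau = model$params$calcium_pool$tau,
    ca0 = model$params$calcium_pool$ca0,
    cell = rep(0L, N), soma_node = which(nodes$is_soma)[1] - 1L,
    cell_layer = 0L, cell_is_pyr = model$kind != "basket", n_layers = 1L,
    node_label = nodes$label,
    syn_tau_r = syn$rise, syn_tau_d = syn$decay, syn_e = syn$e,
    gaba_classes = which(syn$name == "gabaa") - 1L,
    conn_pre = integer(0), conn_node = integer(0), conn_class = integer(0),
    conn_w = numeric(0), conn_delay_steps = integer(0))
  run <- list(
    exo_step = exo$step, exo_node = exo$node, exo_class = exo$class, exo_w = exo$w,
    iapp = rep(0, N), inj_node = inj_node, inj_I = inj_I,
    dt = dt, n_steps = n_steps,
    v_init = if (is.null(v_init)) nodes$v_rest else rep(v_init, N),
    record_nodes = seq_len(N) - 1L, record_soma = TRUE, record_gaba = FALSE,
    spike_threshold = 0, refractory = 1)

  out <- .engine_simulate(net, run)
  v <- out$v
  colnames(v) <- nodes$label
  list(time = out$time, v = v, spikes = out$spikes[[1]],
       dipole = out$dipole[, 1])
}

.na0 <- function(x) { x[is.na(x)] <- 0; x }

.syn_classes <- function(params) {
  s <- params$synapses
  list(name = c("ampa", "gabaa"),
       rise = c(s$ampa$rise_tau, s$gabaa$rise_tau),
       decay = c(s$ampa$decay_tau, s$gabaa$decay_tau),
       e = c(s$ampa$reversal, s$gabaa$reversal))
}

.e_rev <- function(params) {
  unlist(params$reversal[c("na", "k", "ca", "h")], use.names = FALSE)
}

#' Detect spikes in a voltage trajectory
#'
#' Upward crossings of a threshold; crossings closer than 1 ms are coalesced
#' into one spike (refractory coalescing).
#'
#' @param v Voltage trace, mV, on a fixed time grid.
#' @param time Time grid, ms (or scalar `dt` if `is_dt = TRUE`).
#' @param threshold Threshold, mV (default 0).
#' @param refractory Minimum separation between reported spikes, ms.
#' @return Strictly increasing spike times, ms (possibly empty).
#' @export
detect_spikes <- function(v, time, threshold = 0, refractory = 1) {
  stopifnot(length(v) == length(time))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  tt <- time[up]
  if (length(tt) <= 1) return(tt)
  # coalesce runs: each crossing is kept only if the last kept spike is older
  # than the refractory interval
  res <- tt[1]
  for (i in seq_along(tt)[-1]) if (tt[i] - res[length(res)] >= refractory) res <- c(res, tt[i])
  res
}
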