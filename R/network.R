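#' Network configuration for one layer
#'
#' Holds the population sizes, synaptic strengths and weight space constant
#' for a single-layer E-I network.  Populations are 100 pyramidal (E) cells on
#' a 10 x 10 grid and 35 fast-spiking basket (I) cells interleaved on the same
#' grid extent.  Synaptic maximal conductances are per-connection values in uS
#' (the convention of event-driven point synapses); connectivity is
#' all-to-all with strengths scaled by a Gaussian of grid distance.
#'
#' @param layer `"L2"` or `"L5"`.
#' @param g_ei AMPA conductance, E soma -> I soma, uS.
#' @param g_ie GABA-A conductance, I -> E soma, uS.
#' @param g_ii GABA-A conductance, I -> I soma, uS (0 disables I-I wiring, as
#'   in the strong-PING regime).
#' @param n_pyr,n_inh Population counts.
#' @param space_constant Weight space constant, grid units.
#' @param regime Free-text regime label.
#' @return An object of class `cdg_network_config`.
#' @export
network_config <- function(layer = c("L5", "L2"), g_ei, g_ie, g_ii = 0,
                           n_pyr = 100, n_inh = 35, space_constant = 3,
                           regime = "") {
  layer <- match.arg(layer)
  if (any(c(g_ei, g_ie, g_ii) < 0)) stop("synaptic conductances must be >= 0")
  if (space_constant <= 0) stop("space_constant must be positive")
  structure(list(layer = layer, g_ei = g_ei, g_ie = g_ie, g_ii = g_ii,
                 n_pyr = n_pyr, n_inh = n_inh, space_constant = space_constant,
                 regime = regime),
            class = "cdg_network_config")
}

#' Table 1 PING regimes
#'
#' Named synaptic/drive parameter sets for the shipped strong and weak PING
#' regimes.  Conductances in uS, currents in model current units (nA), Poisson
#' rates in Hz.  The weak-PING L5 regime ships in two variants differing in
#' `g_pois` (1e-2 and 0.75e-2).
#'
#' @param regime One of `"l5_strong"`, `"l5_weak"`, `"l5_weak_gpois075"`,
#'   `"l2_weak"`.
#' @return List with `config` (a [network_config()]) and `drive` parameters.
#' @export
ping_regime <- function(regime = c("l5_strong", "l5_weak", "l5_weak_gpois075",
                                   "l2_weak")) {
  regime <- match.arg(regime)
  switch(regime,
    l5_strong = list(
      config = network_config("L5", g_ei = 6e-5, g_ie = 3e-1, g_ii = 0,
                              space_constant = 2.5, regime = "strong PING"),
      drive = list(type = "tonic", i_app = 6)),
    l5_weak = list(
      config = network_config("L5", g_ei = 9.1e-4, g_ie = 8e-2, g_ii = 7.5e-3,
                              space_constant = 3.5, regime = "weak PING"),
      drive = list(type = "poisson", rate = 40, g_pois = 1e-2)),
    l5_weak_gpois075 = list(
      config = network_config("L5", g_ei = 9.1e-4, g_ie = 8e-2, g_ii = 7.5e-3,
                              space_constant = 3.5, regime = "weak PING"),
      drive = list(type = "poisson", rate = 40, g_pois = 0.75e-2)),
    l2_weak = list(
      config = network_config("L2", g_ei = 1.2e-3, g_ie = 7e-3, g_ii = 1e-2,
                              space_constant = 3.5, regime = "weak PING"),
      drive = list(type = "poisson", rate = 140, g_pois = 0.8e-3)))
}

#' Distance-dependent synaptic weight scaling
#'
#' Gaussian kernel `exp(-d^2 / lambda^2)` on grid distance: 1 at distance 0
#' and strictly decreasing, so connectivity is effectively all-to-all with
#' distance-scaled strengths.
#'
#' @param distance Distance in grid units (>= 0).
#' @param space_constant Space constant lambda, grid units (> 0).
#' @return Multiplier in (0, 1].
#' @export
weight_scale <- function(distance, space_constant) {
  if (any(space_constant <= 0)) stop("space constant must be positive")
  if (any(distance < 0)) stop("distance must be >= 0")
  exp(-(distance^2) / space_constant^2)
}

# grid positions: E cells on a 10x10 integer lattice, I cells interleaved on a
# 6x6 lattice over the same extent with the last position dropped (35 cells)
.grid_positions <- function(n_pyr, n_inh) {
  side <- ceiling(sqrt(n_pyr))
  e <- expand.grid(x = seq_len(side) - 1, y = seq_len(side) - 1)[seq_len(n_pyr), ]
  iside <- ceiling(sqrt(n_inh))
  ig <- expand.grid(x = seq(0.5, side - 1.5, length.out = iside),
                    y = seq(0.5, side - 1.5, length.out = iside))
  i <- ig[seq_len(n_inh), ]
  list(e = e, i = i)
}

#' Build a one- or two-layer E-I network
#'
#' Wires pyramidal and basket cells within each requested layer: E -> I AMPA
#' and I -> E GABA-A synapses on somatic compartments, plus I -> I GABA-A
#' where `g_ii > 0` (weak PING).  There are no excitatory-excitatory and no
#' interlaminar synapses; requesting them is an error.
#'
#' @param layers Character vector, subset of `c("L2", "L5")`.
#' @param config A single [network_config()] (for one layer) or a named list
#'   of configs keyed by layer.
#' @param allow_ee,interlaminar Must remain `FALSE`; present so that the
#'   restriction is explicit.
#' @return An object of class `cdg_network` with cell, node and connection
#'   tables ready for [simulate()].
#' @export
build_network <- function(layers, config, allow_ee = FALSE, interlaminar = FALSE) {
  if (isTRUE(allow_ee)) stop("E-E connections are not part of this model")
  if (isTRUE(interlaminar)) stop("interlaminar connections are not part of this model")
  if (!all(layers %in% c("L2", "L5"))) stop("layers must be a subset of c('L2','L5')")
  if (inherits(config, "cdg_network_config")) {
    config <- stats::setNames(list(config), config$layer)
  }
  if (!all(layers %in% names(config)))
    stop("missing config for layer(s): ",
         paste(setdiff(layers, names(config)), collapse = ", "))

  params <- cdg_parameters()
  models <- list(l23_pyramidal = build_cell("l23_pyramidal", params),
                 l5_pyramidal = build_cell("l5_pyramidal", params),
                 basket = build_cell("basket", params))
  syn <- .syn_classes(params)
  delay <- params$synapses$delivery_delay

  cells <- list(); nodes <- list(); conns <- list()
  cell_id <- 0L; node_off <- 0L

  for (ly in layers) {
    cf <- config[[ly]]
    if (!inherits(cf, "cdg_network_config")) stop("config for ", ly, " is not a network_config")
    if (cf$layer != ly) stop("config layer mismatch for ", ly)
    pos <- .grid_positions(cf$n_pyr, cf$n_inh)
    pyr_kind <- if (ly == "L5") "l5_pyramidal" else "l23_pyramidal"

    ids_e <- cell_id + seq_len(cf$n_pyr)
    ids_i <- cell_id + cf$n_pyr + seq_len(cf$n_inh)
    cells[[ly]] <- data.frame(
      cell = c(ids_e, ids_i),
      layer = ly,
      type = rep(c("pyramidal", "basket"), c(cf$n_pyr, cf$n_inh)),
      kind = rep(c(pyr_kind, "basket"), c(cf$n_pyr, cf$n_inh)),
      x = c(pos$e$x, pos$i$x), y = c(pos$e$y, pos$i$y),
      stringsAsFactors = FALSE)

    for (k in seq_len(cf$n_pyr + cf$n_inh)) {
      cid <- cell_id + k
      kind <- if (k <= cf$n_pyr) pyr_kind else "basket"
      nd <- models[[kind]]$nodes
      nd$cell <- cid
      nd$parent <- ifelse(nd$parent < 0, -1L, nd$parent + node_off)
      nd$label <- sprintf("%s.c%d.%s", ly, cid, nd$label)
      nodes[[length(nodes) + 1L]] <- nd
      node_off <- node_off + nrow(nd)
    }

    # distance matrices (grid units, periodic lattice)
    wrap <- params$grid_wrap %||% 10
    d_ei <- .pdist(pos$e, pos$i, wrap)
    d_ii <- .pdist(pos$i, pos$i, wrap)
    lam <- cf$space_constant

    # E -> I (AMPA on basket soma)
    conns[[length(conns) + 1L]] <- data.frame(
      pre = rep(ids_e, times = cf$n_inh),
      post_cell = rep(ids_i, each = cf$n_pyr),
      receptor = "ampa",
      weight = cf$g_ei * weight_scale(as.vector(d_ei), lam),
      delay = delay, stringsAsFactors = FALSE)
    # I -> E (GABA-A on pyramidal soma)
    conns[[length(conns) + 1L]] <- data.frame(
      pre = rep(ids_i, each = cf$n_pyr),
      post_cell = rep(ids_e, times = cf$n_inh),
      receptor = "gabaa",
      weight = cf$g_ie * weight_scale(as.vector(d_ei), lam),
      delay = delay, stringsAsFactors = FALSE)
    # I -> I (GABA-A, weak PING only)
    if (cf$g_ii > 0) {
      ii <- expand.grid(pre = ids_i, post_cell = ids_i)
      ii <- ii[ii$pre != ii$post_cell, , drop = FALSE]
      if (nrow(ii) > 0) {
        dist_ii <- d_ii[cbind(ii$pre - cf$n_pyr - cell_id,
                              ii$post_cell - cf$n_pyr - cell_id)]
        conns[[length(conns) + 1L]] <- data.frame(
          pre = ii$pre, post_cell = ii$post_cell, receptor = "gabaa",
          weight = cf$g_ii * weight_scale(dist_ii, lam),
          delay = delay, stringsAsFactors = FALSE)
      }
    }
    cell_id <- cell_id + cf$n_pyr + cf$n_inh
  }

  cells <- do.call(rbind, cells); rownames(cells) <- NULL
  nodes <- do.call(rbind, nodes); rownames(nodes) <- NULL
  conns <- if (length(conns)) do.call(rbind, conns) else
    data.frame(pre = integer(0), post_cell = integer(0), receptor = character(0),
               weight = numeric(0), delay = numeric(0))
  rownames(conns) <- NULL

  soma_node <- vapply(seq_len(nrow(cells)), function(c)
    which(nodes$cell == c & nodes$is_soma)[1] - 1L, 0L)
  conns$post_node <- soma_node[conns$post_cell] # all network synapses are somatic

  structure(list(layers = layers, config = config, cells = cells,
                 nodes = nodes, connections = conns, soma_node = soma_node,
                 models = models, syn = syn, params = params),
            class = "cdg_network")
}

# Toroidal (periodic) grid distance: the lattice wraps at `wrap` grid units,
# which removes edge effects so the connectivity is translation invariant.
.pdist <- function(a, b, wrap = 10) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    dx <- abs(a$x[i] - b$x[j]); dx <- pmin(dx, wrap - dx)
    dy <- abs(a$y[i] - b$y[j]); dy <- pmin(dy, wrap - dy)
    sqrt(dx^2 + dy^2)
  })
}

#' @export
print.cdg_network <- function(x, ...) {
  cat("<cdg_network>", paste(x$layers, collapse = "+"), "-",
      nrow(x$cells), "cells,", nrow(x$nodes), "segments,",
      nrow(x$connections), "synapses\n")
  invisible(x)
}

#' Synaptic conductance traces from presynaptic spike times
#'
#' Converts spike times into the two-exponential conductance transient of the
#' requested receptor: each spike adds, after the delivery delay, a transient
#' `w * f * (exp(-t/tau_decay) - exp(-t/tau_rise))` normalized so its peak is
#' `w`.  Events superpose linearly.
#'
#' @param spike_times Presynaptic spike times, ms.
#' @param receptor `"ampa"` or `"gabaa"`.
#' @param weight Peak conductance per event, uS.
#' @param duration,dt Output grid, ms.
#' @param delay Delivery delay, ms.
#' @param params Parameter list.
#' @return data.frame with `time` (ms) and `g` (uS), nonnegative everywhere.
#' @export
syn_conductance <- function(spike_times, receptor = c("ampa", "gabaa"),
                            weight = 1, duration = 100, dt = 0.025,
                            delay = NULL, params = cdg_parameters()) {
  receptor <- match.arg(receptor)
  syn <- params$synapses[[receptor]]
  if (is.null(delay)) delay <- params$synapses$delivery_delay
  tr <- syn$rise_tau; td <- syn$decay_tau
  tp <- (td * tr / (td - tr)) * log(td / tr)
  f <- 1 / (exp(-tp / td) - exp(-tp / tr))
  tgrid <- seq(0, duration, by = dt)
  g <- numeric(length(tgrid))
  for (ts in spike_times) {
    rel <- tgrid - ts - delay
    on <- rel >= 0
    g[on] <- g[on] + weight * f * (exp(-rel[on] / td) - exp(-rel[on] / tr))
  }
  data.frame(time = tgrid, g = g)
}

#' Export the network as an edge list
#'
#' @param network A `cdg_network`.
#' @param path Optional file; when given, the edge list is written as
#'   tab-delimited text.
#' @return data.frame with pre id, post id, transmitter, weight (uS), delay (ms).
#' @export
network_edges <- function(network, path = NULL) {
  edges <- network$connections[, c("pre", "post_cell", "receptor", "weight", "delay")]
  names(edges) <- c("pre", "post", "transmitter", "weight", "delay")
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  edges
}
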