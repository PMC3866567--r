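#' Exogenous drive constructors
#'
#' Three classes of exogenous input drive the network: a tonic somatic current
#' to the pyramidal cells (strong PING), independent Poisson trains of AMPA
#' events to each pyramidal cell (weak PING), and rhythmic Gaussian-burst
#' AMPA inputs shared by all pyramidal cells of a layer (subthreshold driven
#' gamma).  Proximal bursts contact the apical oblique dendrite and both
#' basal dendrites branching from the basal trunk; distal bursts contact the
#' most distal apical compartment.  Distal burst cycle means lag the proximal
#' cycle means by `lag` ms.
#'
#' @param i_app Tonic current per pyramidal soma, model current units
#'   (converted to nA by the parameter file's `current_unit`).
#' @param rate Poisson rate per cell, Hz.
#' @param g_max Peak synaptic conductance per event, uS.
#' @param f Burst drive frequency, Hz.
#' @param sigma Temporal s.d. of the per-cycle event Gaussian, ms.
#' @param events_per_cycle Events per drive cycle (10).
#' @param lag Cycle-mean lag, ms (5 for distal; 0 proximal).
#' @param layer Target layer.
#' @param seed Optional drive-local RNG seed; when `NULL` a stream is derived
#'   from the simulation seed.
#' @return A `cdg_drive` object.
#' @name drives
NULL

#' @rdname drives
#' @export
tonic_drive <- function(i_app, layer = "L5") {
  structure(list(type = "tonic", i_app = i_app, layer = layer,
                 target = "soma"), class = "cdg_drive")
}

#' @rdname drives
#' @export
poisson_drive <- function(rate, g_max, layer = "L5", seed = NULL) {
  if (rate < 0) stop("Poisson rate must be >= 0")
  if (g_max < 0) stop("g_max must be >= 0")
  structure(list(type = "poisson", rate = rate, g_max = g_max, layer = layer,
                 target = "soma", seed = seed, per_cell_independent = TRUE),
            class = "cdg_drive")
}

#' @rdname drives
#' @export
burst_drive <- function(input_class = c("proximal", "distal"), f, sigma,
                        events_per_cycle = 10, g_max = 4e-5, lag = NULL,
                        layer = "L5", population = "pyramidal", seed = NULL) {
  input_class <- match.arg(input_class)
  if (f <= 0) stop("burst frequency must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!identical(population, "pyramidal"))
    stop("burst drives target pyramidal cells; ", population,
         " cells have no dendritic target compartments")
  if (is.null(lag)) lag <- if (input_class == "distal") 5 else 0
  targets <- if (input_class == "proximal")
    c("apical_oblique", "basal_2", "basal_3") else "apical_tuft"
  structure(list(type = "burst", input_class = input_class, f = f,
                 sigma = sigma, events_per_cycle = events_per_cycle,
                 g_max = g_max, lag = lag, layer = layer, targets = targets,
                 seed = seed),
            class = "cdg_drive")
}

#' Sample Poisson drive event times
#'
#' Independent homogeneous Poisson event streams, one per cell, with
#' exponential inter-event intervals at the drive rate.  Reproducible given
#' the seed.
#'
#' @param drive A [poisson_drive()].
#' @param n_cells Number of independent streams.
#' @param duration Window length, ms; events fall in `[0, duration)`.
#' @param seed RNG seed (defaults to the drive's own).
#' @return List of numeric vectors of event times (ms), one per cell.
#' @export
sample_poisson_events <- function(drive, n_cells, duration, seed = drive$seed) {
  stopifnot(drive$type == "poisson")
  if (!is.null(seed)) set.seed(seed)
  rate_ms <- drive$rate / 1000
  lapply(seq_len(n_cells), function(i) {
    if (rate_ms == 0) return(numeric(0))
    # draw enough exponential intervals to cover the window
    n_guess <- max(10, ceiling(rate_ms * duration + 6 * sqrt(rate_ms * duration)))
    tt <- cumsum(rexp(n_guess, rate_ms))
    while (length(tt) && tt[length(tt)] < duration)
      tt <- c(tt, tt[length(tt)] + cumsum(rexp(n_guess, rate_ms)))
    tt[tt < duration]
  })
}

#' Sample rhythmic Gaussian-burst event times
#'
#' Cycle means sit at `k/f` (plus the drive lag); each cycle contributes
#' `events_per_cycle` draws from a Gaussian centred on the cycle mean with the
#' drive's temporal s.d.  Draws are independent across events and cycles;
#' event times outside `[0, duration)` are dropped.  With `sigma = 0` all
#' events of a cycle coincide at the cycle mean.
#'
#' The same event times are delivered to every target cell in the simulation.
#'
#' @param drive A [burst_drive()].
#' @param duration Window length, ms.
#' @param seed RNG seed (defaults to the drive's own).
#' @return Sorted numeric vector of event times, ms.
#' @export
sample_burst_events <- function(drive, duration, seed = drive$seed) {
  stopifnot(drive$type == "burst")
  if (!is.null(seed)) set.seed(seed)
  period <- 1000 / drive$f
  means <- seq(drive$lag, duration, by = period)
  ev <- rep(means, each = drive$events_per_cycle) +
    drive$sigma * rnorm(length(means) * drive$events_per_cycle)
  sort(ev[ev >= 0 & ev < duration])
}

#' Attach drives to a network
#'
#' Validates drive targets against the network and returns a configured
#' simulation object for [simulate()].  Tonic drives add a constant somatic
#' current to the pyramidal cells of their layer; Poisson and burst drives
#' enter the synaptic event queue with the shared delivery delay and their
#' per-event conductances.
#'
#' @param network A `cdg_network`.
#' @param drives List of `cdg_drive` objects (possibly empty).
#' @return A `cdg_simulation` object.
#' @export
attach_drives <- function(network, drives = list()) {
  stopifnot(inherits(network, "cdg_network"))
  if (inherits(drives, "cdg_drive")) drives <- list(drives)
  for (d in drives) {
    if (!inherits(d, "cdg_drive")) stop("drives must be cdg_drive objects")
    if (!d$layer %in% network$layers)
      stop("drive targets layer ", d$layer, " which is not in the network")
    if (d$type == "burst") {
      pyr_kind <- if (d$layer == "L5") "l5_pyramidal" else "l23_pyramidal"
      comps <- network$models[[pyr_kind]]$compartments$name
      missing <- setdiff(d$targets, comps)
      if (length(missing))
        stop("burst drive targets unknown compartment(s): ",
             paste(missing, collapse = ", "))
    }
  }
  structure(list(network = network, drives = drives), class = "cdg_simulation")
}

# Resolve drives into engine inputs for one run.
# Returns list(iapp (per node, nA), events = data.frame(time, node, receptor,
# weight), event_log for export).
.resolve_drives <- function(sim, duration, dt, seed) {
  net <- sim$network
  nodes <- net$nodes
  cells <- net$cells
  delay <- net$params$synapses$delivery_delay
  iapp <- numeric(nrow(nodes))
  ev_time <- numeric(0); ev_node <- integer(0); ev_w <- numeric(0)
  ev_cell <- integer(0); ev_comp <- character(0)

  # derived per-drive seed streams, reproducible given the run seed
  n_dr <- length(sim$drives)
  stream_seeds <- rep(NA_integer_, n_dr)
  if (n_dr > 0) {
    set.seed(seed)
    stream_seeds <- sample.int(.Machine$integer.max - 1L, n_dr)
  }

  for (k in seq_along(sim$drives)) {
    d <- sim$drives[[k]]
    dseed <- if (!is.null(d$seed)) d$seed else stream_seeds[k]
    pyr <- cells$cell[cells$layer == d$layer & cells$type == "pyramidal"]
    if (d$type == "tonic") {
      unit <- net$params$current_unit %||% 1
      iapp[net$soma_node[pyr] + 1L] <- iapp[net$soma_node[pyr] + 1L] + d$i_app * unit
    } else if (d$type == "poisson") {
      evs <- sample_poisson_events(d, length(pyr), duration, seed = dseed)
      for (j in seq_along(pyr)) {
        tt <- evs[[j]]
        if (!length(tt)) next
        nd <- net$soma_node[pyr[j]]
        ev_time <- c(ev_time, tt + delay)
        ev_node <- c(ev_node, rep(nd, length(tt)))
        ev_w <- c(ev_w, rep(d$g_max, length(tt)))
        ev_cell <- c(ev_cell, rep(pyr[j], length(tt)))
        ev_comp <- c(ev_comp, rep("soma", length(tt)))
      }
    } else if (d$type == "burst") {
      tt <- sample_burst_events(d, duration, seed = dseed)
      if (!length(tt)) next
      for (comp in d$targets) {
        # middle segment of the target compartment; last segment for the tuft
        for (j in pyr) {
          cn <- which(nodes$cell == j & nodes$comp == comp)
          nd <- if (comp == "apical_tuft") cn[length(cn)] else cn[ceiling(length(cn) / 2)]
          ev_time <- c(ev_time, tt + delay)
          ev_node <- c(ev_node, rep(nd - 1L, length(tt)))
          ev_w <- c(ev_w, rep(d$g_max, length(tt)))
          ev_cell <- c(ev_cell, rep(j, length(tt)))
          ev_comp <- c(ev_comp, rep(comp, length(tt)))
        }
      }
    }
  }
  list(iapp = iapp,
       events = data.frame(time = ev_time, node = ev_node, weight = ev_w,
                           cell = ev_cell, comp = ev_comp,
                           stringsAsFactors = FALSE))
}

#' Export or import drive event lists
#'
#' Event lists are written as tab-delimited text with columns `time` (ms),
#' `cell`, `compartment`, `conductance` (uS) so a published event train can be
#' replayed exactly.
#'
#' @param events data.frame as found in a run bundle's `events` element.
#' @param path File path.
#' @return `read_events` returns the data.frame.
#' @export
write_events <- function(events, path) {
  out <- data.frame(time = events$time, cell = events$cell,
                    compartment = events$comp, conductance = events$weight)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
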