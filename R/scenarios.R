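#' Define a simulation scenario
#'
#' A scenario bundles everything needed to reproduce one network regime
#' end-to-end: layers, per-layer network configuration, drive specifications,
#' duration (550 ms), time step (0.025 ms), analysis window (50-550 ms) and
#' the RNG seed.  Shipped scenarios covering the strong/weak PING and
#' subthreshold regimes are listed by [list_scenarios()] and loaded with
#' [load_scenario()].
#'
#' @param name Scenario name.
#' @param layers Layers to build.
#' @param network Named list of [network_config()]s keyed by layer.
#' @param drives List of `cdg_drive` objects.
#' @param duration,dt Simulated time and step, ms.
#' @param window Analysis window, ms.
#' @param seed Default RNG seed.
#' @return A `cdg_scenario`.
#' @export
scenario <- function(name, layers, network, drives, duration = 550,
                     dt = 0.025, window = c(50, 550), seed = 42) {
  sc <- structure(list(name = name, layers = layers, network = network,
                       drives = drives, duration = duration, dt = dt,
                       window = window, seed = seed),
                  class = "cdg_scenario")
  rep <- validate_scenario(sc)
  if (!rep$valid) stop("invalid scenario: ", paste(rep$errors, collapse = "; "))
  sc
}

#' Validate a scenario
#'
#' Checks field presence, types, and parameter constraints; every problem is
#' reported with its field path.
#'
#' @param sc A `cdg_scenario` (or plain list).
#' @return List with `valid` (logical) and `errors` (character).
#' @export
validate_scenario <- function(sc) {
  errs <- character(0)
  req <- c("name", "layers", "network", "drives", "duration", "dt", "window", "seed")
  miss <- setdiff(req, names(sc))
  if (length(miss)) errs <- c(errs, paste0("missing field(s): ", paste(miss, collapse = ", ")))
  if (!is.null(sc$layers) && !all(sc$layers %in% c("L2", "L5")))
    errs <- c(errs, "layers: must be a subset of c('L2','L5')")
  for (ly in names(sc$network)) {
    cf <- sc$network[[ly]]
    for (g in c("g_ei", "g_ie", "g_ii")) {
      if (!is.null(cf[[g]]) && cf[[g]] < 0)
        errs <- c(errs, sprintf("network.%s.%s: must be >= 0", ly, g))
    }
    if (!is.null(cf$space_constant) && cf$space_constant <= 0)
      errs <- c(errs, sprintf("network.%s.space_constant: must be > 0", ly))
  }
  if (!is.null(sc$duration) && !is.null(sc$dt)) {
    if (sc$dt <= 0) errs <- c(errs, "dt: must be > 0")
    else if (abs(sc$duration / sc$dt - round(sc$duration / sc$dt)) > 1e-9)
      errs <- c(errs, "duration: must be a multiple of dt")
  }
  if (!is.null(sc$window) && !is.null(sc$duration) &&
      (length(sc$window) != 2 || sc$window[2] > sc$duration ||
       sc$window[1] < 0 || sc$window[1] >= sc$window[2]))
    errs <- c(errs, "window: must be c(start, end) within the run")
  for (k in seq_along(sc$drives)) {
    d <- sc$drives[[k]]
    if (!inherits(d, "cdg_drive"))
      errs <- c(errs, sprintf("drives[%d]: not a cdg_drive", k))
  }
  list(valid = length(errs) == 0, errors = errs)
}

#' @export
print.cdg_scenario <- function(x, ...) {
  cat("<cdg_scenario>", x$name, "-", paste(x$layers, collapse = "+"),
      "-", length(x$drives), "drive(s), seed", x$seed, "\n")
  invisible(x)
}

# ---- scenario <-> YAML ------------------------------------------------------

.drive_to_list <- function(d) {
  keep <- switch(d$type,
    tonic = c("type", "i_app", "layer"),
    poisson = c("type", "rate", "g_max", "layer"),
    burst = c("type", "input_class", "f", "sigma", "events_per_cycle",
              "g_max", "lag", "layer"))
  d[keep]
}

.drive_from_list <- function(l, path) {
  known <- c("type", "i_app", "rate", "g_max", "layer", "input_class", "f",
             "sigma", "events_per_cycle", "lag")
  unknown <- setdiff(names(l), known)
  if (length(unknown))
    stop(path, ": unknown key(s): ", paste(unknown, collapse = ", "))
  switch(l$type,
    tonic = tonic_drive(l$i_app, layer = l$layer),
    poisson = poisson_drive(l$rate, l$g_max, layer = l$layer),
    burst = burst_drive(l$input_class, f = l$f, sigma = l$sigma,
                        events_per_cycle = l$events_per_cycle %||% 10,
                        g_max = l$g_max %||% 4e-5, lag = l$lag,
                        layer = l$layer),
    stop(path, ": unknown drive type '", l$type, "'"))
}

#' Read / write scenario configuration files
#'
#' Scenarios are stored as YAML.  Unknown keys are rejected with their field
#' path; a load -> write -> load round trip reproduces the scenario exactly.
#'
#' @param path File path.
#' @return `load_config` returns a `cdg_scenario`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("name", "layers", "duration", "dt", "window", "seed", "network", "drives")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown key(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(c("name", "layers", "network", "drives"), names(y))
  if (length(miss)) stop("missing required field(s): ", paste(miss, collapse = ", "))
  net <- list()
  for (ly in names(y$network)) {
    cf <- y$network[[ly]]
    known_cf <- c("g_ei", "g_ie", "g_ii", "n_pyr", "n_inh", "space_constant", "regime")
    unknown <- setdiff(names(cf), known_cf)
    if (length(unknown))
      stop("network.", ly, ": unknown key(s): ", paste(unknown, collapse = ", "))
    net[[ly]] <- network_config(ly, g_ei = cf$g_ei, g_ie = cf$g_ie,
                                g_ii = cf$g_ii %||% 0,
                                n_pyr = cf$n_pyr %||% 100,
                                n_inh = cf$n_inh %||% 35,
                                space_constant = cf$space_constant %||% 3,
                                regime = cf$regime %||% "")
  }
  drives <- lapply(seq_along(y$drives), function(k)
    .drive_from_list(y$drives[[k]], sprintf("drives[%d]", k)))
  scenario(y$name, unlist(y$layers), net, drives,
           duration = y$duration %||% 550, dt = y$dt %||% 0.025,
           window = unlist(y$window %||% c(50, 550)), seed = y$seed %||% 42)
}

#' @rdname load_config
#' @param sc A `cdg_scenario`.
#' @export
write_config <- function(sc, path) {
  y <- list(name = sc$name, layers = as.list(sc$layers),
            duration = sc$duration, dt = sc$dt,
            window = as.list(sc$window), seed = sc$seed,
            network = lapply(sc$network, function(cf)
              list(g_ei = cf$g_ei, g_ie = cf$g_ie, g_ii = cf$g_ii,
                   n_pyr = cf$n_pyr, n_inh = cf$n_inh,
                   space_constant = cf$space_constant, regime = cf$regime)),
            drives = lapply(sc$drives, .drive_to_list))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' List and load the shipped scenarios
#'
#' One scenario per figure regime: strong PING, weak PING (both `g_pois`
#' variants), the L2/3 weak-PING network, the two-layer aggregate run, and
#' the proximal / proximal+distal subthreshold drive conditions.
#'
#' @return `list_scenarios` returns the scenario names.
#' @export
list_scenarios <- function() {
  files <- list.files(system.file("scenarios", package = "cdgamma"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}

#' @rdname list_scenarios
#' @param name Scenario name (one of `list_scenarios()`) or a path to a
#'   YAML file.
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("scenarios", paste0(name, ".yaml"), package = "cdgamma")
  if (!nzchar(path) || !file.exists(path)) stop("unknown scenario '", name, "'")
  load_config(path)
}

#' Run a scenario end-to-end
#'
#' Builds the network, attaches the drives, integrates, and computes the full
#' analysis set over the scenario window: per-layer firing rates, Welch
#' periodogram and Morlet spectrogram of the (demeaned) CD, extrema and slope
#' ratio, cycle count, and high-gamma epochs.  Deterministic given the seed.
#'
#' @param sc A `cdg_scenario` (or scenario name).
#' @param seed RNG seed; defaults to the scenario seed.
#' @param analysis_decimate Decimation factor applied to the CD before
#'   spectral analysis (40 gives a 1 ms analysis grid from the 0.025 ms
#'   integration grid; the analysed rhythms live far below the implied
#'   500 Hz Nyquist frequency).
#' @return A `cdg_scenario_run`: list with the raw `run` bundle, per-layer
#'   `analysis`, and a one-row `summary` data.frame.
#' @export
run_scenario <- function(sc, seed = NULL, analysis_decimate = 40) {
  if (is.character(sc)) sc <- load_scenario(sc)
  stopifnot(inherits(sc, "cdg_scenario"))
  if (is.null(seed)) seed <- sc$seed
  net <- build_network(sc$layers, sc$network)
  sim <- attach_drives(net, sc$drives)
  run <- simulate(sim, duration = sc$duration, dt = sc$dt, seed = seed)

  analysis <- lapply(sc$layers, function(ly)
    analyze_cd(run, layer = ly, window = sc$window,
               decimate = analysis_decimate))
  names(analysis) <- sc$layers

  first <- analysis[[1]]
  summary <- data.frame(
    scenario = sc$name, seed = seed,
    layer = sc$layers[1],
    e_rate = first$e_rate, e_rate_sd = first$e_rate_sd,
    i_rate = first$i_rate,
    peak_f = first$welch_peak$freq, peak_power = first$welch_peak$power,
    morlet_f = first$morlet_peak$freq,
    n_cycles = first$n_cycles,
    Phi = first$slope_ratio$Phi, Phi_se = first$slope_ratio$se,
    max_cd = first$max_cd,
    n_epochs = nrow(first$epochs),
    stringsAsFactors = FALSE)

  structure(list(scenario = sc, run = run, analysis = analysis,
                 summary = summary),
            class = "cdg_scenario_run")
}

#' @export
print.cdg_scenario_run <- function(x, ...) {
  cat("<cdg_scenario_run>", x$scenario$name, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Waveform analysis of a run's current dipole
#'
#' Applies the full statistics set to one layer's CD over the analysis
#' window: demeaned Welch periodogram (single Hann-tapered segment), Morlet
#' spectrogram, alternating extrema, cycle count, slope ratio, high-gamma
#' epochs, and population firing rates.
#'
#' @param run A `cdg_run`.
#' @param layer Layer to analyse.
#' @param window Analysis window, ms.
#' @param decimate Subsampling factor before spectral analysis.
#' @param low_band Band searched for the dominant Welch rhythm peak, Hz.
#' @param morlet_band Low-gamma band searched for the Morlet power maximum, Hz.
#' @return List of analysis results.
#' @export
analyze_cd <- function(run, layer = run$network$layers[1], window = c(50, 550),
                       decimate = 40, low_band = c(20, 100),
                       morlet_band = c(30, 100)) {
  sel <- run$time >= window[1] & run$time <= window[2]
  dec <- .decimate(run$dipole[[layer]][sel], run$time[sel], decimate)
  x <- dec$x - mean(dec$x)
  welch <- welch_periodogram(x, dec$time)
  fmin <- max(1, ceiling(1000 / diff(range(dec$time))))
  morlet <- morlet_spectrogram(x, dec$time, fmin = fmin)
  msel <- morlet$freq >= morlet_band[1] & morlet$freq <= morlet_band[2]
  mp <- which(morlet$power[msel, , drop = FALSE] ==
              max(morlet$power[msel, , drop = FALSE]), arr.ind = TRUE)[1, ]
  f_dom <- spectral_peak(welch, low_band)$freq
  min_sep <- if (is.finite(f_dom) && f_dom > 0) 500 / f_dom else 0
  extrema <- find_extrema(x, dec$time, min_separation = min_sep)
  phi <- slope_ratio(extrema, min_cycles = 3)
  er <- firing_rates(run, window, "pyramidal", layer)
  ir <- firing_rates(run, window, "basket", layer)
  epochs <- find_high_gamma_epochs(morlet)
  list(layer = layer, window = window,
       cd = data.frame(time = dec$time, value = dec$x),
       welch = welch, welch_peak = spectral_peak(welch, low_band),
       morlet = morlet,
       morlet_peak = list(freq = morlet$freq[msel][mp[1]],
                          power = max(morlet$power[msel, , drop = FALSE])),
       extrema = extrema, n_cycles = sum(extrema$type == "peak"),
       slope_ratio = phi,
       e_rate = mean(er), e_rate_sd = stats::sd(er), i_rate = mean(ir),
       max_cd = max(abs(x)), epochs = epochs)
}

#' Parameter sweep over a scenario
#'
#' Re-runs a scenario with one addressable parameter set to each value and
#' tabulates the rhythm statistics.  Parameters are addressed by a dotted
#' path into the scenario, e.g. `"drives.1.sigma"` (first drive's sigma) or
#' `"network.L5.g_ie"`.  Relative spectral power is reported against the
#' first value.
#'
#' @param sc A `cdg_scenario`.
#' @param param Dotted parameter path.
#' @param values Values to sweep (non-empty).
#' @param seed Seed used for every run (matched seeds across values).
#' @return data.frame with one row per value: value, peak_f, max_pw, Phi,
#'   Phi_se, rel_power.
#' @export
sweep_scenario <- function(sc, param, values, seed = NULL) {
  if (is.character(sc)) sc <- load_scenario(sc)
  if (!length(values)) stop("values must be non-empty")
  parts <- strsplit(param, ".", fixed = TRUE)[[1]]
  set_path <- function(obj, parts, value) {
    key <- parts[1]
    if (grepl("^[0-9]+$", key)) key <- as.integer(key)
    if (length(parts) == 1) {
      if (is.integer(key)) obj[[key]] <- value else obj[[key]] <- value
      return(obj)
    }
    if (is.null(obj[[key]])) stop("cannot address '", param, "' in scenario")
    obj[[key]] <- set_path(obj[[key]], parts[-1], value)
    obj
  }
  rows <- lapply(values, function(v) {
    sc2 <- set_path(unclass(sc), parts, v)
    class(sc2) <- "cdg_scenario"
    out <- run_scenario(sc2, seed = seed)
    s <- out$summary
    data.frame(value = v, peak_f = s$peak_f, max_pw = s$peak_power,
               Phi = s$Phi, Phi_se = s$Phi_se, max_cd = s$max_cd)
  })
  res <- do.call(rbind, rows)
  res$rel_power <- res$max_pw / res$max_pw[1]
  res
}

#' Write a scenario run bundle to a directory
#'
#' Emits delimited text files (CD per layer and aggregate, spike times,
#' exogenous events, summary table) plus a YAML snapshot of the scenario, so
#' a run can be archived and replayed.
#'
#' @param x A `cdg_scenario_run`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_run_bundle <- function(x, dir) {
  stopifnot(inherits(x, "cdg_scenario_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dipole(x$run$dipole, dir, prefix = "cd")
  spikes <- data.frame(
    cell = rep(seq_along(x$run$spikes), lengths(x$run$spikes)),
    time = unlist(x$run$spikes))
  utils::write.table(spikes, file.path(dir, "spikes.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_events(x$run$events, file.path(dir, "events.txt"))
  utils::write.table(x$summary, file.path(dir, "summary.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_config(x$scenario, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
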