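#' Dipole time-series container
#'
#' Per-layer and aggregate equivalent current dipole on a fixed time grid.
#' The aggregate is always the linear sum of the layer series on the
#' identical grid.
#'
#' @param time Time grid, ms.
#' @param layer_cd data.frame of per-layer CD (nAm), one column per layer.
#' @param n_pyr Named vector, pyramidal cells per layer.
#' @param metadata List (regime, seed, ...).
#' @return A `cdg_dipole`: data.frame with `time`, one column per layer and
#'   `aggregate`, plus attributes.
#' @export
dipole_ts <- function(time, layer_cd, n_pyr = NULL, metadata = list()) {
  stopifnot(nrow(layer_cd) == length(time))
  if (any(!vapply(layer_cd, function(x) all(is.finite(x)), TRUE)))
    stop("dipole series contains non-finite values")
  out <- cbind(data.frame(time = time), layer_cd)
  out$aggregate <- rowSums(as.matrix(layer_cd))
  structure(out, class = c("cdg_dipole", "data.frame"),
            n_pyr = n_pyr, metadata = metadata)
}

#' Compute the current dipole from a voltage trajectory
#'
#' The longitudinal current dipole of a layer is the sum over pyramidal cells
#' and over their cable segments of the ohmic axial current between adjacent
#' segments times the segment's length component along the apical axis:
#' `Q = sum_cells sum_i ((v_parent - v_i) / r_i) * z_i`, with `z` signed
#' positive toward the pia, so current flowing away from the soma toward the
#' cortical surface is a positive dipole.  Oblique compartments have `z = 0`
#' and contribute nothing; basket cells are excluded.
#'
#' Units: mV / MOhm * um * 1e-6 = nAm.
#'
#' @param v Voltage matrix, time x node (mV), covering all pyramidal nodes.
#' @param nodes Node table (as in `network$nodes` or `cell$nodes`) aligned
#'   with the columns of `v`; needs `parent` (0-based), `r_ax`, `z` and,
#'   for networks, `cell`.
#' @param cells Optional cell table with `cell`, `type`, `layer`; when absent
#'   all nodes are treated as one pyramidal cell in a single layer.
#' @param time Optional time grid for the returned series.
#' @return A `cdg_dipole` (or plain vector if `time` is `NULL`).
#' @export
compute_dipole <- function(v, nodes, cells = NULL, time = NULL) {
  if (ncol(v) != nrow(nodes)) stop("voltage matrix does not match node table")
  if (is.null(cells)) {
    layer_of_node <- rep("cell", nrow(nodes))
    pyr <- rep(TRUE, nrow(nodes))
  } else {
    layer_of_node <- cells$layer[nodes$cell]
    pyr <- cells$type[nodes$cell] == "pyramidal"
  }
  layers <- unique(layer_of_node)
  res <- matrix(0, nrow(v), length(layers), dimnames = list(NULL, layers))
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent[i]
    if (p < 0 || !pyr[i] || nodes$z[i] == 0) next
    contrib <- (v[, p + 1L] - v[, i]) / nodes$r_ax[i] * nodes$z[i] * 1e-6
    res[, layer_of_node[i]] <- res[, layer_of_node[i]] + contrib
  }
  if (is.null(time)) {
    if (length(layers) == 1L) return(unname(drop(res)))
    return(res)
  }
  dipole_ts(time, as.data.frame(res))
}

#' Baseline renormalization of a dipole series
#'
#' Subtracts the standing (drive-free) dipole of the resting network so
#' oscillations are centred near zero: a constant offset per L2/3 pyramidal
#' cell, and a slowly drifting line `slope * t + intercept` per L5 pyramidal
#' cell over the analysis interval.  The constants are calibrated to this
#' model's resting state and recorded in the parameter file.  The operation
#' is affine and exactly invertible with `invert = TRUE`.
#'
#' @param x Numeric CD series (nAm) or a `cdg_dipole` column.
#' @param layer `"L2"` or `"L5"`.
#' @param time Time grid, ms (required for L5).
#' @param n_pyr Number of pyramidal cells contributing to the series.
#' @param invert Undo the renormalization.
#' @param params Parameter list.
#' @return Renormalized series, same shape as `x`.
#' @export
baseline_renormalize <- function(x, layer = c("L5", "L2"), time = NULL,
                                 n_pyr = 100, invert = FALSE,
                                 params = cdg_parameters()) {
  layer <- match.arg(layer)
  b <- params$baseline
  if (layer == "L2") {
    off <- n_pyr * b$l2_offset
  } else {
    if (is.null(time)) stop("L5 renormalization needs the time grid")
    off <- n_pyr * (b$l5_slope * time + b$l5_intercept)
  }
  if (invert) x + off else x - off
}

#' Extrapolate the network size needed for an observable dipole
#'
#' Given the maximal CD produced by `n_cells` pyramidal cells and assuming
#' the participating fraction scales linearly with network size, returns the
#' number of cells needed to reach the minimal observable source strength
#' (about 10 nAm for MEG/EEG), reported as an order of magnitude.
#'
#' @param max_cd Maximal simulated CD amplitude, nAm (> 0).
#' @param n_cells Number of pyramidal cells that produced it.
#' @param observable_threshold Minimal observable CD, nAm.
#' @return List with `n_required` (cells), `order_of_magnitude` (power of
#'   ten) and `exponent`.
#' @export
estimate_network_size <- function(max_cd, n_cells = 100,
                                  observable_threshold = 10) {
  if (max_cd <= 0) stop("max_cd must be positive")
  n_req <- n_cells * observable_threshold / max_cd
  expn <- round(log10(n_req))
  list(n_required = n_req, order_of_magnitude = 10^expn, exponent = expn)
}

#' Write / read dipole series as delimited text
#'
#' Two columns per file: time (ms) and CD (nAm); one file per layer plus the
#' aggregate when writing a `cdg_dipole`.
#'
#' @param dipole A `cdg_dipole`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_dipole <- function(dipole, dir, prefix = "cd") {
  stopifnot(inherits(dipole, "cdg_dipole"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- setdiff(names(dipole), "time")
  paths <- character(0)
  for (cn in cols) {
    p <- file.path(dir, paste0(prefix, "_", cn, ".txt"))
    utils::write.table(data.frame(time = dipole$time, cd = dipole[[cn]]),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
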