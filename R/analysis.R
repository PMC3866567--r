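#' Read a two-column delimited time series
#'
#' Accepts any whitespace-, comma- or tab-delimited text with two numeric
#' columns (time in ms, value); a header line is detected automatically, so
#' the analysis layer can be used on external current-source data.
#'
#' @param path File path.
#' @return data.frame with `time` and `value`.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[-+0-9.eE]+[,;\\s]+[-+0-9.eE]+\\s*$", first)
  sep <- if (grepl(",", first)) "," else ""
  d <- utils::read.table(path, header = has_header, sep = sep)
  d <- d[, 1:2]
  names(d) <- c("time", "value")
  d
}

#' @rdname read_timeseries
#' @param x data.frame with `time` and `value` (or a numeric vector plus
#'   `time` attribute).
#' @export
write_timeseries <- function(x, path) {
  utils::write.table(x[, c("time", "value")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.dt_of <- function(time) {
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) stop("series must be uniformly sampled")
  dts[1]
}

#' Morlet wavelet spectrogram
#'
#' Continuous wavelet transform with complex Morlet wavelets of a fixed
#' number of cycles (default 7), evaluated on a 1 Hz frequency grid over
#' 1-150 Hz.  Implemented by frequency-domain multiplication with the
#' Gaussian spectrum of each wavelet; the wavelet is normalized so that the
#' modulus of the transform of a pure tone equals the tone amplitude, hence
#' power has the squared units of the input ((nAm)^2 for CD).
#'
#' @param x Numeric series, or data.frame with `time`/`value`.
#' @param time Time grid, ms (ignored when `x` is a data.frame).
#' @param fmin,fmax Frequency range, Hz.
#' @param fstep Frequency grid step, Hz.
#' @param n_cycles Wavelet width in cycles.
#' @param demean Subtract the series mean first.
#' @return A `cdg_spectrogram`: list with `time` (ms), `freq` (Hz), `power`
#'   (freq x time matrix, >= 0).
#' @export
morlet_spectrogram <- function(x, time = NULL, fmin = 1, fmax = 150,
                               fstep = 1, n_cycles = 7, demean = TRUE) {
  if (is.data.frame(x)) { time <- x$time; x <- x$value }
  dt <- .dt_of(time) # ms
  fs <- 1000 / dt    # Hz
  n <- length(x)
  if (n * dt < 1000 / fmin)
    stop("series shorter than one wavelet support at fmin (",
         round(1000 / fmin), " ms)")
  if (demean) x <- x - mean(x)
  freqs <- seq(fmin, fmax, by = fstep)
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1) / n * fs # DFT bin frequencies, Hz
  power <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_f <- f0 / n_cycles # spectral width of the wavelet, Hz
    # one-sided Gaussian kernel; factor 2 restores the analytic-signal
    # amplitude so |W| of a unit tone is 1
    H <- 2 * exp(-(fgrid - f0)^2 / (2 * sigma_f^2))
    H[fgrid > fs / 2] <- 0
    w <- stats::fft(X * H, inverse = TRUE) / n
    power[k, ] <- Mod(w)^2
  }
  structure(list(time = time, freq = freqs, power = power),
            class = "cdg_spectrogram")
}

#' Welch periodogram
#'
#' Stationary Hann-tapered Welch power spectrum.  The default uses a single
#' segment spanning the entire window, matching the stationary analysis of a
#' full 500 ms series; `segment` and `overlap` enable multi-segment
#' averaging.  Scaling is such that a sinusoid of amplitude A yields a peak
#' of A^2/2 (power spectrum convention), so units are the squared units of
#' the input.
#'
#' @param x Numeric series, or data.frame with `time`/`value`.
#' @param time Time grid, ms.
#' @param segment Segment length in samples (`NULL` = whole series).
#' @param overlap Fractional overlap between segments.
#' @param detrend Remove a linear trend per segment.
#' @return A `cdg_periodogram`: data.frame with `freq` (Hz) and `power`.
#' @export
welch_periodogram <- function(x, time = NULL, segment = NULL, overlap = 0.5,
                              detrend = TRUE) {
  if (is.data.frame(x)) { time <- x$time; x <- x$value }
  dt <- .dt_of(time)
  fs <- 1000 / dt
  n <- length(x)
  if (is.null(segment)) segment <- n
  if (segment > n) segment <- n
  step <- max(1, floor(segment * (1 - overlap)))
  starts <- seq(1, n - segment + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1)) # Hann
  sw <- sum(w)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + segment - 1)]
    if (detrend) seg <- stats::lm.fit(cbind(1, seq_len(segment)), seg)$residuals
    X <- stats::fft(seg * w)
    acc <- acc + (Mod(X)^2) * 2 / sw^2
  }
  p <- acc / length(starts)
  nf <- floor(segment / 2) + 1
  out <- data.frame(freq = (seq_len(nf) - 1) * fs / segment, power = p[seq_len(nf)])
  out$power[1] <- out$power[1] / 2 # DC has no conjugate pair
  structure(out, class = c("cdg_periodogram", "data.frame"))
}

#' Locate the spectral peak
#' @param p A `cdg_periodogram` (or data.frame with `freq`, `power`).
#' @param band Optional frequency band `c(lo, hi)`, Hz.
#' @return List with `freq` and `power` at the maximum.
#' @export
spectral_peak <- function(p, band = NULL) {
  d <- as.data.frame(p)
  if (!is.null(band)) d <- d[d$freq >= band[1] & d$freq <= band[2], ]
  i <- which.max(d$power)
  list(freq = d$freq[i], power = d$power[i])
}

#' Alternating local extrema of an oscillatory series
#'
#' Local maxima and minima filtered by topographic prominence (default
#' threshold: 10% of the series interquartile range) and reduced to a
#' strictly alternating peak/trough sequence (between two retained peaks the
#' deepest trough is kept, and vice versa; ties broken by earliest time).
#'
#' @param x Numeric series, or data.frame with `time`/`value`.
#' @param time Time grid, ms.
#' @param prominence Minimal prominence, absolute units; default
#'   `prominence_frac * IQR(x)`.
#' @param prominence_frac Fraction of the IQR used for the default threshold.
#' @param min_separation Minimal spacing between consecutive same-type
#'   extrema, ms (0 disables).  Adjacent peak/trough pairs with the smallest
#'   amplitude difference are merged until the spacing holds, so the sequence
#'   carries one peak per cycle of the dominant rhythm while the surviving
#'   extrema keep their raw times and values.
#' @return data.frame with `time`, `value`, `type` ("peak"/"trough"),
#'   strictly alternating; zero rows if fewer than 2 extrema survive.
#' @export
find_extrema <- function(x, time = NULL, prominence = NULL,
                         prominence_frac = 0.1, min_separation = 0) {
  if (is.data.frame(x)) { time <- x$time; x <- x$value }
  n <- length(x)
  if (is.null(prominence)) prominence <- prominence_frac * stats::IQR(x)
  d <- diff(x)
  sgn <- sign(d)
  # indices of strict local extrema (plateaus: earliest point)
  idx <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-length(sgn)] != 0) + 1L
  if (!length(idx)) return(data.frame(time = numeric(0), value = numeric(0),
                                      type = character(0)))
  type <- ifelse(x[idx] > (x[pmax(idx - 1L, 1L)]), "peak", "trough")
  # prominence: for each extremum, height above (below) the higher (lower) of
  # the two surrounding opposite extrema, computed on the candidate sequence
  keep <- rep(TRUE, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    left <- if (k > 1) x[idx[k - 1]] else x[1]
    right <- if (k < length(idx)) x[idx[k + 1]] else x[n]
    if (type[k] == "peak") {
      prom <- x[i] - max(left, right)
    } else {
      prom <- min(left, right) - x[i]
    }
    if (prom < prominence) keep[k] <- FALSE
  }
  idx <- idx[keep]; type <- type[keep]
  if (!length(idx)) return(data.frame(time = numeric(0), value = numeric(0),
                                      type = character(0)))
  # enforce alternation: among consecutive same-type extrema keep the extreme one
  out_i <- integer(0); out_t <- character(0)
  for (k in seq_along(idx)) {
    if (length(out_i) && type[k] == out_t[length(out_t)]) {
      prev <- out_i[length(out_i)]
      better <- if (type[k] == "peak") x[idx[k]] > x[prev] else x[idx[k]] < x[prev]
      if (better) out_i[length(out_i)] <- idx[k]
    } else {
      out_i <- c(out_i, idx[k]); out_t <- c(out_t, type[k])
    }
  }
  res <- data.frame(time = time[out_i], value = x[out_i], type = out_t,
                    stringsAsFactors = FALSE)
  if (min_separation > 0) res <- .merge_fast_cycles(res, min_separation)
  res
}

# Remove sub-cycle ripple: while two consecutive same-type extrema are closer
# than min_sep, drop the intervening adjacent peak/trough pair with the
# smallest amplitude difference (alternation is preserved by construction).
.merge_fast_cycles <- function(ex, min_sep) {
  repeat {
    if (nrow(ex) < 4) return(ex)
    same <- which(diff(ex$time, lag = 2) < min_sep)
    if (!length(same)) return(ex)
    # candidate pairs inside a too-fast triple: (i+1, i+2) of each same-type gap
    amp <- abs(diff(ex$value))
    cand <- unique(pmin(same + 1, nrow(ex) - 1))
    drop <- cand[which.min(amp[cand])]
    ex <- ex[-c(drop, drop + 1), , drop = FALSE]
  }
}

#' Cycle slope ratio of an oscillation
#'
#' For each full cycle (trough, peak, next trough) the ratio
#' `phi_i = |m_rise| / |m_fall|` of the linear slope from trough to peak and
#' from peak to the next trough.  The summary statistic Phi is the mean of
#' the per-cycle ratios, with its standard error and a one-sided one-sample
#' t-test of the phi_i against 1 (direction chosen by the side of Phi).
#' Phi < 1 marks slow-rise/sharp-fall waveforms (inhibition-paced PING);
#' Phi > 1 marks fast-rise/slow-relaxation waveforms (subthreshold drive).
#'
#' @param extrema Alternating extrema table from [find_extrema()], or a
#'   data.frame with `time`/`value` columns plus `type`.
#' @param min_cycles Minimal number of full cycles required (default 3).
#' @return A `cdg_slope_ratio`: list with `phi` (per cycle), `Phi`, `se`,
#'   `n_cycles`, `t`, `p_value`, `alternative`, `extrema`.
#' @export
slope_ratio <- function(extrema, min_cycles = 3) {
  stopifnot(all(c("time", "value", "type") %in% names(extrema)))
  tp <- extrema$type
  if (length(tp) >= 2 && any(tp[-1] == tp[-length(tp)]))
    stop("extrema sequence must alternate peaks and troughs")
  # start at the first trough
  start <- which(tp == "trough")[1]
  phi <- numeric(0)
  k <- start
  while (!is.na(k) && k + 2 <= length(tp)) {
    t1 <- extrema[k, ]; p <- extrema[k + 1, ]; t2 <- extrema[k + 2, ]
    m_rise <- (p$value - t1$value) / (p$time - t1$time)
    m_fall <- (t2$value - p$value) / (t2$time - p$time)
    if (m_fall != 0) phi <- c(phi, abs(m_rise) / abs(m_fall))
    k <- k + 2
  }
  n <- length(phi)
  if (n < min_cycles) {
    return(structure(list(phi = phi, Phi = NA_real_, se = NA_real_,
                          n_cycles = n, t = NA_real_, p_value = NA_real_,
                          alternative = NA_character_, extrema = extrema),
                     class = "cdg_slope_ratio"))
  }
  Phi <- mean(phi)
  se <- stats::sd(phi) / sqrt(n)
  alt <- if (Phi < 1) "less" else "greater"
  if (se == 0) {
    # degenerate case: identical ratios on every cycle
    tstat <- if (Phi == 1) 0 else sign(Phi - 1) * Inf
    p <- if (Phi == 1) 1 else 0
  } else {
    tstat <- (Phi - 1) / se
    p <- if (alt == "less") stats::pt(tstat, n - 1) else
      stats::pt(tstat, n - 1, lower.tail = FALSE)
  }
  structure(list(phi = phi, Phi = Phi, se = se, n_cycles = n, t = tstat,
                 p_value = p, alternative = alt, extrema = extrema),
            class = "cdg_slope_ratio")
}

#' @export
print.cdg_slope_ratio <- function(x, ...) {
  cat(sprintf("Phi = %.3f +/- %.3f (s.e., %d cycles), one-sided p = %.3g (%s than 1)\n",
              x$Phi, x$se, x$n_cycles, x$p_value, x$alternative))
  invisible(x)
}

#' Spike histogram and PSTH
#'
#' Counts per fixed-width bin; total count is conserved for any binning.
#'
#' @param spikes Numeric event times (ms), or a list of such vectors (pooled).
#' @param bin Bin width, ms (1 for spike histograms, 5 for PSTHs).
#' @param window Optional `c(start, end)` window, ms.
#' @return data.frame with bin left edge `time` and `count`.
#' @export
spike_histogram <- function(spikes, bin = 1, window = NULL) {
  if (bin <= 0) stop("bin width must be positive")
  if (is.list(spikes)) spikes <- unlist(spikes, use.names = FALSE)
  if (is.null(window)) {
    if (!length(spikes)) return(data.frame(time = numeric(0), count = integer(0)))
    window <- c(floor(min(spikes) / bin) * bin, max(spikes) + bin)
  } else {
    spikes <- spikes[spikes >= window[1] & spikes <= window[2]]
  }
  edges <- seq(window[1], window[2] + bin, by = bin)
  ct <- tabulate(findInterval(spikes, edges, rightmost.closed = FALSE),
                 nbins = length(edges) - 1)
  data.frame(time = edges[-length(edges)], count = ct)
}

#' @rdname spike_histogram
#' @param events Event times, ms.
#' @export
psth <- function(events, bin = 5, window = NULL) {
  spike_histogram(events, bin = bin, window = window)
}

#' High-gamma epochs in a spectrogram
#'
#' Finds transient bouts of high-band (default 100-150 Hz) power: local
#' maxima of the band-maximum power trace exceeding a prominence threshold
#' (default 50% of the trace maximum), reported with the time and frequency
#' of maximal power and a window (default 50 ms) centred on it.  Epochs are
#' non-overlapping: maxima within an existing window are absorbed.
#'
#' @param spec A `cdg_spectrogram` covering the band.
#' @param band Frequency band `c(lo, hi)`, Hz.
#' @param window Window width, ms.
#' @param threshold Fraction of the maximal band power required.
#' @param min_rel Minimal band power relative to the spectrogram's global
#'   maximum for any epoch to be reported.
#' @return data.frame with `t_max` (ms), `f` (Hz), `power`, `start`, `end`;
#'   zero rows when the band is silent.
#' @export
find_high_gamma_epochs <- function(spec, band = c(100, 150), window = 50,
                                   threshold = 0.5, min_rel = 0.01) {
  stopifnot(inherits(spec, "cdg_spectrogram"))
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel)) stop("spectrogram does not cover the requested band")
  bp <- apply(spec$power[sel, , drop = FALSE], 2, max)
  bf <- spec$freq[sel][apply(spec$power[sel, , drop = FALSE], 2, which.max)]
  thr <- threshold * max(bp)
  # the band must carry real power relative to the whole spectrogram,
  # otherwise numerical ripple in a silent band would register as epochs
  if (max(bp) <= min_rel * max(spec$power))
    return(data.frame(t_max = numeric(0), f = numeric(0),
                      power = numeric(0), start = numeric(0),
                      end = numeric(0)))
  ord <- order(bp, decreasing = TRUE)
  taken <- data.frame(start = numeric(0), end = numeric(0))
  out <- list()
  t_lo <- min(spec$time); t_hi <- max(spec$time)
  for (i in ord) {
    if (bp[i] < thr) break
    t0 <- spec$time[i]
    if (nrow(taken) && any(t0 >= taken$start & t0 <= taken$end)) next
    # must be a local maximum of the band-power trace
    lo <- max(1, i - 1); hi <- min(length(bp), i + 1)
    if (bp[i] < max(bp[lo:hi])) next
    st <- t0 - window / 2; en <- t0 + window / 2
    # the window must fit inside the analysed interval (this also discards
    # wavelet edge artifacts at the window boundaries)
    if (st < t_lo || en > t_hi) next
    taken <- rbind(taken, data.frame(start = st, end = en))
    out[[length(out) + 1]] <- data.frame(t_max = t0, f = bf[i], power = bp[i],
                                         start = st, end = en)
  }
  if (!length(out)) return(data.frame(t_max = numeric(0), f = numeric(0),
                                      power = numeric(0), start = numeric(0),
                                      end = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$t_max), ]
}

#' Count oscillation cycles via extrema
#'
#' Number of complete cycles (trough-peak-trough) of the dominant rhythm in
#' a window, from the alternating extrema sequence.
#'
#' @inheritParams find_extrema
#' @return Integer cycle count.
#' @export
count_cycles <- function(x, time = NULL, prominence = NULL,
                         prominence_frac = 0.1) {
  ex <- find_extrema(x, time, prominence, prominence_frac)
  sum(ex$type == "peak")
}

# decimate a series (plain subsampling; the signal of interest is far below
# the original Nyquist)
.decimate <- function(x, time, factor) {
  keep <- seq(1, length(x), by = factor)
  list(x = x[keep], time = time[keep])
}

#' Cluster population spikes into volleys
#'
#' Groups a pooled, sorted spike train into volleys separated by silent gaps,
#' as used to count inhibition-paced population cycles in a PING rhythm.
#'
#' @param spikes Numeric spike times (ms), pooled over a population, or a
#'   list of per-cell spike vectors.
#' @param max_gap Largest within-volley inter-spike gap, ms.
#' @param window Optional `c(start, end)` restriction, ms.
#' @return data.frame with one row per volley: `start`, `end`, `n`.
#' @export
cluster_volleys <- function(spikes, max_gap = 5, window = NULL) {
  if (is.list(spikes)) spikes <- unlist(spikes, use.names = FALSE)
  spikes <- sort(spikes)
  if (!is.null(window)) spikes <- spikes[spikes >= window[1] & spikes <= window[2]]
  if (!length(spikes)) return(data.frame(start = numeric(0), end = numeric(0),
                                         n = integer(0)))
  gaps <- which(diff(spikes) > max_gap)
  starts <- c(1L, gaps + 1L)
  ends <- c(gaps, length(spikes))
  data.frame(start = spikes[starts], end = spikes[ends], n = ends - starts + 1L)
}
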