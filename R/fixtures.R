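#' Synthetic waveform and event-train fixtures
#'
#' Generates test signals with exact ground truth so the analysis layer can
#' be validated independently of the simulator.  Amplitudes default to the
#' 1e-2 nAm scale so fixtures exercise the same numeric range as simulated
#' dipoles.
#'
#' Kinds:
#' \describe{
#'   \item{sinusoid}{`f` (Hz), `amplitude`, optional `phase`.}
#'   \item{tone_mixture}{`freqs`, `amplitudes` (vectors).}
#'   \item{asym_triangle}{`rise`, `fall` (ms per half-cycle), `amplitude`;
#'     ground-truth slope ratio is `fall/rise`.}
#'   \item{gated_transient}{`carrier_f`, `carrier_amplitude`, `transient_f`,
#'     `transient_amplitude`, `t_center` (ms), `n_transient_cycles`: a brief
#'     high-frequency bout riding on a slower carrier.}
#'   \item{poisson_train}{`rate` (Hz): event times, exponential intervals.}
#'   \item{burst_train}{`f` (Hz), `sigma` (ms), `events_per_cycle`: rhythmic
#'     Gaussian event bursts.}
#' }
#'
#' @param kind Fixture kind (see Details).
#' @param duration Length, ms.
#' @param dt Sample step, ms (series kinds).
#' @param noise_sd Additive Gaussian noise s.d. (series kinds).
#' @param seed RNG seed.
#' @param ... Kind-specific parameters.
#' @return List with `series` (data.frame `time`, `value`) or `events`
#'   (numeric vector), and `truth` (list of exact ground-truth values).
#' @export
make_fixture <- function(kind = c("sinusoid", "tone_mixture", "asym_triangle",
                                  "gated_transient", "poisson_train",
                                  "burst_train"),
                         duration = 500, dt = 0.5, noise_sd = 0, seed = 1, ...) {
  if (length(kind) != 1L || !kind %in% c("sinusoid", "tone_mixture",
                                         "asym_triangle", "gated_transient",
                                         "poisson_train", "burst_train"))
    stop("unknown fixture kind '", paste(kind, collapse = ","), "'")
  set.seed(seed)
  args <- list(...)
  tgrid <- seq(0, duration, by = dt)
  amp_default <- 1e-2

  add_noise <- function(v) if (noise_sd > 0) v + rnorm(length(v), 0, noise_sd) else v

  if (kind == "sinusoid") {
    f <- args$f %||% 50; A <- args$amplitude %||% amp_default
    ph <- args$phase %||% 0
    v <- A * sin(2 * pi * f * tgrid / 1000 + ph)
    return(list(series = data.frame(time = tgrid, value = add_noise(v)),
                truth = list(f = f, amplitude = A, Phi = 1)))
  }
  if (kind == "tone_mixture") {
    fr <- args$freqs; A <- args$amplitudes %||% rep(amp_default, length(fr))
    v <- rowSums(vapply(seq_along(fr), function(i)
      A[i] * sin(2 * pi * fr[i] * tgrid / 1000), numeric(length(tgrid))))
    return(list(series = data.frame(time = tgrid, value = add_noise(v)),
                truth = list(freqs = fr, amplitudes = A)))
  }
  if (kind == "asym_triangle") {
    rise <- args$rise %||% 15; fall <- args$fall %||% 5
    A <- args$amplitude %||% amp_default
    period <- rise + fall
    phase <- (tgrid %% period)
    v <- ifelse(phase < rise, -A + 2 * A * phase / rise,
                A - 2 * A * (phase - rise) / fall)
    return(list(series = data.frame(time = tgrid, value = add_noise(v)),
                truth = list(Phi = fall / rise, period = period, f = 1000 / period)))
  }
  if (kind == "gated_transient") {
    cf <- args$carrier_f %||% 52; ca <- args$carrier_amplitude %||% amp_default
    tf <- args$transient_f %||% 110; ta <- args$transient_amplitude %||% (4 * amp_default)
    tc <- args$t_center %||% 200; ncyc <- args$n_transient_cycles %||% 1
    half <- ncyc * 1000 / tf / 2
    v <- ca * sin(2 * pi * cf * tgrid / 1000)
    gate <- abs(tgrid - tc) <= half
    v[gate] <- v[gate] + ta * sin(2 * pi * tf * (tgrid[gate] - (tc - half)) / 1000)
    return(list(series = data.frame(time = tgrid, value = add_noise(v)),
                truth = list(carrier_f = cf, transient_f = tf, t_center = tc,
                             window = c(tc - half, tc + half))))
  }
  if (kind == "poisson_train") {
    rate <- args$rate %||% 40
    dr <- poisson_drive(rate, 1)
    ev <- sample_poisson_events(dr, 1, duration, seed = seed)[[1]]
    return(list(events = ev, truth = list(rate = rate, duration = duration)))
  }
  # burst_train
  f <- args$f %||% 50; sigma <- args$sigma %||% 2.5
  epc <- args$events_per_cycle %||% 10
  dr <- burst_drive("proximal", f = f, sigma = sigma, events_per_cycle = epc)
  means <- seq(0, duration, by = 1000 / f)
  ev <- sample_burst_events(dr, duration, seed = seed)
  list(events = ev,
       truth = list(f = f, sigma = sigma, events_per_cycle = epc,
                    cycle_means = means))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
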