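test_that("spectral estimators recover pure tones against an FFT oracle", {
  fx <- make_fixture("sinusoid", f = 50, amplitude = 1e-2, duration = 1000, dt = 0.5)
  x <- fx$series

  w <- welch_periodogram(x)
  expect_true(all(w$power >= 0))
  expect_equal(spectral_peak(w)$freq, 50, tolerance = 1.01)

  # independent FFT oracle for the peak bin
  v <- x$value - mean(x$value)
  sp <- Mod(stats::fft(v))^2
  fr <- (seq_along(v) - 1) / length(v) * 2000
  half <- fr <= 1000
  oracle_f <- fr[half][which.max(sp[half])]
  expect_lt(abs(spectral_peak(w)$freq - oracle_f), 2000 / length(v) + 1e-9)

  # doubling the amplitude quadruples peak power
  fx2 <- make_fixture("sinusoid", f = 50, amplitude = 2e-2, duration = 1000, dt = 0.5)
  w2 <- welch_periodogram(fx2$series)
  expect_equal(spectral_peak(w2)$power / spectral_peak(w)$power, 4, tolerance = 1e-6)

  # Morlet ridge at the tone frequency; two-tone mixture keeps amplitude order
  m <- morlet_spectrogram(x, fmin = 2)
  ridge <- m$freq[which.max(rowMeans(m$power))]
  expect_equal(ridge, 50, tolerance = 1.01)

  mix <- make_fixture("tone_mixture", freqs = c(40, 110),
                      amplitudes = c(2e-2, 1e-2), duration = 1000, dt = 0.5)
  mm <- morlet_spectrogram(mix$series, fmin = 2)
  prof <- rowMeans(mm$power)
  p40 <- max(prof[abs(mm$freq - 40) <= 1])
  p110 <- max(prof[abs(mm$freq - 110) <= 1])
  expect_gt(p40, p110)
  lo <- mm$freq >= 20 & mm$freq <= 60
  hi <- mm$freq >= 90 & mm$freq <= 130
  expect_equal(mm$freq[lo][which.max(prof[lo])], 40, tolerance = 1.01)
  expect_equal(mm$freq[hi][which.max(prof[hi])], 110, tolerance = 1.01)

  expect_error(morlet_spectrogram(x$value[1:100], x$time[1:100], fmin = 1),
               "wavelet support")
})

test_that("extrema detection is robust to small high-frequency ripple", {
  tt <- seq(0, 500, by = 0.5)
  clean <- sin(2 * pi * 20 * tt / 1000)
  ex <- find_extrema(clean, tt)
  expect_equal(sum(ex$type == "peak"), 10)
  expect_equal(sum(ex$type == "trough"), 10)
  # strict alternation
  expect_true(all(ex$type[-1] != ex$type[-nrow(ex)]))

  ripple <- clean + 0.1 * sin(2 * pi * 200 * tt / 1000)
  exr <- find_extrema(ripple, tt)
  expect_equal(sum(exr$type == "peak"), sum(ex$type == "peak"))
})

test_that("slope ratio matches construction on triangle waves", {
  # symmetric triangle: Phi = 1 on every cycle
  sym <- make_fixture("asym_triangle", rise = 10, fall = 10, duration = 200, dt = 0.1)
  phi_s <- slope_ratio(find_extrema(sym$series))
  expect_equal(phi_s$Phi, 1, tolerance = 0.02)

  # rise 15 ms / fall 5 ms: phi_i = 1/3 on every cycle
  asym <- make_fixture("asym_triangle", rise = 15, fall = 5, duration = 200, dt = 0.1)
  phi_a <- slope_ratio(find_extrema(asym$series))
  expect_equal(asym$truth$Phi, 1 / 3)
  expect_true(all(abs(phi_a$phi - 1 / 3) < 0.02))
  expect_equal(phi_a$Phi, 1 / 3, tolerance = 0.02)
  expect_lt(phi_a$p_value, 0.05)
  expect_equal(phi_a$alternative, "less")

  # amplitude scaling and time shift leave Phi unchanged
  sc <- asym$series; sc$value <- sc$value * 7.3
  expect_equal(slope_ratio(find_extrema(sc))$Phi, phi_a$Phi)
  sh <- asym$series; sh$time <- sh$time + 123
  expect_equal(slope_ratio(find_extrema(sh))$Phi, phi_a$Phi)

  # time reversal inverts the per-cycle ratios
  rv <- asym$series
  rv$value <- rev(rv$value)
  phi_r <- slope_ratio(find_extrema(rv))
  expect_equal(phi_r$Phi, 3, tolerance = 0.05)

  # non-alternating sequences are rejected
  bad <- data.frame(time = c(1, 2, 3), value = c(1, 2, 0),
                    type = c("peak", "peak", "trough"))
  expect_error(slope_ratio(bad), "alternate")

  # fewer than 3 cycles: Phi undefined
  short <- make_fixture("asym_triangle", rise = 15, fall = 5, duration = 45, dt = 0.1)
  expect_true(is.na(slope_ratio(find_extrema(short$series))$Phi))
})

test_that("spike histograms conserve counts for any binning", {
  h <- spike_histogram(rep(10.2, 10), bin = 1)
  expect_equal(max(h$count), 10)
  expect_equal(sum(h$count), 10)

  set.seed(4)
  ev <- runif(1000, 0, 1000)
  for (b in c(1, 5, 7)) expect_equal(sum(spike_histogram(ev, bin = b)$count), 1000)

  # uniform stream: per-bin counts within the Poisson 99% band of the mean
  h5 <- psth(ev, bin = 5, window = c(0, 1000))
  mu <- 1000 / (1000 / 5)
  band <- stats::qpois(c(0.005, 0.995), mu)
  frac_in <- mean(h5$count >= band[1] & h5$count <= band[2])
  expect_gt(frac_in, 0.95)

  expect_error(spike_histogram(ev, bin = 0), "bin")
})

test_that("high-gamma epochs localize constructed transients", {
  fx <- make_fixture("gated_transient", carrier_f = 52, transient_f = 110,
                     t_center = 200, n_transient_cycles = 1,
                     duration = 500, dt = 0.5)
  m <- morlet_spectrogram(fx$series, fmin = 2)
  ep <- find_high_gamma_epochs(m)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$t_max, 200, tolerance = 6)
  expect_equal(ep$start, ep$t_max - 25)
  expect_equal(ep$end, ep$t_max + 25)
  expect_true(ep$f >= 100 && ep$f <= 150)

  # two transients 150 ms apart give two disjoint epochs
  s2 <- fx$series
  fx2 <- make_fixture("gated_transient", carrier_f = 52, transient_f = 108,
                      t_center = 350, n_transient_cycles = 1,
                      duration = 500, dt = 0.5)
  s2$value <- s2$value + fx2$series$value -
    1e-2 * sin(2 * pi * 52 * s2$time / 1000)  # remove doubled carrier
  m2 <- morlet_spectrogram(s2, fmin = 2)
  ep2 <- find_high_gamma_epochs(m2)
  expect_equal(nrow(ep2), 2)
  expect_true(all(diff(sort(ep2$t_max)) >= 50))
  expect_equal(sort(ep2$t_max), c(200, 350), tolerance = 8)
})

test_that("time series round-trip through delimited text", {
  d <- data.frame(time = seq(0, 10, 0.5), value = rnorm(21))
  path <- tempfile(fileext = ".txt")
  write_timeseries(d, path)
  back <- read_timeseries(path)
  expect_equal(back$value, d$value)
  # headerless comma-separated input is also accepted
  path2 <- tempfile(fileext = ".csv")
  utils::write.table(d, path2, sep = ",", row.names = FALSE, col.names = FALSE)
  back2 <- read_timeseries(path2)
  expect_equal(back2$value, d$value)
})

test_that("fixture generators produce their stated ground truth", {
  s <- make_fixture("sinusoid", f = 50, amplitude = 1e-2, noise_sd = 0,
                    duration = 200, dt = 0.5)
  expect_equal(max(abs(s$series$value)), 1e-2, tolerance = 1e-3)
  expect_equal(s$truth$f, 50)

  p <- make_fixture("poisson_train", rate = 40, duration = 2000, seed = 9)
  expect_equal(length(p$events), 40 * 2, tolerance = 0.4)

  b <- make_fixture("burst_train", f = 50, sigma = 0, duration = 500, seed = 1)
  expect_length(b$events, 250)

  expect_error(make_fixture("chirp"), "unknown fixture kind")

  # identical seeds give identical fixtures
  a1 <- make_fixture("burst_train", f = 50, sigma = 2.5, duration = 500, seed = 7)
  a2 <- make_fixture("burst_train", f = 50, sigma = 2.5, duration = 500, seed = 7)
  expect_identical(a1$events, a2$events)
})
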