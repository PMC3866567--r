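test_that("cell construction satisfies the morphology rules", {
  l5 <- build_cell("l5_pyramidal")
  l2 <- build_cell("l23_pyramidal")
  bk <- build_cell("basket")

  # basket: one compartment, Na/K/leak only
  expect_equal(nrow(bk$compartments), 1L)
  active <- names(Filter(function(g) g > 0, bk$channels$soma))
  expect_setequal(active, c("na", "k", "leak"))

  # pyramidal layout: soma, apical compartments, one oblique, three basilar
  for (cell in list(l5, l2)) {
    nm <- cell$compartments$name
    expect_true("soma" %in% nm)
    expect_equal(sum(grepl("^basal", nm)), 3L)
    expect_equal(sum(nm == "apical_oblique"), 1L)
  }
  # L5 has one extra apical compartment
  expect_equal(sum(grepl("^apical", l5$compartments$name)),
               sum(grepl("^apical", l2$compartments$name)) + 1L)

  # apical-axis extent ratio is exactly 2.21
  expect_equal(apical_extent(l5) / apical_extent(l2), 2.21, tolerance = 1e-12)

  # oblique does not contribute to the CD
  expect_equal(l5$compartments$z_projection[l5$compartments$name == "apical_oblique"], 0)
  expect_equal(l2$compartments$z_projection[l2$compartments$name == "apical_oblique"], 0)

  # compartments longer than 100 um carry one extra internal point
  expect_equal(l5$compartments$n_internal_points,
               ifelse(l5$compartments$length > 100, 2L, 1L))

  expect_error(build_cell("granule"), "unknown cell kind")
})

test_that("passive charging matches the analytic RC solution", {
  p <- passive_soma_params(leak = 0.1, e_leak = -65)
  cell <- build_cell("basket", p)
  area <- pi * 39 * 20 * 1e-8                 # cm^2
  R <- 1 / (0.1 * area * 1e3)                 # MOhm
  C <- 1.0 * area * 1e3                       # nF
  tau <- R * C                                # ms
  I <- 0.02                                   # nA
  r <- integrate_cell(cell, inputs = list(I = list(soma = I)),
                      dt = 0.025, duration = ceiling(tau) * 3, v_init = -65)
  v_at_tau <- unname(r$v[which.min(abs(r$time - tau)), "soma"])
  expected <- -65 + I * R * (1 - exp(-1))
  # relative error of the charging amplitude < 1%
  expect_lt(abs((v_at_tau - expected) / (I * R)), 0.01)
})

test_that("multi-compartment passive charging matches an implicit-Euler cable oracle", {
  p <- passive_chain_params(leak = 0.1, e_leak = -65)
  cell <- build_cell("basket", p)
  nodes <- cell$nodes
  dt <- 0.025; nsteps <- 4000; I <- 0.05
  r <- integrate_cell(cell, inputs = list(I = list(soma = I)),
                      dt = dt, duration = nsteps * dt, v_init = -65)

  # independent oracle: dense backward-Euler on the 3-node cable
  N <- nrow(nodes)
  gl <- 0.1 * nodes$area * 1e3
  C <- nodes$cap
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    A[i, i] <- C[i] / dt + gl[i]
    pa <- nodes$parent[i]
    if (pa >= 0) {
      ga <- 1 / nodes$r_ax[i]
      A[i, i] <- A[i, i] + ga
      A[pa + 1, pa + 1] <- A[pa + 1, pa + 1] + ga
      A[i, pa + 1] <- A[i, pa + 1] - ga
      A[pa + 1, i] <- A[pa + 1, i] - ga
    }
  }
  v <- rep(-65, N)
  vtrace <- matrix(NA_real_, nsteps + 1, N); vtrace[1, ] <- v
  for (s in seq_len(nsteps)) {
    b <- C / dt * v + gl * (-65)
    b[1] <- b[1] + I
    v <- solve(A, b)
    vtrace[s + 1, ] <- v
  }
  rms <- sqrt(mean((r$v - vtrace)^2)) / diff(range(vtrace))
  expect_lt(rms, 0.005)
})

test_that("a resting cell stays at rest and a driven cell spikes", {
  l5 <- build_cell("l5_pyramidal")
  r <- integrate_cell(l5, dt = 0.025, duration = 550)
  expect_length(r$spikes, 0)
  soma <- r$v[, "soma"]
  last100 <- soma[r$time >= 450]
  expect_lt(max(last100) - min(last100), 0.1)      # drift < 0.1 mV
  expect_true(all(is.finite(r$v)))

  # suprathreshold tonic somatic current elicits spiking within 550 ms
  rs <- integrate_cell(l5, inputs = list(I = list(soma = 1.5)),
                       dt = 0.025, duration = 550)
  expect_gte(length(rs$spikes), 1)
})

test_that("halving the time step moves spike times by < 0.1 ms over a cycle", {
  l5 <- build_cell("l5_pyramidal")
  r1 <- integrate_cell(l5, inputs = list(I = list(soma = 1.2)),
                       dt = 0.025, duration = 60)
  r2 <- integrate_cell(l5, inputs = list(I = list(soma = 1.2)),
                       dt = 0.0125, duration = 60)
  # within one oscillation cycle of the onset (the first two spikes)
  expect_gte(length(r1$spikes), 1)
  expect_gte(length(r2$spikes), 1)
  expect_lt(abs(r1$spikes[1] - r2$spikes[1]), 0.1)
})

test_that("numerical instability is reported with the compartment and time", {
  l5 <- build_cell("l5_pyramidal")
  expect_error(
    integrate_cell(l5, inputs = list(I = list(soma = 1e5)),
                   dt = 0.025, duration = 10),
    "instability.*soma")
})

test_that("detect_spikes finds upward crossings with refractory coalescing", {
  tt <- seq(0, 100, by = 0.1)
  expect_length(detect_spikes(rep(-65, length(tt)), tt), 0)

  v <- rep(-65, length(tt))
  v[tt >= 20 & tt < 21] <- 10
  v[tt >= 40 & tt < 41] <- 10
  s <- detect_spikes(v, tt)
  expect_length(s, 2)
  expect_equal(diff(s), 20, tolerance = 0.01)

  # two crossings 0.5 ms apart coalesce into one spike
  v2 <- rep(-65, length(tt))
  v2[tt >= 20 & tt < 20.2] <- 10
  v2[tt >= 20.5 & tt < 20.7] <- 10
  expect_length(detect_spikes(v2, tt), 1)
})
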