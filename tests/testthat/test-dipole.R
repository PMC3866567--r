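test_that("dipole arithmetic follows the axial-current formula", {
  # two segments: (v_parent - v_child)/r * z, 10 mV / 100 MOhm * 100 um
  nodes <- data.frame(parent = c(-1L, 0L), r_ax = c(NA, 100), z = c(50, 100))
  v <- matrix(c(10, 0), nrow = 1)   # parent 10 mV above child
  q <- compute_dipole(v, nodes)
  expect_equal(q, (10 / 100) * 100 * 1e-6)  # 1e-5 nAm

  # uniform voltage -> zero dipole
  vu <- matrix(c(-65, -65), nrow = 1)
  expect_equal(compute_dipole(vu, nodes), 0)

  # doubling every z doubles Q
  nodes2 <- nodes; nodes2$z <- nodes2$z * 2
  expect_equal(compute_dipole(v, nodes2), 2 * q)
})

test_that("engine dipole equals a brute-force per-segment summation", {
  net <- tiny_network(n_pyr = 3, n_inh = 1)
  sim <- attach_drives(net, list(poisson_drive(100, 1e-2, layer = "L5")))
  run <- simulate(sim, duration = 100, dt = 0.025, seed = 2,
                  record_nodes = seq_len(nrow(net$nodes)))
  nodes <- net$nodes
  pyr <- net$cells$type[nodes$cell] == "pyramidal"
  # independent brute-force loop over segments
  q <- numeric(nrow(run$v))
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent[i] < 0 || !pyr[i] || nodes$z[i] == 0) next
    q <- q + (run$v[, nodes$parent[i] + 1L] - run$v[, i]) / nodes$r_ax[i] *
      nodes$z[i] * 1e-6
  }
  expect_lt(max(abs(q - run$dipole$L5)) / max(abs(q)), 1e-12)

  # linearity: the layer CD is the sum of disjoint per-cell contributions
  qcells <- sapply(1:3, function(cid) {
    sel <- nodes$cell == cid
    sub <- nodes[sel, ]
    # remap parents into the subset (soma roots stay -1)
    sub$parent <- match(sub$parent, which(sel) - 1L) - 1L
    sub$parent[is.na(sub$parent)] <- -1L
    compute_dipole(run$v[, sel, drop = FALSE], sub)
  })
  expect_equal(rowSums(qcells), run$dipole$L5, tolerance = 1e-12)
})

test_that("aggregate CD is the linear sum of the layer series", {
  run <- cached_scenario_run("fig5c_two_layer_weak_ping", seed = 1)$run
  expect_equal(run$dipole$aggregate, run$dipole$L2 + run$dipole$L5)
  expect_true(all(is.finite(run$dipole$aggregate)))
})

test_that("baseline renormalization is affine, invertible, and centres a resting run", {
  x <- rep(2e-3, 100)
  y <- baseline_renormalize(x, "L2", n_pyr = 100)
  off <- 100 * cdg_parameters()$baseline$l2_offset
  expect_equal(y, x - off)
  expect_equal(baseline_renormalize(y, "L2", n_pyr = 100, invert = TRUE), x)

  tt <- seq(50, 550, by = 1)
  y5 <- baseline_renormalize(x[1:length(tt)], "L5", time = tt, n_pyr = 100)
  expect_equal(baseline_renormalize(y5, "L5", time = tt, n_pyr = 100,
                                    invert = TRUE), x[1:length(tt)])
  expect_error(baseline_renormalize(x, "L4"), "arg")
  expect_error(baseline_renormalize(x, "L5"), "time")
})

test_that("a drive-free L2/3 network renormalizes to approximately zero", {
  cfg <- ping_regime("l2_weak")$config
  net <- build_network("L2", cfg)
  run <- simulate(attach_drives(net, list()), duration = 300, dt = 0.025, seed = 1)
  sel <- run$time >= 50
  cd <- baseline_renormalize(run$dipole$L2[sel], "L2", n_pyr = 100)
  off <- abs(100 * cdg_parameters()$baseline$l2_offset)
  expect_lt(max(abs(cd)), off)
})

test_that("network-size extrapolation reports powers of ten", {
  expect_equal(estimate_network_size(0.26, 100, 10)$exponent, 4)
  expect_equal(estimate_network_size(0.019, 100, 10)$exponent, 5)
  r <- estimate_network_size(10, 100, 10)
  expect_equal(r$n_required, 100)
  expect_equal(r$order_of_magnitude, 100)
  expect_error(estimate_network_size(0, 100), "positive")
  expect_error(estimate_network_size(-1, 100), "positive")
})

test_that("dipole series are written as two-column delimited text", {
  d <- dipole_ts(time = 0:10, layer_cd = data.frame(L5 = sin(0:10)))
  dir <- tempfile()
  paths <- write_dipole(d, dir)
  expect_true(all(file.exists(file.path(dir, c("cd_L5.txt", "cd_aggregate.txt")))))
  back <- read_timeseries(file.path(dir, "cd_L5.txt"))
  expect_equal(back$value, sin(0:10))
})
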