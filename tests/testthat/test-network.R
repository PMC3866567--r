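test_that("distance-dependent weight scaling is a decreasing Gaussian", {
  expect_equal(weight_scale(0, 3), 1)
  d <- seq(0, 8, by = 0.5)
  w <- weight_scale(d, 3)
  expect_true(all(diff(w) < 0))
  expect_equal(weight_scale(3, 3), exp(-1))
  expect_error(weight_scale(1, 0), "space constant")
  expect_error(weight_scale(1, -2), "space constant")
})

test_that("network wiring follows the regime rules", {
  strong <- ping_regime("l5_strong")
  expect_equal(strong$config$g_ei, 6e-5)
  expect_equal(strong$config$g_ie, 3e-1)
  expect_equal(strong$config$g_ii, 0)
  weak2 <- ping_regime("l2_weak")
  expect_equal(weak2$config$g_ei, 1.2e-3)
  expect_equal(weak2$config$g_ie, 7e-3)
  expect_equal(weak2$config$g_ii, 1e-2)

  net <- build_network("L5", strong$config)
  expect_equal(sum(net$cells$type == "pyramidal"), 100)
  expect_equal(sum(net$cells$type == "basket"), 35)

  conns <- net$connections
  pre_t <- net$cells$type[conns$pre]
  post_t <- net$cells$type[conns$post_cell]
  # no E-E and, with g_ii = 0, no I-I
  expect_equal(sum(pre_t == "pyramidal" & post_t == "pyramidal"), 0)
  expect_equal(sum(pre_t == "basket" & post_t == "basket"), 0)
  # transmitters: E->I AMPA, I->E GABA-A
  expect_true(all(conns$receptor[pre_t == "pyramidal"] == "ampa"))
  expect_true(all(conns$receptor[pre_t == "basket"] == "gabaa"))

  weak <- ping_regime("l5_weak_gpois075")
  netw <- build_network("L5", weak$config)
  pre_tw <- netw$cells$type[netw$connections$pre]
  post_tw <- netw$cells$type[netw$connections$post_cell]
  expect_gt(sum(pre_tw == "basket" & post_tw == "basket"), 0)

  # two-layer build has zero cross-layer synapses
  net2 <- build_network(c("L2", "L5"),
                        list(L2 = ping_regime("l2_weak")$config,
                             L5 = weak$config))
  cl <- net2$cells$layer
  expect_equal(sum(cl[net2$connections$pre] != cl[net2$connections$post_cell]), 0)

  expect_error(build_network("L5", strong$config, allow_ee = TRUE), "E-E")
  expect_error(build_network("L5", strong$config, interlaminar = TRUE),
               "interlaminar")
})

test_that("synaptic conductance transients have the stated kinetics", {
  # single GABA-A event: tail decays with the 5 ms time constant
  g1 <- syn_conductance(10, "gabaa", weight = 1, duration = 60, dt = 0.025)
  expect_true(all(g1$g >= 0))
  peak_i <- which.max(g1$g)
  expect_gt(g1$time[peak_i], 11)  # peaks after onset (delivery delay 1 ms)
  tail <- g1$time > g1$time[peak_i] + 10 & g1$g > 0
  fit <- stats::lm(log(g1$g[tail]) ~ g1$time[tail])
  expect_equal(unname(stats::coef(fit)[2]), -1 / 5, tolerance = 0.02)

  # zero spikes -> identically zero trace
  g0 <- syn_conductance(numeric(0), "gabaa", duration = 20)
  expect_true(all(g0$g == 0))

  # linear superposition of two events 1 ms apart
  ga <- syn_conductance(10, "ampa", weight = 2, duration = 60)
  gb <- syn_conductance(11, "ampa", weight = 2, duration = 60)
  gab <- syn_conductance(c(10, 11), "ampa", weight = 2, duration = 60)
  expect_lt(max(abs(gab$g - (ga$g + gb$g))), 1e-12 * max(gab$g))
})

test_that("the network exports a well-formed edge list", {
  net <- tiny_network()
  edges <- network_edges(net)
  expect_named(edges, c("pre", "post", "transmitter", "weight", "delay"))
  expect_true(all(edges$weight >= 0))
  expect_true(all(edges$transmitter %in% c("ampa", "gabaa")))
  path <- tempfile(fileext = ".txt")
  network_edges(net, path)
  reread <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(reread), nrow(edges))
})

test_that("removing somatic inhibition abolishes the weak-PING spectral peak", {
  weak <- cached_scenario_run("fig2b_weak_ping", 1)
  a <- weak$analysis$L5
  f0 <- a$welch_peak$freq
  p0 <- a$welch_peak$power

  cfg <- ping_regime("l5_weak_gpois075")$config
  cfg$g_ie <- 0
  net <- build_network("L5", cfg)
  sim <- attach_drives(net, list(poisson_drive(40, 0.75e-2, layer = "L5")))
  run <- simulate(sim, duration = 550, dt = 0.025, seed = 1)
  a2 <- analyze_cd(run, "L5")
  p_at_f0 <- a2$welch$power[which.min(abs(a2$welch$freq - f0))]
  expect_gt(p0 / p_at_f0, 10)
})
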