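test_that("shipped scenario configurations round-trip and validate", {
  expect_true(length(list_scenarios()) >= 12)

  sc <- load_scenario("table1_l5_weak_ping")
  expect_equal(sc$duration, 550)
  expect_equal(sc$dt, 0.025)
  expect_equal(sc$window, c(50, 550))
  # Table values: lambda_pois 40 Hz, g_pois 1e-2 for the L5 weak regime
  expect_equal(sc$drives[[1]]$rate, 40)
  expect_equal(sc$drives[[1]]$g_max, 1e-2)
  expect_equal(sc$network$L5$g_ei, 9.1e-4)
  expect_equal(sc$network$L5$g_ie, 8e-2)
  expect_equal(sc$network$L5$g_ii, 7.5e-3)

  path <- tempfile(fileext = ".yaml")
  write_config(sc, path)
  sc2 <- load_config(path)
  expect_equal(sc2[names(sc2) != "name"], sc[names(sc) != "name"])
  expect_equal(sc2$name, sc$name)
})

test_that("invalid configurations are rejected with field paths", {
  expect_error(network_config("L5", g_ei = 1e-3, g_ie = -1), ">= 0")

  sc <- load_scenario("fig2b_weak_ping")
  bad <- unclass(sc)
  bad$network$L5$g_ie <- -0.1
  rep <- validate_scenario(bad)
  expect_false(rep$valid)
  expect_true(any(grepl("network.L5.g_ie", rep$errors)))

  # unknown keys rejected
  path <- tempfile(fileext = ".yaml")
  write_config(sc, path)
  txt <- readLines(path)
  writeLines(c(txt, "extra_knob: 1"), path)
  expect_error(load_config(path), "unknown key")

  # missing required fields listed
  writeLines("name: x", path)
  expect_error(load_config(path), "missing required field")
})

test_that("a zero-drive scenario yields no spikes and no statistics", {
  sc <- scenario("quiet", "L5",
                 list(L5 = network_config("L5", g_ei = 9.1e-4, g_ie = 8e-2,
                                          g_ii = 7.5e-3, n_pyr = 9, n_inh = 4,
                                          space_constant = 3.5)),
                 drives = list(), duration = 250, window = c(50, 250), seed = 1)
  out <- run_scenario(sc)
  expect_equal(sum(lengths(out$run$spikes)), 0)
  expect_true(is.na(out$summary$Phi))
  expect_equal(out$summary$n_epochs, 0)
})

test_that("runs are bit-reproducible for identical seeds", {
  sc <- scenario("repro", "L5",
                 list(L5 = network_config("L5", g_ei = 9.1e-4, g_ie = 8e-2,
                                          g_ii = 7.5e-3, n_pyr = 9, n_inh = 4,
                                          space_constant = 3.5)),
                 drives = list(poisson_drive(40, 1e-2, layer = "L5")),
                 duration = 250, window = c(50, 250), seed = 3)
  a <- run_scenario(sc, seed = 3)
  b <- run_scenario(sc, seed = 3)
  expect_identical(a$run$dipole$L5, b$run$dipole$L5)
  expect_identical(a$run$spikes, b$run$spikes)
  c <- run_scenario(sc, seed = 4)
  expect_false(identical(a$run$dipole$L5, c$run$dipole$L5))
})

test_that("parameter sweeps tabulate one row per value", {
  sc <- scenario("sw", "L5",
                 list(L5 = network_config("L5", g_ei = 9.1e-4, g_ie = 8e-2,
                                          g_ii = 7.5e-3, n_pyr = 9, n_inh = 4,
                                          space_constant = 3.5)),
                 drives = list(burst_drive("proximal", f = 50, sigma = 2.5,
                                           layer = "L5")),
                 duration = 250, window = c(50, 250), seed = 2)
  expect_error(sweep_scenario(sc, "drives.1.sigma", numeric(0)), "non-empty")

  one <- sweep_scenario(sc, "drives.1.sigma", 2.5, seed = 2)
  ref <- run_scenario(sc, seed = 2)$summary
  expect_equal(one$peak_f, ref$peak_f)
  expect_equal(one$max_pw, ref$peak_power)
  expect_equal(one$rel_power, 1)

  two <- sweep_scenario(sc, "drives.1.sigma", c(2.5, 7.5), seed = 2)
  expect_equal(nrow(two), 2)
  expect_equal(two$rel_power[1], 1)
})

test_that("run bundles are written as replayable text", {
  sc <- scenario("bundle", "L5",
                 list(L5 = network_config("L5", g_ei = 9.1e-4, g_ie = 8e-2,
                                          g_ii = 7.5e-3, n_pyr = 9, n_inh = 4,
                                          space_constant = 3.5)),
                 drives = list(poisson_drive(40, 1e-2, layer = "L5")),
                 duration = 250, window = c(50, 250), seed = 1)
  out <- run_scenario(sc)
  dir <- tempfile()
  write_run_bundle(out, dir)
  expect_true(file.exists(file.path(dir, "cd_L5.txt")))
  expect_true(file.exists(file.path(dir, "spikes.txt")))
  expect_true(file.exists(file.path(dir, "events.txt")))
  expect_true(file.exists(file.path(dir, "scenario.yaml")))
  replay <- load_config(file.path(dir, "scenario.yaml"))
  expect_equal(replay$drives[[1]]$rate, 40)
})
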