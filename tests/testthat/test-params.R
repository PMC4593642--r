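test_that("presets bind pore size, fiber diameter and segmentation", {
  p05 <- sim_params(preset = "pore0.5", seed = 1)
  p15 <- sim_params(preset = "pore1.5", seed = 1)
  expect_equal(p05$network$fiber_diameter, 28)
  expect_equal(p05$network$n_div, 1)
  expect_equal(p15$network$fiber_diameter, 41)
  expect_equal(p15$network$n_div, 3)
  expect_equal(p15$network$pore_size, 1.5)
  expect_error(sim_params(preset = "pore2.0", seed = 1), "unknown preset")
})

test_that("overrides are applied and unknown keys are rejected by name", {
  p <- sim_params(seed = 1, network.pore_size = 0.8, motor.c_m = 0.2)
  expect_equal(p$network$pore_size, 0.8)
  expect_equal(p$motor$c_m, 0.2)
  expect_error(sim_params(seed = 1, network.pore_sizes = 1),
               "pore_sizes")
  expect_error(sim_params(seed = 1, nonsense = 1), "unknown parameter")
})

test_that("validation catches inconsistent physical parameters", {
  expect_error(sim_params(seed = 1, network.pore_size = 0.05),
               "crosslink")
  expect_error(sim_params(seed = 1, network.p_f = 1.4), "p_f")
  expect_error(sim_params(seed = 1, engine.dt_min = 1, engine.dt_max = 0.01),
               "dt_min")
})

test_that("config files round-trip and an empty file yields full defaults", {
  p <- sim_params(preset = "pore1.5", seed = 42, fiber.E_f = 5e5)
  f <- tempfile(fileext = ".yaml")
  write_config(p, f)
  q <- load_config(f)
  expect_equal(unclass(q), unclass(p))

  empty <- tempfile(fileext = ".yaml")
  writeLines("seed: 7", empty)
  d <- load_config(empty)
  expect_equal(d$motor$v_m0, 0.01)
  expect_equal(d$binding$lambda, 0.03)
  expect_equal(d$seed, 7)
})

test_that("configs without a seed or with misspelled keys fail loudly", {
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  expect_error(load_config(f), "seed")
  writeLines(c("seed: 1", "motor:", "  v_m00: 3"), f)
  expect_error(load_config(f), "v_m00")
  writeLines(c("seed: 1", "motors:", "  v_m0: 3"), f)
  expect_error(load_config(f), "motors")
})

test_that("config hash changes when any parameter changes", {
  p <- sim_params(seed = 1)
  q <- sim_params(seed = 1, motor.c_m = 0.11)
  expect_false(config_hash(p) == config_hash(q))
  expect_equal(config_hash(p), config_hash(sim_params(seed = 1)))
})
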