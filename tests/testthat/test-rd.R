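# Reaction-diffusion module: conservation, closed-form kinetics, secretion
# mapping and the integrity update.

rd_quiet <- function(seed = 1, ...) {
  # all reaction constants silenced; no VEGF Dirichlet face
  p <- sim_params(seed = seed,
                  rd = list(k_vegf_decay = 0, k_mmp2_decay = 0,
                            k_ligand_decay = 0, k_ecm_deg = 0,
                            kon_timp2_mmp2 = 0, kon_complex_mt1 = 0,
                            kon_timp2_mt1 = 0, koff_complex = 0,
                            alpha_timp2 = 0, alpha_mt1 = 0,
                            vegf_far = NA), ...)
  p
}

test_that("diffusing species conserve mass under zero reactions and zero flux", {
  p <- rd_quiet()
  fields <- make_fields(p, c(6, 6, 6))
  set.seed(3)
  fields$mmp2 <- array(runif(prod(fields$dims)), fields$dims) * 1e-9
  fields$timp2 <- array(runif(prod(fields$dims)), fields$dims) * 1e-9
  m0_m <- total_mass(fields, "mmp2")
  m0_t <- total_mass(fields, "timp2")
  for (i in 1:1000) fields <- rd_step(fields, p, dt = 0.05)
  expect_lt(abs(total_mass(fields, "mmp2") - m0_m) / m0_m, 1e-6)
  expect_lt(abs(total_mass(fields, "timp2") - m0_t) / m0_t, 1e-6)
  # diffusion homogenized the field
  expect_lt(diff(range(fields$mmp2)) / mean(fields$mmp2), 1e-6)
})

test_that("zero fields with no sources stay identically zero", {
  p <- rd_quiet()
  fields <- make_fields(p, c(4, 4, 4))
  fields$vegf[] <- 0; fields$ligand[] <- 0
  for (i in 1:20) fields <- rd_step(fields, p, dt = 0.5)
  for (nm in c("vegf", "mmp2", "timp2", "ligand", "mt1", "complex")) {
    expect_true(all(fields[[nm]] == 0))
  }
})

test_that("uniform VEGF decays along the closed-form exponential", {
  p <- rd_quiet()
  p$rd$k_vegf_decay <- 8.2e-6
  fields <- make_fields(p, c(4, 4, 4))
  C0 <- 1e-9
  fields$vegf[] <- C0
  t_total <- 1e5
  for (i in 1:100) fields <- rd_step(fields, p, dt = t_total / 100)
  expect_lt(max(abs(fields$vegf - C0 * exp(-8.2e-6 * t_total))) /
              (C0 * exp(-8.2e-6 * t_total)), 1e-4)
})

test_that("the TIMP-2:MMP-2 sink removes both species at identical rates", {
  p <- rd_quiet()
  p$rd$kon_timp2_mmp2 <- 5e5
  fields <- make_fields(p, c(4, 4, 4))
  fields$mmp2[] <- 4e-9
  fields$timp2[] <- 1e-9
  m0 <- total_mass(fields, "mmp2"); t0 <- total_mass(fields, "timp2")
  for (i in 1:50) fields <- rd_step(fields, p, dt = 1)
  dm <- m0 - total_mass(fields, "mmp2")
  dtm <- t0 - total_mass(fields, "timp2")
  expect_gt(dm, 0)
  expect_equal(dm, dtm, tolerance = 1e-9)
})

test_that("secretion sources map filopodial roots to grid cells additively", {
  p <- sim_params(seed = 1)
  fields <- make_fields(p, c(6, 6, 6))
  expect_length(secretion_sources(list(), fields)$cells, 0)
  f1 <- make_filopodium(c(1.2, 1.2, 1.2), c(1, 0, 0), p)
  s1 <- secretion_sources(list(f1), fields)
  expect_length(s1$cells, 1)
  expect_equal(s1$mult, 1)
  # two roots in the same cell add their rates
  f2 <- make_filopodium(c(1.4, 1.4, 1.4), c(1, 0, 0), p)
  s2 <- secretion_sources(list(f1, f2), fields)
  expect_length(s2$cells, 1)
  expect_equal(s2$mult, 2)
  # a root outside the grid clamps to the nearest cell
  f3 <- make_filopodium(c(-3, 2, 2), c(1, 0, 0), p)
  s3 <- secretion_sources(list(f3), fields)
  expect_length(s3$cells, 1)
})

test_that("ECM integrity follows the degradation law and is monotone", {
  p <- sim_params(seed = 2, network.domain = c(4, 4, 4), preset = "pore1.0")
  net <- build_network(p)
  fields <- make_fields(p, c(4, 4, 4))
  # no MMP-2: integrity unchanged
  net1 <- update_ecm_integrity(net, fields, p, dt = 10)
  expect_equal(net1$C_ecm, net$C_ecm)
  # constant 1 uM MMP-2: effective rate k_deg * C = 1.04/s (closed form)
  fields$mmp2[] <- 1e-6
  net2 <- update_ecm_integrity(net, fields, p, dt = 1)
  expect_equal(net2$C_ecm / net$C_ecm,
               rep(exp(-1.04), nrow(net$nodes)), tolerance = 1e-9)
  # monotone non-increasing along any trajectory
  traj <- net
  last <- ecm_integrity(traj)
  for (i in 1:5) {
    fields$mmp2[] <- runif(1) * 1e-6
    traj <- update_ecm_integrity(traj, fields, p, dt = 0.5)
    I <- ecm_integrity(traj)
    expect_true(all(I <= last + 1e-15))
    last <- I
  }
  # disabling degradation freezes the field
  p_off <- p; p_off$rd$degradation <- FALSE
  net3 <- update_ecm_integrity(net, fields, p_off, dt = 10)
  expect_equal(net3$C_ecm, net$C_ecm)
})

test_that("concentrations never go negative and clipping is logged", {
  p <- rd_quiet()
  p$rd$k_mmp2_decay <- 0.5
  fields <- make_fields(p, c(4, 4, 4))
  fields$mmp2[] <- 1e-9
  for (i in 1:30) fields <- rd_step(fields, p, dt = 2)
  expect_true(all(fields$mmp2 >= 0))
  # the VEGF gradient points along +x toward the source face
  p2 <- sim_params(seed = 1)
  f2 <- make_fields(p2, c(6, 6, 6))
  g <- field_gradient(f2, "vegf", c(3, 3, 3))
  expect_gt(g$gradient[1], 0)
  expect_equal(g$gradient[2], 0)
})
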