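test_that("fiber cross-section and stretching modulus follow from diameter", {
  # 28 and 41 nm diameters at E_f = 1 MPa bracket the tabulated ranges
  m28 <- fiber_material(sim_params(seed = 1, network.fiber_diameter = 28))
  m41 <- fiber_material(sim_params(seed = 1, network.fiber_diameter = 41))
  expect_equal(m28$A_f, 6.16e-4, tolerance = 1e-3)     # um^2
  expect_equal(m41$A_f, 1.32e-3, tolerance = 1e-3)
  expect_equal(m28$kappa_s / 1000, 0.616, tolerance = 1e-3)  # nN
  expect_equal(m41$kappa_s / 1000, 1.32, tolerance = 1e-3)
  # internal consistency A_f = pi r^2, kappa_s = E_f A_f to 3 sig figs
  expect_equal(m41$kappa_s, m41$E_f * pi * m41$radius^2, tolerance = 1e-6)
  expect_equal(m41$kappa_b, m41$E_f * pi * m41$radius^4 / 4, tolerance = 1e-6)
  # the bending modulus can be overridden
  mo <- fiber_material(sim_params(seed = 1, fiber.kappa_b = 0.003))
  expect_equal(mo$kappa_b, 0.003)
})

test_that("elastic energy reproduces hand-evaluated cases", {
  p <- sim_params(seed = 1, network.fiber_diameter = 41)  # kappa_s = 1.32 nN
  net <- make_fixture("single-segment", p)
  m <- fiber_material(p)
  # rest state stores no energy
  expect_equal(elastic_energy(net, m), 0)
  # 20% strain on a 1 um segment: kappa_s/2 * (0.2)^2 / 1 = 26.4 pN um
  P <- net$nodes
  P[2, 1] <- 1.2
  expect_equal(elastic_energy(net, m, P), m$kappa_s / 2 * 0.04,
               tolerance = 1e-12)
  expect_equal(elastic_energy(net, m, P), 26.4, tolerance = 2e-3)
  expect_error({net2 <- net; net2$seg_L0[1] <- 0; elastic_energy(net2, m)},
               "rest length")
})

test_that("a stretched segment pulls its ends back with kappa_s * strain", {
  p <- sim_params(seed = 1, network.fiber_diameter = 41)
  net <- make_fixture("single-segment", p)
  m <- fiber_material(p)
  P <- net$nodes
  P[2, 1] <- 1.2
  F <- elastic_forces(net, m, P)
  expect_equal(F[2, 1], -m$kappa_s * 0.2, tolerance = 1e-12)   # ~ -264 pN
  expect_equal(F[1, 1], m$kappa_s * 0.2, tolerance = 1e-12)
  expect_equal(colSums(F), c(0, 0, 0))
  # collinear triple at its rest angle has zero bending force
  expect_equal(max(abs(elastic_forces(net, m))), 0)
})

test_that("analytic forces match the finite-difference energy gradient", {
  # the independent oracle: central differences of elastic_energy
  for (seed in 1:4) {
    net <- random_small_network(seed)
    m <- fiber_material(sim_params(seed = 1, network.fiber_diameter = 34))
    Fa <- elastic_forces(net, m)
    idx <- sample(nrow(net$nodes), 6)
    Ffd <- fd_elastic_forces(net, m, idx)
    scale <- max(abs(Ffd), 1)
    expect_lt(max(abs(Fa[idx, ] - Ffd)) / scale, 1e-6)
  }
})

test_that("energy is invariant to rigid translations and rotations", {
  net <- random_small_network(11)
  m <- fiber_material(sim_params(seed = 1))
  e0 <- elastic_energy(net, m)
  et <- elastic_energy(net, m, sweep(net$nodes, 2, c(1.3, -2.2, 0.7), "+"))
  expect_equal(et, e0, tolerance = 1e-12)
  th <- 0.73
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  er <- elastic_energy(net, m, net$nodes %*% R)
  expect_equal(er, e0, tolerance = 1e-9)
  # net internal force vanishes
  expect_lt(max(abs(colSums(elastic_forces(net, m)))), 1e-8)
})

test_that("bulk-modulus fitting recovers slopes in the 0.2-0.7 window", {
  # exactly linear stress-strain curve: slope recovered exactly
  df <- data.frame(strain = (0:15) / 20)
  df$stress <- 5000 * df$strain                    # 5 kPa modulus
  expect_equal(fit_bulk_modulus(df), 5000, tolerance = 1e-12)
  # samples outside the window do not affect the fit
  df2 <- df
  df2$stress[df2$strain < 0.2 | df2$strain > 0.7] <- 99e9
  expect_equal(fit_bulk_modulus(df2), 5000, tolerance = 1e-12)
  # noisy linear curve: slope within the least-squares confidence interval
  set.seed(42)
  df3 <- data.frame(strain = seq(0, 0.75, 0.025))
  df3$stress <- 2000 * df3$strain + rnorm(nrow(df3), sd = 20)
  sel <- df3$strain >= 0.2 & df3$strain <= 0.7
  ci <- confint(lm(stress ~ strain, df3[sel, ]))["strain", ]
  slope <- fit_bulk_modulus(df3)
  expect_gt(slope, ci[1]); expect_lt(slope, ci[2])
  expect_gt(slope, 1900); expect_lt(slope, 2100)
  # too few samples in the window is an error
  expect_error(fit_bulk_modulus(data.frame(strain = c(0, 0.3, 0.8),
                                           stress = c(0, 1, 2))),
               "fewer than 3")
})

test_that("a rigid translation of the whole network produces zero stress", {
  p <- sim_params(preset = "pore1.0", seed = 3, network.domain = c(4, 4, 4))
  net <- build_network(p)
  m <- fiber_material(p)
  net$nodes <- sweep(net$nodes, 2, c(0.5, 0, 0), "+")
  F <- elastic_forces(net, m)
  lo <- min(net$nodes[, 1]); hi <- max(net$nodes[, 1])
  left <- net$nodes[, 1] <= lo + 0.2
  right <- net$nodes[, 1] >= hi - 0.2
  expect_lt(abs(sum(F[left, 1])), 1e-8)
  expect_lt(abs(sum(F[right, 1])), 1e-8)
})

test_that("the stretch test produces an increasing stress-strain response", {
  p <- sim_params(preset = "pore1.5", seed = 6, network.domain = c(5, 5, 5))
  net <- build_network(p)
  m <- fiber_material(p)
  curve <- run_stretch_test(net, m, max_strain = 0.3, d_strain = 0.1)
  expect_equal(curve$curve$stress[1], 0, tolerance = 1e-6)
  expect_true(all(diff(curve$curve$stress) > 0))
  expect_true(all(curve$curve$converged))
})
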