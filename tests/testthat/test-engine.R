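# Engine: packed-kernel consistency with the module forces, contacts,
# determinism, convergence and global force balance.

test_that("the scene kernel reproduces the module-assembled forces", {
  # independent route: assemble every force term with the R module
  # functions and compare against the compiled whole-scene kernel
  p <- sim_params(seed = 21, preset = "pore1.0", network.domain = c(4, 4, 4),
                  cell.n_subdiv = 0, cell.radius = 1.2,
                  cell.nucleus_radius = 0.5, cell.F_L = 120)
  net <- build_network(p)
  cell <- make_cell(c(2, 2, 2), p)
  filo <- make_filopodium(c(3, 2, 2), c(1, 0, 0), p)
  st <- make_sim_state(p, net = net, cell = cell, filopodia = list(filo))
  st$cell$sf_t <- 3L; st$cell$sf_n <- 5L; st$cell$sf_L0 <- 0.4
  st$cell$fa_n_b[7] <- 25L; st$cell$fa_seg[7] <- 11L
  st$cell$fa_tpar[7] <- 0.3; st$cell$fa_node[7] <- st$net$seg_a[11]

  pk <- ecmigrate:::.pack_state(st)
  res <- ecmigrate:::.scene_eval(pk$Y, ecmigrate:::.scene_args(st, pk))
  n_net <- pk$n_net; n_c <- pk$n_c
  mat <- fiber_material(p)

  F_ref_net <- elastic_forces(st$net, mat)
  mf <- membrane_forces(st$cell, st$net, p)
  nf <- nucleus_sf_forces(st$cell, p)
  F_ref_net <- F_ref_net + mf$F_net
  am <- am_update_and_forces(st$filopodia[[1]], 0, p, dt = 0)
  ct <- resolve_contacts(st)
  F_ref_net <- F_ref_net + ct$net
  F_c_ref <- mf$F_c + ct$cell
  F_filo_ref <- am$forces + ct$filo[[1]]
  # protrusion (no fields: along the growth axis) + root reaction
  fp <- protrusion_force(st$filopodia[[1]], c(0, 0, 0), p)
  F_filo_ref[nrow(F_filo_ref), ] <- F_filo_ref[nrow(F_filo_ref), ] + fp
  F_filo_ref[1, ] <- F_filo_ref[1, ] - fp

  expect_equal(res$F[seq_len(n_net), ], F_ref_net, tolerance = 1e-10)
  expect_equal(res$F[n_net + seq_len(n_c), ], F_c_ref, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$F[n_net + n_c + seq_len(n_c), ], mf$F_t + nf$F_t,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$F[n_net + 2 * n_c + seq_len(n_c), ], nf$F_n,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$F[pk$filo_off[1] + seq_len(pk$filo_len[1]), ],
               F_filo_ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("all internal forces sum to zero over the closed system", {
  # lamellipodium force off: every remaining term is an internal pair
  p <- sim_params(seed = 22, preset = "pore1.0", network.domain = c(4, 4, 4),
                  cell.n_subdiv = 1, cell.radius = 1.5,
                  cell.nucleus_radius = 0.6, cell.F_L = 0)
  net <- build_network(p)
  cell <- make_cell(c(2, 2, 2), p)
  st <- make_sim_state(p, net = net, cell = cell,
                       filopodia = list(make_filopodium(c(2, 2, 2) +
                                          c(1.5, 0, 0) * 0,
                                        c(1, 0, 0), p)))
  st <- engine_step(st)   # let adhesions and contacts engage
  pk <- ecmigrate:::.pack_state(st)
  res <- ecmigrate:::.scene_eval(pk$Y, ecmigrate:::.scene_args(st, pk))
  expect_lt(max(abs(colSums(res$F))), 1e-6)
})

test_that("contact corrections vanish without penetration and relax it away", {
  p <- sim_params(seed = 23)
  net <- make_fixture("single-segment", p)
  filo <- make_filopodium(c(0.5, -2.2, 0), c(0, 1, 0), p)
  st <- make_sim_state(p, net = net, filopodia = list(filo))
  ct <- resolve_contacts(st)
  expect_equal(max(abs(ct$net)), 0)
  expect_equal(max(abs(ct$filo[[1]])), 0)

  # a filopodium lying parallel to the fiber at half fiber-radius depth:
  # repulsion acts along the outward surface normal with an equal and
  # opposite reaction, and relaxation reduces the penetration
  r_f <- fiber_material(p)$radius
  filo2 <- make_filopodium(c(-1.2, r_f / 2, 0), c(1, 0, 0), p,
                           state = FILO_STATES[["tugging"]])
  st2 <- make_sim_state(p, net = net, filopodia = list(filo2))
  ct2 <- resolve_contacts(st2)
  f_probe <- ct2$filo[[1]]
  probe_rows <- which(rowSums(abs(f_probe)) > 0)
  expect_gt(length(probe_rows), 0)
  expect_true(all(f_probe[probe_rows, 2] > 0))   # pushed away from the axis
  tot <- colSums(f_probe) + colSums(ct2$net)
  expect_equal(tot, c(0, 0, 0), tolerance = 1e-9)

  d0 <- st2$filopodia[[1]]$nodes[5, 2]
  st3 <- engine_step(st2)
  expect_gt(st3$filopodia[[1]]$nodes[5, 2], d0)
})

test_that("identical configuration and seed reproduce trajectories bitwise", {
  p <- sim_params(seed = 31)
  run <- function() {
    st <- single_filopodium_scene(p, anchor_stiffness = 5e3)
    simulate_scene(st, 5)$log
  }
  expect_identical(run(), run())
})

test_that("the integrator self-converges under tolerance refinement", {
  # deterministic relaxation of a perturbed network toward equilibrium
  p <- sim_params(seed = 24, preset = "pore1.0", network.domain = c(3, 3, 3))
  final_pos <- function(tol) {
    pp <- p
    pp$engine$ode_tol <- tol
    net <- build_network(pp)
    set.seed(99)
    net$nodes <- net$nodes + matrix(rnorm(length(net$nodes), sd = 0.01),
                                    ncol = 3)
    st <- make_sim_state(pp, net = net)
    t_end <- 0.35   # mid-transient of the relaxation
    while (st$time < t_end - 1e-9) {
      st$dt <- min(st$dt, t_end - st$time)
      st <- engine_step(st)
    }
    st$net$nodes
  }
  ref <- final_pos(1e-7)
  e_coarse <- max(abs(final_pos(4e-4) - ref))
  e_fine <- max(abs(final_pos(1e-4) - ref))
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 4e-4)
})

test_that("an empty simulation returns an empty trajectory without error", {
  p <- sim_params(seed = 25, preset = "pore1.5", network.domain = c(5, 5, 5),
                  cell.n_subdiv = 0, cell.radius = 1.5,
                  cell.nucleus_radius = 0.6,
                  engine.total_time = 0)
  run <- run_simulation(p, replicates = 1)
  expect_s3_class(run, "invasion_run")
  expect_equal(nrow(run$summary), 1)
})

test_that("sustained loading pulls the anchor fiber toward the filopodium", {
  # the traction-field signature: during tugging/contractile phases the
  # bound fiber is displaced toward the filopodium (here, toward the root
  # along -x as the motors pull the tip back)
  p <- sim_params(seed = 26)
  st <- single_filopodium_scene(p, anchor_stiffness = 1e4)
  x0 <- mean(st$net$nodes[, 1])
  res <- simulate_scene(st, 60)
  expect_true(any(res$log$state %in% c(FILO_STATES[["tugging"]],
                                       FILO_STATES[["contractile"]])))
  expect_lt(mean(res$state$net$nodes[, 1]), x0)
})
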