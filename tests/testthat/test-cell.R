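p0 <- sim_params(seed = 1, cell.n_subdiv = 1, cell.radius = 3,
                 cell.nucleus_radius = 1.2)

test_that("the triple membrane builds with equal node counts and rest state", {
  cell <- make_cell(c(0, 0, 0), p0)
  expect_equal(nrow(cell$x_c), nrow(cell$x_t))
  expect_equal(nrow(cell$x_c), nrow(cell$x_n))
  expect_equal(cell$n_nodes, 42)
  # built geometry is the rest state: only the lamellipodium force acts
  mf <- membrane_forces(cell, NULL, p0)
  lead <- which(mf$normals %*% cell$polarization >
                  cos(pi / 180 * p0$cell$leading_cone))
  expect_true(length(lead) > 0)
  interior <- setdiff(seq_len(cell$n_nodes), lead)
  expect_lt(max(abs(mf$F_c[interior, ])), 1e-8)
  expect_lt(max(abs(mf$F_t)), 1e-8)
})

test_that("leading-edge nodes receive exactly 300 pN of lamellipodium force", {
  cell <- make_cell(c(0, 0, 0), p0)
  mf <- membrane_forces(cell, NULL, p0)
  lead <- which(mf$normals %*% cell$polarization >
                  cos(pi / 180 * p0$cell$leading_cone))
  mags <- sqrt(rowSums(mf$F_c[lead, , drop = FALSE]^2))
  expect_equal(unname(mags), rep(300, length(lead)), tolerance = 1e-9)
})

test_that("focal-adhesion force pairs cancel exactly against the fibers", {
  net <- make_fixture("single-segment", p0)
  cell <- make_cell(c(0.5, 0.4, 0), p0)   # fiber passes near the membrane
  # plant an FA by hand on the nearest membrane node
  d <- sqrt(rowSums(sweep(cell$x_c, 2, c(0.5, 0, 0), "-")^2))
  i <- which.min(d)
  cell$fa_n_b[i] <- 40L
  cell$fa_seg[i] <- 1L
  cell$fa_tpar[i] <- 0.5
  cell$fa_node[i] <- 1L
  mf <- membrane_forces(cell, net, p0)
  cell0 <- cell; cell0$fa_n_b[i] <- 0L
  mf0 <- membrane_forces(cell0, net, p0)
  fa_on_cell <- mf$F_c[i, ] - mf0$F_c[i, ]
  expect_gt(vnorm_test(fa_on_cell), 0)
  expect_equal(fa_on_cell + colSums(mf$F_net), c(0, 0, 0), tolerance = 1e-9)
})

test_that("the membrane-cortex mobility coupling solves the 2x2 system", {
  # no cortex drag decouples the rates to F/C
  p <- sim_params(seed = 1, cell.C_cort = 0)
  F_c <- matrix(rnorm(30), 10, 3)
  F_t <- matrix(rnorm(30), 10, 3)
  r <- coupled_membrane_cortex_rates(F_c, F_t, p)
  expect_equal(r$v_c, F_c / p$cell$C_c, tolerance = 1e-12)
  expect_equal(r$v_t, F_t / p$cell$C_t, tolerance = 1e-12)
  # equal forces and equal drags move both layers identically
  r2 <- coupled_membrane_cortex_rates(F_c, F_c, p0)
  expect_equal(r2$v_c, r2$v_t, tolerance = 1e-12)
  # random forces: matches a direct solve of the coupled pair
  cp <- p0$cell
  A <- rbind(c(cp$C_c + cp$C_cort, -cp$C_cort),
             c(-cp$C_cort, cp$C_t + cp$C_cort))
  r3 <- coupled_membrane_cortex_rates(F_c, F_t, p0)
  for (i in 1:10) {
    for (d in 1:3) {
      v <- solve(A, c(F_c[i, d], F_t[i, d]))
      expect_equal(c(r3$v_c[i, d], r3$v_t[i, d]), v, tolerance = 1e-12)
    }
  }
})

test_that("stress-fiber pairs cancel and vanish at rest with stalled motors", {
  cell <- make_cell(c(0, 0, 0), p0)
  # no stress fibers: nucleus forces are membrane-elastic only (zero at rest)
  r0 <- nucleus_sf_forces(cell, p0)
  expect_lt(max(abs(r0$F_n)), 1e-8)
  expect_equal(max(abs(r0$F_t)), 0)
  # one stress fiber at its rest length with stalled motors: no force
  cell$sf_t <- 1L; cell$sf_n <- 1L
  cell$sf_L0 <- vnorm_test(cell$x_n[1, ] - cell$x_t[1, ])
  r1 <- nucleus_sf_forces(cell, p0)
  expect_lt(max(abs(r1$F_t)), 1e-9)
  # contracted rest length: transduce and nucleus loads cancel exactly
  cell$sf_L0 <- 0.5 * cell$sf_L0
  r2 <- nucleus_sf_forces(cell, p0)
  expect_gt(vnorm_test(r2$F_t[1, ]), 0)
  expect_equal(r2$F_t[1, ] + (r2$F_n[1, ] - r0$F_n[1, ]), c(0, 0, 0),
               tolerance = 1e-9)
  # contraction shortens the rest length at 2 v_m
  L_before <- cell$sf_L0
  r3 <- nucleus_sf_forces(cell, p0, dt = 1)
  ten <- p0$motor$E_AM * p0$motor$A_AM / max(L_before, 0.05) *
    (vnorm_test(cell$x_n[1, ] - cell$x_t[1, ]) - L_before)
  v <- myosin_velocity(max(ten, 0), p0)
  expect_equal(unname(r3$cell$sf_L0), unname(max(L_before - 2 * v, 0.05)),
               tolerance = 1e-12)
})

test_that("the nucleus volume penalty restores the rest volume", {
  cell <- make_cell(c(0, 0, 0), p0)
  V0 <- ecmigrate:::mesh_volume(cell$x_n, cell$faces)
  expect_equal(V0, cell$vol0_n)
  # inflate the nucleus: penalty pushes every node inward
  cell$x_n <- cell$x_n * 1.1
  r <- nucleus_sf_forces(cell, p0)
  inward <- rowSums(r$F_n * cell$x_n)
  expect_true(mean(inward < 0) > 0.9)
})
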