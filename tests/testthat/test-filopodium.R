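p0 <- sim_params(seed = 1)

test_that("the myosin force-velocity law matches its landmark points", {
  expect_equal(myosin_velocity(0, p0), 0.01)                 # 10 nm/s unloaded
  expect_equal(myosin_velocity(p0$motor$F_stall, p0), 0)     # stall
  expect_equal(myosin_velocity(1500, p0), 0)                 # clamped past stall
  expect_equal(myosin_velocity(500, p0) * 1000, 10 * 0.5 / 1.05,
               tolerance = 1e-12)                            # ~4.76 nm/s
  # strictly decreasing on [0, F_stall)
  F <- seq(0, 999, length.out = 50)
  expect_true(all(diff(myosin_velocity(F, p0)) < 0))
  expect_error(myosin_velocity(-1, p0), "non-negative")
})

test_that("protrusion force follows the VEGF gradient with a documented fallback", {
  filo <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p0)
  # linear VEGF ramp along +x: 2 nN along +x
  expect_equal(protrusion_force(filo, c(3e-9, 0, 0), p0), c(2000, 0, 0))
  # uniform VEGF: falls back to the growth axis, same magnitude
  expect_equal(protrusion_force(filo, c(0, 0, 0), p0), c(2000, 0, 0))
  # phase gating: no protrusion when not outgrowing
  filo$state <- FILO_STATES[["retractile"]]
  expect_equal(protrusion_force(filo, c(3e-9, 0, 0), p0), c(0, 0, 0))
})

test_that("anchor geometry: perpendicular gap, formation gate, tie-break", {
  net <- make_fixture("single-segment", p0)   # segment from (0,0,0) to (1,0,0)
  # tip 50 nm above the midpoint: L_b = 50 nm, x_L is the perpendicular foot
  fc <- candidate_anchor(c(0.5, 0.05, 0), net, p0)
  expect_equal(fc$L_b, 0.05, tolerance = 1e-12)
  expect_equal(fc$x_L, c(0.5, 0, 0), tolerance = 1e-12)
  expect_equal(fc$n_R, c(0, -1, 0), tolerance = 1e-12)
  expect_equal(unname(fc$n_b), 0L)
  # gap of 150 nm: no focal complex forms
  expect_null(candidate_anchor(c(0.5, 0.15, 0), net, p0))
  # two equidistant segments: deterministic lowest-id tie-break
  net2 <- net
  net2$nodes <- rbind(net$nodes, c(0, 0.1, 0), c(1, 0.1, 0))
  net2$seg_a <- c(net$seg_a, 3L); net2$seg_b <- c(net$seg_b, 4L)
  net2$seg_L0 <- c(net$seg_L0, 1); net2$seg_type <- c(1L, 1L)
  net2$seg_active <- c(TRUE, TRUE); net2$seg_fiber <- c(1L, 2L)
  net2$ligand_cap <- rep(300, 4); net2$ligand_bound <- numeric(4)
  fc2 <- candidate_anchor(c(0.5, 0.05, 0), net2, p0)
  expect_equal(fc2$seg, 1L)
})

test_that("binding sampling matches the analytic Monte-Carlo rate", {
  net <- make_fixture("single-segment", p0)
  fc <- candidate_anchor(c(0.5, 0.05, 0), net, p0)
  rng <- rng_stream(123, "binding")
  expect_error(sample_bond_formation(fc, net, p0, 0, rng), "positive")

  # saturated ligand pool: k_on = 0, nothing binds
  net_sat <- net
  net_sat$ligand_bound[fc$ligand_node] <- net_sat$ligand_cap[fc$ligand_node]
  r <- sample_bond_formation(fc, net_sat, p0, 1e-3, rng)
  expect_equal(r$added, 0L)

  # 300 free ligands, k_f = 1, dt = 1e-3: p_b = 1 - exp(-0.3) ~ 0.259;
  # a fresh single receptor binds with that probability (binomial oracle)
  p1 <- p0
  p1$binding$receptor_capacity <- 1
  n <- 4000
  hits <- 0
  for (i in seq_len(n)) {
    r <- sample_bond_formation(fc, net, p1, 1e-3, rng)
    hits <- hits + r$added
  }
  pb <- 1 - exp(-0.3)
  se <- sqrt(pb * (1 - pb) / n)
  expect_lt(abs(hits / n - pb), 3 * se)

  # bond-count conservation: bonds + free ligands = capacity
  r <- sample_bond_formation(fc, net, p0, 0.1, rng)
  expect_equal(r$fc$n_b + r$net$ligand_cap[fc$ligand_node] -
                 r$net$ligand_bound[fc$ligand_node],
               r$net$ligand_cap[fc$ligand_node])
  expect_lte(r$fc$n_b, p0$binding$receptor_capacity)
})

test_that("Bell rupture kinetics match the analytic off-rate", {
  kT <- thermal_energy_of(p0)
  # unstressed bonds dissociate at exactly 1/s; compression does not help
  expect_equal(bell_off_rate(p0$binding$lambda, p0), 1)
  expect_equal(bell_off_rate(0.01, p0), 1)
  # per-bond force k_b T / x_b makes the exponent exactly one
  Lb <- p0$binding$lambda + kT / p0$binding$x_b / p0$binding$kappa_LR
  expect_equal(bell_off_rate(Lb, p0), exp(1), tolerance = 1e-12)

  # ensemble mean lifetime at constant force matches 1/k_off within 3 sigma
  net <- make_fixture("single-segment", p0)
  fc <- candidate_anchor(c(0.5, 0.05, 0), net, p0)
  fc$n_b <- 10000L
  net$ligand_bound[fc$ligand_node] <- 0    # pool bookkeeping not under test
  k_off <- bell_off_rate(fc$L_b, p0)
  rng <- rng_stream(7, "rupture")
  dt <- 0.02
  t <- 0
  lifetimes <- numeric(0)
  n0 <- fc$n_b
  while (fc$n_b > 0 && t < 100) {
    r <- sample_bond_rupture(fc, net, p0, dt, rng)
    lifetimes <- c(lifetimes, rep(t + dt, fc$n_b - r$fc$n_b))
    fc <- r$fc
    t <- t + dt
  }
  # discrete sampling adds ~dt/2 bias; compare against the discretized mean
  disc_mean <- dt / (1 - exp(-k_off * dt))
  se <- (1 / k_off) / sqrt(n0)
  expect_lt(abs(mean(lifetimes) - disc_mean), 3 * se + dt)
})

test_that("focal-complex forces obey the bond law and action-reaction", {
  net <- make_fixture("single-segment", p0)
  fc <- candidate_anchor(c(0.5, 0.05, 0), net, p0)
  # zero bonds, zero force
  expect_equal(fc_force(fc, net, p0)$on_tip, c(0, 0, 0))
  # bonds at rest length: zero force
  fc$n_b <- 50L
  fc$L_b <- p0$binding$lambda
  expect_equal(fc_force(fc, net, p0)$on_tip, c(0, 0, 0))
  # 100 bonds stretched 10 nm at 1 pN/nm: 1 nN toward the fiber
  fc$n_b <- 100L
  fc$L_b <- p0$binding$lambda + 0.01
  ff <- fc_force(fc, net, p0)
  expect_equal(vnorm_test(ff$on_tip), 1000, tolerance = 1e-9)
  # reaction on the two fiber nodes balances the tip force exactly
  expect_equal(ff$on_tip + colSums(ff$on_fiber), c(0, 0, 0))
})

test_that("AM compartments contract at twice the sliding speed", {
  filo <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p0, length = 2.4)
  L0 <- filo$L_am
  # stalled motors leave rest lengths unchanged
  r <- am_update_and_forces(filo, 0, p0, dt = 1)
  expect_equal(r$filo$L_am, L0)
  # v_m = 10 nm/s for 1 s shortens each compartment by 20 nm
  r <- am_update_and_forces(filo, 0.01, p0, dt = 1)
  expect_equal(r$filo$L_am, L0 - 0.02)
  # unstressed compartments exert no force
  expect_equal(max(abs(am_update_and_forces(filo, 0, p0, dt = 0)$forces)), 0)
  # rest lengths floor instead of crossing zero
  r2 <- am_update_and_forces(filo, 10, p0, dt = 10)
  expect_true(all(r2$filo$L_am >= 0.05))
})

test_that("the phase machine follows the documented flow", {
  p <- p0
  # outgrowing reaching L_max without an FC leaves outgrowing
  f <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p, length = 4.5)
  f <- advance_state(f, p, 0.01)
  expect_equal(f$state, FILO_STATES[["retractile"]])
  # outgrowing with a formed FC switches to tugging
  f <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p)
  f$fc <- list(n_b = 10L)
  f <- advance_state(f, p, 0.01)
  expect_equal(f$state, FILO_STATES[["tugging"]])
  # tugging whose bonds all ruptured falls back to outgrowing
  f$fc$n_b <- 0L
  f <- advance_state(f, p, 0.01, had_bonds = TRUE)
  expect_equal(f$state, FILO_STATES[["outgrowing"]])
  expect_equal(f$n_cycles, 1L)
  # tugging above the tension gate matures into contractile
  f$state <- FILO_STATES[["tugging"]]; f$t_state <- 10; f$fc$n_b <- 50L
  f <- advance_state(f, p, 0.01, F_TR = 1200)
  expect_equal(f$state, FILO_STATES[["contractile"]])
  # retractile at L_min decays
  f <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p, length = 2,
                       state = FILO_STATES[["retractile"]])
  f <- advance_state(f, p, 0.01)
  expect_equal(f$state, FILO_STATES[["decay"]])
  expect_true(f$released)
  # outgrowing timeout retracts
  f <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p)
  f$t_state <- 61
  f <- advance_state(f, p, 0.01)
  expect_equal(f$state, FILO_STATES[["retractile"]])
  expect_error(advance_state(structure(list(state = 9L), class = "filopodium"),
                             p, 0.01), "state")
})

test_that("the time-averaged tip speed is the path length over elapsed time", {
  tr <- data.frame(time = c(0, 50, 100), x = c(0, 0, 0), y = 0, z = 0)
  expect_equal(mean_speed(tr), 0)
  tr$x <- c(0, 2.5, 5)
  expect_equal(mean_speed(tr), 0.05)          # 5 um over 100 s
  # constant-speed motion recovered at any sampling rate
  t <- seq(0, 80, by = 7)
  tr2 <- data.frame(time = t, x = 0.03 * t, y = 0, z = 0)
  expect_equal(mean_speed(tr2, 0, 80), 0.03 * 77 / 80, tolerance = 1e-12)
  expect_error(mean_speed(tr, 10, 10), "t0")
  expect_error(mean_speed(tr[1, ]))
})
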