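test_that("network generation is deterministic under a fixed seed", {
  p <- sim_params(preset = "pore1.0", seed = 5, network.domain = c(4, 4, 4))
  expect_identical(build_network(p), build_network(p))
  p2 <- sim_params(preset = "pore1.0", seed = 6, network.domain = c(4, 4, 4))
  expect_false(identical(build_network(p)$nodes, build_network(p2)$nodes))
})

test_that("a seed is required and undersized domains are refused", {
  p <- sim_params(preset = "pore1.0", seed = 1, network.domain = c(4, 4, 4))
  p$seed <- NULL
  expect_error(build_network(p), "seed")
  expect_error(
    build_network(sim_params(preset = "pore1.5", seed = 1,
                             network.domain = c(4, 4, 2))),
    "domain")
})

test_that("measured pore size tracks the target within 20% for all presets", {
  for (pr in c("pore0.5", "pore1.0", "pore1.5")) {
    p <- sim_params(preset = pr, seed = 3, network.domain = c(5, 5, 5))
    net <- build_network(p)
    expect_lt(abs(measure_pore_size(net) - p$network$pore_size),
              0.2 * p$network$pore_size)
  }
})

test_that("edges split into n_div fiber segments plus two 30 nm crosslink segments", {
  p <- sim_params(preset = "pore1.5", seed = 2, network.domain = c(5, 5, 5))
  net <- build_network(p)
  n_edges <- length(net$edge_a)
  expect_equal(sum(net$seg_type == 2L), 2L * n_edges)
  expect_equal(sum(net$seg_type == 1L), p$network$n_div * n_edges)
  expect_true(all(abs(net$seg_L0[net$seg_type == 2L] - 0.03) < 1e-12))
  # n_div + 1 fiber nodes per edge
  expect_equal(nrow(net$nodes) - net$n_crosslink,
               (p$network$n_div + 1L) * n_edges)
})

test_that("every fiber node carries the full ligand capacity and initial ECM", {
  p <- sim_params(preset = "pore0.5", seed = 2, network.domain = c(3, 3, 3))
  net <- build_network(p)
  fib <- net$node_type == 2L
  expect_true(all(net$ligand_cap[fib] == 300))
  expect_true(all(net$ligand_bound == 0))
  expect_true(all(net$C_ecm == p$rd$C_ecm0))
  expect_true(all(ecm_integrity(net) == 1))
})

test_that("crosslinking rate matches p_f and joins respect the 60-degree rule", {
  p <- sim_params(preset = "pore1.0", seed = 9, network.domain = c(5, 5, 5))
  net <- build_network(p)
  expect_equal(net$cross_n_0f,
               floor(0.7 * net$cross_n_fs + 0.5))
  # interior crosslink nodes of a chain bend by less than 60 degrees
  on_chain <- net$bend_b[net$node_type[net$bend_b] == 1L]
  expect_true(length(on_chain) > 0)
  ang <- net$bend_theta0[net$node_type[net$bend_b] == 1L]
  expect_true(all(ang < pi / 3 + 1e-9))
})

test_that("degradation detaches round((1-I) N0f) ends, monotonically", {
  p <- sim_params(preset = "pore1.0", seed = 4, network.domain = c(4, 4, 4))
  net <- build_network(p)
  rng <- rng_stream(1, "degradation")

  # undamaged: nothing changes
  net1 <- apply_crosslink_degradation(net, rng)
  expect_identical(net1$cross_n_uf, integer(length(net$cross_n_uf)))

  # half-integrity at one node with N0f = 4 detaches exactly 2
  k <- which(net$cross_n_0f == 4)[1]
  expect_false(is.na(k))
  net2 <- net
  net2$C_ecm[k] <- 0.5 * net2$C_ecm0
  net2 <- apply_crosslink_degradation(net2, rng)
  expect_equal(net2$cross_n_uf[k], 2)

  # full damage detaches all initially crosslinked ends everywhere
  net3 <- net
  net3$C_ecm[seq_len(net3$n_crosslink)] <- 0
  net3 <- apply_crosslink_degradation(net3, rng)
  expect_equal(net3$cross_n_uf, net3$cross_n_0f)

  # monotone: recovering integrity never re-forms crosslinks
  net4 <- net2
  net4$C_ecm[k] <- net4$C_ecm0
  net4 <- apply_crosslink_degradation(net4, rng)
  expect_equal(net4$cross_n_uf[k], 2)

  # conservation: node count and chain membership untouched
  expect_identical(net3$nodes, net$nodes)
  expect_identical(net3$chains, net$chains)
  expect_identical(net3$seg_a, net$seg_a)

  # out-of-range integrity is an invariant violation
  net5 <- net
  net5$C_ecm[1] <- 2 * net5$C_ecm0
  expect_error(apply_crosslink_degradation(net5, rng), "integrity")
})

test_that("detached count is non-decreasing along an integrity trajectory", {
  p <- sim_params(preset = "pore1.0", seed = 8, network.domain = c(4, 4, 4))
  net <- build_network(p)
  rng <- rng_stream(2, "degradation")
  prev <- 0L
  for (I in c(0.9, 0.75, 0.6, 0.42, 0.2, 0.05)) {
    net$C_ecm[seq_len(net$n_crosslink)] <- I * net$C_ecm0
    net <- apply_crosslink_degradation(net, rng)
    tot <- sum(net$cross_n_uf)
    expect_gte(tot, prev)
    expect_equal(tot, sum(floor((1 - I) * net$cross_n_0f + 0.5)))
    prev <- tot
  }
})
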