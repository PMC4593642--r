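# Shared scene builders for the test suite.  Everything is generated in
# code; sizes are kept small so the default run stays fast.

# parameters for a small, fully-featured invasion scene
small_invasion_params <- function(preset, seed, total_time = 60,
                                  domain = c(4.5, 4.5, 4.5)) {
  sim_params(preset = preset, seed = seed,
             network.domain = domain,
             cell.n_subdiv = 1,            # 42-node membranes
             cell.radius = 2, cell.nucleus_radius = 0.8,
             filopodium.max_filopodia = 3,
             engine.total_time = total_time)
}

# random perturbed subnetwork with <= max_nodes nodes, for gradient oracles
random_small_network <- function(seed, max_nodes = 50, sd = 0.03) {
  p <- sim_params(preset = "pore1.0", seed = seed,
                  network.domain = c(3, 3, 3))
  net <- build_network(p)
  set.seed(seed + 1000)
  net$nodes <- net$nodes + matrix(rnorm(length(net$nodes), sd = sd), ncol = 3)
  net
}

# central-difference gradient of the elastic energy (independent oracle)
fd_elastic_forces <- function(net, material, idx, h = 1e-6) {
  F <- matrix(0, length(idx), 3)
  for (r in seq_along(idx)) {
    i <- idx[r]
    for (d in 1:3) {
      Pp <- net$nodes; Pp[i, d] <- Pp[i, d] + h
      Pm <- net$nodes; Pm[i, d] <- Pm[i, d] - h
      F[r, d] <- -(elastic_energy(net, material, Pp) -
                     elastic_energy(net, material, Pm)) / (2 * h)
    }
  }
  F
}

thermal_energy_of <- function(p) 1.380649e-5 * p$binding$temperature

vnorm_test <- function(v) sqrt(sum(v * v))
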