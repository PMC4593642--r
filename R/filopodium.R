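# Single-filopodium penetration dynamics: protrusive outgrowth, stochastic
# focal-complex (FC) formation/rupture at the tip, acto-myosin contraction,
# and the seven-state phase machine.
#
# Phase codes: 0 inactive, 1 active, 2 outgrowing, 3 tugging, 4 contractile,
# 5 retractile, 6 decay.

#' Filopodium phase labels
#' @export
FILO_STATES <- c("inactive" = 0L, "active" = 1L, "outgrowing" = 2L,
                 "tugging" = 3L, "contractile" = 4L, "retractile" = 5L,
                 "decay" = 6L)

#' Create a filopodium
#'
#' A filopodium is a chain of `n_am + 1` nodes (root first, tip last)
#' subdivided into `n_am` contractile acto-myosin (AM) compartments whose
#' rest lengths shorten at twice the myosin sliding speed.  The compartment
#' stiffness is `kappa_AM = E_AM A_AM / L_AM` and is recomputed whenever the
#' rest length changes.
#'
#' @param root 3-vector root position (um) on the cell membrane.
#' @param axis unit 3-vector growth direction.
#' @param params a `sim_params` object.
#' @param length initial length (um, default `filopodium$L_init`).
#' @param state initial phase (default outgrowing).
#' @param root_node optional cell-membrane node id the root is attached to.
#' @return an object of class `filopodium`.
#' @export
make_filopodium <- function(root, axis, params, length = NULL,
                            state = FILO_STATES[["outgrowing"]],
                            root_node = NA_integer_) {
  fp <- params$filopodium
  L <- if (is.null(length)) fp$L_init else length
  axis <- unitize(axis)
  n <- fp$n_am + 1L
  s <- seq(0, L, length.out = n)
  nodes <- matrix(rep(root, each = n), n, 3) + outer(s, axis)
  structure(list(
    nodes = nodes, L_am = rep(L / fp$n_am, fp$n_am),
    state = as.integer(state), t_state = 0,
    axis = axis, root_node = root_node, fc = NULL,
    n_cycles = 0L, id = NA_integer_
  ), class = "filopodium")
}

#' Filopodium length
#' @param filo a `filopodium`.
#' @return summed node spacing (um).
#' @export
filopodium_length <- function(filo) {
  X <- filo$nodes
  n <- nrow(X)
  dx <- X[-1, 1] - X[-n, 1]; dy <- X[-1, 2] - X[-n, 2]; dz <- X[-1, 3] - X[-n, 3]
  sum(sqrt(dx * dx + dy * dy + dz * dz))
}

#' Myosin force-velocity relation
#'
#' The muscle-type force-velocity law for non-muscle myosin II sliding on
#' actin: `v_m = v_m0 (F_stall - F) / (F_stall + c_m F)`, clamped at zero
#' for loads at or beyond stall.  Unloaded speed 10 nm/s, stall force 1 nN,
#' shape factor `c_m` = 0.1 by default.
#'
#' @param F_TR sensed elastic load at the tip (pN, non-negative; vectorized).
#' @param params a `sim_params` object.
#' @return sliding speed in um/s.
#' @examples
#' p <- sim_params(seed = 1)
#' myosin_velocity(0, p) * 1000     # 10 nm/s unloaded
#' myosin_velocity(1000, p)         # 0 at stall
#' @export
myosin_velocity <- function(F_TR, params) {
  if (any(F_TR < 0)) stop("load must be non-negative")
  m <- params$motor
  v <- m$v_m0 * (m$F_stall - F_TR) / (m$F_stall + m$c_m * F_TR)
  pmax(v, 0)
}

#' Protrusion force at the filopodial tip
#'
#' Actin polymerization exerts `F_P,max` on the tip node, oriented along
#' the unit VEGF gradient (chemotactic steering).  Applied only in the
#' outgrowing phase; when the local gradient vanishes the current growth
#' axis is used as a documented fallback.
#'
#' @param filo a `filopodium`.
#' @param grad_vegf 3-vector VEGF concentration gradient at the tip
#'   (arbitrary scale; only its direction is used).
#' @param params a `sim_params` object.
#' @return 3-vector force (pN).
#' @export
protrusion_force <- function(filo, grad_vegf, params) {
  if (filo$state != FILO_STATES[["outgrowing"]]) return(c(0, 0, 0))
  g <- vnorm(grad_vegf)
  dir <- if (g < 1e-30) filo$axis else grad_vegf / g
  params$filopodium$F_P_max * dir
}

## ---- focal-complex geometry and kinetics ----------------------------------

#' Candidate focal-complex anchor near a tip
#'
#' Finds the nearest active fiber segment to the tip and computes the FC
#' geometry: bond root `x_L` (closest point on the segment), bond direction
#' `n_R` (tip towards `x_L`), gap `h_p` and stretched bond length `L_b`.
#' No anchor is returned when the gap is 100 nm or more (the FC formation
#' gate).  Ties between equidistant segments break deterministically on the
#' lowest segment id.
#'
#' @param tip 3-vector tip position.
#' @param net a `fiber_network`.
#' @param params a `sim_params` object.
#' @param index optional [segment_index()] over the network's fiber
#'   segments; brute force otherwise.
#' @return a list of class `focal_complex` with `n_b = 0`, or `NULL`.
#' @export
candidate_anchor <- function(tip, net, params, index = NULL) {
  range <- params$binding$contact_range
  cand <- if (!is.null(index)) {
    q <- query_segments(index, tip, range)
    q[net$seg_type[q] == 1L & net$seg_active[q]]
  } else {
    which(net$seg_type == 1L & net$seg_active)
  }
  if (!length(cand)) return(NULL)
  cand <- sort(cand)
  A <- net$nodes[net$seg_a[cand], , drop = FALSE]
  B <- net$nodes[net$seg_b[cand], , drop = FALSE]
  cl <- point_segment_closest(tip, A, B)
  i <- which.min(cl$dist)               # first minimum = lowest segment id
  if (cl$dist[i] >= range) return(NULL)
  seg <- cand[i]
  .fc_geometry(tip, net, seg, cl$t[i])
}

# FC geometry for tip against segment `seg` at parametric position t
.fc_geometry <- function(tip, net, seg, tpar, n_b = 0L) {
  a <- net$seg_a[seg]; b <- net$seg_b[seg]
  xa <- net$nodes[a, ]; xb <- net$nodes[b, ]
  x_L <- xa + tpar * (xb - xa)
  d <- x_L - tip
  h <- vnorm(d)
  if (h < 1e-9) {                       # tip on the fiber axis: perturb
    tip <- tip + c(1e-6, 0, 0)
    d <- x_L - tip
    h <- vnorm(d)
  }
  n_R <- d / h
  # outward fiber-surface normal via (B-A) x ((tip-A) x (B-A))
  ax <- xb - xa
  w <- .cross3(ax, .cross3(tip - xa, ax))
  nw <- vnorm(w)
  n_w <- if (nw < 1e-12) -n_R else w / nw
  ligand_node <- if (tpar < 0.5) a else b
  structure(list(
    seg = seg, tpar = tpar, x_L = x_L, n_R = n_R, n_w = n_w,
    h_p = h, L_b = h, n_b = as.integer(n_b), ligand_node = ligand_node
  ), class = "focal_complex")
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Re-project an existing FC to the current tip/fiber geometry: the anchor's
# parametric position slides to the nearest point each step, so the binding
# site migrates along the fiber as forces evolve (emergent tip crawling).
fc_update_geometry <- function(fc, tip, net) {
  a <- net$seg_a[fc$seg]; b <- net$seg_b[fc$seg]
  xa <- net$nodes[a, ]
  d <- net$nodes[b, ] - xa
  len2 <- max(sum(d * d), 1e-300)
  t <- min(1, max(0, sum((tip - xa) * d) / len2))
  g <- .fc_geometry(tip, net, fc$seg, t, n_b = fc$n_b)
  g$ligand_node <- fc$ligand_node       # pool follows the original node
  g
}

#' Monte-Carlo receptor-ligand bond formation
#'
#' Each free receptor at the FC site binds within `dt` with probability
#' `p_b = 1 - exp(-k_on dt)`, `k_on = k_f (C_L - C_b) A_L` where
#' `(C_L - C_b) A_L` is the number of unbound ligands in the node's pool.
#' Newly bound ligands are marked in the pool; the draw never exceeds the
#' free-ligand count.
#'
#' @param fc a `focal_complex`.
#' @param net the `fiber_network` owning the ligand pool.
#' @param params a `sim_params` object.
#' @param dt time interval (s, positive).
#' @param rng an [rng_stream()].
#' @return list(fc, net, added).
#' @export
sample_bond_formation <- function(fc, net, params, dt, rng) {
  if (dt <= 0) stop("dt must be positive")
  node <- fc$ligand_node
  free <- net$ligand_cap[node] - net$ligand_bound[node]
  avail <- params$binding$receptor_capacity - fc$n_b
  if (free <= 0 || avail <= 0) return(list(fc = fc, net = net, added = 0L))
  k_on <- params$binding$k_f * free
  p_b <- 1 - exp(-k_on * dt)
  added <- with_rng(rng, stats::rbinom(1L, as.integer(avail), p_b))
  added <- min(added, as.integer(free))
  fc$n_b <- fc$n_b + added
  net$ligand_bound[node] <- net$ligand_bound[node] + added
  list(fc = fc, net = net, added = added)
}

#' Bell slip-bond rupture sampling
#'
#' Each bond ruptures within `dt` with probability `1 - exp(-k_off dt)`
#' where `k_off = k_off0 exp[kappa_LR (L_b - lambda) x_b / (k_b T)]`
#' (Bell's equation; unstressed rate 1/s, maximum rupture force
#' `k_b T / x_b` of about 200 pN per bond).  Compressed bonds
#' (`L_b < lambda`) rupture at the unstressed rate.  Ruptured ligands are
#' returned to the pool.
#'
#' @inheritParams sample_bond_formation
#' @param k_off_scale multiplier on the unstressed off-rate (used for the
#'   slower-turnover focal adhesions of the cell body).
#' @return list(fc, net, lost).
#' @export
sample_bond_rupture <- function(fc, net, params, dt, rng, k_off_scale = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (fc$n_b <= 0) return(list(fc = fc, net = net, lost = 0L))
  k_off <- bell_off_rate(fc$L_b, params) * k_off_scale
  p <- 1 - exp(-k_off * dt)
  lost <- with_rng(rng, stats::rbinom(1L, fc$n_b, p))
  fc$n_b <- fc$n_b - lost
  net$ligand_bound[fc$ligand_node] <- net$ligand_bound[fc$ligand_node] - lost
  list(fc = fc, net = net, lost = lost)
}

#' Bell dissociation rate for a stretched bond
#'
#' @param L_b stretched bond length (um; vectorized).
#' @param params a `sim_params` object.
#' @return off-rate in 1/s.
#' @export
bell_off_rate <- function(L_b, params) {
  bd <- params$binding
  ext <- pmax(L_b - bd$lambda, 0)      # compression does not accelerate rupture
  bd$k_off0 * exp(bd$kappa_LR * ext * bd$x_b / thermal_energy(params))
}

#' Focal-complex force pair
#'
#' The FC force on the filopodial tip is
#' `n_b kappa_LR (L_b - lambda) n_R`; the equal-and-opposite reaction is
#' distributed to the anchor segment's two end nodes by linear interpolation
#' at the parametric position, so the pair sums to zero exactly.
#'
#' @param fc a `focal_complex`.
#' @param net a `fiber_network`.
#' @param params a `sim_params` object.
#' @return list: `on_tip` 3-vector (pN), `fiber_nodes` the two end-node
#'   ids, `on_fiber` a 2x3 matrix of reaction forces.
#' @export
fc_force <- function(fc, net, params) {
  if (is.null(fc) || fc$n_b == 0) {
    return(list(on_tip = c(0, 0, 0), fiber_nodes = integer(0),
                on_fiber = matrix(0, 0, 3)))
  }
  f <- fc$n_b * params$binding$kappa_LR * (fc$L_b - params$binding$lambda) *
    fc$n_R
  wts <- c(1 - fc$tpar, fc$tpar)
  list(on_tip = f,
       fiber_nodes = c(net$seg_a[fc$seg], net$seg_b[fc$seg]),
       on_fiber = -outer(wts, f))
}

## ---- acto-myosin compartments ---------------------------------------------

#' Acto-myosin compartment update and forces
#'
#' Updates each compartment's rest length by `dL/dt = -2 v_m` (sliding at
#' both ends), floors the rest length at a minimum node spacing, recomputes
#' the stiffness `kappa_AM = E_AM A_AM / L_AM`, and returns the elastic
#' forces at the compartment boundary nodes from the stored AM energy
#' `H = sum kappa_j/2 (d_j - L_j)^2`.
#'
#' @param filo a `filopodium`.
#' @param v_m myosin sliding speed (um/s; scalar or per compartment).
#' @param params a `sim_params` object.
#' @param dt time step (s).
#' @param grow rest-length growth rate (um/s, total over the chain) applied
#'   during protrusive outgrowth; 0 otherwise.
#' @return list: `filo` with updated rest lengths, `forces`
#'   (`n_am + 1` x 3, pN).
#' @export
am_update_and_forces <- function(filo, v_m, params, dt, grow = 0) {
  n_am <- length(filo$L_am)
  floor_L <- 0.05
  L <- filo$L_am - 2 * v_m * dt + grow * dt / n_am
  filo$L_am <- pmax(L, floor_L)
  kappa <- params$motor$E_AM * params$motor$A_AM / filo$L_am
  F <- .cpp_chain_springs(filo$nodes, filo$L_am, kappa)
  list(filo = filo, forces = F)
}

## ---- phase machine ----------------------------------------------------------

#' Advance the filopodium phase machine
#'
#' Implements the phase flow: active starts outgrowing; outgrowing switches
#' to tugging when an FC forms within the phase's time budget and to
#' retractile on timeout or at the length cap `L_max` = 4.5 um; tugging
#' switches to contractile when the tip tension exceeds the contractile
#' threshold while the rupture test passes, back to outgrowing when the
#' rupture test fails (all bonds lost), and to retractile when the dwell
#' budget expires; contractile falls to retractile on complete bond loss;
#' retractile ends in decay at `L_min` = 2 um.  Timers reset on every
#' transition.
#'
#' @param filo a `filopodium` whose FC/bond state is current for this step.
#' @param params a `sim_params` object.
#' @param dt elapsed time this step (s).
#' @param F_TR current tip tension magnitude (pN).
#' @param had_bonds whether the FC held bonds before this step's rupture
#'   draw (the rupture test examines bond survival).
#' @return the filopodium with updated state/timer; `$released` is TRUE
#'   when the caller must return remaining bonds to the ligand pool.
#' @export
advance_state <- function(filo, params, dt, F_TR = 0, had_bonds = FALSE) {
  fp <- params$filopodium
  s <- filo$state
  S <- FILO_STATES
  if (!s %in% S) stop("unknown filopodium state: ", s)
  L <- filopodium_length(filo)
  n_b <- if (is.null(filo$fc)) 0L else filo$fc$n_b
  gate <- fp$contractile_threshold_per_um * fp$diameter
  new <- s
  filo$released <- FALSE
  if (s == S[["active"]]) {
    new <- S[["outgrowing"]]
  } else if (s == S[["outgrowing"]]) {
    if (n_b > 0) {
      new <- S[["tugging"]]
    } else if (L >= fp$L_max || filo$t_state >= fp$outgrow_timeout) {
      new <- S[["retractile"]]
    }
  } else if (s == S[["tugging"]]) {
    if (had_bonds && n_b == 0) {                 # rupture test failed
      new <- S[["outgrowing"]]
      filo$n_cycles <- filo$n_cycles + 1L
    } else if (n_b > 0 && F_TR >= gate && filo$t_state >= fp$tugging_min) {
      # the maturation dwell lets the mechanical transient of the initial
      # grab relax, so the gate senses motor-built tension
      new <- S[["contractile"]]
    } else if (L <= fp$L_min) {
      # the tip has dragged its compliant anchor all the way back
      new <- S[["decay"]]
      filo$n_cycles <- filo$n_cycles + 1L
      filo$released <- TRUE
    } else if (filo$t_state >= fp$tugging_dwell) {
      new <- S[["retractile"]]
      filo$n_cycles <- filo$n_cycles + 1L
      filo$released <- TRUE
    }
  } else if (s == S[["contractile"]]) {
    if (n_b == 0) {
      new <- S[["retractile"]]
    } else if (L <= fp$L_min) {
      new <- S[["decay"]]
      filo$released <- TRUE
    }
  } else if (s == S[["retractile"]]) {
    if (L <= fp$L_min) {
      new <- S[["decay"]]
      filo$released <- TRUE
    }
  } else if (s == S[["decay"]] || s == S[["inactive"]]) {
    # terminal for the phase machine; the engine recycles decayed filopodia
  } else {
    stop("unknown filopodium state: ", s)
  }
  if (new != s) {
    filo$state <- as.integer(new)
    filo$t_state <- 0
  } else {
    filo$t_state <- filo$t_state + dt
  }
  filo
}

#' Time-averaged speed of a trajectory
#'
#' Path length of successive displacements divided by the elapsed time,
#' over samples within `[t0, tf]`.
#'
#' @param trajectory a data frame or matrix with columns `time, x, y, z`.
#' @param t0,tf averaging window (defaults to the full record).
#' @return speed (um/s).
#' @export
mean_speed <- function(trajectory, t0 = NULL, tf = NULL) {
  tr <- as.data.frame(trajectory)
  names(tr)[1:4] <- c("time", "x", "y", "z")
  if (is.null(t0)) t0 <- min(tr$time)
  if (is.null(tf)) tf <- max(tr$time)
  if (tf <= t0) stop("tf must exceed t0")
  tr <- tr[tr$time >= t0 & tr$time <= tf, , drop = FALSE]
  if (nrow(tr) < 2) stop("need at least 2 samples in [t0, tf]")
  tr <- tr[order(tr$time), ]
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
  sum(steps) / (tf - t0)
}

#' @export
print.filopodium <- function(x, ...) {
  st <- names(FILO_STATES)[match(x$state, FILO_STATES)]
  cat(sprintf("<filopodium> state %s, length %.2f um, %d AM compartments, %s bonds\n",
              st, filopodium_length(x), length(x$L_am),
              if (is.null(x$fc)) "no FC" else paste0("FC with ", x$fc$n_b)))
  invisible(x)
}
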