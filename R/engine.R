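# Orchestration of the coupled system: fiber network, cell body, filopodia
# and reaction-diffusion fields advance together under overdamped dynamics
# dx/dt = F/C with an embedded adaptive explicit pair (Heun/Euler) honoring
# the engine tolerance and step clamp; stochastic bond events are applied
# once per accepted macro-step with the accepted dt (jump-adapted
# splitting); reaction-diffusion and degradation advance on a slower
# operator-split cadence; fiber nodes beyond the active-domain radius are
# frozen boundaries.

#' Create a simulation state
#'
#' @param params a `sim_params` object (must carry a seed).
#' @param net a `fiber_network` (or `NULL` for a network-free scene).
#' @param cell a `cell_body` or `NULL`.
#' @param filopodia list of `filopodium` objects.
#' @param fields a `concentration_fields` or `NULL` (no chemistry).
#' @param tether optional list(idx, anchor, k): network nodes tied to fixed
#'   anchor points by springs of stiffness `k` (pN/um); used by
#'   single-filopodium scenes to emulate soft/stiff surroundings.
#' @param fixed_net integer ids of network nodes held fixed.
#' @param root_fixed hold filopodium roots fixed (scenes without a cell).
#' @return an object of class `sim_state`.
#' @export
make_sim_state <- function(params, net = NULL, cell = NULL,
                           filopodia = list(), fields = NULL,
                           tether = NULL, fixed_net = integer(0),
                           root_fixed = is.null(cell)) {
  if (is.null(params$seed)) stop("a seed is required")
  for (i in seq_along(filopodia)) filopodia[[i]]$id <- i
  st <- structure(list(
    params = params, net = net, cell = cell, filopodia = filopodia,
    fields = fields, tether = tether, fixed_net = fixed_net,
    root_fixed = root_fixed,
    time = 0, dt = params$engine$dt_max,
    material = if (!is.null(net)) fiber_material(params) else NULL,
    rng_bind = rng_stream(params$seed, "binding"),
    rng_rupt = rng_stream(params$seed, "rupture"),
    rng_nucl = rng_stream(params$seed, "nucleation"),
    rng_degr = rng_stream(params$seed, "degradation"),
    net_free = NULL, seg_idx = NULL,
    last_rd = 0, last_refresh = -Inf, last_fa = 0, last_index = -Inf,
    next_filo_id = length(filopodia) + 1L,
    n_steps = 0L, events = list()
  ), class = "sim_state")
  refresh_active_domain(st)
}

# recompute the active domain (free network nodes) and the spatial index
refresh_active_domain <- function(st) {
  if (is.null(st$net)) {
    st$last_refresh <- st$time
    return(st)
  }
  en <- st$params$engine
  P <- st$net$nodes
  free <- rep(FALSE, nrow(P))
  centers <- list()
  if (!is.null(st$cell)) centers <- c(centers, list(colMeans(st$cell$x_c)))
  for (f in st$filopodia) {
    if (f$state %in% 2:5) centers <- c(centers, list(f$nodes[nrow(f$nodes), ]))
  }
  if (!length(centers)) centers <- list(colMeans(P))
  for (ctr in centers) {
    free <- free | (row_norms(sweep(P, 2, ctr)) < en$active_radius)
  }
  free[st$fixed_net] <- FALSE
  st$net_free <- which(free)
  st$seg_idx <- segment_index(P, st$net$seg_a, st$net$seg_b,
                              active = which(st$net$seg_active),
                              cell = max(0.5, st$net$pore_size))
  st$last_refresh <- st$time
  st$last_index <- st$time
  st$args_head <- NULL
  st
}

## ---- force assembly --------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# combined contact evaluation: all probe nodes (membrane + live filopodia)
# against active fiber segments in one compiled pass
.all_contacts <- function(st) {
  r_f <- st$material$radius
  pad <- st$params$engine$contact_pad %||% 0.15
  pad_cell <- st$params$engine$contact_pad_cell %||% 0.05
  nprobe_cell <- if (!is.null(st$cell)) st$cell$n_nodes else 0L
  probes <- if (nprobe_cell) st$cell$x_c else matrix(0, 0, 3)
  ranges <- rep(r_f + pad_cell, nprobe_cell)
  spans <- vector("list", length(st$filopodia))
  off <- nprobe_cell
  for (k in seq_along(st$filopodia)) {
    f <- st$filopodia[[k]]
    if (!(f$state %in% 2:5)) next
    nn <- nrow(f$nodes)
    probes <- rbind(probes, f$nodes)
    ranges <- c(ranges, rep(r_f + pad, nn - 1L), r_f)  # bare radius at the tip
    spans[[k]] <- off + seq_len(nn)
    off <- off + nn
  }
  res <- .cpp_contact_forces(st$net$nodes, st$net$seg_a, st$net$seg_b,
                             st$net$seg_active, probes, ranges,
                             st$params$engine$contact_stiffness)
  list(cell = if (nprobe_cell) res$probes[seq_len(nprobe_cell), , drop = FALSE],
       filo = lapply(spans, function(sp) {
         if (is.null(sp)) NULL else res$probes[sp, , drop = FALSE]
       }),
       net = res$net)
}

#' Contact repulsion corrections
#'
#' Detects cell-membrane and filopodial nodes penetrating fiber cylinders
#' (distance below the fiber radius plus a surface-thickness pad) and adds
#' a linear elastic repulsion along the outward fiber-surface normal, with
#' the symmetric reaction on the fiber's segment end nodes.
#'
#' @param st a `sim_state`.
#' @return list of correction-force matrices (`net`, `cell`, per-filopodium
#'   list `filo`), zero everywhere when nothing penetrates.
#' @export
resolve_contacts <- function(st) {
  if (is.null(st$net)) {
    return(list(net = matrix(0, 0, 3), cell = NULL,
                filo = vector("list", length(st$filopodia))))
  }
  .all_contacts(st)
}

## ---- packed scene representation -------------------------------------------

# Pack every position into one matrix (network, x_c, x_t, x_n, filopodia)
# and precompute the per-step quantities the compiled kernel needs.
.pack_state <- function(st) {
  p <- st$params
  n_net <- if (!is.null(st$net)) nrow(st$net$nodes) else 0L
  n_c <- if (!is.null(st$cell)) st$cell$n_nodes else 0L
  nf <- length(st$filopodia)
  filo_len <- vapply(st$filopodia, function(f) nrow(f$nodes), integer(1))
  filo_off <- n_net + 3L * n_c +
    c(0L, cumsum(filo_len))[seq_len(max(nf, 1))]
  if (!nf) filo_off <- integer(0)
  parts <- vector("list", 4 + nf)
  if (n_net) parts[[1]] <- st$net$nodes
  if (n_c) {
    parts[[2]] <- st$cell$x_c; parts[[3]] <- st$cell$x_t
    parts[[4]] <- st$cell$x_n
  }
  for (k in seq_len(nf)) parts[[4 + k]] <- st$filopodia[[k]]$nodes
  Y <- do.call(rbind, Filter(Negate(is.null), parts))
  free_mask <- rep(FALSE, n_net)
  free_mask[st$net_free] <- TRUE
  L_am <- unlist(lapply(st$filopodia, function(f) f$L_am))
  L_am_off <- c(0L, cumsum(filo_len - 1L))[seq_len(max(nf, 1))]
  if (!nf) {
    L_am <- numeric(0); L_am_off <- integer(0)
  }
  states <- vapply(st$filopodia, function(f) f$state, integer(1))
  fc_seg <- vapply(st$filopodia, function(f) {
    if (is.null(f$fc)) 0L else f$fc$seg
  }, integer(1))
  fc_nb <- vapply(st$filopodia, function(f) {
    if (is.null(f$fc)) 0 else as.numeric(f$fc$n_b)
  }, numeric(1))
  F_P <- matrix(0, max(nf, 0), 3)
  for (k in seq_len(nf)) {
    f <- st$filopodia[[k]]
    if (f$state == FILO_STATES[["outgrowing"]]) {
      grad <- if (!is.null(st$fields)) {
        field_gradient(st$fields, "vegf", f$nodes[nrow(f$nodes), ])$gradient
      } else c(0, 0, 0)
      F_P[k, ] <- protrusion_force(f, grad, p)
    }
  }
  roots <- vapply(st$filopodia, function(f) {
    if (is.na(f$root_node)) 0L else f$root_node
  }, integer(1))
  fa_i <- if (n_c) which(st$cell$fa_n_b > 0) else integer(0)
  list(Y = Y, n_net = n_net, n_c = n_c,
       filo_off = filo_off, filo_len = filo_len, states = states,
       L_am = L_am, L_am_off = L_am_off,
       fc_seg = fc_seg, fc_nb = fc_nb, F_P = F_P, roots = roots,
       free_mask = free_mask, fa_i = fa_i)
}

# argument list for the compiled kernel.  The head (network topology, cell
# topology, adhesion tables, material constants) only changes at event
# boundaries and is cached on the state; the per-step tail carries the
# filopodium pack.
.scene_args <- function(st, pk) {
  head <- st$args_head
  if (is.null(head)) head <- .scene_args_head(st, pk)
  c(head,
    list(pk$filo_off, pk$filo_len, pk$states, pk$L_am, pk$L_am_off,
         pk$fc_seg, pk$fc_nb, pk$F_P, pk$roots, st$root_fixed,
         if (!is.null(st$net)) st$material$radius else 0,
         st$params$engine$contact_pad %||% 0.15,
         st$params$engine$contact_pad_cell %||% 0.05,
         st$params$engine$contact_stiffness))
}

.scene_args_head <- function(st, pk) {
  p <- st$params
  net <- st$net
  cell <- st$cell
  e0i <- matrix(0L, 0, 2)
  f0i <- matrix(0L, 0, 3)
  mat <- st$material
  list(
    pk$n_net, pk$n_c,
    if (!is.null(net)) net$seg_a else integer(0),
    if (!is.null(net)) net$seg_b else integer(0),
    if (!is.null(net)) net$seg_L0 else numeric(0),
    if (!is.null(net)) net$seg_active else logical(0),
    if (!is.null(mat)) mat$kappa_s else 0,
    if (!is.null(net)) net$bend_a else integer(0),
    if (!is.null(net)) net$bend_b else integer(0),
    if (!is.null(net)) net$bend_c else integer(0),
    if (!is.null(net)) net$bend_theta0 else numeric(0),
    if (!is.null(net)) net$bend_L0 else numeric(0),
    if (!is.null(net)) net$bend_seg1 else integer(0),
    if (!is.null(net)) net$bend_seg2 else integer(0),
    if (!is.null(mat)) mat$kappa_b else 0,
    pk$free_mask,
    if (!is.null(st$tether)) st$tether$idx else integer(0),
    if (!is.null(st$tether)) st$tether$anchor else matrix(0, 0, 3),
    if (!is.null(st$tether)) st$tether$k else 0,
    if (!is.null(cell)) cell$edges else e0i,
    if (!is.null(cell)) cell$L0_c else numeric(0),
    if (!is.null(cell)) cell$L0_t else numeric(0),
    if (!is.null(cell)) cell$L0_n else numeric(0),
    if (!is.null(cell)) cell$cort_L0 else numeric(0),
    p$cell$kappa_memb, p$cell$kappa_cort,
    if (!is.null(cell)) cell$faces else f0i,
    if (!is.null(cell)) cell$vol0_n else 1,
    p$cell$kappa_vol,
    if (!is.null(cell)) cell$polarization else c(1, 0, 0),
    cos(deg2rad(p$cell$leading_cone)), p$cell$F_L,
    pk$fa_i,
    if (length(pk$fa_i)) cell$fa_seg[pk$fa_i] else integer(0),
    if (length(pk$fa_i)) as.numeric(cell$fa_n_b[pk$fa_i]) else numeric(0),
    p$binding$kappa_LR, p$binding$lambda,
    if (!is.null(cell)) cell$sf_t else integer(0),
    if (!is.null(cell)) cell$sf_n else integer(0),
    if (!is.null(cell)) cell$sf_L0 else numeric(0),
    p$motor$E_AM * p$motor$A_AM,
    p$cell$C_c, p$cell$C_t, p$cell$C_n, p$cell$C_cort,
    p$fiber$C_e, p$filopodium$C_f)
}

# one compiled evaluation of all velocities (and forces) at positions Y
.scene_eval <- function(Y, args) {
  do.call(.cpp_scene_eval, c(list(Y), args))
}

.unpack_state <- function(st, Y, pk) {
  if (pk$n_net) st$net$nodes <- Y[seq_len(pk$n_net), , drop = FALSE]
  if (pk$n_c) {
    oc <- pk$n_net
    st$cell$x_c <- Y[oc + seq_len(pk$n_c), , drop = FALSE]
    st$cell$x_t <- Y[oc + pk$n_c + seq_len(pk$n_c), , drop = FALSE]
    st$cell$x_n <- Y[oc + 2L * pk$n_c + seq_len(pk$n_c), , drop = FALSE]
  }
  for (k in seq_along(st$filopodia)) {
    st$filopodia[[k]]$nodes <-
      Y[pk$filo_off[k] + seq_len(pk$filo_len[k]), , drop = FALSE]
  }
  st
}

## ---- macro step -------------------------------------------------------------

#' Advance the simulation by one accepted macro-step
#'
#' Assembles all force terms, advances the overdamped node equations with
#' the embedded adaptive pair (local error kept below `engine$ode_tol`,
#' step clamped to `[dt_min, dt_max]`), then applies the stochastic bond
#' events, acto-myosin rest-length updates and the filopodium phase machine
#' with the accepted dt, followed by the slower reaction-diffusion /
#' degradation substep and the periodic active-domain refresh.
#'
#' @param st a `sim_state`.
#' @return the advanced state (`st$dt` holds the accepted step).
#' @export
engine_step <- function(st) {
  en <- st$params$engine
  pk <- .pack_state(st)
  if (is.null(st$args_head)) st$args_head <- .scene_args_head(st, pk)
  args <- .scene_args(st, pk)
  Y <- pk$Y
  v1 <- .scene_eval(Y, args)$V
  # mixed absolute/relative tolerance on the local position error (um)
  tol <- en$ode_tol * (1 + max(abs(Y)))
  dt <- st$dt
  repeat {
    Ye <- Y + dt * v1
    v2 <- .scene_eval(Ye, args)$V
    err <- dt / 2 * max(abs(v2 - v1))
    if (err <= tol || dt <= en$dt_min * (1 + 1e-9)) break
    dt <- max(en$dt_min, dt * max(0.3, 0.9 * sqrt(tol / max(err, 1e-300))))
  }
  st <- .unpack_state(st, Y + (dt / 2) * (v1 + v2), pk)   # Heun update
  st$time <- st$time + dt
  st$dt <- clamp(dt * min(2, max(0.5, 0.9 * sqrt(tol / max(err, 1e-300)))),
                 en$dt_min, en$dt_max)
  st$n_steps <- st$n_steps + 1L
  st <- .apply_events(st, dt)
  ## reaction-diffusion / degradation cadence
  if (!is.null(st$fields) && st$time - st$last_rd >= st$params$rd$interval) {
    dtr <- st$time - st$last_rd
    live <- Filter(function(f) f$state %in% 2:5, st$filopodia)
    src <- secretion_sources(live, st$fields)
    eg <- if (!is.null(st$net)) ecm_concentration_grid(st$net, st$fields) else NULL
    st$fields <- rd_step(st$fields, st$params, src, dtr, ecm_grid = eg)
    if (!is.null(st$net)) {
      st$net <- update_ecm_integrity(st$net, st$fields, st$params, dtr)
      if (st$params$rd$degradation) {
        st$net <- apply_crosslink_degradation(st$net, st$rng_degr)
        st$args_head <- NULL
      }
    }
    st$last_rd <- st$time
  }
  if (st$time - st$last_refresh >= en$active_refresh) {
    st <- refresh_active_domain(st)
  } else if (st$time - st$last_index >= 1 && !is.null(st$net)) {
    st$seg_idx <- segment_index(st$net$nodes, st$net$seg_a, st$net$seg_b,
                                active = which(st$net$seg_active),
                                cell = max(0.5, st$net$pore_size))
    st$last_index <- st$time
  }
  st
}

# stochastic bond events, AM contraction and the phase machine (accepted dt)
.apply_events <- function(st, dt) {
  p <- st$params
  fp <- p$filopodium
  # new-anchor searches run on a short cadence; bond kinetics every step
  st$do_search <- st$time - (st$last_search %||% -Inf) >=
    (p$engine$search_interval %||% 0.05)
  if (st$do_search) st$last_search <- st$time
  for (k in seq_along(st$filopodia)) {
    f <- st$filopodia[[k]]
    if (!(f$state %in% 1:5)) next
    tip <- f$nodes[nrow(f$nodes), ]
    F_TR <- 0
    had_bonds <- !is.null(f$fc) && f$fc$n_b > 0
    if (!is.null(st$net)) {
      if (is.null(f$fc) && f$state %in% c(2L, 3L) && st$do_search) {
        anc <- candidate_anchor(tip, st$net, p, index = st$seg_idx)
        if (!is.null(anc)) f$fc <- anc
      }
      if (!is.null(f$fc)) {
        if (!st$net$seg_active[f$fc$seg]) {            # anchor fiber degraded
          st$net$ligand_bound[f$fc$ligand_node] <-
            st$net$ligand_bound[f$fc$ligand_node] - f$fc$n_b
          f$fc <- NULL
        } else {
          f$fc <- fc_update_geometry(f$fc, tip, st$net)
          if (f$fc$n_b > 0) {
            rr <- sample_bond_rupture(f$fc, st$net, p, dt, st$rng_rupt)
            f$fc <- rr$fc; st$net <- rr$net
          }
          if (f$state %in% 2:4 && f$fc$h_p < p$binding$contact_range) {
            bb <- sample_bond_formation(f$fc, st$net, p, dt, st$rng_bind)
            f$fc <- bb$fc; st$net <- bb$net
          }
          ff <- fc_force(f$fc, st$net, p)
          F_TR <- vnorm(ff$on_tip)
          if (f$fc$n_b == 0 && f$fc$h_p >= p$binding$contact_range) f$fc <- NULL
        }
      }
    }
    ## motor activity / growth by phase
    if (f$state == 2L) {
      am <- am_update_and_forces(f, 0, p, dt, grow = fp$v_poly)
      f <- am$filo
    } else if (f$state %in% c(3L, 4L)) {
      v_m <- myosin_velocity(min(F_TR, p$motor$F_stall), p)
      am <- am_update_and_forces(f, v_m, p, dt)
      f <- am$filo
    } else if (f$state == 5L) {
      am <- am_update_and_forces(f, p$motor$v_m0, p, dt)
      f <- am$filo
    }
    f <- advance_state(f, p, dt, F_TR = F_TR, had_bonds = had_bonds)
    if (isTRUE(f$released) && !is.null(f$fc)) {
      if (!is.null(st$net)) {
        st$net$ligand_bound[f$fc$ligand_node] <-
          st$net$ligand_bound[f$fc$ligand_node] - f$fc$n_b
      }
      f$fc <- NULL
    }
    st$filopodia[[k]] <- f
  }
  ## cell-side events at a coarser cadence
  if (!is.null(st$cell) && st$time - st$last_fa >= (p$engine$fa_interval %||% 0.1)) {
    st <- .cell_events(st, st$time - st$last_fa)
    st$last_fa <- st$time
  }
  st <- .nucleation_events(st, dt)
  st
}

# FA bond kinetics, stress-fiber nucleation/contraction, polarization
.cell_events <- function(st, dt) {
  p <- st$params
  cp <- p$cell
  cell <- st$cell
  if (!is.null(st$net)) {
    normals <- mesh_normals(cell$x_c, cell$faces)
    for (i in seq_len(cell$n_nodes)) {
      x <- cell$x_c[i, ]
      if (cell$fa_n_b[i] > 0 || !is.na(cell$fa_seg[i])) {
        seg <- cell$fa_seg[i]
        if (!st$net$seg_active[seg]) {                  # anchor degraded
          st$net$ligand_bound[cell$fa_node[i]] <-
            st$net$ligand_bound[cell$fa_node[i]] - cell$fa_n_b[i]
          cell$fa_n_b[i] <- 0L; cell$fa_seg[i] <- NA_integer_
          next
        }
        fc <- list(seg = seg, tpar = cell$fa_tpar[i], n_b = cell$fa_n_b[i],
                   ligand_node = cell$fa_node[i])
        g <- fc_update_geometry(fc, x, st$net)
        if (g$n_b > 0) {
          rr <- sample_bond_rupture(g, st$net, p, dt, st$rng_rupt,
                                    k_off_scale = cp$fa_koff_scale)
          g <- rr$fc; st$net <- rr$net
        }
        if (g$h_p < p$binding$contact_range) {
          pp <- p; pp$binding$receptor_capacity <- cp$fa_cap
          bb <- sample_bond_formation(g, st$net, pp, dt, st$rng_bind)
          g <- bb$fc; st$net <- bb$net
        }
        if (g$n_b == 0 && g$h_p >= p$binding$contact_range) {
          cell$fa_seg[i] <- NA_integer_
        } else {
          cell$fa_seg[i] <- g$seg; cell$fa_tpar[i] <- g$tpar
        }
        cell$fa_n_b[i] <- g$n_b
      } else {
        anc <- candidate_anchor(x, st$net, p, index = st$seg_idx)
        if (!is.null(anc)) {
          pp <- p; pp$binding$receptor_capacity <- cp$fa_cap
          bb <- sample_bond_formation(anc, st$net, pp, dt, st$rng_bind)
          st$net <- bb$net
          if (bb$fc$n_b > 0) {
            cell$fa_seg[i] <- bb$fc$seg; cell$fa_tpar[i] <- bb$fc$tpar
            cell$fa_node[i] <- bb$fc$ligand_node
            cell$fa_n_b[i] <- bb$fc$n_b
          }
        }
      }
    }
    ## stress fibers nucleate from mature FAs toward the nearest nucleus node
    mature <- which(cell$fa_n_b >= cp$fa_maturity)
    for (i in mature) {
      if (length(cell$sf_t) >= cp$sf_max || i %in% cell$sf_t) next
      d <- row_norms(sweep(cell$x_n, 2, cell$x_t[i, ]))
      j <- which.min(d)
      cell$sf_t <- c(cell$sf_t, i)
      cell$sf_n <- c(cell$sf_n, j)
      cell$sf_L0 <- c(cell$sf_L0, d[j])
    }
  }
  ## stress-fiber contraction
  nf <- nucleus_sf_forces(cell, p, dt = dt)
  cell <- nf$cell
  ## polarization: exponential moving average toward recent displacement
  ctr <- colMeans(cell$x_c)
  if (!is.null(st$prev_centroid)) {
    disp <- ctr - st$prev_centroid
    if (vnorm(disp) > 1e-9) {
      m <- cp$polarization_memory
      cell$polarization <- unitize(m * cell$polarization +
                                     (1 - m) * unitize(disp))
    }
  }
  st$prev_centroid <- ctr
  st$cell <- cell
  st$args_head <- NULL
  st
}

# filopodium nucleation and recycling
.nucleation_events <- function(st, dt) {
  p <- st$params
  fp <- p$filopodium
  if (is.null(st$cell)) {
    if (isTRUE(st$respawn)) {
      ## rootless scenes recycle decayed filopodia in place
      for (k in seq_along(st$filopodia)) {
        f <- st$filopodia[[k]]
        if (f$state == FILO_STATES[["decay"]]) {
          nf <- make_filopodium(f$nodes[1, ], f$axis, p,
                                state = FILO_STATES[["outgrowing"]])
          nf$id <- st$next_filo_id
          nf$n_cycles <- f$n_cycles
          st$next_filo_id <- st$next_filo_id + 1L
          st$filopodia[[k]] <- nf
        }
      }
    }
    return(st)
  }
  ## decayed filopodia are retired from the scene
  st$filopodia <- Filter(function(f) f$state %in% 1:5, st$filopodia)
  live <- length(st$filopodia)
  want <- fp$max_filopodia - live
  if (want <= 0) return(st)
  p_attempt <- 1 - exp(-fp$nucleation_rate * dt)
  tries <- with_rng(st$rng_nucl, stats::rbinom(1L, want, p_attempt))
  if (tries > 0) {
    normals <- mesh_normals(st$cell$x_c, st$cell$faces)
    ang <- acos(clamp(normals %*% st$cell$polarization, -1, 1))
    elig <- which(ang < deg2rad(fp$polarity_max_angle))
    used <- vapply(st$filopodia, function(f) {
      if (f$state %in% 1:5) f$root_node else NA_integer_
    }, integer(1))
    elig <- setdiff(elig, used[!is.na(used)])
    if (!length(elig)) return(st)
    picks <- with_rng(st$rng_nucl,
                      sample(elig, min(tries, length(elig))))
    for (i in picks) {
      axis <- normals[i, ]
      if (!is.null(st$fields)) {
        g <- field_gradient(st$fields, "vegf", st$cell$x_c[i, ])$gradient
        if (vnorm(g) > 1e-30) axis <- unitize(axis + unitize(g))
      }
      f <- make_filopodium(st$cell$x_c[i, ], axis, p,
                           state = FILO_STATES[["active"]], root_node = i)
      f$id <- st$next_filo_id
      st$next_filo_id <- st$next_filo_id + 1L
      st$filopodia[[length(st$filopodia) + 1L]] <- f
    }
  }
  st
}

## ---- simulation loops -------------------------------------------------------

#' Run a scene and record trajectories
#'
#' Steps the state to `total_time`, recording filopodial tip and root
#' positions, phase, bond count and tip tension at the snapshot cadence
#' (the observables of the per-filopodium event log).
#'
#' @param st a `sim_state`.
#' @param total_time simulated duration (s); 0 returns an empty record.
#' @param progress print occasional progress lines.
#' @return list: final `state`, `log` (data frame: time, filo id, state,
#'   L_f, n_b, F_TR, tip/root coordinates), `centroid` (data frame of cell
#'   centroid positions, if a cell is present).
#' @export
simulate_scene <- function(st, total_time, progress = FALSE) {
  snap <- st$params$engine$snapshot
  logs <- list()
  cent <- list()
  nxt <- 0
  t_end <- st$time + total_time
  while (st$time < t_end - 1e-12) {
    if (st$time >= nxt - 1e-12) {
      logs[[length(logs) + 1L]] <- .snapshot_row(st)
      if (!is.null(st$cell)) {
        cent[[length(cent) + 1L]] <-
          data.frame(time = st$time, t(colMeans(st$cell$x_c)))
      }
      nxt <- nxt + snap
      if (progress && length(logs) %% 60 == 1) {
        message(sprintf("t = %.0f s (%d steps)", st$time, st$n_steps))
      }
    }
    st <- engine_step(st)
  }
  logs[[length(logs) + 1L]] <- .snapshot_row(st)
  if (!is.null(st$cell)) {
    cent[[length(cent) + 1L]] <-
      data.frame(time = st$time, t(colMeans(st$cell$x_c)))
  }
  log <- do.call(rbind, logs)
  centroid <- if (length(cent)) {
    out <- do.call(rbind, cent)
    names(out) <- c("time", "x", "y", "z")
    out
  } else NULL
  list(state = st, log = log, centroid = centroid)
}

.snapshot_row <- function(st) {
  rows <- lapply(st$filopodia, function(f) {
    if (!(f$state %in% 1:5)) return(NULL)
    tip <- f$nodes[nrow(f$nodes), ]
    root <- f$nodes[1, ]
    ff <- if (!is.null(f$fc) && !is.null(st$net)) {
      fc_force(f$fc, st$net, st$params)$on_tip
    } else c(0, 0, 0)
    data.frame(time = st$time, filo = f$id, state = f$state,
               L_f = filopodium_length(f),
               n_b = if (is.null(f$fc)) 0L else f$fc$n_b,
               F_TR = vnorm(ff),
               tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
               root_x = root[1], root_y = root[2], root_z = root[3])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(time = st$time, filo = NA_integer_, state = NA_integer_,
                      L_f = NA_real_, n_b = NA_integer_, F_TR = NA_real_,
                      tip_x = NA_real_, tip_y = NA_real_, tip_z = NA_real_,
                      root_x = NA_real_, root_y = NA_real_, root_z = NA_real_))
  }
  do.call(rbind, rows)
}

#' Full invasion simulation with replicates
#'
#' Builds the invasion scene for the configured network preset -- a fiber
#' network filling the box, concentration fields with the VEGF source on
#' the far +x face, and a cell placed at the ECM/medium interface (centroid
#' just outside the -x face, leading edge inside the gel, polarized along
#' +x) -- and runs `replicates` independent seeds.  Per replicate the
#' filopodial tip and root mean speeds (path length over elapsed time) are
#' averaged over filopodia alive for at least two snapshots.
#'
#' @param params a `sim_params` object; `engine$total_time` sets the
#'   simulated duration.
#' @param replicates number of independent runs (distinct derived seeds).
#' @param progress print progress.
#' @return object of class `invasion_run`: `summary` (per-replicate tip and
#'   root speeds, um/s), `mean_tip`, `mean_root`, `sem_tip`, `sem_root`,
#'   `logs` (per-replicate event logs), `params`.
#' @export
run_simulation <- function(params, replicates = 5, progress = FALSE) {
  tips <- roots <- numeric(replicates)
  logs <- vector("list", replicates)
  cents <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    p <- params
    p$seed <- (params$seed * 1000L + r) %% .Machine$integer.max
    st <- .invasion_scene(p)
    res <- simulate_scene(st, p$engine$total_time, progress = progress)
    logs[[r]] <- res$log
    cents[[r]] <- res$centroid
    sp <- .log_speeds(res$log)
    tips[r] <- sp$tip; roots[r] <- sp$root
    if (progress) {
      message(sprintf("replicate %d: tip %.4g um/s, root %.4g um/s",
                      r, tips[r], roots[r]))
    }
  }
  structure(list(
    summary = data.frame(replicate = seq_len(replicates),
                         tip_speed = tips, root_speed = roots),
    mean_tip = mean(tips, na.rm = TRUE), mean_root = mean(roots, na.rm = TRUE),
    sem_tip = stats::sd(tips, na.rm = TRUE) / sqrt(sum(!is.na(tips))),
    sem_root = stats::sd(roots, na.rm = TRUE) / sqrt(sum(!is.na(roots))),
    logs = logs, centroids = cents, params = params
  ), class = "invasion_run")
}

.invasion_scene <- function(p) {
  net <- build_network(p)
  cellpar <- p$cell
  ctr <- c(-0.55 * cellpar$radius,
           p$network$domain[2] / 2, p$network$domain[3] / 2)
  cell <- make_cell(ctr, p, polarization = c(1, 0, 0))
  fields <- make_fields(p, p$network$domain)
  ## interface nodes of the -x face are held (gel clamped far from the cell)
  far <- which(net$nodes[, 1] > p$network$domain[1] - p$network$pore_size / 2)
  make_sim_state(p, net = net, cell = cell, fields = fields, fixed_net = far)
}

.log_speeds <- function(log) {
  log <- log[!is.na(log$filo), , drop = FALSE]
  if (!nrow(log)) return(list(tip = NA_real_, root = NA_real_))
  per_filo <- split(log, log$filo)
  tip_sp <- root_sp <- numeric(0)
  for (df in per_filo) {
    if (nrow(df) < 2 || max(df$time) - min(df$time) <= 0) next
    tip_sp <- c(tip_sp, mean_speed(df[, c("time", "tip_x", "tip_y", "tip_z")]))
    root_sp <- c(root_sp,
                 mean_speed(df[, c("time", "root_x", "root_y", "root_z")]))
  }
  list(tip = if (length(tip_sp)) mean(tip_sp) else NA_real_,
       root = if (length(root_sp)) mean(root_sp) else NA_real_)
}

#' @export
print.invasion_run <- function(x, ...) {
  cat(sprintf("<invasion_run> %d replicates, preset %s, %g s simulated\n",
              nrow(x$summary), x$params$preset, x$params$engine$total_time))
  cat(sprintf("  tip  speed: %.4g +/- %.2g um/s (mean +/- SEM)\n",
              x$mean_tip, x$sem_tip))
  cat(sprintf("  root speed: %.4g +/- %.2g um/s\n",
              x$mean_root, x$sem_root))
  invisible(x)
}

#' Single-filopodium scene against a tethered fiber
#'
#' The canonical regime probe: one filopodium with a fixed root grows along
#' +x toward a single fiber segment held by tether springs of stiffness
#' `anchor_stiffness`; with a soft tether the tip shows repeated
#' load-and-fail cycles, with a stiff tether sustained loading into the
#' contractile phase (motor-clutch behavior).  Decayed filopodia respawn at
#' the same root so cycling can continue.
#'
#' @param params a `sim_params` object (seed required).
#' @param anchor_stiffness tether stiffness (pN/um); soft < 1 pN/nm
#'   (1000 pN/um), stiff > 10 pN/nm.
#' @return a `sim_state`.
#' @export
single_filopodium_scene <- function(params, anchor_stiffness,
                                    standoff = 0.55) {
  p <- params
  fp <- p$filopodium
  L0 <- fp$L_init
  nodes <- rbind(c(L0 + standoff, -0.5, 0), c(L0 + standoff, 0.5, 0))
  net <- .minimal_network(nodes, p)
  filo <- make_filopodium(c(0, 0, 0), c(1, 0, 0), p)
  st <- make_sim_state(p, net = net, filopodia = list(filo),
                       tether = list(idx = 1:2, anchor = nodes,
                                     k = anchor_stiffness),
                       root_fixed = TRUE)
  st$respawn <- TRUE
  st
}

#' Count load-and-fail cycles in an event log
#'
#' A cycle is one loading episode in which the tip tension rises to at
#' least `hi` and subsequently collapses below `lo` (bond rupture, release
#' or filopodium decay) -- the motor-clutch traction signature on soft
#' anchors.
#'
#' @param log an event log from [simulate_scene()].
#' @param hi loading threshold (pN).
#' @param lo collapse threshold (pN).
#' @return integer cycle count.
#' @export
count_load_fail_cycles <- function(log, hi = 100, lo = 10) {
  f <- log$F_TR[!is.na(log$F_TR)]
  loaded <- FALSE
  n <- 0L
  for (v in f) {
    if (!loaded && v >= hi) loaded <- TRUE
    if (loaded && v < lo) { n <- n + 1L; loaded <- FALSE }
  }
  n
}

# a bare two-node, one-segment fiber network
.minimal_network <- function(nodes, p) {
  structure(list(
    nodes = nodes, node_type = c(2L, 2L),
    seg_a = 1L, seg_b = 2L, seg_L0 = vnorm(nodes[2, ] - nodes[1, ]),
    seg_type = 1L, seg_fiber = 1L, seg_active = TRUE,
    cross_seg_node = NA_integer_,
    edge_a = integer(0), edge_b = integer(0), cs_idx = NULL,
    chains = list(c(1L, 2L)),
    bend_a = integer(0), bend_b = integer(0), bend_c = integer(0),
    bend_theta0 = numeric(0), bend_L0 = numeric(0),
    bend_seg1 = integer(0), bend_seg2 = integer(0),
    n_crosslink = 0L, cross_n_fs = integer(0), cross_n_0f = integer(0),
    cross_n_uf = integer(0),
    ligand_cap = rep(p$network$ligand_capacity, 2),
    ligand_bound = c(0, 0),
    C_ecm = rep(p$rd$C_ecm0, 2), C_ecm0 = p$rd$C_ecm0,
    domain = c(4, 2, 2), pore_size = 1,
    fiber_diameter = p$network$fiber_diameter, seed = p$seed
  ), class = "fiber_network")
}
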