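#' Fiber material properties
#'
#' Derives the mechanical moduli of a single collagen fiber from its
#' diameter and Young's modulus: cross-section `A_f = pi r^2`, second
#' moment `I_f = pi r^4 / 4`, stretching modulus `kappa_s = E_f A_f` (pN)
#' and bending modulus `kappa_b = E_f I_f` (pN um^2, overridable via
#' `fiber.kappa_b`).
#'
#' @param params a `sim_params` object, or a number interpreted as fiber
#'   diameter in nm with the default 1 MPa modulus.
#' @param fiber_diameter optional diameter override (nm).
#' @return a list of class `fiber_material` with fields `E_f` (pN/um^2),
#'   `radius` (um), `A_f` (um^2), `I_f` (um^4), `kappa_s` (pN), `kappa_b`
#'   (pN um^2), `C_e` (pN s/um).
#' @examples
#' m <- fiber_material(sim_params(seed = 1, network.fiber_diameter = 41))
#' m$kappa_s / 1000   # stretching modulus in nN
#' @export
fiber_material <- function(params, fiber_diameter = NULL) {
  if (is.numeric(params)) {
    params <- sim_params(seed = 0, network.fiber_diameter = params)
  }
  stopifnot(inherits(params, "sim_params"))
  d_nm <- if (!is.null(fiber_diameter)) fiber_diameter else
    params$network$fiber_diameter
  r <- d_nm / 2000                      # nm diameter -> um radius
  E <- params$fiber$E_f
  A <- pi * r^2
  I <- pi * r^4 / 4
  kb <- if (!is.null(params$fiber$kappa_b)) params$fiber$kappa_b else E * I
  structure(list(E_f = E, radius = r, A_f = A, I_f = I,
                 kappa_s = E * A, kappa_b = kb, C_e = params$fiber$C_e),
            class = "fiber_material")
}

# stretching + bending forces and total energy in one pass (compiled kernel)
.net_forces_energy <- function(net, material, P = net$nodes) {
  .cpp_net_forces(P, net$seg_a, net$seg_b, net$seg_L0, net$seg_active,
                  material$kappa_s,
                  net$bend_a, net$bend_b, net$bend_c,
                  net$bend_theta0, net$bend_L0,
                  net$bend_seg1, net$bend_seg2,
                  material$kappa_b)
}

#' Total elastic energy of a fiber network
#'
#' Sum over fibers of the stretching energy
#' `kappa_s/2 (L - L0)^2 / L0` per segment and the bending energy
#' `kappa_b/2 (theta - theta0)^2 / L0` per interior node, angles taken
#' between coaxial neighbour segments within each chain only.
#'
#' @param net a `fiber_network`; positions may be overridden via `P`.
#' @param material a `fiber_material`.
#' @param P optional node-position matrix (defaults to `net$nodes`).
#' @return energy in pN um.
#' @export
elastic_energy <- function(net, material, P = net$nodes) {
  if (any(net$seg_L0[net$seg_active] <= 0)) stop("zero rest length in network")
  .net_forces_energy(net, material, P)$energy
}

#' Nodal elastic forces of a fiber network
#'
#' The force on every node is minus the gradient of [elastic_energy()] with
#' respect to that node's position (virtual work).  The angle derivative
#' uses `theta = acos(t_k . t_k+1)`; the `1/sin(theta)` singularity at
#' collinearity is removed analytically (the prefactor
#' `(theta - theta0)/sin(theta)` tends to 1 for straight rest angles) and
#' guarded numerically elsewhere.
#'
#' @inheritParams elastic_energy
#' @return an `n x 3` matrix of forces (pN); rows sum to zero over an
#'   isolated network.
#' @export
elastic_forces <- function(net, material, P = net$nodes) {
  .net_forces_energy(net, material, P)$F
}

## ---- quasi-static relaxation ----------------------------------------------

# FIRE (fast inertial relaxation engine) minimization of the network's
# elastic energy over the free nodes; `fixed` nodes are held.  Used by the
# stretch-test protocol between strain increments, where only the relaxed
# fixed point matters.  Returns list(P, converged, resid).
relax_network <- function(net, material, fixed, P = net$nodes,
                          tol_force = 1e-4 * material$kappa_s,
                          max_iter = 40000, extra_force = NULL) {
  free <- setdiff(seq_len(nrow(P)), fixed)
  if (!length(free)) return(list(P = P, converged = TRUE, resid = 0))
  # stable step from the stiffest spring (30 nm crosslink segments)
  kmax <- material$kappa_s / min(net$seg_L0[net$seg_active]) +
    material$kappa_b / min(net$seg_L0[net$seg_active])^3
  dt0 <- 0.5 / sqrt(kmax)
  dt <- dt0; dtmax <- 20 * dt0
  a0 <- 0.1; alpha <- a0; n_good <- 0L
  V <- matrix(0, nrow(P), 3)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    F <- elastic_forces(net, material, P)
    if (!is.null(extra_force)) F <- F + extra_force
    Ff <- F[free, , drop = FALSE]
    resid <- max(abs(Ff))
    if (resid < tol_force) return(list(P = P, converged = TRUE, resid = resid))
    Vf <- V[free, , drop = FALSE]
    p <- sum(Ff * Vf)
    if (p > 0) {
      n_good <- n_good + 1L
      vn <- sqrt(sum(Vf^2)); fn <- sqrt(sum(Ff^2))
      Vf <- (1 - alpha) * Vf + alpha * (Ff / max(fn, 1e-300)) * vn
      if (n_good > 5L) { dt <- min(dt * 1.1, dtmax); alpha <- alpha * 0.99 }
    } else {
      Vf[] <- 0; dt <- max(dt * 0.5, dt0 * 1e-3); alpha <- a0; n_good <- 0L
    }
    Vf <- Vf + Ff * dt
    P[free, ] <- P[free, , drop = FALSE] + Vf * dt
    V[free, ] <- Vf
  }
  list(P = P, converged = FALSE, resid = resid)
}

#' In-silico uniaxial stretch test
#'
#' Emulates the gel rheology protocol: the two opposing boundary node sets
#' along `axis` are displaced symmetrically at a constant nominal stretch
#' speed; between strain increments the interior is relaxed quasi-statically
#' to mechanical equilibrium, and the axial stress is recorded as the sum of
#' boundary reaction forces divided by the undeformed cross-sectional area
#' of the domain face.
#'
#' @param net a `fiber_network`.
#' @param material a `fiber_material`.
#' @param speed nominal stretching speed (um/s; e.g. 5e-4 = 0.5 nm/s).
#'   Recorded as metadata; the quasi-static stress-strain response is
#'   rate-independent.
#' @param max_strain maximum engineering strain.
#' @param d_strain strain increment between recorded samples.
#' @param axis stretch axis (1, 2 or 3).
#' @param boundary_frac fraction of the domain extent clamped at each face.
#' @return an object of class `stress_strain_curve`: a data frame with
#'   columns `strain`, `stress` (Pa = pN/um^2) and `converged`, plus the
#'   fitted bulk modulus over strain 0.2-0.7 when the curve reaches 0.7.
#' @export
run_stretch_test <- function(net, material, speed = 5e-4, max_strain = 0.75,
                             d_strain = 0.05, axis = 1,
                             boundary_frac = 0.06) {
  P0 <- net$nodes
  lo <- min(P0[, axis]); hi <- max(P0[, axis])
  L <- hi - lo
  margin <- boundary_frac * L
  left <- which(P0[, axis] <= lo + margin)
  right <- which(P0[, axis] >= hi - margin)
  if (!length(left) || !length(right)) {
    stop("network has no opposing boundary node sets along this axis")
  }
  fixed <- c(left, right)
  area <- prod(net$domain[-axis])
  strains <- seq(0, max_strain, by = d_strain)
  stress <- conv <- numeric(length(strains))
  P <- P0
  for (i in seq_along(strains)) {
    eps <- strains[i]
    P[left, axis] <- P0[left, axis] - eps * L / 2
    P[right, axis] <- P0[right, axis] + eps * L / 2
    rx <- relax_network(net, material, fixed, P)
    P <- rx$P
    Fel <- elastic_forces(net, material, P)
    # reaction force the network exerts on each grip
    f_right <- sum(Fel[right, axis])
    f_left <- sum(Fel[left, axis])
    stress[i] <- (abs(f_right) + abs(f_left)) / 2 / area
    conv[i] <- rx$converged
  }
  out <- structure(list(
    curve = data.frame(strain = strains, stress = stress,
                       converged = as.logical(conv)),
    stretch_speed = speed, axis = axis, area = area,
    fit_window = c(0.2, 0.7), fitted_modulus = NA_real_
  ), class = "stress_strain_curve")
  if (max(strains) >= 0.7) out$fitted_modulus <- fit_bulk_modulus(out)
  out
}

#' Fit the bulk modulus of a stress-strain curve
#'
#' Least-squares slope of stress versus strain restricted to the strain
#' window 0.2-0.7, the linear regime used to characterize the in-silico
#' gels.
#'
#' @param curve a `stress_strain_curve`, or a data frame with `strain` and
#'   `stress` columns.
#' @param window fitting window on strain.
#' @return modulus in Pa (pN/um^2).
#' @export
fit_bulk_modulus <- function(curve, window = c(0.2, 0.7)) {
  df <- if (inherits(curve, "stress_strain_curve")) curve$curve else curve
  sel <- df$strain >= window[1] - 1e-12 & df$strain <= window[2] + 1e-12
  if (sum(sel) < 3) stop("fewer than 3 samples in the fitting window")
  unname(coef(stats::lm(stress ~ strain, data = df[sel, ]))[2])
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("<stress_strain_curve> %d samples to strain %.2g, speed %g nm/s\n",
              nrow(x$curve), max(x$curve$strain), x$stretch_speed * 1000))
  if (!is.na(x$fitted_modulus)) {
    cat(sprintf("  fitted bulk modulus (strain %.1f-%.1f): %.4g Pa\n",
                x$fit_window[1], x$fit_window[2], x$fitted_modulus))
  }
  if (any(!x$curve$converged)) {
    cat(sprintf("  flagged samples (non-equilibrated): %d\n",
                sum(!x$curve$converged)))
  }
  invisible(x)
}

#' @export
plot.stress_strain_curve <- function(x, ...) {
  plot(x$curve$strain, x$curve$stress, type = "b", pch = 16,
       xlab = "strain", ylab = "stress (Pa)", ...)
  if (!is.na(x$fitted_modulus)) {
    sel <- x$curve$strain >= x$fit_window[1] & x$curve$strain <= x$fit_window[2]
    fit <- stats::lm(stress ~ strain, data = x$curve[sel, ])
    lines(x$curve$strain[sel], fitted(fit), col = 2, lwd = 2)
  }
  invisible(x)
}
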