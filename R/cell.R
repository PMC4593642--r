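# Simplified triple-membrane cell mechanics: cell membrane, transduce layer
# and nuclear membrane as concentric triangulated spheres sharing one
# topology, coupled by Kelvin-Voigt cortex elements (membrane-transduce)
# and contractile stress fibers (transduce-nucleus).  Focal adhesions on
# membrane nodes use the same Bell/Monte-Carlo bond machinery as filopodial
# focal complexes, with a slower unstressed turnover.

# subdivided icosahedron on the unit sphere: 12/42/162/642 vertices
icosphere <- function(subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / row_norms(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- get0(key, envir = mid_cache)
      if (!is.null(m)) return(m)
      p <- unitize(v[i, ] + v[j, ])
      v <<- rbind(v, p)
      assign(key, nrow(v), envir = mid_cache)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; cc <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  list(vertices = v, faces = f, edges = e)
}

#' Create a cell body
#'
#' Builds the three concentric triangulated membranes (cell membrane,
#' transduce layer, nuclear membrane; equal node counts) at a given center,
#' with edge-spring rest lengths and the nucleus rest volume taken from the
#' built geometry.
#'
#' @param center 3-vector (um).
#' @param params a `sim_params` object; `cell$n_subdiv` sets the mesh
#'   refinement (12/42/162/642 nodes for 0/1/2/3).
#' @param polarization initial unit polarization axis (default +x).
#' @return an object of class `cell_body`.
#' @export
make_cell <- function(center, params, polarization = c(1, 0, 0)) {
  cp <- params$cell
  mesh <- icosphere(cp$n_subdiv)
  n <- nrow(mesh$vertices)
  x_c <- sweep(mesh$vertices * cp$radius, 2, center, "+")
  x_t <- sweep(mesh$vertices * cp$radius * cp$transduce_frac, 2, center, "+")
  x_n <- sweep(mesh$vertices * cp$nucleus_radius, 2, center, "+")
  eL <- function(X) row_norms(X[mesh$edges[, 2], , drop = FALSE] -
                                X[mesh$edges[, 1], , drop = FALSE])
  structure(list(
    x_c = x_c, x_t = x_t, x_n = x_n,
    edges = mesh$edges, faces = mesh$faces, n_nodes = n,
    L0_c = eL(x_c), L0_t = eL(x_t), L0_n = eL(x_n),
    cort_L0 = row_norms(x_c - x_t),
    vol0_n = mesh_volume(x_n, mesh$faces),
    fa_n_b = integer(n), fa_seg = rep(NA_integer_, n),
    fa_tpar = numeric(n), fa_node = rep(NA_integer_, n),
    sf_t = integer(0), sf_n = integer(0), sf_L0 = numeric(0),
    polarization = unitize(polarization)
  ), class = "cell_body")
}

# signed volume of a closed triangulated surface
mesh_volume <- function(V, faces) {
  a <- V[faces[, 1], , drop = FALSE]
  b <- V[faces[, 2], , drop = FALSE]
  cc <- V[faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(a * cr) / 6)
}

# outward vertex normals (area-weighted face normals, normalized)
mesh_normals <- function(V, faces) {
  a <- V[faces[, 1], , drop = FALSE]
  b <- V[faces[, 2], , drop = FALSE]
  cc <- V[faces[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) N <- add_rows(N, faces[, k], fn)
  normalize_rows(N)
}

# edge-spring forces for one layer (compiled kernel)
.edge_spring_forces <- function(X, edges, L0, kappa) {
  .cpp_edge_springs(X, edges, L0, kappa)
}

# vectorized focal-adhesion cluster forces over all membrane nodes with FAs
.fa_forces <- function(cell, net, params, x_c) {
  F_c <- matrix(0, nrow(x_c), 3)
  F_net <- matrix(0, nrow(net$nodes), 3)
  ii <- which(cell$fa_n_b > 0)
  if (!length(ii)) return(list(F_c = F_c, F_net = F_net))
  segs <- cell$fa_seg[ii]
  a <- net$seg_a[segs]; b <- net$seg_b[segs]
  A <- net$nodes[a, , drop = FALSE]; B <- net$nodes[b, , drop = FALSE]
  X <- x_c[ii, , drop = FALSE]
  d <- B - A
  len2 <- pmax(rowSums(d * d), 1e-300)
  t <- clamp(rowSums((X - A) * d) / len2, 0, 1)
  foot <- A + d * t
  w <- foot - X
  L_b <- pmax(row_norms(w), 1e-12)
  n_R <- w / L_b
  f <- cell$fa_n_b[ii] * params$binding$kappa_LR *
    (L_b - params$binding$lambda)
  Fi <- n_R * f
  F_c <- add_rows(F_c, ii, Fi)
  F_net <- add_rows(F_net, a, -Fi * (1 - t))
  F_net <- add_rows(F_net, b, -Fi * t)
  list(F_c = F_c, F_net = F_net)
}

# nucleus volume-preservation penalty forces
.volume_forces <- function(V, faces, vol0, kappa) {
  vol <- mesh_volume(V, faces)
  coef <- -kappa * (vol - vol0) / vol0 / 6
  a <- V[faces[, 1], , drop = FALSE]
  b <- V[faces[, 2], , drop = FALSE]
  cc <- V[faces[, 3], , drop = FALSE]
  cr <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                             p[, 3] * q[, 1] - p[, 1] * q[, 3],
                             p[, 1] * q[, 2] - p[, 2] * q[, 1])
  F <- matrix(0, nrow(V), 3)
  F <- add_rows(F, faces[, 1], coef * cr(b, cc))
  F <- add_rows(F, faces[, 2], coef * cr(cc, a))
  add_rows(F, faces[, 3], coef * cr(a, b))
}

#' Cell membrane and cortex forces
#'
#' Assembles the force balance of the membrane (CC) and transduce (CT)
#' layers: focal-adhesion forces (stochastic Bell-bond clusters anchored to
#' nearby fibers; reactions applied to fiber nodes so each pair sums to
#' zero), membrane edge-spring elasticity, a constant-magnitude 300 pN
#' lamellipodium force on leading-edge nodes (outward normals within 60
#' degrees of the polarization axis), and cortical Kelvin-Voigt tension
#' pairs between the two layers.
#'
#' @param cell a `cell_body`.
#' @param net a `fiber_network` (FA anchors; may be `NULL` for an isolated
#'   cell).
#' @param params a `sim_params` object.
#' @param normals optional cached outward membrane normals.
#' @return list: `F_c`, `F_t` (n x 3 force matrices, pN), `F_net`
#'   (reactions on fiber nodes, n_net x 3 or NULL), `normals`.
#' @export
membrane_forces <- function(cell, net, params, normals = NULL) {
  cp <- params$cell
  F_c <- .edge_spring_forces(cell$x_c, cell$edges, cell$L0_c, cp$kappa_memb)
  F_t <- .edge_spring_forces(cell$x_t, cell$edges, cell$L0_t, cp$kappa_memb)
  # cortical tension pairs (spring part of the Kelvin-Voigt element; the
  # dashpot enters the mobility coupling of Eq-10 form)
  d <- cell$x_c - cell$x_t
  L <- pmax(row_norms(d), 1e-300)
  ten <- cp$kappa_cort * (L - cell$cort_L0)
  uhat <- d / L
  F_c <- F_c - uhat * ten
  F_t <- F_t + uhat * ten
  # lamellipodium force on leading-edge nodes
  if (is.null(normals)) normals <- mesh_normals(cell$x_c, cell$faces)
  lead <- which(normals %*% cell$polarization > cos(deg2rad(cp$leading_cone)))
  if (length(lead)) {
    F_c[lead, ] <- F_c[lead, ] + cp$F_L * normals[lead, , drop = FALSE]
  }
  # focal-adhesion cluster forces + reactions on fiber nodes
  F_net <- NULL
  if (!is.null(net)) {
    fa <- .fa_forces(cell, net, params, cell$x_c)
    F_c <- F_c + fa$F_c
    F_net <- fa$F_net
  }
  list(F_c = F_c, F_t = F_t, F_net = F_net, normals = normals)
}

#' Coupled membrane-cortex velocity solve
#'
#' The membrane (CC) and transduce (CT) overdamped equations are coupled by
#' the cortex drag `C_cort`; per node the 2x2 mobility system
#' \deqn{\begin{pmatrix}\dot x_c\\ \dot x_t\end{pmatrix} =
#'   \frac{1}{C_c C_t + C_{cort}(C_c + C_t)}
#'   \begin{pmatrix}C_t + C_{cort} & C_{cort}\\
#'                  C_{cort} & C_c + C_{cort}\end{pmatrix}
#'   \begin{pmatrix}F_c\\ F_t\end{pmatrix}}
#' is applied to the two force sums.  With `C_cort = 0` the rates decouple
#' to `F/C`.
#'
#' @param F_c,F_t force matrices for the two layers (pN).
#' @param params a `sim_params` object.
#' @return list of velocity matrices `v_c`, `v_t` (um/s).
#' @export
coupled_membrane_cortex_rates <- function(F_c, F_t, params) {
  cp <- params$cell
  det <- cp$C_c * cp$C_t + cp$C_cort * (cp$C_c + cp$C_t)
  list(
    v_c = ((cp$C_t + cp$C_cort) * F_c + cp$C_cort * F_t) / det,
    v_t = (cp$C_cort * F_c + (cp$C_c + cp$C_cort) * F_t) / det
  )
}

#' Nucleus and stress-fiber forces
#'
#' Nuclear-membrane elastic forces (edge springs plus a volume-preservation
#' penalty) and stress-fiber contractile forces.  Each stress fiber is a
#' single acto-myosin compartment linking a transduce node to a nucleus
#' node; its rest length shortens at twice the myosin sliding speed under
#' its current tension, and action-reaction holds exactly per fiber.
#'
#' @param cell a `cell_body`.
#' @param params a `sim_params` object.
#' @param dt time step for stress-fiber rest-length contraction (0 for a
#'   pure force query).
#' @return list: `F_t` (stress-fiber forces on transduce nodes), `F_n`
#'   (nucleus forces), updated `cell`.
#' @export
nucleus_sf_forces <- function(cell, params, dt = 0) {
  cp <- params$cell
  F_n <- .edge_spring_forces(cell$x_n, cell$edges, cell$L0_n, cp$kappa_memb)
  F_n <- F_n + .volume_forces(cell$x_n, cell$faces, cell$vol0_n, cp$kappa_vol)
  F_t <- matrix(0, cell$n_nodes, 3)
  if (length(cell$sf_t)) {
    d <- cell$x_n[cell$sf_n, , drop = FALSE] - cell$x_t[cell$sf_t, , drop = FALSE]
    L <- pmax(row_norms(d), 1e-300)
    kappa <- params$motor$E_AM * params$motor$A_AM / pmax(cell$sf_L0, 0.05)
    ten <- kappa * (L - cell$sf_L0)
    if (dt > 0) {
      v <- myosin_velocity(pmax(ten, 0), params)
      cell$sf_L0 <- pmax(cell$sf_L0 - 2 * v * dt, 0.05)
    }
    uhat <- d / L
    F_t <- add_rows(F_t, cell$sf_t, uhat * ten)
    F_n <- add_rows(F_n, cell$sf_n, -uhat * ten)
  }
  list(F_t = F_t, F_n = F_n, cell = cell)
}

#' @export
print.cell_body <- function(x, ...) {
  cat(sprintf(
    "<cell_body> %d nodes per layer, %d FAs (%d bonds), %d stress fibers\n",
    x$n_nodes, sum(x$fa_n_b > 0), sum(x$fa_n_b), length(x$sf_t)))
  cat(sprintf("  centroid (%.2f, %.2f, %.2f) um, polarization (%.2f, %.2f, %.2f)\n",
              mean(x$x_c[, 1]), mean(x$x_c[, 2]), mean(x$x_c[, 3]),
              x$polarization[1], x$polarization[2], x$polarization[3]))
  invisible(x)
}
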