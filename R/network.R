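#' Procedurally generate a cross-linked ECM fiber network
#'
#' Emulates a collagen gel as a graph of straight fibers joined at crosslink
#' nodes.  Crosslink seeds are laid on a jittered lattice at the target pore
#' spacing; candidate fibers are the k-nearest-neighbour edges between seeds
#' (radius-capped).  Each crosslink-to-crosslink line is divided into
#' `n_div` fiber segments plus two 30 nm crosslink segments carrying
#' `n_div + 1` fiber nodes.  Segment sets meeting at a crosslink are joined
#' coaxially into longer fibers when they continue within 60 degrees of
#' straight (closer to collinear than to folded); pairing among eligible
#' continuations is random.  At each crosslink node a fraction `p_f`
#' (rounded) of the incident fiber ends is crosslinked; un-crosslinked ends
#' dangle free.  Every fiber node carries a ligand pool
#' (`ligand_capacity` = 300 molecules) and the initial ECM concentration
#' `C_ECM0`; the local integrity `I_ECM = C_ECM / C_ECM0` drives
#' [apply_crosslink_degradation()].
#'
#' Networks are bit-reproducible: identical parameters and seed give
#' identical node lists and connectivity.
#'
#' @param params a `sim_params` object (only the `network`, `fiber` and `rd`
#'   groups are used) with a non-NULL seed.
#' @return an object of class `fiber_network`: node positions and types,
#'   segment table (endpoints, rest lengths, fiber/crosslink type, activity),
#'   bending triples with rest angles, fiber chains, the per-crosslink-node
#'   table (N_fs, N_0f, N_uf), ligand pools and ECM concentrations.
#' @examples
#' net <- build_network(sim_params(preset = "pore1.5",
#'                                 network.domain = c(6, 6, 6), seed = 1))
#' net
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(params$seed)) stop("a seed is required to build a network")
  nw <- params$network
  if (any(nw$domain < 3 * nw$pore_size)) {
    stop("domain extent must be at least 3 x pore_size in every direction")
  }
  rng <- rng_stream(params$seed, "network")
  pore <- nw$pore_size
  clen <- nw$crosslink_len

  ## crosslink seeds: jittered lattice at the target spacing
  ncell <- pmax(2L, as.integer(round(nw$domain / pore)))
  sp <- nw$domain / ncell
  gx <- (seq_len(ncell[1]) - 0.5) * sp[1]
  gy <- (seq_len(ncell[2]) - 0.5) * sp[2]
  gz <- (seq_len(ncell[3]) - 0.5) * sp[3]
  X <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(X) <- NULL
  ncl <- nrow(X)
  X <- X + with_rng(rng, matrix(runif(3 * ncl, -nw$jitter, nw$jitter), ncl, 3)) * pore
  X[, 1] <- clamp(X[, 1], 0, nw$domain[1])
  X[, 2] <- clamp(X[, 2], 0, nw$domain[2])
  X[, 3] <- clamp(X[, 3], 0, nw$domain[3])

  ## candidate edges: mutualized kNN within a radius cap
  edges <- .knn_edges(X, k = nw$knn, rmax = nw$max_edge_factor * pore)
  elen <- row_norms(X[edges[, 2], , drop = FALSE] - X[edges[, 1], , drop = FALSE])
  keep <- elen > 2 * clen + 1e-6
  edges <- edges[keep, , drop = FALSE]
  elen <- elen[keep]
  ne <- nrow(edges)
  ndiv <- nw$n_div
  nfn <- ndiv + 1L                     # fiber nodes per edge

  ## fiber nodes along each edge: crosslink segment, n_div fiber segments,
  ## crosslink segment
  ea <- X[edges[, 1], , drop = FALSE]
  u <- (X[edges[, 2], , drop = FALSE] - ea) / elen
  step <- (elen - 2 * clen) / ndiv
  fpos <- matrix(0, ne * nfn, 3)
  for (j in seq_len(nfn)) {
    fpos[seq_len(ne) + (j - 1L) * ne, ] <- ea + u * (clen + (j - 1L) * step)
  }
  fid <- function(e, j) ncl + (j - 1L) * ne + e   # fiber-node index
  nodes <- rbind(X, fpos)
  node_type <- c(rep(1L, ncl), rep(2L, ne * nfn))

  ## segments: 2 crosslink + n_div fiber per edge
  e_all <- seq_len(ne)
  cs_a <- cbind(edges[, 1], fid(e_all, 1L))            # crosslink seg, a-end
  cs_b <- cbind(fid(e_all, nfn), edges[, 2])           # crosslink seg, b-end
  fs_a <- fs_b <- NULL
  for (j in seq_len(ndiv)) {
    fs_a <- c(fs_a, fid(e_all, j))
    fs_b <- c(fs_b, fid(e_all, j + 1L))
  }
  seg_a <- c(cs_a[, 1], cs_b[, 1], fs_a)
  seg_b <- c(cs_a[, 2], cs_b[, 2], fs_b)
  seg_type <- c(rep(2L, 2L * ne), rep(1L, ndiv * ne))
  seg_L0 <- c(rep(clen, 2L * ne), rep(step, ndiv))
  cross_seg_node <- c(edges[, 1], edges[, 2], rep(NA_integer_, ndiv * ne))
  cs_idx <- cbind(e_all, e_all + ne)   # crosslink segment id per (edge, end)

  ## crosslinking: each node links round(p_f * N_fs) of its incident ends
  inc_node <- c(edges[, 1], edges[, 2])        # node of each edge-end
  inc_seg <- c(cs_idx[, 1], cs_idx[, 2])       # its crosslink segment
  n_fs <- tabulate(inc_node, nbins = ncl)
  seg_active <- rep(TRUE, length(seg_a))
  by_node <- split(inc_seg, inc_node)
  n_0f <- integer(ncl)
  with_rng(rng, {
    for (nm in names(by_node)) {
      k <- as.integer(nm)
      segs <- by_node[[nm]]
      m <- round_half_up(nw$p_f * length(segs))
      n_0f[k] <- m
      if (m < length(segs)) {
        off <- sample(segs, length(segs) - m)
        seg_active[off] <- FALSE
      }
    }
  })

  ## coaxial joining: ends continuing within 60 deg of straight may merge
  ## into one fiber; pairing is random among eligible pairs
  join <- .coaxial_joins(X, edges, rng)

  ## assemble chains (ordered node paths) and bending triples
  asm <- .assemble_chains(edges, join, fid, nfn, ndiv, ne, ncl)
  chains <- asm$chains
  seg_fiber <- integer(length(seg_a))
  seg_fiber[2L * ne + seq_len(ndiv * ne)] <-
    asm$edge_chain[rep(e_all, ndiv)]
  bends <- .bending_triples(nodes, chains, seg_a, seg_b)

  lig_cap <- ifelse(node_type == 2L, nw$ligand_capacity, 0)
  storage.mode(seg_a) <- "integer"
  storage.mode(seg_b) <- "integer"
  storage.mode(cross_seg_node) <- "integer"
  for (nm in c("a", "b", "c", "s1", "s2")) storage.mode(bends[[nm]]) <- "integer"
  net <- structure(list(
    nodes = nodes, node_type = node_type,
    seg_a = seg_a, seg_b = seg_b, seg_L0 = seg_L0,
    seg_type = seg_type, seg_fiber = seg_fiber, seg_active = seg_active,
    cross_seg_node = cross_seg_node,
    edge_a = edges[, 1], edge_b = edges[, 2], cs_idx = cs_idx,
    chains = chains,
    bend_a = bends$a, bend_b = bends$b, bend_c = bends$c,
    bend_theta0 = bends$theta0, bend_L0 = bends$L0,
    bend_seg1 = bends$s1, bend_seg2 = bends$s2,
    n_crosslink = ncl,
    cross_n_fs = n_fs, cross_n_0f = n_0f, cross_n_uf = integer(ncl),
    ligand_cap = lig_cap, ligand_bound = numeric(length(lig_cap)),
    C_ecm = rep(params$rd$C_ecm0, nrow(nodes)),
    C_ecm0 = params$rd$C_ecm0,
    domain = nw$domain, pore_size = pore,
    fiber_diameter = nw$fiber_diameter, seed = params$seed
  ), class = "fiber_network")
  net
}

# mutualized k-nearest-neighbour edges with a radius cap, via a cell list
.knn_edges <- function(X, k, rmax) {
  n <- nrow(X)
  cell <- rmax
  lo <- apply(X, 2, min) - 1e-9
  key <- floor(sweep(X, 2, lo) / cell)
  dims <- apply(key, 2, max) + 1L
  lin <- key[, 1] + dims[1] * (key[, 2] + dims[2] * key[, 3]) + 1
  buckets <- vector("list", prod(dims))
  grp <- split(seq_len(n), lin)
  buckets[as.integer(names(grp))] <- grp
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_a <- integer(0); out_b <- integer(0)
  keymat <- key
  for (i in seq_len(n)) {
    kk <- sweep(offs, 2, keymat[i, ], "+")
    ok <- kk[, 1] >= 0 & kk[, 1] < dims[1] & kk[, 2] >= 0 & kk[, 2] < dims[2] &
      kk[, 3] >= 0 & kk[, 3] < dims[3]
    linq <- kk[ok, 1] + dims[1] * (kk[ok, 2] + dims[2] * kk[ok, 3]) + 1
    cand <- unlist(buckets[linq], use.names = FALSE)
    cand <- cand[cand != i]
    if (!length(cand)) next
    d <- row_norms(sweep(X[cand, , drop = FALSE], 2, X[i, ], "-"))
    sel <- cand[d <= rmax]
    d <- d[d <= rmax]
    if (length(sel) > k) {
      o <- order(d)[seq_len(k)]
      sel <- sel[o]
    }
    out_a <- c(out_a, rep.int(i, length(sel)))
    out_b <- c(out_b, sel)
  }
  a <- pmin(out_a, out_b); b <- pmax(out_a, out_b)
  e <- unique(cbind(a, b))
  dimnames(e) <- NULL
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# For each crosslink node: eligible continuation pairs of incident edge-ends
# (away-pointing directions at an angle above 120 deg, i.e. the interior
# bend deviates less than 60 deg from straight); accept pairs in random
# order, each end used at most once.  Returns a 4-column matrix
# (node, edge1, edge2, endcode1*2+endcode2) of accepted joins.
.coaxial_joins <- function(X, edges, rng) {
  ne <- nrow(edges)
  inc_node <- c(edges[, 1], edges[, 2])
  inc_edge <- c(seq_len(ne), seq_len(ne))
  inc_end <- c(rep(1L, ne), rep(2L, ne))   # 1 = a-end, 2 = b-end
  dir <- rbind(
    X[edges[, 2], , drop = FALSE] - X[edges[, 1], , drop = FALSE],
    X[edges[, 1], , drop = FALSE] - X[edges[, 2], , drop = FALSE]
  )
  dir <- normalize_rows(dir)               # away-pointing at the end's node
  by_node <- split(seq_along(inc_node), inc_node)
  joins <- matrix(integer(0), 0, 4)
  with_rng(rng, {
    for (nm in names(by_node)) {
      ids <- by_node[[nm]]
      if (length(ids) < 2) next
      d <- dir[ids, , drop = FALSE]
      cosm <- d %*% t(d)
      pr <- which(upper.tri(cosm) & cosm < -0.5, arr.ind = TRUE)  # > 120 deg
      if (!nrow(pr)) next
      pr <- pr[sample.int(nrow(pr)), , drop = FALSE]
      used <- logical(length(ids))
      for (r in seq_len(nrow(pr))) {
        i <- pr[r, 1]; j <- pr[r, 2]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        joins <- rbind(joins, c(as.integer(nm),
                                inc_edge[ids[i]], inc_edge[ids[j]],
                                inc_end[ids[i]] * 10L + inc_end[ids[j]]))
      }
    }
  })
  joins
}

# Walk edges through coaxial joins into ordered chains (node paths through
# interior crosslink nodes); returns chains and the chain id of each edge.
.assemble_chains <- function(edges, join, fid, nfn, ndiv, ne, ncl) {
  # continuation map: key (edge, end) -> c(other edge, its end, join node)
  cont <- vector("list", 2L * ne)
  ckey <- function(e, end) (end - 1L) * ne + e
  if (nrow(join)) {
    for (r in seq_len(nrow(join))) {
      e1 <- join[r, 2]; e2 <- join[r, 3]
      end1 <- join[r, 4] %/% 10L; end2 <- join[r, 4] %% 10L
      cont[[ckey(e1, end1)]] <- c(e2, end2, join[r, 1])
      cont[[ckey(e2, end2)]] <- c(e1, end1, join[r, 1])
    }
  }
  edge_nodes <- function(e, from_end) {
    # fiber-node path of edge e entering from `from_end`
    js <- seq_len(nfn)
    if (from_end == 2L) js <- rev(js)
    fid(rep.int(e, nfn), js)
  }
  edge_chain <- integer(ne)
  chains <- list()
  for (e0 in seq_len(ne)) {
    if (edge_chain[e0]) next
    cid <- length(chains) + 1L
    # walk backwards to the chain start (guard cycles)
    e <- e0; end <- 1L; guard <- 0L
    repeat {
      prv <- cont[[ckey(e, end)]]
      if (is.null(prv) || edge_chain[prv[1]] || prv[1] == e0 && guard > 0L) break
      guard <- guard + 1L
      e <- prv[1]; end <- prv[2]
      end <- if (end == 1L) 2L else 1L   # enter from the other side
      if (guard > ne) break
    }
    # walk forward collecting nodes
    path <- integer(0)
    enter <- if (end == 1L) 1L else 2L
    repeat {
      edge_chain[e] <- cid
      path <- c(path, edge_nodes(e, enter))
      nxt_end <- if (enter == 1L) 2L else 1L
      nxt <- cont[[ckey(e, nxt_end)]]
      if (is.null(nxt) || edge_chain[nxt[1]]) break
      path <- c(path, nxt[3])            # interior crosslink node
      e <- nxt[1]
      enter <- nxt[2]
    }
    chains[[cid]] <- path
  }
  list(chains = chains, edge_chain = edge_chain)
}

# Bending triples along each chain path; rest angles from built geometry.
.bending_triples <- function(nodes, chains, seg_a, seg_b) {
  segkey <- paste(pmin(seg_a, seg_b), pmax(seg_a, seg_b))
  seg_of <- seq_along(seg_a)
  names(seg_of) <- segkey
  a <- b <- cc <- s1 <- s2 <- integer(0)
  for (path in chains) {
    n <- length(path)
    if (n < 3) next
    ia <- path[1:(n - 2)]; ib <- path[2:(n - 1)]; ic <- path[3:n]
    k1 <- paste(pmin(ia, ib), pmax(ia, ib))
    k2 <- paste(pmin(ib, ic), pmax(ib, ic))
    a <- c(a, ia); b <- c(b, ib); cc <- c(cc, ic)
    s1 <- c(s1, unname(seg_of[k1])); s2 <- c(s2, unname(seg_of[k2]))
  }
  if (!length(a)) {
    return(list(a = integer(0), b = integer(0), c = integer(0),
                theta0 = numeric(0), L0 = numeric(0),
                s1 = integer(0), s2 = integer(0)))
  }
  t1 <- normalize_rows(nodes[b, , drop = FALSE] - nodes[a, , drop = FALSE])
  t2 <- normalize_rows(nodes[cc, , drop = FALSE] - nodes[b, , drop = FALSE])
  theta0 <- acos(clamp(rowSums(t1 * t2), -1, 1))
  L1 <- row_norms(nodes[b, , drop = FALSE] - nodes[a, , drop = FALSE])
  L2 <- row_norms(nodes[cc, , drop = FALSE] - nodes[b, , drop = FALSE])
  list(a = a, b = b, c = cc, theta0 = theta0, L0 = (L1 + L2) / 2,
       s1 = s1, s2 = s2)
}

#' Mean nearest-crosslink spacing of a network
#'
#' The measured pore size: mean over crosslink nodes of the distance to the
#' nearest other crosslink node.
#'
#' @param net a `fiber_network`.
#' @return length in um.
#' @export
measure_pore_size <- function(net) {
  X <- net$nodes[seq_len(net$n_crosslink), , drop = FALSE]
  n <- nrow(X)
  nn <- numeric(n)
  # cell list at pore-size scale keeps this O(n)
  cell <- net$pore_size * 1.6
  lo <- apply(X, 2, min) - 1e-9
  key <- floor(sweep(X, 2, lo) / cell)
  dims <- apply(key, 2, max) + 1L
  lin <- key[, 1] + dims[1] * (key[, 2] + dims[2] * key[, 3]) + 1
  buckets <- vector("list", prod(dims))
  grp <- split(seq_len(n), lin)
  buckets[as.integer(names(grp))] <- grp
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(n)) {
    kk <- sweep(offs, 2, key[i, ], "+")
    ok <- kk[, 1] >= 0 & kk[, 1] < dims[1] & kk[, 2] >= 0 & kk[, 2] < dims[2] &
      kk[, 3] >= 0 & kk[, 3] < dims[3]
    linq <- kk[ok, 1] + dims[1] * (kk[ok, 2] + dims[2] * kk[ok, 3]) + 1
    cand <- unlist(buckets[linq], use.names = FALSE)
    cand <- cand[cand != i]
    if (!length(cand)) { nn[i] <- NA; next }
    nn[i] <- min(row_norms(sweep(X[cand, , drop = FALSE], 2, X[i, ], "-")))
  }
  mean(nn, na.rm = TRUE)
}

#' ECM integrity at each node
#'
#' @param net a `fiber_network`.
#' @return `C_ECM / C_ECM0` per node, in `[0, 1]`.
#' @export
ecm_integrity <- function(net) clamp(net$C_ecm / net$C_ecm0, 0, 1)

#' Apply proteolytic crosslink degradation
#'
#' At each crosslink node k the number of uncrosslinked (degraded) fiber
#' ends is driven to `N_uf = round((1 - I_ECM,k) * N_0f)` (round-half-up),
#' where `I_ECM,k` is the local ECM integrity and `N_0f` the initial
#' crosslinked count.  Newly detached ends are chosen uniformly at random
#' among the still-crosslinked ones; detachment removes the 30 nm
#' crosslink-segment coupling (the fiber persists as a free chain) and is
#' monotone: crosslinks never re-form.
#'
#' @param net a `fiber_network` with current `C_ecm` (see
#'   [update_ecm_integrity()]).
#' @param rng an [rng_stream()] for the detachment choice.
#' @return the updated network.
#' @export
apply_crosslink_degradation <- function(net, rng) {
  I <- net$C_ecm[seq_len(net$n_crosslink)] / net$C_ecm0
  if (any(I < -1e-9 | I > 1 + 1e-9)) {
    stop("ECM integrity outside [0, 1]")
  }
  I <- clamp(I, 0, 1)
  target <- round_half_up((1 - I) * net$cross_n_0f)
  need <- target - net$cross_n_uf
  todo <- which(need > 0)
  if (!length(todo)) return(net)
  is_cross <- net$seg_type == 2L
  with_rng(rng, {
    for (k in todo) {
      cand <- which(is_cross & net$seg_active &
                      !is.na(net$cross_seg_node) & net$cross_seg_node == k)
      m <- min(need[k], length(cand))
      if (m <= 0) next
      off <- if (length(cand) == 1L) cand else sample(cand, m)
      net$seg_active[off] <- FALSE
      net$cross_n_uf[k] <- net$cross_n_uf[k] + m
    }
  })
  net
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf(
    "<fiber_network> %d nodes (%d crosslink, %d fiber), %d segments, %d chains\n",
    nrow(x$nodes), x$n_crosslink, nrow(x$nodes) - x$n_crosslink,
    length(x$seg_a), length(x$chains)))
  cat(sprintf("  domain %s um, target pore %.2g um, measured %.3g um\n",
              paste(x$domain, collapse = "x"), x$pore_size,
              measure_pore_size(x)))
  cat(sprintf("  fiber diameter %g nm, crosslinked ends %d/%d (detached %d)\n",
              x$fiber_diameter, sum(x$cross_n_0f) - sum(x$cross_n_uf),
              sum(x$cross_n_fs), sum(x$cross_n_uf)))
  invisible(x)
}
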