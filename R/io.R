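# Result serialization, fixtures and visualization export shared by all
# modules.

#' Write simulation outputs with a manifest
#'
#' Serializes a result bundle to a directory: per-replicate event logs and
#' centroid tracks as CSV, the configuration as YAML, a summary JSON, the
#' network as VTK when present, and a manifest recording the configuration
#' hash, seed and package version.  Reruns with the same configuration and
#' seed produce byte-identical CSVs.
#'
#' @param bundle an `invasion_run`, or a list with optional elements
#'   `logs`, `centroids`, `summary`, `network`, `params`.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  written <- character(0)
  wr <- function(fname) {
    written <<- c(written, fname)
    file.path(dir, fname)
  }
  if (!is.null(bundle$logs)) {
    for (r in seq_along(bundle$logs)) {
      utils::write.csv(bundle$logs[[r]],
                       wr(sprintf("events_rep%02d.csv", r)),
                       row.names = FALSE)
    }
  }
  if (!is.null(bundle$centroids)) {
    for (r in seq_along(bundle$centroids)) {
      if (is.null(bundle$centroids[[r]])) next
      utils::write.csv(bundle$centroids[[r]],
                       wr(sprintf("centroid_rep%02d.csv", r)),
                       row.names = FALSE)
    }
  }
  if (!is.null(bundle$summary)) {
    utils::write.csv(bundle$summary, wr("summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(mean_tip = bundle$mean_tip, sem_tip = bundle$sem_tip,
           mean_root = bundle$mean_root, sem_root = bundle$sem_root),
      wr("summary.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$network)) {
    write_network_vtk(bundle$network, wr("network.vtk"))
  }
  if (!is.null(bundle$params)) {
    write_config(bundle$params, wr("config.yaml"))
  }
  manifest <- list(
    package = "ecmigrate",
    version = as.character(utils::packageVersion("ecmigrate")),
    seed = if (!is.null(bundle$params)) bundle$params$seed else NA,
    config_hash = if (!is.null(bundle$params)) config_hash(bundle$params) else NA,
    files = written
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export a fiber network as legacy-VTK polylines
#'
#' Writes an ASCII VTK file with fibers as line cells and per-point data
#' (node type, ECM integrity) for visualization in ParaView.
#'
#' @param net a `fiber_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_vtk <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(net$nodes)
  act <- which(net$seg_active)
  writeLines(c("# vtk DataFile Version 3.0",
               "ecmigrate fiber network", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  utils::write.table(format(net$nodes, scientific = TRUE, digits = 7),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("LINES %d %d", length(act), 3 * length(act)), con)
  utils::write.table(cbind(2L, net$seg_a[act] - 1L, net$seg_b[act] - 1L),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS integrity float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(ecm_integrity(net), digits = 6), con)
  writeLines(c("SCALARS node_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(net$node_type), con)
  invisible(path)
}

#' Canned deterministic test scenes
#'
#' Tiny fixtures used throughout the test suite and handy for interactive
#' exploration; every fixture builds in well under a second and is fully
#' deterministic given the seed in `params`.
#'
#' \describe{
#'   \item{"single-segment"}{a two-node fiber at rest.}
#'   \item{"triangle"}{three fibers forming a triangle of crosslinks.}
#'   \item{"lattice-5um"}{a 5x5x5 um network at the 1 um pore preset
#'     (~125 crosslinks).}
#'   \item{"one-filopodium-one-fiber"}{a `sim_state` with one filopodium
#'     whose tip sits 50 nm from a tethered fiber.}
#' }
#'
#' @param name fixture name.
#' @param params a `sim_params`; defaults to `sim_params(seed = 1)`.
#' @return a `fiber_network` or `sim_state` depending on the fixture.
#' @export
make_fixture <- function(name, params = sim_params(seed = 1)) {
  switch(
    name,
    "single-segment" = .minimal_network(rbind(c(0, 0, 0), c(1, 0, 0)), params),
    "triangle" = {
      p <- params
      pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.8, 0))
      net <- .minimal_network(pts[1:2, ], p)
      # extend the two-node fixture into a closed triangle by hand
      net$nodes <- pts
      net$node_type <- rep(2L, 3)
      net$seg_a <- c(1L, 2L, 3L)
      net$seg_b <- c(2L, 3L, 1L)
      net$seg_L0 <- row_norms(net$nodes[net$seg_b, ] - net$nodes[net$seg_a, ])
      net$seg_type <- rep(1L, 3)
      net$seg_fiber <- 1:3
      net$seg_active <- rep(TRUE, 3)
      net$cross_seg_node <- rep(NA_integer_, 3)
      net$chains <- list(1L:2L, 2L:3L, c(3L, 1L))
      net$ligand_cap <- rep(params$network$ligand_capacity, 3)
      net$ligand_bound <- numeric(3)
      net$C_ecm <- rep(params$rd$C_ecm0, 3)
      net
    },
    "lattice-5um" = {
      p <- sim_params(preset = "pore1.0", seed = params$seed,
                      network.domain = c(5, 5, 5))
      build_network(p)
    },
    "one-filopodium-one-fiber" =
      single_filopodium_scene(params, anchor_stiffness = 1e4),
    stop("unknown fixture name: ", name)
  )
}
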