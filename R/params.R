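#' Simulation parameter set
#'
#' Builds the full nested parameter list used by every module, with defaults
#' for an endothelial cell invading a cross-linked collagen network.  Values
#' are stored in the package unit system (lengths um, forces pN, time s,
#' stiffness pN/um, drag pN s/um, pressure pN/um^2, concentrations M).
#'
#' Three network presets couple pore size, fiber diameter and segmentation:
#' `"pore0.5"` (pore 0.5 um, diameter 28 nm, n_div 1), `"pore1.0"`
#' (1.0 um, 34 nm, 2) and `"pore1.5"` (1.5 um, 41 nm, 3).  These mimic
#' collagen gels polymerized at pH 9, 7 and 5 respectively: higher pH gives
#' thinner fibers and smaller pores.
#'
#' Parameter groups:
#' \describe{
#'   \item{network}{pore size (um), fiber diameter (nm), segments per fiber
#'     `n_div`, 30 nm crosslink-segment length, initial crosslinking ratio
#'     `p_f` = 0.7, ligand capacity 300 molecules per fiber node, domain
#'     extent (um).}
#'   \item{fiber}{Young's modulus `E_f` (default 1 MPa = 1e6 pN/um^2), drag
#'     `C_e`, optional bending-modulus override `kappa_b`.}
#'   \item{motor}{unloaded myosin sliding speed `v_m0` = 10 nm/s, stall
#'     force 1 nN, shape factor `c_m` = 0.1, acto-myosin modulus
#'     `E_AM` = 230 kPa and cross-section `A_AM` = 7.07e-2 um^2.}
#'   \item{binding}{ligand-receptor spring 1 pN/nm, rest length 30 nm,
#'     forward rate `k_f` = 1 /molecule/s, unstressed off-rate 1 /s, Bell
#'     length `x_b` = 0.02 nm, thermal energy at 310 K, 100 nm contact
#'     gate.}
#'   \item{filopodium}{8 AM compartments, length limits 2 and 4.5 um,
#'     protrusion force cap 2 nN, polymerization speed, phase time budgets,
#'     contractile tension gate (3 nN/um x 0.3 um diameter = 0.9 nN).}
#'   \item{cell}{triple icosphere membranes, membrane/cortex stiffnesses,
#'     FA bond cap 100 per node, lamellipodium force 300 pN, 60 deg
#'     leading-edge cone.}
#'   \item{rd}{diffusivities, decay/association/secretion constants of the
#'     seven-species proteolysis network, grid spacing, initial ECM
#'     concentration 10 uM.}
#'   \item{engine}{ODE tolerance 1e-4, time-step clamp [1e-3, 1e-2] s,
#'     15 um active-domain radius refreshed every 10 s, contact stiffness.}
#' }
#'
#' @param preset optional preset name (`"pore0.5"`, `"pore1.0"`,
#'   `"pore1.5"`) binding pore size, fiber diameter and `n_div`.
#' @param seed integer root seed; required for any stochastic operation.
#' @param ... named overrides as `group.name = value`, e.g.
#'   `network.pore_size = 1.5` or nested lists per group.
#' @return an object of class `sim_params` (nested named list).
#' @examples
#' p <- sim_params(preset = "pore1.5", seed = 1)
#' p$network$fiber_diameter  # 41 nm
#' @export
sim_params <- function(preset = NULL, seed = NULL, ...) {
  p <- list(
    network = list(
      pore_size = 1.0,          # um, target mean nearest-crosslink spacing
      fiber_diameter = 34,      # nm
      n_div = 2,                # fiber segments per crosslink-to-crosslink line
      crosslink_len = 0.03,     # um, 30 nm crosslink segments
      p_f = 0.7,                # initial crosslinking ratio per incident fiber
      ligand_capacity = 300,    # molecules per fiber node (A_L * C_L)
      domain = c(10, 10, 10),   # um
      jitter = 0.1,             # lattice jitter as a fraction of pore size
      knn = 4,                  # candidate edges per crosslink seed
      max_edge_factor = 1.8     # drop candidate edges longer than this x pore
    ),
    fiber = list(
      E_f = 1e6,                # pN/um^2 (1 MPa)
      C_e = 1000,               # pN s/um (0.001 N s/m)
      kappa_b = NULL            # pN um^2; NULL = E_f * pi r^4 / 4
    ),
    motor = list(
      v_m0 = 0.01,              # um/s (10 nm/s unloaded sliding speed)
      F_stall = 1000,           # pN
      c_m = 0.1,                # dimensionless force-velocity shape factor
      E_AM = 2.3e5,             # pN/um^2 (230 kPa)
      A_AM = 7.07e-2            # um^2
    ),
    binding = list(
      kappa_LR = 1000,          # pN/um (1 pN/nm) ligand-receptor spring
      lambda = 0.03,            # um, unstressed bond length (30 nm)
      k_f = 1,                  # /molecule/s forward rate
      k_off0 = 1,               # /s unstressed dissociation rate
      x_b = 2e-5,               # um (0.02 nm) Bell transition-state distance
      temperature = 310,        # K
      contact_range = 0.1,      # um, 100 nm focal-complex formation gate
      receptor_capacity = 300   # integrins available at one focal-complex site
    ),
    filopodium = list(
      n_am = 8,                 # acto-myosin compartments per filopodium
      L_max = 4.5,              # um, outgrowing length cap
      L_min = 2.0,              # um, retractile length floor
      L_init = 2.1,             # um, length at nucleation
      diameter = 0.3,           # um
      F_P_max = 2000,           # pN protrusion force cap
      v_poly = 0.05,            # um/s polymerization-limited outgrowth speed
      C_f = 1000,               # pN s/um node drag
      outgrow_timeout = 60,     # s without an FC before retraction
      tugging_dwell = 60,       # s in tugging before giving up
      tugging_min = 5,          # s of FC maturation before the contractile gate
      contractile_threshold_per_um = 3000, # pN/um (3 nN/um)
      polarity_max_angle = 45,  # deg, nucleation cone about polarization
      max_filopodia = 6,
      nucleation_rate = 0.2     # attempts /s when below max_filopodia
    ),
    cell = list(
      n_subdiv = 3,             # icosphere refinement: 12/42/162/642 nodes
      radius = 7.5,             # um cell membrane radius
      nucleus_radius = 3.0,     # um
      transduce_frac = 0.92,    # transduce layer radius / membrane radius
      kappa_memb = 50,          # pN/um (5e-5 N/m) membrane edge springs
      kappa_cort = 8000,        # pN/um (8e-3 N/m) cortex Kelvin-Voigt spring
      C_cort = 6000,            # pN s/um (0.006 N s/m) cortex drag
      C_c = 1000, C_t = 1000, C_n = 1000, # pN s/um layer drags
      fa_cap = 100,             # max clustered integrins per membrane node
      fa_koff_scale = 0.2,      # FA turnover slower than FC (> 5 min vs < 5 min)
      fa_maturity = 30,         # bonds before a stress fiber nucleates
      F_L = 300,                # pN lamellipodium force on leading-edge nodes
      leading_cone = 60,        # deg about the polarization axis
      sf_max = 40,              # stress-fiber cap
      kappa_vol = 5e3,          # pN/um^2 nucleus volume-preservation penalty
      polarization_memory = 0.99 # EMA factor for the polarization axis
    ),
    rd = list(
      spacing = 1.0,            # um Cartesian grid spacing
      D_vegf = 68.8,            # um^2/s
      D_mmp2 = 68.8,
      D_timp2 = 1.29,
      D_ligand = 1e-3,
      k_vegf_decay = 8.2e-6,    # /s
      k_mmp2_decay = 1.7e-3,
      k_ligand_decay = 1e-4,
      k_ecm_deg = 1.04e6,       # /M/s
      kon_timp2_mmp2 = 5e5,     # /M/s
      kon_complex_mt1 = 1.95e4, # /M/s (activated MMP-2 release)
      kon_timp2_mt1 = 2.74e6,   # /M/s
      koff_complex = 2e-4,      # /s
      alpha_timp2 = 1e-3,       # M/s secretion at filopodial roots
      alpha_mt1 = 1e-1,         # M/s
      C_ecm0 = 1e-5,            # M (10 uM initial ECM concentration)
      C_ligand0 = 1e-5,         # M initial soluble ligand
      vegf_far = 1.31e-9,       # M fixed VEGF on the far +x face (50 ng/ml)
      C_max = 2e-7,             # M cap on the protease species (see vignette)
      secretion_model = "ligand_scaled", # or "constant" (see vignette)
      interval = 0.5,           # s between reaction-diffusion updates
      degradation = TRUE        # FALSE models an MT1-MMP-deficient cell
    ),
    engine = list(
      ode_tol = 1e-4,
      dt_min = 1e-3, dt_max = 1e-2,   # s
      active_radius = 15,       # um about cell centroid and filopodial tips
      active_refresh = 10,      # s
      contact_stiffness = 2e4,  # pN/um elastic repulsion
      contact_pad = 0.15,       # um surface pad for filopodial shafts
      contact_pad_cell = 0.05,  # um membrane pad (inside the 100 nm FA gate)
      fa_interval = 0.1,        # s cadence of cell-side adhesion events
      search_interval = 0.1,    # s cadence of new-anchor searches
      snapshot = 1,             # s trajectory sampling cadence
      total_time = 600          # s
    ),
    seed = seed,
    preset = if (is.null(preset)) NA_character_ else preset
  )
  if (!is.null(preset)) {
    pp <- .network_presets()[[preset]]
    if (is.null(pp)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(.network_presets()), collapse = ", "))
    }
    p$network[names(pp)] <- pp
  }
  p <- .apply_overrides(p, list(...))
  class(p) <- "sim_params"
  validate_params(p)
  p
}

.network_presets <- function() {
  list(
    "pore0.5" = list(pore_size = 0.5, fiber_diameter = 28, n_div = 1),
    "pore1.0" = list(pore_size = 1.0, fiber_diameter = 34, n_div = 2),
    "pore1.5" = list(pore_size = 1.5, fiber_diameter = 41, n_div = 3)
  )
}

.apply_overrides <- function(p, dots) {
  for (nm in names(dots)) {
    val <- dots[[nm]]
    if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L || is.null(p[[parts[1]]]) ||
          !(parts[2] %in% names(p[[parts[1]]]))) {
        stop("unknown parameter '", nm, "'")
      }
      p[[parts[1]]][[parts[2]]] <- val
    } else if (nm %in% c("seed", "preset")) {
      p[[nm]] <- val
    } else if (nm %in% names(p) && is.list(val)) {
      bad <- setdiff(names(val), names(p[[nm]]))
      if (length(bad)) stop("unknown parameter '", nm, ".", bad[1], "'")
      p[[nm]][names(val)] <- val
    } else {
      stop("unknown parameter '", nm, "'")
    }
  }
  p
}

#' Validate a parameter set
#'
#' Checks positivity, range and consistency invariants; called by
#' [sim_params()] and [load_config()].
#'
#' @param p a `sim_params` object.
#' @return `p`, invisibly; errors describe the offending field.
#' @export
validate_params <- function(p) {
  nw <- p$network
  stopifnot(
    "pore_size must exceed twice the crosslink-segment length" =
      nw$pore_size > 2 * nw$crosslink_len,
    "n_div must be a positive integer" = nw$n_div >= 1,
    "p_f must lie in [0,1]" = nw$p_f >= 0 && nw$p_f <= 1,
    "ligand_capacity must be positive" = nw$ligand_capacity > 0,
    "domain must have 3 positive extents" =
      length(nw$domain) == 3 && all(nw$domain > 0)
  )
  stopifnot(
    p$fiber$E_f > 0, p$fiber$C_e > 0,
    p$motor$v_m0 > 0, p$motor$F_stall > 0, p$motor$c_m > 0,
    p$binding$kappa_LR > 0, p$binding$lambda > 0, p$binding$x_b > 0,
    p$binding$k_f > 0, p$binding$k_off0 > 0,
    p$filopodium$L_min < p$filopodium$L_max,
    p$engine$dt_min <= p$engine$dt_max, p$engine$ode_tol > 0
  )
  invisible(p)
}

# thermal energy k_b T in pN um
thermal_energy <- function(p) 1.380649e-5 * p$binding$temperature

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>",
      if (!is.na(x$preset)) paste0(" preset=", x$preset) else "",
      "\n", sep = "")
  cat(sprintf("  network: pore %.2g um, fiber %g nm, n_div %d, p_f %.2g, domain %s um\n",
              x$network$pore_size, x$network$fiber_diameter, x$network$n_div,
              x$network$p_f, paste(x$network$domain, collapse = "x")))
  cat(sprintf("  fiber:   E_f %.3g MPa, kappa_s %.3g nN, kappa_b %.3g pN um^2\n",
              x$fiber$E_f / 1e6, fiber_material(x)$kappa_s / 1000,
              fiber_material(x)$kappa_b))
  cat(sprintf("  motor:   v_m0 %g nm/s, F_stall %g nN, c_m %g\n",
              x$motor$v_m0 * 1000, x$motor$F_stall / 1000, x$motor$c_m))
  cat(sprintf("  engine:  dt [%g, %g] s, tol %g, seed %s\n",
              x$engine$dt_min, x$engine$dt_max, x$engine$ode_tol,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

## ---- config file round-trip -----------------------------------------------

#' Load a simulation configuration file
#'
#' Reads a YAML configuration, overlays it on the package defaults (an empty
#' file yields the full default set), rejects unknown keys by name, and
#' validates the result.  A `seed` must be present either in the file or as
#' an argument.
#'
#' @param path path to a YAML file.
#' @param seed optional seed overriding the file.
#' @return a `sim_params` object.
#' @export
load_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  preset <- raw$preset
  raw$preset <- NULL
  file_seed <- raw$seed
  raw$seed <- NULL
  p <- sim_params(preset = preset,
                  seed = if (!is.null(seed)) seed else file_seed)
  defaults <- unclass(p)
  for (grp in names(raw)) {
    if (!grp %in% names(defaults) || !is.list(defaults[[grp]])) {
      stop("unknown configuration group '", grp, "'")
    }
    bad <- setdiff(names(raw[[grp]]), names(defaults[[grp]]))
    if (length(bad)) {
      stop("unknown configuration key '", grp, ".", bad[1], "'")
    }
    defaults[[grp]][names(raw[[grp]])] <- raw[[grp]]
  }
  if (is.null(defaults$seed)) {
    stop("configuration must supply a seed (determinism is required)")
  }
  p <- defaults
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' Write a configuration file
#'
#' Serializes a parameter set to YAML such that
#' `load_config(write_config(p, f))` reproduces `p`.
#'
#' @param p a `sim_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "sim_params"))
  out <- unclass(p)
  out$preset <- if (is.na(out$preset)) NULL else out$preset
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Stable short hash of a parameter set
#'
#' Used in output manifests to fingerprint the exact configuration.
#'
#' @param p a `sim_params` object.
#' @return 8-character hexadecimal string.
#' @export
config_hash <- function(p) {
  s <- paste(deparse(unclass(p)), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
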