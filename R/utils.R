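# Small numeric helpers shared across modules.
# Package-wide unit system: lengths um, forces pN, time s, energy pN um,
# stiffness pN/um, drag pN s/um, pressure pN/um^2 (= Pa), concentration M.

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m, eps = 1e-300) {
  n <- row_norms(m)
  m / pmax(n, eps)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
# Accumulate rows of `contrib` (m x 3) into `mat` (n x 3) at rows `idx`,
# summing duplicates (scatter-add).
add_rows <- function(mat, idx, contrib) {
  if (length(idx) == 0L) return(mat)
  s <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  mat[rows, ] <- mat[rows, ] + s
  mat
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

deg2rad <- function(d) d * pi / 180

## ---- named RNG substreams -------------------------------------------------

# All stochastic draws flow through named substreams derived from one root
# seed, so modules can be exercised in isolation with reproducible draws.

.stream_hash <- function(name) {
  v <- utf8ToInt(name)
  h <- 104729
  for (ch in v) h <- (h * 131 + ch) %% 2147483629
  h
}

#' Create a named random-number substream
#'
#' Substreams isolate the stochastic draws of different modules (network
#' generation, bond formation, bond rupture, nucleation, ...) so that one
#' root seed reproduces every draw regardless of module call order.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return an opaque stream object for [with_rng()].
#' @export
rng_stream <- function(seed, name = "default") {
  if (is.null(seed) || is.na(seed)) stop("a seed is required (determinism)")
  s <- (as.numeric(seed) %% 2147483629) + .stream_hash(name)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(s %% 2147483629))
  env$state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  env$name <- name
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression under a stream's RNG state
#'
#' The global RNG state is swapped in, the expression evaluated, and the
#' advanced state stored back on the stream; the caller's RNG state is
#' untouched.
#'
#' @param rng a stream from [rng_stream()].
#' @param expr expression to evaluate.
#' @export
with_rng <- function(rng, expr) {
  ge <- globalenv()
  old <- ge$.Random.seed
  ge$.Random.seed <- rng$state
  on.exit({
    rng$state <- ge$.Random.seed
    if (is.null(old)) {
      rm(".Random.seed", envir = ge)
    } else {
      ge$.Random.seed <- old
    }
  })
  expr
}

## ---- spatial hashing of segments ------------------------------------------

# Uniform-grid bucket index over segment midpoints; queries return candidate
# segments within `radius` of a point (conservatively padded by the longest
# half-segment). Rebuilt at the engine's active-domain refresh cadence.

segment_index <- function(P, seg_a, seg_b, active = NULL, cell = 1) {
  if (is.null(active)) active <- seq_along(seg_a)
  if (length(active) == 0L) {
    return(structure(list(empty = TRUE, cell = cell), class = "segment_index"))
  }
  A <- P[seg_a[active], , drop = FALSE]
  B <- P[seg_b[active], , drop = FALSE]
  mid <- (A + B) / 2
  halflen <- 0.5 * row_norms(B - A)
  lo <- apply(mid, 2, min) - 1e-9
  key <- floor(sweep(mid, 2, lo) / cell)
  dims <- apply(key, 2, max) + 1L
  lin <- key[, 1] + dims[1] * (key[, 2] + dims[2] * key[, 3]) + 1
  buckets <- vector("list", prod(dims))
  grp <- split(active, lin)
  buckets[as.integer(names(grp))] <- grp
  structure(list(
    empty = FALSE, buckets = buckets, lo = lo, dims = dims,
    cell = cell, maxhalf = max(halflen)
  ), class = "segment_index")
}

# candidate segment ids near point x (3-vector)
query_segments <- function(index, x, radius) {
  if (isTRUE(index$empty)) return(integer(0))
  r <- radius + index$maxhalf
  n <- ceiling(r / index$cell)
  k0 <- floor((x - index$lo) / index$cell)
  rng1 <- (k0[1] - n):(k0[1] + n)
  rng2 <- (k0[2] - n):(k0[2] + n)
  rng3 <- (k0[3] - n):(k0[3] + n)
  rng1 <- rng1[rng1 >= 0 & rng1 < index$dims[1]]
  rng2 <- rng2[rng2 >= 0 & rng2 < index$dims[2]]
  rng3 <- rng3[rng3 >= 0 & rng3 < index$dims[3]]
  if (!length(rng1) || !length(rng2) || !length(rng3)) return(integer(0))
  g <- expand.grid(rng1, rng2, rng3)
  lin <- g[, 1] + index$dims[1] * (g[, 2] + index$dims[2] * g[, 3]) + 1
  unlist(index$buckets[lin], use.names = FALSE)
}

# closest point on segments [A_i, B_i] to point x; returns list(t, dist, foot)
point_segment_closest <- function(x, A, B) {
  d <- B - A
  xa <- sweep(A, 2, x, "-")
  len2 <- pmax(rowSums(d * d), 1e-300)
  t <- clamp(-rowSums(xa * d) / len2, 0, 1)
  foot <- A + d * t
  dist <- row_norms(sweep(foot, 2, x, "-"))
  list(t = t, dist = dist, foot = foot)
}
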