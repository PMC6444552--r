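#' Synthetic landscape generator
#'
#' Builds the standard test landscapes in code, so no analysis depends on
#' external GIS data.  Kinds:
#'
#' * `"homogeneous"` — all-zero resistance (free space).
#' * `"river_corridor"` — a single meandering zero-resistance channel of
#'   fixed width crossing the extent west to east, amid resistance 1.  The
#'   centerline is itself a seeded correlated random walk (heading clamped
#'   to keep eastward progress, reflected at the north/south margins), so
#'   the channel has realistic sinuosity; it is rasterized as a buffered
#'   polyline, which guarantees one connected zero-resistance component.
#' * `"dendritic_network"` — a binary branching channel network (a
#'   stylized river network): a trunk entering from the south splits in
#'   two at each level; `depth` levels give `2^(depth-1)` leaf channels.
#' * `"patches"` — zero-resistance discs scattered in a graded matrix.
#' * `"graded"` — a smooth west-to-east resistance gradient plus smoothed
#'   seeded noise (heterogeneous but nowhere impassable).
#'
#' Generation is fully deterministic given `(kind, parameters, seed)` and
#' never touches the file system.  Channel widths below 2 cells are
#' rejected: a walker whose maximum step length respects the rule of thumb
#' (at most half the thinnest feature) could not be tested on them.
#'
#' @param kind landscape kind (see above).
#' @param n_cells grid side in cells (square raster; default 300).
#' @param cellsize cell side in map units (default 10).
#' @param seed integer seed for the stochastic kinds.
#' @param corridor_width channel width in cells (river/dendritic; default
#'   6).
#' @param depth branching depth of the dendritic network (default 3).
#' @param n_patches,patch_radius disc count and radius (map units) for
#'   `"patches"`.
#' @param matrix_resistance resistance of the matrix between patches
#'   (default 0.8).
#' @return a `resistance_raster` with origin (0, 0).
#' @examples
#' river <- synthetic_landscape("river_corridor", n_cells = 100, seed = 1)
#' @export
synthetic_landscape <- function(kind = c("homogeneous", "river_corridor",
                                         "dendritic_network", "patches",
                                         "graded"),
                                n_cells = 300, cellsize = 10, seed = 1,
                                corridor_width = 6, depth = 3,
                                n_patches = 8, patch_radius = NULL,
                                matrix_resistance = 0.8) {
  kind <- match.arg(kind)
  n_cells <- as.integer(n_cells)
  side <- n_cells * cellsize
  extent <- c(0, side, 0, side)
  if (kind %in% c("river_corridor", "dendritic_network") &&
      corridor_width < 2)
    stop("'corridor_width' must be at least 2 cells")
  set.seed(seed)
  switch(kind,
    homogeneous = resistance_raster(matrix(0, n_cells, n_cells),
                                    0, 0, cellsize),
    river_corridor = {
      center <- meander_centerline(side, cellsize)
      raster_from_shapes(
        list(shape_line(center, resistance = 0,
                        buffer = corridor_width * cellsize / 2)),
        background = 1, extent = extent, cellsize = cellsize
      )
    },
    dendritic_network = {
      segs <- dendritic_segments(side, depth)
      shapes <- lapply(segs, shape_line, resistance = 0,
                       buffer = corridor_width * cellsize / 2)
      raster_from_shapes(shapes, background = 1, extent = extent,
                         cellsize = cellsize)
    },
    patches = {
      if (is.null(patch_radius)) patch_radius <- side / 15
      vals <- matrix(matrix_resistance, n_cells, n_cells)
      cx <- (rep(seq_len(n_cells), each = n_cells) - 0.5) * cellsize
      cy <- (n_cells - rep(seq_len(n_cells), times = n_cells) + 0.5) * cellsize
      px <- stats::runif(n_patches, patch_radius, side - patch_radius)
      py <- stats::runif(n_patches, patch_radius, side - patch_radius)
      for (p in seq_len(n_patches)) {
        hit <- (cx - px[p])^2 + (cy - py[p])^2 <= patch_radius^2
        vals[hit] <- 0
      }
      resistance_raster(vals, 0, 0, cellsize)
    },
    graded = {
      grad <- matrix(rep(seq(0, 0.9, length.out = n_cells), each = n_cells),
                     n_cells, byrow = FALSE)
      noise <- matrix(stats::runif(n_cells^2, -0.5, 0.5), n_cells)
      for (i in 1:8) noise <- smooth_once(noise)
      resistance_raster(pmin(pmax(grad + noise, 0), 0.99), 0, 0, cellsize)
    }
  )
}

# Meandering centerline: a correlated random walk marching west to east,
# heading clamped to +/- 60 degrees off east, reflected off the margins.
meander_centerline <- function(side, cellsize) {
  grid <- angular_grid(72)
  w <- turning_kernel(0, 0.97, grid)
  inc <- wrap_angle(grid$angles)
  x <- 0; y <- side / 2; theta <- 0
  margin <- side / 6
  pts <- matrix(c(x, y), 1)
  while (x < side) {
    theta <- theta + inc[sample.int(grid$K, 1L, prob = w)]
    theta <- max(-pi / 3, min(pi / 3, theta))
    if ((y < margin && theta < 0) || (y > side - margin && theta > 0))
      theta <- -theta
    x <- x + cellsize * cos(theta)
    y <- y + cellsize * sin(theta)
    pts <- rbind(pts, c(x, y))
  }
  pts
}

# Binary branching tree of straight channel segments, trunk from the
# south edge heading north; depth levels, children at +/- 30 degrees.
dendritic_segments <- function(side, depth) {
  segs <- list()
  recurse <- function(x, y, angle, len, level) {
    x2 <- x + len * cos(angle); y2 <- y + len * sin(angle)
    x2 <- max(0, min(side, x2)); y2 <- max(0, min(side, y2))
    segs[[length(segs) + 1]] <<- rbind(c(x, y), c(x2, y2))
    if (level < depth) {
      recurse(x2, y2, angle + pi / 6, len * 0.75, level + 1)
      recurse(x2, y2, angle - pi / 6, len * 0.75, level + 1)
    }
  }
  recurse(side / 2, 0, pi / 2, side / (depth + 0.5), 1)
  segs
}

smooth_once <- function(m) {
  n <- nrow(m)
  up <- m[c(1, seq_len(n - 1)), ]
  dn <- m[c(seq_len(n - 1) + 1, n), ]
  lf <- m[, c(1, seq_len(ncol(m) - 1))]
  rt <- m[, c(seq_len(ncol(m) - 1) + 1, ncol(m))]
  (m + up + dn + lf + rt) / 5
}

#' Known-parameter reference trajectory
#'
#' Simulates a trajectory and bundles it with the exact generating
#' parameters, for parameter-recovery experiments: fit a model to the
#' (downsampled) trajectory and score the fit against the bundled truth.
#'
#' @param sp the generating [species()].
#' @param raster optional `resistance_raster` (e.g. from
#'   [synthetic_landscape()]).
#' @param n_steps number of high-frequency steps.
#' @param seed integer seed; the bundle is bit-identical for a fixed seed.
#' @param start optional start location (default as in [simulate_walk()]).
#' @return list of class `reference_trajectory` with elements `trajectory`,
#'   `species`, `parameters` (named vector of generating values) and
#'   `seed`.
#' @export
reference_trajectory <- function(sp, raster = NULL, n_steps = 10000,
                                 seed = 1, start = NULL) {
  traj <- simulate_walk(sp, n_steps, raster = raster, start = start,
                        seed = seed)
  S <- n_states(sp)
  pars <- c(
    stats::setNames(state_field(sp, "concentration"),
                    paste0("concentration_", seq_len(S))),
    stats::setNames(state_field(sp, "step_length"),
                    paste0("step_length_", seq_len(S))),
    stats::setNames(state_field(sp, "perceptual_range"),
                    paste0("perceptual_range_", seq_len(S)))
  )
  if (S > 1) {
    offs <- numeric(0)
    for (i in seq_len(S)) for (j in seq_len(S)) if (i != j)
      offs <- c(offs, sp$transitions[i, j])
    pars <- c(pars, stats::setNames(offs, off_diag_names(S)))
  }
  structure(list(trajectory = traj, species = sp, parameters = pars,
                 seed = seed),
            class = "reference_trajectory")
}
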