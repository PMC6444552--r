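#' Resistance attenuation of a step
#'
#' The landscape slows the walker down: the realized step is the intended
#' step scaled by `1 - mean(resistance at start, resistance at intended
#' end)`.  If the mean resistance along the chosen direction is 0 the full
#' user-defined step length is realized; if it is 1 the walker does not
#' move at all; intermediate values shorten the step linearly.
#'
#' @param raster a `resistance_raster` or `NULL` (no raster: fraction 1).
#' @param from,to numeric `c(x, y)` start and intended end of the step.
#' @return fraction in \[0, 1\].
#' @export
step_fraction <- function(raster, from, to) {
  if (is.null(raster)) return(1)
  1 - (resistance_at(raster, from[1], from[2]) +
         resistance_at(raster, to[1], to[2])) / 2
}

#' Advance one step along a drawn heading
#'
#' Moves from `location` along `heading` by the state's maximum step
#' length scaled by [step_fraction()].  Because averaging endpoint
#' resistances can still land the walker on an impassable (resistance 1)
#' cell, a guard then ray-marches back along the segment in increments of
#' a quarter cell to the farthest point whose cell is passable; if no such
#' point short of the start exists the walker stays in place.  A walker
#' standing on passable ground therefore never comes to rest on an
#' impassable cell.
#'
#' @param location numeric `c(x, y)`.
#' @param heading radians.
#' @param state a `movement_state` (its `step_length` is the intended step).
#' @param raster a `resistance_raster` or `NULL`.
#' @return numeric `c(x, y)` of the new location.
#' @export
advance <- function(location, heading, state, raster = NULL) {
  L <- state$step_length
  if (L <= 0) return(location)
  ux <- cos(heading); uy <- sin(heading)
  if (is.null(raster)) return(location + L * c(ux, uy))
  to <- location + L * c(ux, uy)
  d <- step_fraction(raster, location, to) * L
  if (d <= 0) return(location)
  land <- location + d * c(ux, uy)
  if (resistance_at(raster, land[1], land[2]) >= 1) {
    ds <- seq(d, 0, by = -raster$cellsize / 4)
    if (ds[length(ds)] != 0) ds <- c(ds, 0)
    rs <- resistance_at(raster, location[1] + ds * ux, location[2] + ds * uy)
    j <- which(rs < 1)[1]
    if (is.na(j)) return(location)
    d <- ds[j]
    land <- location + d * c(ux, uy)
  }
  land
}

#' Simulate a multistate movement trajectory
#'
#' Runs the high-frequency stepping simulation.  Each step: (1) the
#' behavioral state is redrawn from the transition matrix; (2–3) the
#' landscape within the state's perceptual range is sampled along radial
#' lines and summed into an empirical heading distribution
#' ([perception_distribution()]); (4) a discrete wrapped-normal turning
#' kernel is built, centered on the previous step heading
#' ([turning_kernel()]); (5–6) the two distributions are multiplied and a
#' heading drawn from the product; (7) the step length is attenuated by the
#' mean endpoint resistance ([step_fraction()]); (8) the walker moves,
#' subject to the impassability guard ([advance()]).  The "previous step
#' heading" is the direction of the last step with nonzero displacement:
#' zero-length steps (resting, or a fully blocked walker) leave the heading
#' memory unchanged.
#'
#' With no raster the landscape term is uniform, so the combined
#' distribution reduces exactly to the turning kernel; the simulator then
#' uses an equivalent vectorized sampler (heading indices perform a random
#' walk on the angular grid driven by kernel draws), which is considerably
#' faster.  The two code paths implement the same process.
#'
#' @param sp a [species()].
#' @param n_steps number of steps to simulate (>= 1).
#' @param raster optional `resistance_raster`; the start location must lie
#'   on a passable (resistance < 1) cell.
#' @param start numeric `c(x, y)` start location.  Default: the raster
#'   center (or `c(0, 0)` with no raster); with a raster, the passable cell
#'   center nearest the raster center is used.
#' @param start_state initial state index (default 1).
#' @param start_heading initial heading in radians; default drawn uniformly
#'   on the angular grid.
#' @param grid an [angular_grid()] (default 72 headings, 5-degree
#'   resolution).
#' @param samples_per_line perception samples per radial line; default as
#'   in [perception_distribution()].
#' @param seed optional integer seed; if supplied, `set.seed(seed)` is
#'   called first so the trajectory is fully reproducible.
#' @return data frame with `n_steps + 1` rows and columns `step` (0-based),
#'   `x`, `y`, `state`.  Attribute `trapped_steps` counts steps on which the
#'   combined distribution had no support (walker boxed in).
#' @examples
#' levy <- species(
#'   list(state_rw(10, 200), state_crw(0.95, 10, 200)),
#'   transition_matrix(c(0.01, 0.01))
#' )
#' traj <- simulate_walk(levy, 3000, seed = 1)
#' @export
simulate_walk <- function(sp, n_steps, raster = NULL, start = NULL,
                          start_state = 1L, start_heading = NULL,
                          grid = angular_grid(), samples_per_line = NULL,
                          seed = NULL) {
  stopifnot(inherits(sp, "species"))
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1) stop("'n_steps' must be >= 1")
  if (start_state < 1 || start_state > n_states(sp))
    stop("'start_state' is not a valid state index")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- default_start(raster)
  start <- as.numeric(start)
  if (!is.null(raster) && resistance_at(raster, start[1], start[2]) >= 1)
    stop("start location lies on an impassable (resistance 1) cell")

  if (is.null(raster)) {
    simulate_homogeneous(sp, n_steps, start, start_state, start_heading, grid)
  } else {
    simulate_landscape(sp, n_steps, raster, start, start_state,
                       start_heading, grid, samples_per_line)
  }
}

default_start <- function(raster) {
  if (is.null(raster)) return(c(0, 0))
  ext <- raster_extent(raster)
  cx <- (ext["xmin"] + ext["xmax"]) / 2
  cy <- (ext["ymin"] + ext["ymax"]) / 2
  if (resistance_at(raster, cx, cy) < 1) return(c(cx, cy))
  # passable cell center nearest the raster center (deterministic)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- raster$cellsize
  xc <- raster$xll + (rep(seq_len(nc), each = nr) - 0.5) * cs
  yc <- raster$yll + (nr - rep(seq_len(nr), times = nc) + 0.5) * cs
  pass <- as.vector(raster$values) < 1
  if (!any(pass)) stop("raster has no passable cell")
  i <- which(pass)[which.min((xc[pass] - cx)^2 + (yc[pass] - cy)^2)]
  c(xc[i], yc[i])
}

# Fast equivalent sampler for homogeneous space: the perception term is
# uniform, the combined distribution is the kernel itself, and on a regular
# grid the kernel centered on a grid heading is a circular shift of the
# kernel centered on angle 0 — so heading indices are a modular random walk
# driven by iid kernel-increment draws per state.
simulate_homogeneous <- function(sp, n_steps, start, start_state,
                                 start_heading, grid) {
  K <- grid$K
  states <- simulate_state_chain(sp$transitions, n_steps, start_state)
  L <- state_field(sp, "step_length")[states]
  moving <- L > 0

  inc <- integer(n_steps)
  for (s in seq_len(n_states(sp))) {
    idx <- which(states == s & moving)
    if (!length(idx)) next
    w <- turning_kernel(0, sp$states[[s]]$concentration, grid)
    inc[idx] <- sample.int(K, length(idx), replace = TRUE, prob = w) - 1L
  }

  if (is.null(start_heading)) {
    h0 <- sample.int(K, 1L) - 1L
  } else {
    # arbitrary initial heading: the first moving step draws its absolute
    # heading from the kernel centered on it; later steps are increments
    h0 <- on_grid_index(start_heading, grid)
    first <- which(moving)[1]
    if (is.na(h0) && !is.na(first)) {
      s <- states[first]
      w <- turning_kernel(start_heading, sp$states[[s]]$concentration, grid)
      k_abs <- sample.int(K, 1L, prob = w) - 1L
      inc[first] <- 0L
      h0 <- k_abs
    } else if (is.na(h0)) h0 <- 0L
  }

  h <- (h0 + cumsum(inc)) %% K
  theta <- grid$angles[h + 1L]
  x <- start[1] + cumsum(L * cos(theta))
  y <- start[2] + cumsum(L * sin(theta))
  traj <- data.frame(
    step = 0:n_steps,
    x = c(start[1], x), y = c(start[2], y),
    state = c(as.integer(start_state), states)
  )
  attr(traj, "trapped_steps") <- 0L
  traj
}

on_grid_index <- function(heading, grid) {
  k <- (heading %% (2 * pi)) / (2 * pi) * grid$K
  kr <- round(k)
  if (abs(k - kr) < 1e-9) as.integer(kr %% grid$K) else NA_integer_
}

# General per-step loop with landscape perception.
simulate_landscape <- function(sp, n_steps, raster, start, start_state,
                               start_heading, grid, samples_per_line) {
  K <- grid$K
  S <- n_states(sp)
  cs <- raster$cellsize
  Ls <- state_field(sp, "step_length")
  cum_tm <- t(apply(sp$transitions, 1, cumsum))

  base_kernel <- vector("list", S)
  offs <- vector("list", S)
  for (s in seq_len(S)) {
    base_kernel[[s]] <- turning_kernel(0, sp$states[[s]]$concentration, grid)
    spl <- samples_per_line %||%
      max(2L, as.integer(ceiling(sp$states[[s]]$perceptual_range / (cs / 2))))
    offs[[s]] <- perception_offsets(sp$states[[s]]$perceptual_range, grid, spl)
  }
  kidx <- seq_len(K) - 1L  # 0-based grid indices, for kernel shifting

  x <- start[1]; y <- start[2]
  cur <- as.integer(start_state)
  if (is.null(start_heading)) {
    h <- sample.int(K, 1L) - 1L; mu <- grid$angles[h + 1L]
  } else {
    h <- on_grid_index(start_heading, grid); mu <- start_heading
  }
  r_here <- resistance_at(raster, x, y)

  xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
  sts <- integer(n_steps + 1)
  xs[1] <- x; ys[1] <- y; sts[1] <- cur
  trapped <- 0L
  u_state <- stats::runif(n_steps)

  for (t in seq_len(n_steps)) {
    if (S > 1) {
      row <- cum_tm[cur, ]
      nxt <- 1L
      while (u_state[t] > row[nxt]) nxt <- nxt + 1L
      cur <- nxt
    }
    off <- offs[[cur]]
    cond <- 1 - resistance_at(raster, x + off$dx, y + off$dy)
    per <- .rowSums(cond, K, length(cond) / K)
    ker <- if (is.na(h)) turning_kernel(mu, sp$states[[cur]]$concentration, grid)
           else base_kernel[[cur]][((kidx - h) %% K) + 1L]
    w <- per * ker
    if (sum(w) <= 0) {
      w <- ker
      trapped <- trapped + 1L
    }
    k <- sample.int(K, 1L, prob = w)
    L <- Ls[cur]
    if (L > 0) {
      ux <- cos(grid$angles[k]); uy <- sin(grid$angles[k])
      r_to <- resistance_at(raster, x + L * ux, y + L * uy)
      d <- (1 - (r_here + r_to) / 2) * L
      if (d > 0) {
        r_land <- resistance_at(raster, x + d * ux, y + d * uy)
        if (r_land >= 1) {
          ds <- seq(d, 0, by = -cs / 4)
          if (ds[length(ds)] != 0) ds <- c(ds, 0)
          rs <- resistance_at(raster, x + ds * ux, y + ds * uy)
          j <- which(rs < 1)[1]
          d <- if (is.na(j)) 0 else ds[j]
        }
        if (d > 0) {
          x <- x + d * ux; y <- y + d * uy
          r_here <- resistance_at(raster, x, y)
          h <- k - 1L
        }
      }
    }
    xs[t + 1] <- x; ys[t + 1] <- y; sts[t + 1] <- cur
  }

  traj <- data.frame(step = 0:n_steps, x = xs, y = ys, state = sts)
  attr(traj, "trapped_steps") <- trapped
  traj
}

#' Write or read a trajectory CSV
#'
#' Plain CSV with columns `step, x, y, state`, the interchange format used
#' by the command-line interface.
#'
#' @param traj trajectory data frame as returned by [simulate_walk()].
#' @param path file path.
#' @return `read_trajectory()` returns the trajectory data frame.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(format(traj, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}
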