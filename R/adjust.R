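#' Species model template for parameter approximation
#'
#' Describes the family of species the optimizer searches: the number of
#' behavioral states, per-state bounds for the turning-angle concentration
#' and the maximum step length, and bounds for the off-diagonal state
#' switching probabilities.  Perceptual ranges are fixed (not searched):
#' they only alter movements when varied over orders of magnitude, which
#' makes them weakly identifiable from step statistics.
#'
#' The decision vector layout is fixed and documented: per state
#' `(concentration, step_length)` in state order, followed by the
#' off-diagonal transition probabilities in row-major order.  Bounds
#' guarantee that every in-bounds vector decodes to a valid species (each
#' row's off-diagonal upper bounds must sum to at most 1).
#'
#' @param n_states number of behavioral states (>= 1).
#' @param concentration_bounds length-2 vector (or `n_states x 2` matrix)
#'   of bounds for the concentration, inside \[0, 1\].
#' @param step_length_bounds bounds for the maximum step length (map
#'   units), same shapes.
#' @param perceptual_range fixed perceptual range(s), recycled over states.
#' @param transition_bounds length-2 bounds for every off-diagonal
#'   switching probability; upper bound must not exceed
#'   `1 / (n_states - 1)`.
#' @return a `species_template` with elements `lower`, `upper` (named
#'   decision-vector bounds) and the fixed values.
#' @examples
#' tpl <- species_template(1, step_length_bounds = c(0, 50))
#' @export
species_template <- function(n_states,
                             concentration_bounds = c(0, 1),
                             step_length_bounds = c(0, 100),
                             perceptual_range = 100,
                             transition_bounds = NULL) {
  n_states <- as.integer(n_states)
  if (is.na(n_states) || n_states < 1) stop("'n_states' must be >= 1")
  cb <- expand_bounds(concentration_bounds, n_states, "concentration_bounds")
  if (any(cb < 0) || any(cb > 1))
    stop("'concentration_bounds' must lie inside [0, 1]")
  sb <- expand_bounds(step_length_bounds, n_states, "step_length_bounds")
  if (any(sb < 0)) stop("'step_length_bounds' must be non-negative")
  pr <- rep_len(perceptual_range, n_states)

  n_off <- n_states * (n_states - 1L)
  if (n_off > 0) {
    if (is.null(transition_bounds))
      transition_bounds <- c(0, min(0.5, 1 / (n_states - 1)))
    if (transition_bounds[2] * (n_states - 1) > 1 + 1e-12)
      stop("transition upper bound too large: a row could sum past 1")
    tb <- matrix(rep(transition_bounds, each = n_off), n_off)
  } else tb <- matrix(numeric(0), 0, 2)

  par_names <- c(
    as.vector(rbind(paste0("concentration_", seq_len(n_states)),
                    paste0("step_length_", seq_len(n_states)))),
    off_diag_names(n_states)
  )
  lower <- c(as.vector(rbind(cb[, 1], sb[, 1])), tb[, 1])
  upper <- c(as.vector(rbind(cb[, 2], sb[, 2])), tb[, 2])
  names(lower) <- names(upper) <- par_names
  structure(
    list(n_states = n_states, lower = lower, upper = upper,
         perceptual_range = pr),
    class = "species_template"
  )
}

expand_bounds <- function(b, n, what) {
  if (is.matrix(b)) {
    if (!all(dim(b) == c(n, 2))) stop("'", what, "' matrix must be n_states x 2")
  } else {
    if (length(b) != 2) stop("'", what, "' must be c(lower, upper)")
    b <- matrix(rep(b, each = n), n)
  }
  if (any(b[, 2] < b[, 1])) stop("'", what, "' has upper < lower")
  b
}

off_diag_names <- function(S) {
  if (S < 2) return(character(0))
  out <- character(0)
  for (i in seq_len(S)) for (j in seq_len(S)) if (i != j)
    out <- c(out, sprintf("p_%d_to_%d", i, j))
  out
}

#' Decode a decision vector into a species
#'
#' Inverse of the documented template layout: per-state
#' `(concentration, step_length)` pairs, then row-major off-diagonal
#' switching probabilities.  `encode_species()` is the exact inverse.
#'
#' @param template a [species_template()].
#' @param vector numeric decision vector within the template bounds.
#' @return `decode_species()`: a valid [species()]; `encode_species()`: a
#'   decision vector.
#' @export
decode_species <- function(template, vector) {
  S <- template$n_states
  nv <- length(template$lower)
  if (length(vector) != nv)
    stop(sprintf("decision vector has length %d, template expects %d",
                 length(vector), nv))
  if (any(vector < template$lower - 1e-9) ||
      any(vector > template$upper + 1e-9))
    stop("decision vector violates the template bounds")
  states <- lapply(seq_len(S), function(s)
    movement_state(vector[2 * s - 1], vector[2 * s],
                   template$perceptual_range[s],
                   label = paste0("state", s)))
  tm <- diag(S)
  if (S > 1) {
    off <- vector[(2 * S + 1):nv]
    m <- matrix(0, S, S)
    k <- 1
    for (i in seq_len(S)) for (j in seq_len(S)) if (i != j) {
      m[i, j] <- off[k]; k <- k + 1
    }
    tm <- transition_matrix(m)
  }
  species(states, tm, name = "decoded")
}

#' @rdname decode_species
#' @param sp a `species` matching the template's state count.
#' @export
encode_species <- function(template, sp) {
  S <- template$n_states
  if (n_states(sp) != S) stop("species state count does not match template")
  v <- numeric(0)
  for (s in seq_len(S))
    v <- c(v, sp$states[[s]]$concentration, sp$states[[s]]$step_length)
  if (S > 1)
    for (i in seq_len(S)) for (j in seq_len(S)) if (i != j)
      v <- c(v, sp$transitions[i, j])
  stats::setNames(v, names(template$lower))
}

#' Pooled step-statistic histograms of an observed track
#'
#' Computes the turning-angle and step-length histograms the
#' pattern-oriented fit matches against.  If the track carries a `time`
#' column it is split into segments wherever the sampling gap exceeds 1.5
#' times the modal interval (irregular telemetry), statistics are computed
#' per segment and the histograms pooled; without timestamps the whole
#' track is one segment.  Step-length bin edges span
#' `[0, 1.1 * max observed length]`.
#'
#' @param track data frame with columns `x`, `y` and optionally `time`.
#' @param angle_bins,step_bins number of histogram bins (defaults 16, 20).
#' @return list with `angle_counts`, `step_counts`, `angle_edges`,
#'   `step_edges`, `n_steps`.
#' @export
observed_histograms <- function(track, angle_bins = 16, step_bins = 20) {
  if (nrow(track) < 3) stop("observed track too short")
  if (all(track$x == track$x[1] & track$y == track$y[1]))
    stop("degenerate observed track: all locations identical")
  if (nrow(track) < 30)
    warning("observed track has fewer than 30 locations; histograms may be unstable")
  segs <- split_track_segments(track)
  angles <- numeric(0); lengths <- numeric(0)
  for (seg in segs) {
    if (nrow(seg) < 3) next
    rs <- sample_movement(seg, 1)
    lengths <- c(lengths, rs$step_length[-1])
    angles <- c(angles, rs$turning_angle[-(1:2)])
  }
  if (!length(lengths)) stop("no usable track segment of 3+ locations")
  a_edges <- angular_bins(angle_bins)
  s_edges <- seq(0, max(lengths) * 1.1, length.out = step_bins + 1)
  if (max(lengths) == 0) s_edges <- seq(0, 1, length.out = step_bins + 1)
  list(
    angle_counts = bin_counts(angles, a_edges),
    step_counts = bin_counts(lengths, s_edges),
    angle_edges = a_edges, step_edges = s_edges,
    n_steps = length(lengths)
  )
}

# Split a timestamped track at gaps > 1.5x the modal sampling interval.
split_track_segments <- function(track) {
  if (is.null(track$time) || nrow(track) < 3) return(list(track))
  dt <- diff(track$time)
  if (!length(dt) || any(dt <= 0)) return(list(track))
  modal <- as.numeric(names(sort(table(signif(dt, 6)), decreasing = TRUE))[1])
  cuts <- which(dt > 1.5 * modal)
  if (!length(cuts)) return(list(track))
  starts <- c(1, cuts + 1)
  ends <- c(cuts, nrow(track))
  lapply(seq_along(starts), function(i) track[starts[i]:ends[i], , drop = FALSE])
}

#' Objective evaluation of one candidate parameter set
#'
#' Simulates the decoded candidate at high frequency, downsamples by the
#' same factor that separates the simulation frequency from the observed
#' one, and measures the L1 distances between the simulated and observed
#' turning-angle and step-length histograms (on the observed track's
#' binning; simulated step lengths beyond the top edge are counted in the
#' last bin).  Both objectives are minimized by the optimizer.
#'
#' @param vector decision vector (within template bounds).
#' @param template a [species_template()].
#' @param observed histograms from [observed_histograms()].
#' @param m downsampling factor between simulation and observation
#'   frequency.
#' @param n_sim_steps number of high-frequency simulation steps.
#' @param raster optional `resistance_raster` for the simulation.
#' @param start simulation start location.
#' @param seed optional seed making the evaluation deterministic.
#' @return named numeric `c(angle, step)` of histogram distances in
#'   \[0, 2\].
#' @export
evaluate_candidate <- function(vector, template, observed, m, n_sim_steps,
                               raster = NULL, start = NULL, seed = NULL) {
  sp <- decode_species(template, vector)
  traj <- simulate_walk(sp, n_sim_steps, raster = raster, start = start,
                        seed = seed)
  rs <- sample_movement(traj, m)
  lengths <- rs$step_length[-1]
  angles <- rs$turning_angle[-(1:2)]
  lengths <- pmin(lengths, max(observed$step_edges))
  c(
    angle = distribution_distance(bin_counts(angles, observed$angle_edges),
                                  observed$angle_counts),
    step = distribution_distance(bin_counts(lengths, observed$step_edges),
                                 observed$step_counts)
  )
}

#' Approximate simulation parameters from an observed track
#'
#' Pattern-oriented parameter approximation: searches the template's
#' parameter space with NSGA-II for species whose high-frequency
#' simulations, downsampled by `m`, reproduce the observed track's
#' turning-angle and step-length distributions.  Each candidate is scored
#' by one fresh stochastic simulation (no re-evaluation averaging), the
#' standard desk-scale practice for pattern-oriented calibration; the
#' optimizer's elitism uses the frozen scores, so per-generation objective
#' minima never increase along the trace.
#'
#' @param track observed track: data frame with columns `x`, `y` and
#'   optionally `time` (used only to split irregular tracks at gaps).
#'   At least 30 locations are recommended.
#' @param template a [species_template()].
#' @param m ratio of simulation frequency to observation frequency: each
#'   observed step is assumed to span `m` simulation steps.
#' @param pop_size,generations NSGA-II population size and generation
#'   count (defaults 100 and 50).
#' @param n_sim_steps simulated steps per evaluation; default
#'   `m * (nrow(track) - 1)` so the downsampled simulation has as many
#'   steps as the observation.
#' @param raster optional `resistance_raster` the simulations run on.
#' @param start simulation start; default the first observed location (or
#'   the nearest passable cell when a raster is given and that location is
#'   impassable).
#' @param seed master seed for the whole run (population initialization,
#'   genetic operators, candidate simulations).
#' @param ... further arguments passed to [nsga2()].
#' @return an `nsga2_trace` (see [trace_as_df()]) with attributes
#'   `template`, `observed`, `m`.
#' @examples
#' \donttest{
#' truth <- species(state_crw(0.95, 10, 200))
#' obs <- sample_movement(simulate_walk(truth, 5000, seed = 7), m = 10)
#' fit <- adjust_model(obs, species_template(1, step_length_bounds = c(0, 50)),
#'                     m = 10, pop_size = 30, generations = 10, seed = 1)
#' }
#' @export
adjust_model <- function(track, template, m, pop_size = 100,
                         generations = 50, n_sim_steps = NULL, raster = NULL,
                         start = NULL, seed = NULL, ...) {
  stopifnot(inherits(template, "species_template"))
  if (!all(c("x", "y") %in% names(track)))
    stop("'track' must have columns x and y")
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("'m' must be an integer >= 1")
  observed <- observed_histograms(track)
  if (is.null(n_sim_steps)) n_sim_steps <- m * (nrow(track) - 1L)
  if (n_sim_steps < m * 2 + 1) stop("'n_sim_steps' too small to resample")
  if (is.null(start)) {
    start <- c(track$x[1], track$y[1])
    if (!is.null(raster) && resistance_at(raster, start[1], start[2]) >= 1)
      start <- default_start(raster)
  }
  if (!is.null(seed)) set.seed(seed)
  fn <- function(v) evaluate_candidate(v, template, observed, m, n_sim_steps,
                                       raster = raster, start = start)
  res <- nsga2(fn, template$lower, template$upper,
               pop_size = pop_size, generations = generations, ...)
  attr(res, "template") <- template
  attr(res, "observed") <- observed
  attr(res, "m") <- m
  res
}
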