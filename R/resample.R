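#' Downsample a trajectory to telemetry-like resolution
#'
#' Keeps every `m`-th location of a high-frequency trajectory (rows 1,
#' 1+m, 1+2m, ... — exact thinning, coordinates are untouched) and computes
#' the step-wise statistics a field biologist would derive from telemetry
#' fixes:
#'
#' * `step_length` — Euclidean distance between consecutive kept locations;
#' * `turning_angle` — signed difference between consecutive kept-step
#'   headings, wrapped to `(-pi, pi]`;
#' * `accum_resistance` — sum of the resistance at the `m - 1` skipped
#'   high-frequency locations inside the step (0 when no raster is given;
#'   the kept endpoints are not included in the sum).
#'
#' Statistics are aligned to the kept location that *ends* the step, so the
#' first row has no step statistics and the first two rows no turning
#' angle (`NA`).
#'
#' @param traj trajectory data frame (columns `x`, `y`; as from
#'   [simulate_walk()] or any coordinate table).
#' @param m downsampling factor (>= 1); `m = 1` keeps every location.
#' @param raster optional `resistance_raster` for accumulated resistance.
#' @return a `resampled_track`: data frame with columns `x`, `y`,
#'   `step_length`, `turning_angle`, `accum_resistance` and attribute `m`.
#' @examples
#' sp <- species(state_crw(0.95, 10, 200))
#' rs <- sample_movement(simulate_walk(sp, 1000, seed = 1), m = 10)
#' @export
sample_movement <- function(traj, m = 1, raster = NULL) {
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("'m' must be an integer >= 1")
  n <- nrow(traj)
  if (n <= 2 * m)
    stop(sprintf("trajectory too short to resample: %d rows with m = %d", n, m))
  keep <- seq(1L, n, by = m)
  x <- traj$x[keep]; y <- traj$y[keep]
  k <- length(keep)

  dx <- diff(x); dy <- diff(y)
  len <- sqrt(dx^2 + dy^2)
  head_ang <- atan2(dy, dx)
  turn <- wrap_angle(diff(head_ang))

  accum <- numeric(k - 1)
  if (!is.null(raster) && m > 1) {
    # resistance at the m-1 intermediate high-frequency locations per step
    inter <- setdiff(seq_len(keep[k]), keep)
    r <- resistance_at(raster, traj$x[inter], traj$y[inter])
    grp <- (inter - 1L) %/% m + 1L
    accum <- as.vector(rowsum(r, grp))  # grp is numeric: rows sort 1..k-1
  }

  out <- data.frame(
    x = x, y = y,
    step_length = c(NA, len),
    turning_angle = c(NA, NA, turn),
    accum_resistance = c(NA, accum)
  )
  attr(out, "m") <- m
  class(out) <- c("resampled_track", "data.frame")
  out
}

#' Histogram utilities with a fixed edge convention
#'
#' `bin_counts()` counts values into left-closed bins
#' `[e1, e2), [e2, e3), ..., [eB, eB+1]` (a value on an interior edge goes
#' to the bin on its right; the last bin is closed).  `angular_bins()`
#' returns `B` equal-width edges spanning `(-pi, pi]`.
#'
#' @param values numeric vector (empty input gives all-zero counts).
#' @param edges monotone increasing numeric vector of bin edges.
#' @param B number of angular bins (>= 2).
#' @return `bin_counts()`: integer vector of `length(edges) - 1` counts
#'   summing to `length(values)`.
#' @export
bin_counts <- function(values, edges) {
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE))
    stop("'edges' must be strictly increasing with at least two values")
  values <- values[!is.na(values)]
  nb <- length(edges) - 1
  if (!length(values)) return(integer(nb))
  if (any(values < edges[1]) || any(values > edges[length(edges)]))
    stop("values fall outside the histogram edges")
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = nb)
}

#' @rdname bin_counts
#' @export
angular_bins <- function(B = 16) {
  if (B < 2) stop("'B' must be >= 2")
  seq(-pi, pi, length.out = B + 1)
}

#' Distance between two step-statistic distributions
#'
#' Quantifies how different two empirical distributions (as histogram
#' counts on a shared binning) are.  The default is the L1 distance between
#' the relative-frequency vectors: 0 for identical relative frequencies, 2
#' for distributions with disjoint support.  This is the metric the
#' pattern-oriented parameter approximation minimizes.  The 1-D Wasserstein
#' (earth mover's) distance is available as an alternative; it requires the
#' bin `edges` to weight displacement by distance.
#'
#' @param counts_a,counts_b non-negative count vectors on the same binning.
#' @param method `"l1"` (default) or `"wasserstein"`.
#' @param edges bin edges, required for `method = "wasserstein"`.
#' @return non-negative scalar; 0 iff the relative frequencies coincide.
#' @export
distribution_distance <- function(counts_a, counts_b,
                                  method = c("l1", "wasserstein"),
                                  edges = NULL) {
  method <- match.arg(method)
  if (length(counts_a) != length(counts_b))
    stop("count vectors use different binnings")
  sa <- sum(counts_a); sb <- sum(counts_b)
  if (sa == 0 && sb == 0) return(0)
  pa <- if (sa > 0) counts_a / sa else counts_a
  pb <- if (sb > 0) counts_b / sb else counts_b
  if (method == "l1") return(sum(abs(pa - pb)))
  if (is.null(edges) || length(edges) != length(counts_a) + 1)
    stop("'edges' (length = bins + 1) required for the Wasserstein distance")
  sum(abs(cumsum(pa - pb))[-length(pa)] * diff(edges)[-1])
}
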