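# Shared builders for the test suite.  Everything is generated in code.

# Two-state "Levy-like" walker: uniform RW plus strongly correlated CRW.
levy_species <- function(prange = 200, switch_12 = 0.01, switch_21 = 0.01) {
  species(
    list(state_rw(10, prange), state_crw(0.95, 10, prange)),
    transition_matrix(c(switch_12, switch_21)),
    name = "levy-like"
  )
}

# Strictly aquatic two-state walker (water = 0, everything else = 1).
aquatic_species <- function() {
  species(
    list(state_rw(10, 100), state_crw(0.95, 10, 500)),
    transition_matrix(c(0.01, 0.002)),
    name = "aquatic"
  )
}

# Tiny raster from a matrix literal, cell size 10, origin (0, 0).
tiny_raster <- function(values, cellsize = 10) {
  resistance_raster(values, 0, 0, cellsize)
}

# Realized turning angles of a trajectory, wrapped to (-pi, pi].
realized_turns <- function(traj) {
  dx <- diff(traj$x); dy <- diff(traj$y)
  h <- atan2(dy, dx)
  a <- diff(h)
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# Mean resultant length of a sample of angles.
mean_resultant_length <- function(angles) Mod(mean(exp(1i * angles)))

# Map angles (any branch) to their nearest 1-based index on the K-angle
# grid; robust to floating-point noise in recomputed headings.
kernel_index <- function(angles, K = 72) {
  (round((angles %% (2 * pi)) / (2 * pi) * K) %% K) + 1L
}

# Chi-square goodness of fit with small-expectation bins pooled into one.
pooled_chisq_p <- function(counts, probs, min_expected = 5) {
  n <- sum(counts)
  small <- probs * n < min_expected
  if (any(small)) {
    counts <- c(counts[!small], sum(counts[small]))
    probs <- c(probs[!small], sum(probs[small]))
  }
  if (length(counts) < 2) return(1)
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}

# Flood fill over the zero-resistance cells of a raster; returns the
# number of connected components (4-neighborhood).
zero_components <- function(raster) {
  zero <- raster$values == 0
  lab <- matrix(0L, nrow(zero), ncol(zero))
  comp <- 0L
  for (i in seq_len(nrow(zero))) for (j in seq_len(ncol(zero))) {
    if (!zero[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    queue <- matrix(c(i, j), 1)
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      r <- cur[1]; c <- cur[2]
      if (r < 1 || c < 1 || r > nrow(zero) || c > ncol(zero)) next
      if (!zero[r, c] || lab[r, c] != 0L) next
      lab[r, c] <- comp
      queue <- rbind(queue, c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    }
  }
  list(n = comp, labels = lab)
}
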