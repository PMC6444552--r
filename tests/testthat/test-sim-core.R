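test_that("the discrete wrapped-normal kernel matches a direct wrapped sum", {
  grid <- angular_grid(72)
  # independent oracle: wrap a plain normal density over +/- 12 turns
  wrapped_sum <- function(theta, mu, rho) {
    sigma <- sqrt(-2 * log(rho))
    rowSums(sapply(-12:12, function(j)
      dnorm(theta - mu + 2 * pi * j, 0, sigma)))
  }
  for (rho in c(0.5, 0.75, 0.95)) {
    f <- wrapped_sum(grid$angles, 1.1, rho)
    expect_equal(turning_kernel(1.1, rho, grid), f / sum(f),
                 tolerance = 1e-10)
  }
})

test_that("kernel limits: uniform at rho 0, point mass at rho 1", {
  grid <- angular_grid(72)
  expect_identical(turning_kernel(2, 0, grid), rep(1 / 72, 72))
  w <- turning_kernel(pi / 2, 1, grid)
  expect_identical(sum(w > 0), 1L)
  expect_identical(grid$angles[which(w == 1)], pi / 2)
})

test_that("the discrete kernel preserves the mean resultant length", {
  grid <- angular_grid(72)
  for (rho in c(0, 0.5, 0.75, 0.95)) {
    w <- turning_kernel(0, rho, grid)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_lt(abs(Mod(sum(w * exp(1i * grid$angles))) - rho), 1e-3)
  }
})

test_that("perception weights follow hand-computed line sums on a corridor", {
  # 9x9 cells, 3-cell-wide zero channel running east-west through the middle
  vals <- matrix(1, 9, 9); vals[4:6, ] <- 0
  r <- tiny_raster(vals)  # channel spans y in [30, 60)
  grid <- angular_grid(72)
  w <- perception_distribution(r, 45, 45, perceptual_range = 40,
                               grid = grid, samples_per_line = 8)
  # brute-force oracle: enumerate every sample point
  oracle <- sapply(grid$angles, function(a) {
    radii <- 40 * (1:8) / 8
    sum(1 - resistance_at(r, 45 + radii * cos(a), 45 + radii * sin(a)))
  })
  expect_equal(w, oracle)
  east <- w[1]; north <- w[which.min(abs(grid$angles - pi / 2))]
  expect_identical(east, 8)        # whole line in the channel
  expect_gt(east, 2 * north)       # channel strongly favored
})

test_that("a fully enclosed walker perceives nothing beyond its own cell", {
  vals <- matrix(1, 5, 5); vals[3, 3] <- 0
  r <- tiny_raster(vals)
  grid <- angular_grid(72)
  w <- perception_distribution(r, 25, 25, perceptual_range = 30,
                               grid = grid, samples_per_line = 6)
  radii <- 30 * (1:6) / 6
  oracle <- sapply(grid$angles, function(a)
    sum(1 - resistance_at(r, 25 + radii * cos(a), 25 + radii * sin(a))))
  expect_equal(w, oracle)
  # samples at radius >= 5 * sqrt(2) can leave the central cell; no line can
  # collect more conductance than the number of in-cell sample radii
  expect_true(all(w <= sum(radii < 10 * sqrt(2))))
})

test_that("combine_distributions obeys its algebra", {
  grid <- angular_grid(72)
  unif <- rep(1 / 72, 72)
  ker <- turning_kernel(0.3, 0.9, grid)
  expect_lt(max(abs(combine_distributions(unif, ker) - ker)), 1e-12)
  expect_lt(max(abs(combine_distributions(ker, unif) - ker)), 1e-12)
  # property: normalized, and zero wherever either factor is zero
  set.seed(5)
  for (i in 1:20) {
    a <- runif(72) * rbinom(72, 1, 0.7)
    b <- runif(72) * rbinom(72, 1, 0.7)
    cmb <- combine_distributions(a, b)
    if (is.null(cmb)) {
      expect_true(all(a * b == 0))
    } else {
      expect_equal(sum(cmb), 1, tolerance = 1e-12)
      expect_true(all(cmb[a == 0 | b == 0] == 0))
    }
  }
  # disjoint supports
  expect_null(combine_distributions(c(1, 0, 0, 0, 0, 0, 0, 0),
                                    c(0, 1, 0, 0, 0, 0, 0, 0)))
})

test_that("draw_heading draws the grid angles with the right frequencies", {
  grid <- angular_grid(8)
  pm <- numeric(8); pm[3] <- 1  # point mass on pi/2
  set.seed(2)
  expect_true(all(replicate(30, draw_heading(pm, grid)) == pi / 2))
  set.seed(9)
  draws <- replicate(2e4, draw_heading(rep(1, 8), grid))
  counts <- table(factor(round(draws, 10), levels = round(grid$angles, 10)))
  se <- sqrt(2e4 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - 2e4 / 8) < 4 * se))
  # determinism
  set.seed(33); a <- replicate(10, draw_heading(rep(1, 8), grid))
  set.seed(33); b <- replicate(10, draw_heading(rep(1, 8), grid))
  expect_identical(a, b)
})

test_that("step_fraction is linear in mean endpoint resistance", {
  r <- tiny_raster(matrix(c(0, 1), 1, 2))  # cells [0,10) res 0, [10,20) res 1
  expect_identical(step_fraction(r, c(5, 5), c(5, 5)), 1)
  expect_identical(step_fraction(r, c(15, 5), c(15, 5)), 0)
  expect_identical(step_fraction(r, c(5, 5), c(15, 5)), 0.5)
  expect_identical(step_fraction(NULL, c(0, 0), c(100, 100)), 1)
})

test_that("advance shortens blocked steps to the last passable point", {
  # cells: [0,10) res 0, [10,20) res 1, [20,30) res 1
  r <- tiny_raster(matrix(c(0, 1, 1), 1, 3))
  st <- state_rw(10, 100)
  # attenuation: frac = 1 - (0 + 1)/2 = 0.5 -> raw landing at x = 10 (res 1);
  # guard oracle: march back in cell/4 = 2.5 increments -> x = 7.5 passable
  land <- advance(c(5, 5), 0, st, r)
  d_raw <- 0.5 * 10
  ds <- seq(d_raw, 0, by = -2.5)
  d_oracle <- ds[which(resistance_at(r, 5 + ds, 5) < 1)[1]]
  expect_identical(land, c(5 + d_oracle, 5))
  expect_identical(land[1], 7.5)
  # unobstructed: full step
  expect_equal(advance(c(5, 5), pi, st, NULL), c(-5, 5))
  # resting: no movement
  expect_identical(advance(c(5, 5), 0, state_resting(10), r), c(5, 5))
})

test_that("homogeneous simulations realize exact step lengths and kernel turns", {
  sp <- species(state_crw(0.95, 10, 200))
  traj <- simulate_walk(sp, 20000, seed = 4)
  expect_identical(nrow(traj), 20001L)
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_true(all(abs(d - 10) < 1e-9))
  turns <- realized_turns(traj)
  grid <- angular_grid(72)
  ker <- turning_kernel(0, 0.95, grid)
  counts <- tabulate(kernel_index(turns, 72), nbins = 72)
  expect_gt(pooled_chisq_p(counts, ker), 0.01)
})

test_that("no-raster and uniform-raster simulations agree in law", {
  # the vectorized homogeneous path and the per-step landscape loop are two
  # implementations of the same process; on an all-zero raster they must
  # produce the same turning-angle law
  sp <- species(state_crw(0.9, 5, 50))
  flat <- resistance_raster(matrix(0, 200, 200), 0, 0, 10)
  t_fast <- simulate_walk(sp, 15000, seed = 21, start = c(1000, 1000))
  t_loop <- simulate_walk(sp, 15000, raster = flat, seed = 22,
                          start = c(1000, 1000))
  a <- realized_turns(t_fast); b <- realized_turns(t_loop)
  # bin on the angular grid itself (float bin edges would straddle the
  # grid angles and flip boundary cells on fp noise)
  ca <- tabulate(kernel_index(a, 72), 72)
  cb <- tabulate(kernel_index(b, 72), 72)
  pool <- ca + cb >= 10
  if (any(!pool)) {
    ca <- c(ca[pool], sum(ca[!pool])); cb <- c(cb[pool], sum(cb[!pool]))
  }
  p <- suppressWarnings(chisq.test(rbind(ca, cb))$p.value)
  expect_gt(p, 0.001)
  db <- sqrt(diff(t_loop$x)^2 + diff(t_loop$y)^2)
  expect_true(all(abs(db - 5) < 1e-9))
})

test_that("heading memory is carried unchanged through resting", {
  sp <- species(
    list(state_crw(1, 10, 50), state_resting(50)),
    transition_matrix(c(0.3, 0.3))
  )
  # fast path
  traj <- simulate_walk(sp, 300, seed = 6)
  dx <- diff(traj$x); dy <- diff(traj$y)
  moved <- dx != 0 | dy != 0
  heads <- unique(round(atan2(dy[moved], dx[moved]), 12))
  expect_length(heads, 1)  # rho = 1: every move continues the same heading
  # landscape loop path on a uniform raster behaves the same
  flat <- resistance_raster(matrix(0, 100, 100), 0, 0, 10)
  traj2 <- simulate_walk(sp, 300, raster = flat, seed = 6, start = c(500, 500))
  dx2 <- diff(traj2$x); dy2 <- diff(traj2$y)
  moved2 <- dx2 != 0 | dy2 != 0
  expect_length(unique(round(atan2(dy2[moved2], dx2[moved2]), 12)), 1)
  # resting rows repeat the previous coordinate exactly
  expect_true(all(traj$x[-1][!moved] == traj$x[-nrow(traj)][!moved]))
})

test_that("random-walk mean squared displacement grows linearly", {
  sp <- species(state_rw(10, 200))
  set.seed(12)
  n <- 200; reps <- 400
  msd <- replicate(reps, {
    tr <- simulate_walk(sp, n)
    (tr$x[n + 1] - tr$x[1])^2 + (tr$y[n + 1] - tr$y[1])^2
  })
  # diffusion oracle: E|X_n|^2 = n L^2 for a uniform-turning walk
  expect_lt(abs(mean(msd) - n * 100) / (n * 100), 0.15)
})

test_that("simulations are confined by impassable terrain and extent", {
  r <- synthetic_landscape("river_corridor", n_cells = 120, seed = 8)
  traj <- simulate_walk(aquatic_species(), 4000, raster = r, seed = 9)
  expect_true(all(resistance_at(r, traj$x, traj$y) == 0))
  ext <- raster_extent(r)
  expect_true(all(traj$x >= ext["xmin"] & traj$x <= ext["xmax"]))
  expect_true(all(traj$y >= ext["ymin"] & traj$y <= ext["ymax"]))
  # per-step displacement never exceeds the state's maximum step length
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_true(all(d <= 10 + 1e-9))
})

test_that("a boxed-in walker waits instead of teleporting", {
  vals <- matrix(1, 5, 5); vals[3, 3] <- 0
  r <- tiny_raster(vals)
  sp <- species(state_crw(0.95, 10, 100))
  traj <- simulate_walk(sp, 100, raster = r, start = c(25, 25), seed = 10)
  expect_true(all(resistance_at(r, traj$x, traj$y) == 0))
  expect_true(all(abs(traj$x - 25) < 10 & abs(traj$y - 25) < 10))
})

test_that("simulation input validation and determinism contracts hold", {
  sp <- levy_species()
  expect_error(simulate_walk(sp, 0), ">= 1")
  r <- tiny_raster(matrix(c(0, 1), 1, 2))
  expect_error(simulate_walk(sp, 10, raster = r, start = c(15, 5)),
               "impassable")
  a <- simulate_walk(sp, 500, seed = 99)
  b <- simulate_walk(sp, 500, seed = 99)
  expect_identical(a, b)
  rr <- synthetic_landscape("river_corridor", n_cells = 60, seed = 2)
  a2 <- simulate_walk(aquatic_species(), 300, raster = rr, seed = 99)
  b2 <- simulate_walk(aquatic_species(), 300, raster = rr, seed = 99)
  expect_identical(a2, b2)
})
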