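test_that("template decision vectors decode to valid species", {
  tpl <- species_template(2, step_length_bounds = c(0, 50),
                          perceptual_range = 200)
  # layout: (rho1, L1, rho2, L2, p12, p21)
  sp <- decode_species(tpl, c(0, 10, 0.95, 10, 0.01, 0.01))
  expect_identical(length(sp$states), 2L)
  expect_identical(sp$states[[1]]$concentration, 0)
  expect_identical(sp$states[[2]]$concentration, 0.95)
  expect_identical(sp$states[[2]]$step_length, 10)
  expect_equal(sp$transitions,
               matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
  expect_error(decode_species(tpl, c(2, 10, 0.95, 10, 0.01, 0.01)),
               "bounds")
  expect_error(decode_species(tpl, c(0, 10)), "length")
})

test_that("encode_species is the exact inverse of decode_species", {
  tpl <- species_template(2, step_length_bounds = c(0, 50),
                          perceptual_range = c(100, 500))
  v <- c(0.3, 12, 0.9, 4, 0.05, 0.2)
  sp <- decode_species(tpl, v)
  expect_equal(unname(encode_species(tpl, sp)), v)
  tpl1 <- species_template(1, step_length_bounds = c(0, 50))
  sp1 <- decode_species(tpl1, c(0.95, 10))
  expect_equal(unname(encode_species(tpl1, sp1)), c(0.95, 10))
})

test_that("template bounds guarantee valid transition rows", {
  expect_error(
    species_template(3, transition_bounds = c(0, 0.9)),
    "row could sum past 1"
  )
  tpl3 <- species_template(3)
  set.seed(1)
  for (i in 1:20) {
    v <- runif(length(tpl3$lower), tpl3$lower, tpl3$upper)
    sp <- decode_species(tpl3, v)
    expect_true(all(abs(rowSums(sp$transitions) - 1) < 1e-12))
    expect_true(all(sp$transitions >= 0 & sp$transitions <= 1))
  }
})

test_that("observed_histograms pools segments split at time gaps", {
  set.seed(2)
  xy <- data.frame(x = cumsum(rnorm(60)), y = cumsum(rnorm(60)))
  xy$time <- c(1:30, 61:90)  # one gap of 31 >> modal interval 1
  pooled <- observed_histograms(xy)
  # manual two-segment oracle
  s1 <- sample_movement(xy[1:30, ], 1)
  s2 <- sample_movement(xy[31:60, ], 1)
  lengths <- c(s1$step_length[-1], s2$step_length[-1])
  angles <- c(s1$turning_angle[-(1:2)], s2$turning_angle[-(1:2)])
  expect_identical(pooled$n_steps, length(lengths))
  expect_identical(pooled$step_edges[21], max(lengths) * 1.1)
  expect_identical(pooled$angle_counts, bin_counts(angles, angular_bins(16)))
  expect_identical(pooled$step_counts, bin_counts(lengths, pooled$step_edges))
})

test_that("observed_histograms rejects degenerate tracks", {
  bad <- data.frame(x = rep(1, 40), y = rep(2, 40))
  expect_error(observed_histograms(bad), "degenerate")
  short <- data.frame(x = cumsum(rnorm(10)), y = cumsum(rnorm(10)))
  expect_warning(observed_histograms(short), "fewer than 30")
})

test_that("evaluate_candidate is deterministic and bounded by 2", {
  truth <- species(state_crw(0.95, 10, 200))
  obs <- observed_histograms(
    sample_movement(simulate_walk(truth, 5000, seed = 3), 10)
  )
  tpl <- species_template(1, step_length_bounds = c(0, 50),
                          perceptual_range = 200)
  a <- evaluate_candidate(c(0.95, 10), tpl, obs, 10, 5000, seed = 8)
  b <- evaluate_candidate(c(0.95, 10), tpl, obs, 10, 5000, seed = 8)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 2))
  # a candidate that cannot move far enough: step-length histograms disjoint
  worst <- evaluate_candidate(c(0.95, 0.2), tpl, obs, 10, 5000, seed = 8)
  expect_gt(worst[["step"]], 1.8)
  # the generating parameters score near the replicate noise floor
  expect_lt(a[["step"]], 0.5)
  expect_lt(a[["angle"]], 0.5)
})

test_that("nsga2 solves the Schaffer two-objective problem", {
  res <- nsga2(function(x) c(x^2, (x - 2)^2), lower = -10, upper = 10,
               pop_size = 40, generations = 50, seed = 5)
  front <- res$front[[50]]
  expect_true(all(front$par1 >= -0.05 & front$par1 <= 2.05))
  # front spread covers the Pareto set [0, 2]
  expect_lt(min(front$par1), 0.5)
  expect_gt(max(front$par1), 1.5)
})

test_that("nsga2 degenerates to a single-objective minimizer", {
  res <- nsga2(function(x) (x - 1.3)^2, lower = -10, upper = 10,
               pop_size = 20, generations = 40, seed = 6)
  best <- res$population[which.min(res$objectives[, 1]), 1]
  # grid-search oracle at resolution 0.01
  grid <- seq(-10, 10, by = 0.01)
  opt <- grid[which.min((grid - 1.3)^2)]
  expect_lt(abs(best - opt), 0.02)
})

test_that("crowding and domination follow the documented tie rules", {
  obj <- matrix(c(1, 2, 2, 1, 1.5, 1.5, 3, 3), ncol = 2, byrow = TRUE)
  rank <- nondominated_rank(obj)
  expect_identical(rank, c(1L, 1L, 1L, 2L))
  cd <- crowding_distance(obj[rank == 1L, , drop = FALSE])
  expect_identical(cd[1], Inf)  # per-objective extremes rank first
  expect_identical(cd[2], Inf)
  expect_true(is.finite(cd[3]))
  # identical individuals: boundary slots get Inf, interior get 0
  same <- matrix(1, 5, 2)
  cds <- crowding_distance(same)
  expect_identical(sum(is.infinite(cds)), 2L)
  expect_true(all(cds[is.finite(cds)] == 0))
})

test_that("adjust_model recovers known single-state parameters", {
  truth <- species(state_crw(0.95, 10, 200))
  ref <- reference_trajectory(truth, n_steps = 10000, seed = 17)
  obs <- sample_movement(ref$trajectory, m = 10)
  tpl <- species_template(1, step_length_bounds = c(0, 50),
                          perceptual_range = 200)
  fit <- adjust_model(obs, tpl, m = 10, pop_size = 40, generations = 15,
                      seed = 18)
  front <- fit$front[[15]]
  hit <- abs(front$par1 - 0.95) <= 0.05 & abs(front$par2 - 10) <= 2
  expect_true(any(hit))
})

test_that("adjust traces are elitist and reproducible", {
  truth <- species(state_crw(0.9, 8, 100))
  obs <- sample_movement(simulate_walk(truth, 2000, seed = 20), 5)
  tpl <- species_template(1, step_length_bounds = c(0, 30))
  run <- function() adjust_model(obs, tpl, m = 5, pop_size = 12,
                                 generations = 6, seed = 21)
  a <- run(); b <- run()
  expect_identical(trace_as_df(a), trace_as_df(b))
  mins <- t(sapply(a$front, function(f) c(min(f$obj1), min(f$obj2))))
  expect_true(all(diff(mins[, 1]) <= 1e-12))
  expect_true(all(diff(mins[, 2]) <= 1e-12))
  # all emitted candidates respect the template bounds
  df <- trace_as_df(a)
  expect_true(all(df$par1 >= 0 & df$par1 <= 1))
  expect_true(all(df$par2 >= 0 & df$par2 <= 30))
})
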