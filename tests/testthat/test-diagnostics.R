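test_that("effective edges sit at the inflection points", {
  g <- grid_1d(L = 20, nx = 800)
  # sech profile: inflections at +- sqrt(2) acosh(sqrt(2))
  e <- effective_edges(1 / cosh(g$x1 / sqrt(2)), g)
  x_true <- sqrt(2) * acosh(sqrt(2))
  expect_equal(unname(e["right"]), x_true, tolerance = 1e-3)
  expect_equal(unname(e["left"]), -x_true, tolerance = 1e-3)
  # even profiles give symmetric edges
  e2 <- effective_edges(exp(-g$x1^2 / 7), g)
  expect_equal(unname(e2["right"] + e2["left"]), 0, tolerance = 1e-9)
  # logistic front: inflection exactly at the front position
  c0 <- 4.3
  e3 <- effective_edges(1 / (1 + exp(g$x1 - c0)), g)
  expect_equal(unname(e3["right"]), c0, tolerance = 1e-2)
  # flat profile has no edges
  e4 <- effective_edges(rep(1, 800), g)
  expect_true(all(is.na(e4)))
})

test_that("edge detection commutes with mirror reflection", {
  g <- grid_1d(L = 20, nx = 400)
  n <- 1 / cosh((g$x1 - 3) / 2)
  e <- effective_edges(n, g)
  e_m <- effective_edges(rev(n), g)
  expect_equal(unname(e_m["right"]), -unname(e["left"]), tolerance = 1e-9)
  expect_equal(unname(e_m["left"]), -unname(e["right"]), tolerance = 1e-9)
})

test_that("wave metrics are exact for rigid translation", {
  g <- grid_1d(L = 40, nx = 800)
  p <- typical_params()
  times <- seq(0, 10, by = 1)
  speed_true <- 1
  states <- lapply(times, function(t) {
    prof <- pmin(0.7, 1 / cosh((abs(g$x1) - 5 - speed_true * t) / 2) * 2)
    population_state(prof, 0, 1, t = t, grid = g)
  })
  traj <- structure(list(times = times, states = states, grid = g,
                         params = p, env = linear_optimum(g, 0),
                         schedule = NULL), class = "trajectory")
  wm <- wave_metrics(traj, window = c(2, 10))
  expect_equal(wm$speed, speed_true, tolerance = 0.02)
  expect_equal(wm$amplitude, 0.7)                      # plateau height
  # stationary profile -> zero speed
  states0 <- lapply(times, function(t)
    population_state(1 / cosh(g$x1 / 2), 0, 1, t = t, grid = g))
  traj0 <- structure(list(times = times, states = states0, grid = g,
                          params = p, env = linear_optimum(g, 0),
                          schedule = NULL), class = "trajectory")
  expect_equal(wave_metrics(traj0, c(0, 10))$speed, 0, tolerance = 1e-9)
  expect_error(wave_metrics(traj, window = c(9.5, 10)), "insufficient")
})

test_that("adaptation time is zero for an initially adapted site and Inf when never reached", {
  g <- grid_1d(L = 10, nx = 80)
  p <- typical_params()
  env <- linear_optimum(g, 1)
  mk <- function(qoff) lapply(0:5, function(t)
    population_state(1, env$Q + qoff, 1, t = t, grid = g))
  traj <- structure(list(times = 0:5, states = mk(0), grid = g, params = p,
                         env = env, schedule = NULL), class = "trajectory")
  expect_equal(adaptation_time(traj), 0)
  traj2 <- structure(list(times = 0:5, states = mk(5), grid = g, params = p,
                          env = env, schedule = NULL), class = "trajectory")
  expect_equal(adaptation_time(traj2), Inf)
})

test_that("fluctuation mean density averages the steady cycle extrema", {
  g <- grid_1d(L = 10, nx = 80)
  p <- typical_params()
  env <- linear_optimum(g, 1)
  sch <- shift_schedule(2, 5)
  # synthetic peak series alternating 0.4 / 0.8 each half-period
  times <- seq(0, 12, by = 0.5)
  states <- lapply(times, function(t)
    population_state(if (t %% 2 < 1) 0.4 else 0.8, env$Q, 1, t = t, grid = g))
  traj <- structure(list(times = times, states = states, grid = g, params = p,
                         env = env, schedule = sch), class = "trajectory")
  fm <- fluctuation_mean_density(traj)
  expect_equal(fm$mean_density, 0.6)
  expect_true(fm$steady)
  expect_false(fm$extinct)
  # amplitude-0 schedule reduces to the final static value
  traj$schedule <- NULL
  expect_equal(fluctuation_mean_density(traj, NULL)$mean_density, 0.4)
  # an unsteady series warns
  states2 <- lapply(times, function(t)
    population_state(0.8 * exp(-0.2 * t), env$Q, 1, t = t, grid = g))
  traj2 <- structure(list(times = times, states = states2, grid = g,
                          params = p, env = env, schedule = sch),
                     class = "trajectory")
  expect_warning(fluctuation_mean_density(traj2), "not steady")
})

test_that("extinction classification needs both low density and decline", {
  g <- grid_1d(L = 10, nx = 80)
  p <- typical_params()
  env <- linear_optimum(g, 1)
  mk_traj <- function(peaks) structure(
    list(times = seq_along(peaks) - 1,
         states = lapply(peaks, function(pk)
           population_state(pk, env$Q, 1, grid = g)),
         grid = g, params = p, env = env, schedule = NULL),
    class = "trajectory")
  expect_true(classify_extinction(mk_traj(c(0.5, 1e-2, 1e-3, 5e-4, 2e-4)), p))
  expect_true(classify_extinction(mk_traj(rep(0, 5)), p))
  expect_false(classify_extinction(mk_traj(rep(0.9, 5)), p))   # persistent
  expect_false(classify_extinction(mk_traj(c(1e-4, 1e-4, 0.5, 0.9, 0.9)), p))
})
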