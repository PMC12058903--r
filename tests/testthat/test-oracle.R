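test_that("competition factor quadrature matches the closed form", {
  expect_equal(competition_factor(0, 4), 1)
  expect_equal(competition_factor(1, 4), sqrt(4 / 5), tolerance = 1e-6)
  expect_equal(competition_factor(4, 4), sqrt(1 / 2), tolerance = 1e-6)
  expect_equal(competition_factor(2.5, 1.3), sqrt(1.3 / 3.8), tolerance = 1e-6)
})

test_that("moment extraction recovers Gaussian and mixture moments", {
  g <- grid_1d(L = 5, nx = 16)
  p_axis <- seq(-12, 12, length.out = 301)
  s <- population_state(0.7, 1.2, 2.5, grid = g)
  ps <- gaussian_phenotype_state(s, g, p_axis)
  m <- extract_moments(ps)
  expect_equal(m$n[1, 1], 0.7, tolerance = 1e-8)
  expect_equal(m$q[1, 1], 1.2, tolerance = 1e-8)
  expect_equal(m$v[1, 1], 2.5, tolerance = 1e-6)

  # two-Gaussian mixture: closed-form mixture moments
  w <- c(0.3, 0.7); mu <- c(-2, 1.5); s2 <- c(0.8, 1.6)
  f <- matrix(w[1] * dnorm(p_axis, mu[1], sqrt(s2[1])) +
                w[2] * dnorm(p_axis, mu[2], sqrt(s2[2])),
              nrow = 16, ncol = length(p_axis), byrow = TRUE)
  mx <- extract_moments(phenotype_grid_state(f, p_axis, g))
  mean_mix <- sum(w * mu)
  var_mix <- sum(w * (s2 + mu^2)) - mean_mix^2
  expect_equal(mx$n[1, 1], 1, tolerance = 1e-8)
  expect_equal(mx$q[1, 1], mean_mix, tolerance = 1e-8)
  expect_equal(mx$v[1, 1], var_mix, tolerance = 1e-6)

  # empty cells report undefined moments
  f0 <- f; f0[1, ] <- 0
  m0 <- extract_moments(phenotype_grid_state(f0, p_axis, g))
  expect_true(is.na(m0$q[1, 1]) && is.na(m0$v[1, 1]))
  expect_equal(m0$n[1, 1], 0)
})

test_that("mutation grows trait variance at rate U in isolation", {
  g <- grid_1d(L = 5, nx = 16)
  p <- model_params(A = 0, R = 1, S = 0, U = 0.05, D = 0)
  p$R <- 0                          # growth off entirely
  env <- linear_optimum(g, 0, params = p)
  p_axis <- seq(-10, 10, length.out = 241)
  ps <- gaussian_phenotype_state(population_state(1, 0, 1, grid = g), g, p_axis)
  v0 <- extract_moments(ps)$v[8, 1]
  dt <- 0.005
  for (k in 1:100) ps <- step_phenotype_density(ps, env, p, dt)
  v1 <- extract_moments(ps)$v[8, 1]
  expect_equal((v1 - v0) / 0.5, p$U, tolerance = 0.02)
})

test_that("oracle mass is conserved with growth off and reflecting walls", {
  g <- grid_1d(L = 5, nx = 24)
  p <- model_params(A = 6, R = 2, S = 0, U = 0.02)
  p$R <- 0
  env <- linear_optimum(g, 0.5, params = p)
  p_axis <- seq(-12, 12, length.out = 121)
  s0 <- population_state(exp(-g$x1^2 / 4), 0.3 * g$x1, 1, grid = g)
  ps <- gaussian_phenotype_state(s0, g, p_axis)
  mass0 <- sum(ps$f) * ps$dp * g$dx[1]
  for (k in 1:50) ps <- step_phenotype_density(ps, env, p, 0.002)
  mass1 <- sum(ps$f) * ps$dp * g$dx[1]
  expect_equal(mass1, mass0, tolerance = 1e-6)
})

test_that("phenotype-resolved moment rates validate the Gaussian closure", {
  ## Gaussian-in-p initial data: the oracle's (dn, dq, dv) must match the
  ## closed three-field right-hand side, with error decreasing under grid
  ## refinement.
  p <- model_params(A = 6, R = 2, V = 4, S = 0.2, U = 0.02)
  err_at <- function(nx, np) {
    g <- habitat_grid(c(-10, 10), nx)
    env <- linear_optimum(g, 0.8, params = p)
    s <- population_state(0.8 * exp(-g$x1^2 / 8),
                          env$Q * 0.7, 1 + 0.2 * exp(-g$x1^2 / 10), grid = g)
    p_axis <- seq(min(s$q) - 12, max(s$q) + 12, length.out = np)
    ps <- gaussian_phenotype_state(s, g, p_axis)
    rates <- oracle_moment_rates(ps, env, p, eps = 1e-4)
    closed <- model_rhs(s, env, p, g, scheme = "central")
    sel <- s$n[, 1] > 0.05                 # inside the effective range
    scale <- function(x) max(abs(x[sel]))
    max(max(abs((rates$dn - closed$dn[, 1])[sel])) / scale(closed$dn),
        max(abs((rates$dq - closed$dq[, 1])[sel])) / scale(closed$dq),
        max(abs((rates$dv - closed$dv[, 1])[sel])) / scale(closed$dv))
  }
  e_coarse <- err_at(40, 101)
  e_mid <- err_at(80, 201)
  e_fine <- err_at(160, 401)
  expect_lt(e_mid, e_coarse)
  expect_lt(e_fine, e_mid)
  expect_lt(e_fine, 0.05)
})
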