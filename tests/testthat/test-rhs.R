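test_that("each equation equals the sum of its registry terms", {
  g <- grid_1d(L = 20, nx = 160)
  p <- typical_params(A = 10)
  env <- linear_optimum(g, 1.5, params = p)
  s <- expansion_initial_state(g, env)
  r <- model_rhs(s, env, p, g)
  expect_equal(r$dn, with(r$terms, t14 + t15 + t16))
  expect_equal(r$dq, with(r$terms, t17 + t18 + t19 + t20 + t21 + t22))
  expect_equal(r$dv, with(r$terms, t23 + t24 + t25 + t26 + t27 + t28))
  dr <- density_rhs(s, env, p, g)
  expect_equal(dr$field, r$dn)
  expect_named(trait_mean_rhs(s, env, p, g)$terms, paste0("t", 17:22))
  expect_named(trait_variance_rhs(s, env, p, g)$terms, paste0("t", 23:28))
})

test_that("directed-dispersal velocity follows mismatch and gradient", {
  g <- grid_1d(nx = 400)
  p <- typical_params(A = 10)
  env <- linear_optimum(g, 100, params = p)   # effectively saturated
  # q = Q -> no directed movement
  s_adapted <- adapted_state(g, env)
  u <- advection_velocity(s_adapted, env, p, g)
  expect_equal(max(abs(u$u1)), 0)
  # mismatch of one utilisation variance at saturation: speed ~ A
  s_mis <- population_state(1, env$Q + p$V, 1, grid = g)
  u <- advection_velocity(s_mis, env, p, g)
  interior <- interior_1d(g)
  expect_equal(max(u$u1[interior, 1]), 10, tolerance = 0.02)
  # q > Q with gradient along +x -> velocity points in +x
  expect_true(all(u$u1[interior, 1] > 0))
  s_neg <- population_state(1, env$Q - 1, 1, grid = g)
  expect_true(all(advection_velocity(s_neg, env, p, g)$u1[interior, 1] < 0))
})

test_that("reaction terms reproduce their closed-form values", {
  g <- grid_1d(nx = 64)
  p <- typical_params(A = 0)
  env <- linear_optimum(g, 0.5, params = p)
  # logistic equilibrium: n = K, q = Q, v = 0 -> dn identically 0
  s_eq <- adapted_state(g, env, n = 1, v = 0)
  r <- model_rhs(s_eq, env, p, g)
  interior <- interior_1d(g)
  expect_lt(max(abs(r$dn[interior, 1])), 1e-10)
  # n = K = 1, q = Q, v = 1: reaction rate = 2(1 - sqrt(0.8)) - 0.1
  s1 <- adapted_state(g, env, n = 1, v = 1)
  r1 <- model_rhs(s1, env, p, g)
  expect_equal(r1$terms$t16[interior, 1][1],
               2 * (1 - sqrt(0.8)) - 0.1, tolerance = 1e-12)
  # selection on the mean: flat Q, q - Q = 1, v = 2, A = 0 -> dq = -S (q-Q) v
  env0 <- linear_optimum(g, 0, params = p)
  s2 <- population_state(1, env0$Q + 1, 2, grid = g)
  r2 <- model_rhs(s2, env0, p, g)
  expect_equal(r2$dq[interior, 1][1], -0.2 * 1 * 2, tolerance = 1e-12)
  # mutation-selection balance: n = 0 -> dv = -S v^2 + U, zero at sqrt(U/S)
  v_bal <- sqrt(p$U / p$S)
  s3 <- population_state(0, env0$Q, v_bal, grid = g)
  r3 <- model_rhs(s3, env0, p, g)
  expect_lt(max(abs(r3$dv)), 1e-12)
  expect_equal(model_rhs(population_state(0, env0$Q, 1, grid = g),
                         env0, p, g)$dv[1, 1], -p$S + p$U, tolerance = 1e-12)
})

test_that("adapted homogeneous equilibrium is a fixed point in the interior", {
  g <- grid_1d(L = 30, nx = 240)
  for (A in c(0, 10)) {
    p <- typical_params(A = A)
    env <- linear_optimum(g, 1, params = p)
    eq <- equilibrium_density(p, 1)
    s <- adapted_state(g, env, n = eq$n_star, v = eq$v_star)
    r <- model_rhs(s, env, p, g)
    interior <- interior_1d(g, margin = 6)
    expect_lt(max(abs(r$dn[interior, 1])), 1e-6)
    expect_lt(max(abs(r$dq[interior, 1])), 1e-6)
    expect_lt(max(abs(r$dv[interior, 1])), 1e-6)
  }
})

test_that("variance inflation by random gene flow is nonnegative and vanishes as V grows", {
  g <- grid_1d(L = 20, nx = 160)
  p <- typical_params(A = 4)
  env <- linear_optimum(g, 1.5, params = p)
  s <- expansion_initial_state(g, env)
  r <- model_rhs(s, env, p, g)
  expect_true(all(r$terms$t25 >= 0))
  # competition contribution to dv -> 0 as V -> infinity
  comp_part <- function(V) {
    pV <- typical_params(A = 0, V = V)
    envV <- linear_optimum(g, 0, params = pV)
    sV <- adapted_state(g, envV, n = 1, v = 1)
    model_rhs(sV, envV, pV, g)$terms$t28[80, 1] + pV$S * 1 - pV$U
  }
  vals <- vapply(c(4, 40, 4000), comp_part, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 1e-3)
})

test_that("mirror symmetry: reflected states give reflected rates", {
  g <- grid_1d(L = 20, nx = 160)
  p <- typical_params(A = 10)
  env <- linear_optimum(g, 1.5, params = p)
  s <- expansion_initial_state(g, env)
  # break symmetry deliberately before mirroring
  s$n <- s$n * (1 + 0.3 * sin(g$X1 / 5))
  s$v <- s$v + 0.2 * exp(-(g$X1 - 3)^2 / 10)
  Q0 <- 0                                  # Q = 1.5 x, antisymmetric about 0
  mirror <- function(f) f[rev(seq_len(nrow(f))), , drop = FALSE]
  s_m <- population_state(mirror(s$n), 2 * Q0 - mirror(s$q), mirror(s$v),
                          grid = g)
  r <- model_rhs(s, env, p, g)
  r_m <- model_rhs(s_m, env, p, g)
  expect_equal(r_m$dn, mirror(r$dn), tolerance = 1e-10)
  expect_equal(r_m$dq, -mirror(r$dq), tolerance = 1e-10)
  expect_equal(r_m$dv, mirror(r$dv), tolerance = 1e-10)
})

test_that("gene-flow decomposition is exact and directed flow needs A > 0", {
  g <- grid_1d(L = 20, nx = 160)
  p0 <- typical_params(A = 0)
  env <- linear_optimum(g, 1.5, params = p0)
  s <- expansion_initial_state(g, env)
  gf0 <- gene_flow_decomposition(s, env, p0, g)
  expect_equal(max(abs(gf0$directed)), 0)
  p <- typical_params(A = 10)
  env <- linear_optimum(g, 1.5, params = p)
  gf <- gene_flow_decomposition(s, env, p, g, split19 = TRUE)
  expect_equal(gf$total, gf$random + gf$directed)
  r <- model_rhs(s, env, p, g)
  expect_equal(gf$random, r$terms$t17 + r$terms$t18)
  # product-rule split of the divergence term reconstructs it (central form)
  expect_equal(gf$div_split$variance_gradient + gf$div_split$gradient_divergence,
               r$terms$t19, tolerance = 1e-10)
})
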