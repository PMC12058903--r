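## Phenotype-resolved reference simulator on a small (x, p) grid.
##
## Evolves the full phenotype density f(x, p) = n(x) phi(x, p) under
## diffusion in space, per-phenotype directed advection, intrinsic growth
## with the phenotype-competition convolution computed by quadrature, and
## mutation as diffusion along the phenotype axis. Used to validate the
## Gaussian moment closure of the three-field model by brute force; coarse
## grids and short horizons only.

#' Phenotype-resolved grid state
#'
#' @param f density over `(x, p)`, a `nx x np` matrix, `N/(X Q)`.
#' @param p_axis phenotype coordinates (equally spaced), `Q`.
#' @param grid a 1D [habitat_grid].
#' @return an object of class `phenotype_grid_state`.
#' @export
phenotype_grid_state <- function(f, p_axis, grid) {
  stopifnot(grid$m == 1L, is.matrix(f), nrow(f) == grid$nx[1],
            ncol(f) == length(p_axis))
  if (any(f < -1e-12)) stop("phenotype density must be nonnegative")
  dp <- diff(p_axis)
  if (max(abs(dp - dp[1])) > 1e-9 * abs(dp[1]))
    stop("p_axis must be equally spaced")
  s <- list(f = pmax(f, 0), p_axis = p_axis, dp = dp[1], grid = grid, t = 0)
  class(s) <- "phenotype_grid_state"
  s
}

#' Gaussian-in-phenotype initial data
#'
#' Builds the phenotype density corresponding to moments `(n, q, v)`:
#' `f(x, p) = n(x) Normal(p; q(x), v(x))`.
#'
#' @param state a [population_state] on a 1D grid.
#' @param grid the [habitat_grid].
#' @param p_axis phenotype coordinates; should span at least `q +- 6 sqrt(v)`.
#' @return a [phenotype_grid_state].
#' @export
gaussian_phenotype_state <- function(state, grid, p_axis) {
  f <- t(vapply(seq_len(grid$nx[1]), function(i)
    state$n[i, 1] * stats::dnorm(p_axis, state$q[i, 1], sqrt(state$v[i, 1])),
    numeric(length(p_axis))))
  phenotype_grid_state(f, p_axis, grid)
}

#' Mean competition factor by quadrature
#'
#' The population-average strength of phenotype-dependent competition for a
#' Gaussian phenotype distribution with variance `v`: the double integral of
#' the Gaussian competition kernel (variance `2V`) against the phenotype
#' distribution in both arguments. Analytically equals `sqrt(V/(v+V))`;
#' computed here by trapezoidal quadrature as an independent check.
#'
#' @param v trait variance, `Q^2` (>= 0).
#' @param V phenotype utilisation variance, `Q^2` (> 0).
#' @param np number of quadrature nodes.
#' @param width half-width of the quadrature domain in phenotype standard
#'   deviations.
#' @return dimensionless scalar in `(0, 1]`.
#' @examples
#' competition_factor(1, 4)        # ~ sqrt(0.8)
#' @export
competition_factor <- function(v, V, np = 401, width = 10) {
  stopifnot(v >= 0, V > 0)
  if (v == 0) return(1)
  half <- width * sqrt(v)
  p <- seq(-half, half, length.out = np)
  dp <- p[2] - p[1]
  phi <- stats::dnorm(p, 0, sqrt(v))
  alpha <- exp(-outer(p, p, "-")^2 / (4 * V))
  val <- as.numeric(phi %*% alpha %*% phi) * dp^2
  if (!is.finite(val)) stop("quadrature for the competition factor did not converge")
  val
}

## growth rate g(x, p) with the competition convolution done by quadrature
oracle_growth <- function(f, p_axis, dp, env, params) {
  alpha <- exp(-outer(p_axis, p_axis, "-")^2 / (4 * params$V))
  compet <- f %*% alpha * dp                      # integral alpha(p,p') f(x,p') dp'
  Q <- env$Q[, 1]
  mism2 <- outer(Q, p_axis, function(Qx, p) (p - Qx)^2)
  params$R * (1 - compet / env$K[, 1]) - (params$S / 2) * mism2
}

oracle_rhs <- function(state, env, params) {
  f <- state$f
  grid <- state$grid
  p <- state$p_axis
  dp <- state$dp
  dx <- grid$dx[1]
  nx <- nrow(f)
  np <- ncol(f)

  ## diffusion in x (reflecting: clamped ghost rows)
  f_up <- f[c(2:nx, nx), , drop = FALSE]
  f_dn <- f[c(1, 1:(nx - 1)), , drop = FALSE]
  diff_x <- params$D[1] * (f_up - 2 * f + f_dn) / dx^2

  ## per-phenotype advection in conservative flux form with centred face
  ## values (the oracle runs on smooth Gaussian data, where upwinding would
  ## add phenotype-dependent numerical diffusion); zero flux at the walls
  pg <- env_pg(env, grid, params)$g1[, 1]
  Q <- env$Q[, 1]
  u <- params$A * (matrix(p, nx, np, byrow = TRUE) - Q) / params$V * pg
  u_face <- 0.5 * (u + u[c(2:nx, nx), , drop = FALSE])
  f_next <- f[c(2:nx, nx), , drop = FALSE]
  Fp <- u_face * 0.5 * (f + f_next)
  Fp[nx, ] <- 0
  Fm <- Fp[c(1, 1:(nx - 1)), , drop = FALSE]
  Fm[1, ] <- 0
  adv_x <- -(Fp - Fm) / dx

  ## growth with competition convolution
  growth <- oracle_growth(f, p, dp, env, params) * f

  ## mutation: diffusion along p with coefficient U/2, absorbing tails
  f_pp <- f[, c(2:np, np), drop = FALSE]; f_pp[, np] <- 0
  f_pm <- f[, c(1, 1:(np - 1)), drop = FALSE]; f_pm[, 1] <- 0
  mut <- (params$U / 2) * (f_pp - 2 * f + f_pm) / dp^2

  diff_x + adv_x + growth + mut
}

#' Advance the phenotype-resolved density
#'
#' One explicit Heun step of the phenotype-resolved dynamics: diffusion in
#' space, directed advection with the per-phenotype velocity
#' `A (p - Q)/V` times the perceived gradient, intrinsic growth with the
#' competition convolution evaluated by quadrature, and mutation as
#' phenotype diffusion with coefficient `U/2` (so that trait variance grows
#' at rate `U` in isolation).
#'
#' @param state a [phenotype_grid_state].
#' @param env an [environment_field] on the same spatial grid.
#' @param params a [model_params].
#' @param dt time step, `T`; must satisfy the explicit stability bounds.
#' @return the advanced [phenotype_grid_state].
#' @export
step_phenotype_density <- function(state, env, params, dt) {
  k1 <- oracle_rhs(state, env, params)
  mid <- state
  mid$f <- pmax(state$f + dt * k1, 0)
  k2 <- oracle_rhs(mid, env, params)
  f_new <- state$f + dt / 2 * (k1 + k2)
  if (min(f_new) < -1e-6 * max(abs(f_new)))
    stop("stability error: phenotype density became significantly negative")
  state$f <- pmax(f_new, 0)
  state$t <- state$t + dt
  state
}

#' Extract population moments from a phenotype-resolved state
#'
#' Integrates the phenotype density along the phenotype axis to recover
#' density, trait mean and trait variance. Cells whose density falls below
#' `eps` report `NA` mean and variance (moments of an empty population are
#' undefined).
#'
#' @param state a [phenotype_grid_state].
#' @param eps density threshold below which moments are undefined.
#' @return a [population_state] (with `NA` trait fields where undefined;
#'   note these fail `population_state` validation, so the object is
#'   assembled directly).
#' @export
extract_moments <- function(state, eps = 1e-12) {
  f <- state$f
  p <- state$p_axis
  dp <- state$dp
  n <- rowSums(f) * dp
  q <- as.numeric(f %*% p) * dp / ifelse(n > eps, n, NA)
  v <- vapply(seq_along(n), function(i) {
    if (is.na(q[i])) return(NA_real_)
    sum(f[i, ] * (p - q[i])^2) * dp / n[i]
  }, numeric(1))
  out <- list(n = matrix(n, ncol = 1), q = matrix(q, ncol = 1),
              v = matrix(v, ncol = 1), t = state$t)
  class(out) <- "population_state"
  out
}

#' Moment rates from the phenotype-resolved model
#'
#' Computes the instantaneous rates of change of `(n, q, v)` implied by the
#' phenotype-resolved right-hand side, for direct comparison against the
#' closed three-field model: `dn = integral of df`, and the chain-rule
#' expressions for the mean and variance of a normalised density.
#'
#' @param state a [phenotype_grid_state].
#' @param env an [environment_field].
#' @param params a [model_params].
#' @param eps density threshold below which rates are reported `NA`.
#' @return list of vectors `dn`, `dq`, `dv` along the spatial grid.
#' @export
oracle_moment_rates <- function(state, env, params, eps = 1e-8) {
  df <- oracle_rhs(state, env, params)
  f <- state$f
  p <- state$p_axis
  dp <- state$dp
  n <- rowSums(f) * dp
  ok <- n > eps
  q <- ifelse(ok, as.numeric(f %*% p) * dp / n, NA)
  dn <- rowSums(df) * dp
  dM1 <- as.numeric(df %*% p) * dp              # d/dt integral p f dp
  dq <- ifelse(ok, (dM1 - q * dn) / n, NA)
  v <- vapply(seq_along(n), function(i) {
    if (!ok[i]) return(NA_real_)
    sum(f[i, ] * (p - q[i])^2) * dp / n[i]
  }, numeric(1))
  dM2 <- vapply(seq_along(n), function(i) {
    if (!ok[i]) return(NA_real_)
    sum(df[i, ] * (p - q[i])^2) * dp
  }, numeric(1))
  dv <- ifelse(ok, (dM2 - v * dn) / n, NA)
  list(dn = dn, dq = dq, dv = dv)
}
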