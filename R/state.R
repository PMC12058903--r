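#' Population state
#'
#' The three co-evolving fields of the model at one time point: population
#' density `n` (`N/X^m`), trait mean `q` (`Q`) and trait variance `v`
#' (`Q^2`). Trait mean and variance are dynamically defined everywhere but
#' only biologically meaningful inside the effective range (where `n` is
#' appreciable); see [cap_variance] for reporting.
#'
#' @param n,q,v density, trait-mean and trait-variance fields (scalar,
#'   vector or matrix on the grid).
#' @param t current time, `T`.
#' @param grid a [habitat_grid].
#' @return an object of class `population_state`.
#' @export
population_state <- function(n, q, v, t = 0, grid) {
  n <- as_field(n, grid); q <- as_field(q, grid); v <- as_field(v, grid)
  if (!all(is.finite(n)) || !all(is.finite(q)) || !all(is.finite(v)))
    stop("population state fields must be finite")
  if (any(n < 0)) stop("population density must be nonnegative")
  if (any(v < 0)) stop("trait variance must be nonnegative")
  s <- list(n = n, q = q, v = v, t = t)
  class(s) <- "population_state"
  s
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state at t = %g T: max n = %.4g, q in [%.3g, %.3g], max v = %.4g\n",
              x$t, max(x$n), min(x$q), max(x$q), max(x$v)))
  invisible(x)
}

#' Cap trait variance for reporting
#'
#' Trait variance grows without biological meaning outside the effective
#' range of the species. For plotting and reporting it is capped at
#' `v_max`; the cap is purely diagnostic and is never fed back into the
#' dynamics.
#'
#' @param state a [population_state].
#' @param v_max reporting cap, `Q^2`.
#' @return the state with `v` clipped to `[0, v_max]`.
#' @export
cap_variance <- function(state, v_max = 100) {
  state$v <- pmin(state$v, v_max)
  state
}

#' Expansion-front initial condition
#'
#' The standard seeding profile for range-expansion runs: a hyperbolic-
#' secant density pulse at the habitat centre, a trait mean whose gradient
#' is a fraction of the environmental gradient and which matches the
#' optimum exactly at the centre (a perfectly adapted core), and constant
#' trait variance.
#'
#' @param grid a [habitat_grid] (centred at the origin).
#' @param env an [environment_field].
#' @param n0 peak density of the seed pulse, `N/X^m`.
#' @param q_gradient_frac initial trait-mean gradient as a fraction of the
#'   environmental gradient.
#' @param v0 initial trait variance, `Q^2`.
#' @return a [population_state] at `t = 0`.
#' @examples
#' g <- habitat_grid(c(-50, 50), 400)
#' env <- linear_optimum(g, 1.5)
#' s0 <- expansion_initial_state(g, env)   # n(0,0) = 0.5, q(0,0) = Q(0)
#' @export
expansion_initial_state <- function(grid, env, n0 = 0.5,
                                    q_gradient_frac = 0.6, v0 = 1) {
  r <- sqrt(grid$X1^2 + grid$X2^2)
  n <- n0 / cosh(r / sqrt(2))
  ic <- cell_index(grid, c(0, 0))
  Qc <- env$Q[ic[1], ic[2]]
  q <- Qc + q_gradient_frac * (env$Q - Qc)
  population_state(n, q, matrix(v0, grid$nx[1], grid$nx[2]), t = 0, grid = grid)
}

#' Established initial condition for fluctuation runs
#'
#' Builds the seeding profile used in the fluctuating-optimum experiments
#' (sech pulse of peak 0.8, trait-mean gradient 0.7 of the environmental
#' gradient, unit variance) and then integrates it for `t_establish` time
#' units in the static environment, returning the resulting established
#' population with its clock reset to zero.
#'
#' @param grid a [habitat_grid].
#' @param env an [environment_field].
#' @param params a [model_params].
#' @param t_establish length of the preliminary run, `T`.
#' @param options a [solver_options] for the preliminary run.
#' @return a [population_state] at `t = 0`.
#' @export
fluctuation_initial_state <- function(grid, env, params, t_establish = 4,
                                      options = solver_options()) {
  s0 <- expansion_initial_state(grid, env, n0 = 0.8, q_gradient_frac = 0.7,
                                v0 = 1)
  options$t_end <- t_establish
  options$record_every <- t_establish
  traj <- integrate_model(s0, env, params, grid, options)
  s <- traj$states[[length(traj$states)]]
  s$t <- 0
  s
}
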