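#' Time-integration options
#'
#' @param dt optional fixed upper bound on the step, `T`; by default the
#'   step is chosen adaptively from the explicit stability bounds.
#' @param cfl_safety fraction of the explicit stability bound actually used
#'   (0 < `cfl_safety` <= 1).
#' @param advection_scheme `"upwind"` (default; positivity-preserving) or
#'   `"central"`.
#' @param t_end integration horizon, `T`.
#' @param record_every interval between recorded states, `T`.
#' @param clip_negative clip small negative densities/variances produced by
#'   round-off after each step.
#' @param v_cap in-dynamics safeguard cap on trait variance, `Q^2`
#'   (triggered only if variance diverges outside the effective range).
#' @param max_clip_fraction abort threshold: clipped mass per step relative
#'   to total population mass.
#' @return an object of class `solver_options`.
#' @export
solver_options <- function(dt = NULL, cfl_safety = 0.9,
                           advection_scheme = c("upwind", "central"),
                           t_end = 40, record_every = 1,
                           clip_negative = TRUE, v_cap = 1e4,
                           max_clip_fraction = 1e-6) {
  advection_scheme <- match.arg(advection_scheme)
  stopifnot(cfl_safety > 0, cfl_safety <= 1, t_end > 0, record_every > 0)
  if (!is.null(dt)) stopifnot(dt > 0, record_every >= dt)
  o <- list(dt = dt, cfl_safety = cfl_safety,
            advection_scheme = advection_scheme, t_end = t_end,
            record_every = record_every, clip_negative = clip_negative,
            v_cap = v_cap, max_clip_fraction = max_clip_fraction)
  class(o) <- "solver_options"
  o
}

## per-axis maximum effective advection speeds for the CFL bound:
## mismatch velocity (density and q/v advection), v-weighted directed
## velocity, and the random-gene-flow velocity 2 D grad(log n)
max_speeds <- function(state, env, params, grid) {
  pg <- env_pg(env, grid, params)
  v <- pmax(state$v, 0)
  mis <- abs(state$q - env$Q)
  phi <- params$A * pmax(mis, v) / params$V
  s1 <- max(phi * abs(pg$g1) +
              2 * params$D[1] * abs(grad_log_field(state$n, grid, 1L)))
  s2 <- if (grid$m == 2L)
    max(phi * abs(pg$g2) +
          2 * params$D[2] * abs(grad_log_field(state$n, grid, 2L)))
  else 0
  c(s1, s2)
}

#' Integrate the coupled model
#'
#' Advances the population state with an explicit second-order Runge-Kutta
#' (Heun) method on the method-of-lines system. The step size is chosen each
#' step as `cfl_safety` times the harmonic combination of the diffusive
#' bound `1 / (2 sum_i D_i/dx_i^2)` and the advective bound
#' `dx_i / max speed` (the combined explicit limit is tighter than either
#' bound alone), further capped by the inverse of the largest local
#' growth/decay rate over live cells (strong maladaptation makes the
#' reaction stiff), and is additionally shortened so that steps land exactly on recording
#' times and optimum-shift events. Boundary conditions (reflecting /
#' periodic per grid axis) are built into the discrete operators.
#'
#' @param state0 initial [population_state].
#' @param env an [environment_field].
#' @param params a [model_params].
#' @param grid a [habitat_grid].
#' @param options a [solver_options].
#' @param schedule optional [shift_schedule] of abrupt optimum shifts,
#'   applied as instantaneous replacement of the optimum between steps.
#' @return an object of class `trajectory`: recorded `times`, `states`,
#'   the `events` applied, the run's grid/params/env, a log of clipped mass,
#'   and a `completed` flag (FALSE if the integration aborted on a
#'   non-finite state, in which case the last valid state is kept).
#' @examples
#' g <- habitat_grid(c(-20, 20), 160)
#' p <- model_params(A = 10)
#' env <- linear_optimum(g, 1.5, params = p)
#' s0 <- expansion_initial_state(g, env)
#' traj <- integrate_model(s0, env, p, g, solver_options(t_end = 2))
#' @export
integrate_model <- function(state0, env, params, grid,
                            options = solver_options(), schedule = NULL) {
  check_params_grid(params, grid)
  if (is.null(env$pg)) env$pg <- perceived_gradient(env, grid, params)
  scheme <- options$advection_scheme
  t <- state0$t
  t_end <- options$t_end
  record_times <- seq(t, t_end, by = options$record_every)
  if (record_times[length(record_times)] < t_end - 1e-12)
    record_times <- c(record_times, t_end)
  event_times <- if (!is.null(schedule))
    seq(0, t_end, by = schedule$period / 2) else numeric(0)
  stops <- sort(unique(c(record_times, event_times, t_end)))
  stops <- stops[stops > t + 1e-12]

  diff_bound <- 1 / (2 * sum(params$D[seq_len(grid$m)] /
                               grid$dx[seq_len(grid$m)]^2))
  cellvol <- grid$cell_volume

  state <- state0
  times <- state$t
  states <- list(state)
  events <- data.frame(time = numeric(0), shift = numeric(0))
  clipped <- 0
  completed <- TRUE

  env_eff <- apply_schedule(env, schedule, t)
  if (!is.null(schedule))
    events <- rbind(events, data.frame(time = t, shift = env_eff$shift))

  next_stop_idx <- 1L
  while (t < t_end - 1e-12) {
    sp <- max_speeds(state, env_eff, params, grid)
    adv_bound <- suppressWarnings(
      min(grid$dx[seq_len(grid$m)][sp[seq_len(grid$m)] > 0] /
            sp[seq_len(grid$m)][sp[seq_len(grid$m)] > 0]))
    if (!is.finite(adv_bound)) adv_bound <- Inf
    ## harmonic combination: the explicit limit when diffusion and advection
    ## act together is tighter than the minimum of the separate bounds
    dt <- options$cfl_safety / (1 / diff_bound + 1 / adv_bound)
    ## reaction bound: where the population is alive, one step must not
    ## overshoot a stiff local decay (strong maladaptation load)
    live <- state$n > 1e-8
    if (any(live)) {
      vv <- pmax(state$v, 0)
      rate <- abs(params$R - (params$R / env_eff$K) *
                    sqrt(params$V / (vv + params$V)) * state$n -
                    (params$S / 2) * ((state$q - env_eff$Q)^2 + vv))
      dt <- min(dt, options$cfl_safety / max(rate[live], 1e-12))
    }
    if (!is.null(options$dt)) dt <- min(dt, options$dt)
    stop_t <- stops[next_stop_idx]
    dt <- min(dt, stop_t - t)

    k1 <- model_rhs(state, env_eff, params, grid, scheme)
    mid <- list(n = state$n + dt * k1$dn, q = state$q + dt * k1$dq,
                v = state$v + dt * k1$dv)
    mid$n[mid$n < 0] <- 0
    mid$v[mid$v < 0] <- 0
    class(mid) <- "population_state"
    k2 <- model_rhs(mid, env_eff, params, grid, scheme)
    n_new <- state$n + dt / 2 * (k1$dn + k2$dn)
    q_new <- state$q + dt / 2 * (k1$dq + k2$dq)
    v_new <- state$v + dt / 2 * (k1$dv + k2$dv)

    if (!all(is.finite(n_new)) || !all(is.finite(q_new)) ||
        !all(is.finite(v_new))) {
      warning("non-finite state at t = ", signif(t, 6),
              "; aborting with last valid state")
      completed <- FALSE
      break
    }

    if (options$clip_negative) {
      neg_mass <- -sum(n_new[n_new < 0]) * cellvol
      tot_mass <- sum(abs(n_new)) * cellvol
      if (tot_mass > 0 && neg_mass > options$max_clip_fraction * tot_mass)
        stop("stability error: clipped density mass ", signif(neg_mass, 3),
             " exceeds safeguard at t = ", signif(t, 6))
      clipped <- clipped + neg_mass
      n_new[n_new < 0] <- 0
      v_new[v_new < 0] <- 0
      v_new[v_new > options$v_cap] <- options$v_cap
    }

    t <- t + dt
    state <- list(n = n_new, q = q_new, v = v_new, t = t)
    class(state) <- "population_state"

    if (abs(t - stop_t) < 1e-10) {
      if (stop_t %in% event_times && !is.null(schedule)) {
        env_eff <- apply_schedule(env, schedule, t)
        events <- rbind(events, data.frame(time = t, shift = env_eff$shift))
      }
      if (any(abs(record_times - t) < 1e-9)) {
        times <- c(times, t)
        states[[length(states) + 1L]] <- state
      }
      next_stop_idx <- next_stop_idx + 1L
      if (next_stop_idx > length(stops)) break
    }
  }

  traj <- list(times = times, states = states, events = events,
               grid = grid, params = params, env = env, schedule = schedule,
               clipped_mass = clipped, completed = completed)
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d states over t = [%g, %g] T on a %dD grid\n",
              length(x$times), min(x$times), max(x$times), x$grid$m))
  if (!x$completed) cat("  (integration aborted before the horizon)\n")
  invisible(x)
}

#' Extract the final state of a trajectory
#' @param traj a `trajectory`.
#' @return the last recorded [population_state].
#' @export
final_state <- function(traj) traj$states[[length(traj$states)]]
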