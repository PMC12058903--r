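#' Effective range edges of a density profile
#'
#' The effective edges of an expanding population are the inflection points
#' of its density profile: the outermost zero crossings of the discrete
#' second derivative on each flank of the wave, refined by local linear
#' interpolation. Crossings in the essentially empty tail (density below
#' `n_floor` times the peak) are ignored.
#'
#' @param n_profile 1D density profile (vector, or single-column field).
#' @param grid a 1D [habitat_grid] (or the grid whose axis-1 coordinates
#'   match the profile).
#' @param n_floor relative density floor for edge detection.
#' @return named numeric vector `c(left =, right =)` of edge positions, `X`;
#'   `NA` where no inflection exists (flat or monotone profile).
#' @examples
#' g <- habitat_grid(c(-20, 20), 400)
#' edges <- effective_edges(1 / cosh(g$x1 / sqrt(2)), g)
#' # ~ +-sqrt(2) * acosh(sqrt(2)) = +-1.2465
#' @export
effective_edges <- function(n_profile, grid, n_floor = 1e-3) {
  n <- as.numeric(n_profile)
  x <- grid$x1
  stopifnot(length(n) == length(x))
  peak <- max(n)
  if (peak <= 0 || stats::sd(n) < 1e-14)
    return(c(left = NA_real_, right = NA_real_))
  dx <- grid$dx[1]
  i_peak <- which.max(n)
  d2 <- c(NA, diff(n, differences = 2), NA) / dx^2
  live <- n > n_floor * peak

  find_edge <- function(idx) {
    ## outermost sign change of d2 along idx (ordered core -> tail)
    cross <- NA_real_
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if (!live[i] || is.na(d2[i]) || is.na(d2[j])) next
      if (d2[i] == 0) cross <- x[i]
      else if (d2[i] * d2[j] < 0)
        cross <- x[i] + (x[j] - x[i]) * d2[i] / (d2[i] - d2[j])
    }
    cross
  }
  c(left = find_edge(rev(seq_len(i_peak))),
    right = find_edge(seq(i_peak, length(n))))
}

#' Travelling-wave metrics of a trajectory
#'
#' Measures the approximate speed and amplitude of the expansion wave, and
#' the trait variance attained at the habitat centre: the speed is the
#' least-squares slope of the right effective-edge position against time
#' over the requested window (the caller excludes the initial transient),
#' the amplitude is the peak density of the final recorded state, and the
#' core variance is the trait variance at the habitat centre at the final
#' state.
#'
#' @param traj a `trajectory` (1D).
#' @param window time interval `c(t0, t1)` for the speed fit; defaults to
#'   the second half of the trajectory.
#' @return an object of class `wave_metrics`: `speed` (`X/T`), `amplitude`
#'   (`N/X^m`), `core_variance` (`Q^2`) and the per-time `edge_positions`.
#' @export
wave_metrics <- function(traj, window = NULL) {
  times <- traj$times
  default_window <- is.null(window)
  if (default_window) window <- c(mean(range(times)), max(times))
  sel <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(sel) < 3L && default_window) sel <- seq_along(times)
  if (length(sel) < 3L) stop("insufficient data: fewer than 3 records in window")
  edges <- t(vapply(traj$states, function(s)
    effective_edges(s$n[, 1], traj$grid), c(left = 0, right = 0)))
  right <- edges[sel, "right"]
  ok <- is.finite(right)
  speed <- if (sum(ok) >= 3L)
    unname(stats::coef(stats::lm(right[ok] ~ times[sel][ok]))[2]) else NA_real_
  fin <- final_state(traj)
  ic <- cell_index(traj$grid, c(0, 0))
  m <- list(speed = speed, amplitude = max(fin$n),
            core_variance = fin$v[ic[1], ic[2]],
            edge_positions = data.frame(time = times, edges))
  class(m) <- "wave_metrics"
  m
}

#' @export
print.wave_metrics <- function(x, ...) {
  cat(sprintf("wave_metrics: speed = %.4g X/T, amplitude = %.4g, core variance = %.4g Q^2\n",
              x$speed, x$amplitude, x$core_variance))
  invisible(x)
}

#' Time to local adaptation
#'
#' First recorded time at which the trait mean matches the local optimum
#' within `tolerance` at the given location, sustained through all later
#' records; `Inf` if the tolerance is never reached and held.
#'
#' @param traj a `trajectory`.
#' @param location physical location (defaults to the habitat centre).
#' @param tolerance adaptation tolerance on `|q - Q|`, `Q`.
#' @return time in `T`, or `Inf`.
#' @export
adaptation_time <- function(traj, location = c(0, 0), tolerance = 0.1) {
  ic <- cell_index(traj$grid, location)
  Q <- traj$env$Q[ic[1], ic[2]]
  mis <- vapply(traj$states, function(s) abs(s$q[ic[1], ic[2]] - Q), numeric(1))
  ok <- mis <= tolerance
  sustained <- rev(cumprod(rev(ok))) > 0
  if (!any(sustained)) return(Inf)
  traj$times[which(sustained)[1]]
}

#' Steady-state mean peak density under periodic fluctuations
#'
#' For a run with a periodic optimum-shift schedule, extracts the series of
#' peak (spatial maximum) densities, locates the extrema of the final
#' fluctuation cycle, checks that the cycle amplitude is steady (relative
#' change of the extrema below `steady_tol` over the last two periods) and
#' returns the mean of the steady minimum and maximum.
#'
#' @param traj a `trajectory` integrated with a schedule.
#' @param schedule the [shift_schedule] used (defaults to the trajectory's).
#' @param steady_tol relative steadiness tolerance.
#' @return list with `mean_density`, `cycle_min`, `cycle_max`, `steady`
#'   (logical; a warning is raised and the last-cycle value returned when
#'   not converged) and `extinct`.
#' @export
fluctuation_mean_density <- function(traj, schedule = traj$schedule,
                                     steady_tol = 0.01) {
  peaks <- vapply(traj$states, function(s) max(s$n), numeric(1))
  times <- traj$times
  if (is.null(schedule) || schedule$amplitude == 0) {
    val <- peaks[length(peaks)]
    return(list(mean_density = val, cycle_min = val, cycle_max = val,
                steady = TRUE, extinct = val < 1e-3))
  }
  period <- schedule$period
  t_end <- max(times)
  cyc <- function(k) {
    sel <- times > t_end - k * period - 1e-9 &
      times <= t_end - (k - 1) * period + 1e-9
    c(min(peaks[sel]), max(peaks[sel]))
  }
  last <- cyc(1); prev <- cyc(2); prev2 <- cyc(3)
  ref <- max(last, 1e-12)
  steady <- all(abs(last - prev) <= steady_tol * ref) &&
    all(abs(prev - prev2) <= steady_tol * max(prev, 1e-12))
  if (!steady)
    warning("peak-density cycle not steady; returning last-cycle value")
  extinct <- max(last) < 1e-3
  list(mean_density = mean(last), cycle_min = last[1], cycle_max = last[2],
       steady = steady, extinct = extinct)
}

#' Classify a completed run as extinct
#'
#' A run is classed extinct when the maximum density over the habitat at
#' the final time is below the extinction floor and the peak-density series
#' has been decreasing over the last three recorded periods (or records,
#' for unscheduled runs).
#'
#' @param traj a `trajectory`.
#' @param params a [model_params] (uses `extinction_floor`).
#' @return logical.
#' @export
classify_extinction <- function(traj, params = traj$params) {
  peaks <- vapply(traj$states, function(s) max(s$n), numeric(1))
  fin <- peaks[length(peaks)]
  if (fin >= params$extinction_floor) return(FALSE)
  if (fin == 0) return(TRUE)
  k <- length(peaks)
  if (!is.null(traj$schedule)) {
    per_rec <- max(1L, round(traj$schedule$period /
                               max(diff(traj$times)[1], 1e-12)))
    idx <- unique(pmax(1L, k - (0:3) * per_rec))
  } else {
    idx <- pmax(1L, k - 0:3)
  }
  all(diff(peaks[rev(idx)]) <= 1e-12)
}

#' Tidy metrics row for a run
#'
#' One-row data frame of the headline diagnostics, suitable for appending
#' to a sweep CSV.
#'
#' @param traj a 1D `trajectory`.
#' @param window speed-fit window, as in [wave_metrics].
#' @return a data frame.
#' @export
run_metrics <- function(traj, window = NULL) {
  wm <- wave_metrics(traj, window)
  p <- traj$params
  data.frame(A = p$A, R = p$R, S = p$S, V = p$V, U = p$U,
             speed = wm$speed, amplitude = wm$amplitude,
             core_variance = wm$core_variance,
             adaptation_time = adaptation_time(traj),
             extinct = classify_extinction(traj))
}
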