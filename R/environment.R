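#' Environmental fields: trait optimum and carrying capacity
#'
#' Bundles the optimum trait field `Q(x)`, the carrying-capacity field
#' `K(x)`, the exact spatial gradient of `Q`, and (when parameters are
#' supplied) the perceived gradient that directed dispersal acts on.
#'
#' @param grid a [habitat_grid].
#' @param Q optimum trait field (scalar, vector or matrix), units `Q`.
#' @param K carrying-capacity field, `N/X^m`; must be positive everywhere.
#' @param params optional [model_params]; if given, the perceived gradient is
#'   precomputed and cached in the returned object.
#' @param gradQ optional list `list(g1, g2)` with the exact gradient
#'   components of `Q`; computed by central differences when omitted (an
#'   analytic gradient is attached by [linear_optimum]).
#' @return an object of class `environment_field` with elements `Q`, `K`,
#'   `gradQ` and (if `params` given) `pg`, the perceived gradient.
#' @seealso [linear_optimum], [perceived_gradient], [apply_schedule]
#' @export
environment_field <- function(grid, Q, K = 1, params = NULL, gradQ = NULL) {
  Q <- as_field(Q, grid)
  K <- as_field(K, grid)
  if (!all(is.finite(Q))) stop("Q must be finite everywhere")
  if (any(K <= 0)) stop("carrying capacity K must be positive everywhere")
  if (is.null(gradQ)) {
    gradQ <- list(g1 = grad_axis(Q, grid, 1L), g2 = grad_axis(Q, grid, 2L))
  } else {
    gradQ <- list(g1 = as_field(gradQ[[1]], grid), g2 = as_field(gradQ[[2]], grid))
  }
  env <- list(Q = Q, K = K, gradQ = gradQ, pg = NULL, shift = 0)
  class(env) <- "environment_field"
  if (!is.null(params)) env$pg <- perceived_gradient(env, grid, params)
  env
}

#' Perceived environmental gradient
#'
#' The gradient of the trait optimum as acted on by dispersing individuals:
#' the exact gradient is rescaled by the saturation factor
#' `Pi / (Pi + ||grad Q||)`, so its magnitude never exceeds `Pi` while its
#' direction always matches the actual gradient. Near each reflecting
#' boundary the boundary-normal component is additionally multiplied by a
#' smooth half-cosine ramp `sin^2(pi d / (2 delta))` of the distance `d` to
#' the wall, so that individuals sense the boundary and never attempt to
#' cross it; periodic axes are untouched.
#'
#' @param env an [environment_field].
#' @param grid a [habitat_grid].
#' @param params a [model_params] (uses `Pi` and `delta`).
#' @return list `list(g1, g2)` of perceived-gradient component fields, `Q/X`.
#' @examples
#' g <- habitat_grid(c(-50, 50), 400)
#' env <- linear_optimum(g, slope = 1.5)
#' pg <- perceived_gradient(env, g, model_params())
#' max(abs(pg$g1))  # <= Pi
#' @export
perceived_gradient <- function(env, grid, params) {
  g1 <- env$gradQ$g1
  g2 <- env$gradQ$g2
  if (!all(is.finite(g1)) || !all(is.finite(g2)))
    stop("invalid field: non-finite gradient of Q")
  nrm <- sqrt(g1^2 + g2^2)
  ups <- params$Pi / (params$Pi + nrm)
  p1 <- ups * g1
  p2 <- ups * g2
  if (params$delta > 0) {
    if (grid$boundary[1] == "reflecting")
      p1 <- p1 * boundary_ramp(grid$X1, grid$extents[[1]], params$delta)
    if (grid$m == 2L && grid$boundary[2] == "reflecting")
      p2 <- p2 * boundary_ramp(grid$X2, grid$extents[[2]], params$delta)
  }
  list(g1 = p1, g2 = p2)
}

boundary_ramp <- function(X, ext, delta) {
  d <- pmin(X - ext[1], ext[2] - X)
  w <- matrix(1, nrow(X), ncol(X))
  sel <- d < delta
  w[sel] <- sin(pi * d[sel] / (2 * delta))^2
  w
}

#' Linear trait optimum
#'
#' Builds an environment whose trait optimum increases linearly along axis 1
#' (and is constant along axis 2 in 2D), with an exact analytic gradient.
#'
#' @param grid a [habitat_grid].
#' @param slope gradient of the optimum along axis 1, `Q/X` (>= 0).
#' @param origin_value optimum value at `x1 = 0`, units `Q`.
#' @param K carrying capacity (scalar or field).
#' @param params optional [model_params] to precompute the perceived gradient.
#' @return an [environment_field].
#' @export
linear_optimum <- function(grid, slope, origin_value = 0, K = 1, params = NULL) {
  stopifnot(slope >= 0)
  Q <- origin_value + slope * grid$X1
  environment_field(grid, Q, K, params,
                    gradQ = list(matrix(slope, grid$nx[1], grid$nx[2]),
                                 matrix(0, grid$nx[1], grid$nx[2])))
}

#' Periodic abrupt shifts of the trait optimum
#'
#' Describes square-wave fluctuations of the environment: at the start of
#' each period the whole optimum field is shifted up by `amplitude` (with no
#' change in its gradient); at the midpoint it is shifted back down. The
#' pattern repeats from `t = 0`.
#'
#' @param period fluctuation period, `T` (> 0).
#' @param amplitude shift amplitude, `Q` (>= 0).
#' @return an object of class `shift_schedule`.
#' @export
shift_schedule <- function(period, amplitude) {
  stopifnot(period > 0, amplitude >= 0)
  s <- list(period = period, amplitude = amplitude)
  class(s) <- "shift_schedule"
  s
}

#' Apply a shift schedule at a given time
#'
#' Returns the environment with the optimum shifted according to the
#' schedule phase at time `t`: raised by the amplitude during the first half
#' of each period, back at its base value during the second half. The
#' gradient (and hence the perceived gradient) is unchanged. Idempotent: the
#' shift is applied relative to the stored base optimum.
#'
#' @param env an [environment_field].
#' @param schedule a [shift_schedule] (or `NULL` for no change).
#' @param t time, `T`.
#' @return the environment effective at time `t`.
#' @export
apply_schedule <- function(env, schedule, t) {
  if (is.null(schedule)) return(env)
  stopifnot(t >= 0)
  up <- (t %% schedule$period) < schedule$period / 2
  offset <- if (up) schedule$amplitude else 0
  if (offset == env$shift) return(env)
  env$Q <- env$Q + (offset - env$shift)
  env$shift <- offset
  env
}
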