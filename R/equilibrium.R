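#' Equilibrium trait variance of the adapted homogeneous population
#'
#' Far from the habitat boundary, the expanding population converges to a
#' spatially homogeneous state with trait mean equal to the optimum. Its
#' trait variance `v*` is the positive real root of a cubic whose
#' coefficients combine mutation, gene-flow inflation by the environmental
#' gradient, directed-dispersal deflation and selection:
#' \deqn{5 S v^3 + (4SV - 2R + 8 (A/V) \Upsilon g^2) v^2
#'       - 4 (U + 2 D g^2 - 2 (A/V) \Upsilon g^2 V) v
#'       - 4 (U + 2 D g^2) V = 0,}
#' with `g` the gradient magnitude and `Upsilon = Pi/(Pi + g)` the
#' perception saturation factor. When several positive roots exist the one
#' continuous in `g` from the zero-gradient branch is selected.
#'
#' @param params a [model_params] (1D; uses `D[1]`).
#' @param grad_mag magnitude of the environmental gradient, `Q/X` (>= 0).
#' @return list with `v_star` (`Q^2`) and `converged`.
#' @examples
#' equilibrium_variance(model_params(A = 0), 0)$v_star  # ~ 1.12
#' @export
equilibrium_variance <- function(params, grad_mag) {
  stopifnot(grad_mag >= 0)
  ## track the positive branch continuously from g = 0
  gs <- if (grad_mag == 0) 0 else seq(0, grad_mag, length.out = 16L)
  v_prev <- NA_real_
  for (g in gs) {
    roots <- variance_cubic_roots(params, g)
    if (length(roots) == 0L)
      return(list(v_star = NA_real_, converged = FALSE))
    v_prev <- if (is.na(v_prev)) min(roots)
    else roots[which.min(abs(roots - v_prev))]
  }
  list(v_star = v_prev, converged = TRUE)
}

variance_cubic_roots <- function(params, g) {
  D <- params$D[1]; A <- params$A; V <- params$V
  S <- params$S; R <- params$R; U <- params$U
  ups <- params$Pi / (params$Pi + g)
  co <- c(-4 * (U + 2 * D * g^2) * V,
          -4 * (U + 2 * D * g^2 - 2 * (A / V) * ups * g^2 * V),
          4 * S * V - 2 * R + 8 * (A / V) * ups * g^2,
          5 * S)
  z <- polyroot(co)
  re <- Re(z[abs(Im(z)) < 1e-8 * (1 + abs(Re(z)))])
  sort(re[re > 0])
}

#' Equilibrium population density of the adapted homogeneous population
#'
#' Given the equilibrium trait variance, the homogeneous adapted density is
#' \deqn{n^* = (K/R) \sqrt{(v^* + V)/V} (R - S v^*/2),}
#' floored at zero: the square-root factor is the competitive release of a
#' phenotypically variable population, and the bracket is growth net of the
#' phenotypic load.
#'
#' @param params a [model_params].
#' @param grad_mag gradient magnitude, `Q/X`.
#' @param K carrying capacity, `N/X^m`.
#' @param v_star optional precomputed equilibrium variance.
#' @return an object of class `equilibrium_result` with `v_star`, `n_star`,
#'   `grad_mag` and `converged`.
#' @export
equilibrium_density <- function(params, grad_mag, K = 1, v_star = NULL) {
  if (is.null(v_star)) {
    eq <- equilibrium_variance(params, grad_mag)
  } else {
    eq <- list(v_star = v_star, converged = TRUE)
  }
  n_star <- if (is.na(eq$v_star)) NA_real_ else
    max(0, (K / params$R) * sqrt((eq$v_star + params$V) / params$V) *
          (params$R - params$S / 2 * eq$v_star))
  out <- list(v_star = eq$v_star, n_star = n_star, grad_mag = grad_mag,
              converged = eq$converged)
  class(out) <- "equilibrium_result"
  out
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("equilibrium at g = %g: v* = %.4g Q^2, n* = %.4g\n",
              x$grad_mag, x$v_star, x$n_star))
  invisible(x)
}

#' Critical environmental gradient
#'
#' The gradient magnitude beyond which the adapted homogeneous population
#' cannot persist (`n* = 0`, at which point `v* = 2R/S`). It solves the
#' implicit equation
#' \deqn{g^2 = (4R^2 - SU) / (2 (SD - 2R (A/V) \Upsilon(g))),}
#' with the saturation factor evaluated at the solution; solved here by
#' bracketed root finding on the interval where the denominator is
#' positive. For purely random dispersal (`A = 0`) the closed form
#' `sqrt(2R^2/(SD) - U/(2D))` is returned. If no finite solution exists
#' below `g_max`, `Inf` is returned (extinction by gradient alone is then
#' unreachable).
#'
#' @param params a [model_params].
#' @param g_max upper end of the search bracket, `Q/X`.
#' @return list with `grad_mag` (`Q/X`, possibly `Inf`) and `converged`.
#' @examples
#' critical_gradient(model_params(A = 0, U = 0))$grad_mag  # sqrt(40) ~ 6.325
#' @export
critical_gradient <- function(params, g_max = 1e3) {
  D <- params$D[1]; A <- params$A; V <- params$V
  S <- params$S; R <- params$R; U <- params$U; Pi <- params$Pi
  if (S <= 0 || 4 * R^2 - S * U <= 0)
    return(list(grad_mag = Inf, converged = TRUE))
  if (A == 0) {
    val <- 2 * R^2 / (S * D) - U / (2 * D)
    return(list(grad_mag = if (val > 0) sqrt(val) else NA_real_,
                converged = TRUE))
  }
  denom <- function(g) 2 * (S * D - 2 * R * (A / V) * Pi / (Pi + g))
  fn <- function(g) g^2 * denom(g) - (4 * R^2 - S * U)
  g_lo <- max(0, Pi * (2 * R * A / (V * S * D) - 1)) + 1e-9
  if (denom(g_lo) <= 0) g_lo <- g_lo + 1e-6
  if (fn(g_max) < 0) return(list(grad_mag = Inf, converged = TRUE))
  ## fn < 0 near g_lo (denominator -> 0+), > 0 at g_max
  r <- tryCatch(stats::uniroot(fn, c(g_lo, g_max), tol = 1e-10),
                error = function(e) NULL)
  if (is.null(r)) return(list(grad_mag = NA_real_, converged = FALSE))
  list(grad_mag = r$root, converged = TRUE)
}

#' Equilibrium and critical-gradient sweep
#'
#' Tabulates the adapted homogeneous equilibrium `(n*, v*)` over a grid of
#' environmental-gradient magnitudes and dispersal propensities, together
#' with the critical gradient for each propensity. The table mirrors the
#' analytic curves against which long-run simulated wave amplitudes and
#' core trait variances are validated.
#'
#' @param params base [model_params] (the `A` slot is overridden).
#' @param gradients gradient magnitudes to tabulate, `Q/X`.
#' @param A_values dispersal propensities to tabulate, `X^2/T`.
#' @param K carrying capacity.
#' @return a data frame with columns `A`, `grad_mag`, `v_star`, `n_star`,
#'   `critical_gradient`.
#' @export
equilibrium_sweep <- function(params = model_params(),
                              gradients = seq(0, 6, by = 0.5),
                              A_values = c(0, 4, 10), K = 1) {
  rows <- lapply(A_values, function(A) {
    p <- params; p$A <- A
    gc <- critical_gradient(p)$grad_mag
    do.call(rbind, lapply(gradients, function(g) {
      eq <- equilibrium_density(p, g, K)
      data.frame(A = A, grad_mag = g, v_star = eq$v_star, n_star = eq$n_star,
                 critical_gradient = gc)
    }))
  })
  do.call(rbind, rows)
}
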