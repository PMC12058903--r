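#' Model parameters
#'
#' Container for the ecological and genetic parameters of the model. Defaults
#' are the typical values used throughout the numerical studies: a generalist
#' species with unit diffusion, moderate optimal-dispersal propensity, weak
#' stabilising selection and a small mutational input of trait variance.
#'
#' @param D per-axis diffusion coefficients of random dispersal (diagonal
#'   tensor), units `X^2/T`. A scalar is recycled to both axes.
#' @param A propensity to disperse optimally, `X^2/T`. `A = 0` switches
#'   matching habitat choice off entirely.
#' @param R maximum intrinsic growth rate, `1/T`.
#' @param V variance of the phenotype utilisation distribution, `Q^2`.
#'   Small `V` means specialised individuals (strong phenotypic potential for
#'   directed dispersal, weak competition between unlike phenotypes).
#' @param S strength of stabilising selection, `1/(Q^2 T)`.
#' @param U rate of increase in trait variance due to mutation, `Q^2/T`.
#' @param Pi maximum perceived magnitude of the environmental gradient,
#'   `Q/X`. The perceived gradient saturates at this value.
#' @param delta boundary-sensing distance, `X`: within this distance of a
#'   reflecting boundary the normal component of the perceived gradient is
#'   smoothly tapered to zero.
#' @param extinction_floor density below which a completed run is classified
#'   extinct, `N/X^m`.
#' @return an object of class `model_params`.
#' @examples
#' model_params()                  # typical parameter set
#' model_params(A = 10, V = 1)     # strongly dispersing specialist
#' @export
model_params <- function(D = 1, A = 4, R = 2, V = 4, S = 0.2, U = 0.02,
                         Pi = 1, delta = 2, extinction_floor = 1e-3) {
  D <- rep_len(as.numeric(D), 2L)
  stopifnot(all(D >= 0), A >= 0, R > 0, V > 0, S >= 0, U >= 0, Pi > 0,
            delta >= 0, extinction_floor >= 0)
  p <- list(D = D, A = A, R = R, V = V, S = S, U = U, Pi = Pi, delta = delta,
            extinction_floor = extinction_floor)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params:\n")
  cat(sprintf("  D = (%g, %g) X^2/T, A = %g X^2/T, R = %g 1/T\n",
              x$D[1], x$D[2], x$A, x$R))
  cat(sprintf("  V = %g Q^2, S = %g 1/(Q^2 T), U = %g Q^2/T\n", x$V, x$S, x$U))
  cat(sprintf("  Pi = %g Q/X, delta = %g X, extinction floor = %g\n",
              x$Pi, x$delta, x$extinction_floor))
  invisible(x)
}

check_params_grid <- function(params, grid) {
  shortest <- min(vapply(grid$extents, diff, numeric(1)))
  if (params$delta >= shortest / 2)
    stop("boundary-sensing distance delta must be below half the shortest axis length")
  invisible(TRUE)
}
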