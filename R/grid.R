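#' Discretised rectangular habitat
#'
#' Builds a cell-centred finite-volume grid over an open rectangular habitat
#' in one or two spatial dimensions. Fields on the grid are stored as
#' `n1 x n2` matrices (with `n2 = 1` in 1D), where axis 1 is the direction of
#' the environmental gradient in all shipped scenarios.
#'
#' @param extents numeric vector `c(a, b)` for a 1D habitat, or a list of two
#'   such vectors for a 2D habitat, in units of `X`.
#' @param nx integer number of cells per axis (recycled to the dimension).
#' @param boundary character vector of per-axis boundary types,
#'   `"reflecting"` or `"periodic"`. Defaults: 1D is reflecting at both ends;
#'   2D is reflecting on axis 1 and periodic on axis 2.
#' @return an object of class `habitat_grid` with elements `m`, `extents`,
#'   `nx`, `dx`, `x1`, `x2`, `X1`, `X2` (cell-centre coordinate matrices),
#'   `boundary` and `cell_volume`.
#' @examples
#' g <- habitat_grid(c(-50, 50), nx = 400)
#' g2 <- habitat_grid(list(c(-50, 50), c(-50, 50)), nx = 200)
#' @export
habitat_grid <- function(extents, nx, boundary = NULL) {
  if (is.numeric(extents)) extents <- list(extents)
  m <- length(extents)
  if (!m %in% c(1L, 2L)) stop("habitat must be 1- or 2-dimensional")
  nx <- rep_len(as.integer(nx), m)
  if (any(nx < 8L)) stop("at least 8 cells are required per axis")
  for (ext in extents) {
    if (length(ext) != 2L || !all(is.finite(ext)) || diff(ext) <= 0)
      stop("each extent must be a finite increasing interval c(a, b)")
  }
  if (is.null(boundary)) {
    boundary <- if (m == 1L) "reflecting" else c("reflecting", "periodic")
  }
  boundary <- match.arg(boundary, c("reflecting", "periodic"), several.ok = TRUE)
  boundary <- rep_len(boundary, m)
  if (m == 1L && boundary[1L] != "reflecting")
    stop("1D habitats use reflecting boundaries at both ends")

  dx <- vapply(seq_len(m), function(i) diff(extents[[i]]) / nx[i], numeric(1))
  centres <- lapply(seq_len(m), function(i)
    extents[[i]][1L] + dx[i] * (seq_len(nx[i]) - 0.5))

  n1 <- nx[1L]
  n2 <- if (m == 2L) nx[2L] else 1L
  x1 <- centres[[1L]]
  x2 <- if (m == 2L) centres[[2L]] else 0
  g <- list(
    m = m, extents = extents, nx = c(n1, n2), dx = c(dx, 1)[1:2],
    x1 = x1, x2 = x2,
    X1 = matrix(x1, n1, n2), X2 = matrix(x2, n1, n2, byrow = TRUE),
    boundary = c(boundary, "periodic")[1:2],
    cell_volume = prod(dx)
  )
  class(g) <- "habitat_grid"
  g
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat(sprintf("habitat_grid: %dD, %s cells\n", x$m,
              paste(x$nx[seq_len(x$m)], collapse = " x ")))
  for (i in seq_len(x$m)) {
    cat(sprintf("  axis %d: (%g, %g) X, dx = %g, %s\n", i,
                x$extents[[i]][1], x$extents[[i]][2], x$dx[i], x$boundary[i]))
  }
  invisible(x)
}

## coerce a scalar/vector/matrix to a field matrix on the grid
as_field <- function(x, grid) {
  if (length(x) == 1L) return(matrix(x, grid$nx[1], grid$nx[2]))
  if (is.matrix(x)) {
    if (!all(dim(x) == grid$nx)) stop("field dimensions do not match grid")
    return(x)
  }
  if (length(x) == grid$nx[1] && grid$nx[2] == 1L) return(matrix(x, ncol = 1L))
  stop("cannot interpret object as a field on this grid")
}

#' Index of the grid cell nearest to a physical location
#'
#' @param grid a [habitat_grid].
#' @param location physical coordinates (recycled to the dimension), `X`.
#' @return integer vector `c(i1, i2)` of matrix indices (`i2 = 1` in 1D).
#' @export
cell_index <- function(grid, location) {
  location <- rep_len(location, grid$m)
  i1 <- which.min(abs(grid$x1 - location[1]))
  i2 <- if (grid$m == 2L) which.min(abs(grid$x2 - location[2])) else 1L
  c(i1, i2)
}
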