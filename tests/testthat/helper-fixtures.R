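# Shared fixtures for the test suite: small grids and typical parameters.

typical_params <- function(...) model_params(...)

grid_1d <- function(L = 50, nx = 400) habitat_grid(c(-L, L), nx)

grid_2d <- function(L = 20, nx = 40) habitat_grid(list(c(-L, L), c(-L, L)), nx)

# homogeneous adapted state on a linear optimum
adapted_state <- function(grid, env, n = 1, v = 1) {
  population_state(n, env$Q, v, grid = grid)
}

# interior cell selector (at least `margin` X away from axis-1 walls)
interior_1d <- function(grid, margin = 5) {
  abs(grid$x1 - mean(grid$extents[[1]])) <
    (diff(grid$extents[[1]]) / 2 - margin)
}
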