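#' Fragmented-landscape specification
#'
#' Parameters of the patchy carrying-capacity generator: narrow rectangular
#' patches of fixed width whose long dimension is aligned with the
#' environmental gradient on the right half of the habitat and perpendicular
#' to it on the left half, tiled side by side with no gaps, plus an enlarged
#' central patch in which the population is seeded.
#'
#' @param patch_width patch width (short dimension), `X`.
#' @param patch_length_range inclusive integer range of patch lengths, `X`.
#' @param K_core carrying capacity at a patch centre, `N/X^2`.
#' @param K_edge carrying capacity at a patch edge, `N/X^2`.
#' @param central_patch side length of the square central seeding patch, `X`.
#' @param end_ramp length of the half-cosine capacity ramp at each end of a
#'   patch's long axis, `X`. The default `NULL` uses half the patch length,
#'   i.e. a full tensor half-cosine bump whose core capacity peaks only at
#'   the patch centre. A short ramp (e.g. 1 X) instead gives each patch a
#'   flat-topped ridge of core capacity along its whole length, which
#'   strengthens the contrast between gradient-aligned and
#'   gradient-perpendicular patches at the price of higher absolute
#'   in-patch densities.
#' @param seed integer seed for the deterministic patch-length draw.
#' @return an object of class `fragmentation_spec`.
#' @export
fragmentation_spec <- function(patch_width = 2, patch_length_range = c(10, 15),
                               K_core = 1, K_edge = 0.05, central_patch = 20,
                               end_ramp = NULL, seed = 1L) {
  stopifnot(patch_width > 0, length(patch_length_range) == 2,
            patch_length_range[1] <= patch_length_range[2],
            K_edge > 0, K_core >= K_edge, central_patch > 0,
            is.null(end_ramp) || end_ramp > 0)
  s <- list(patch_width = patch_width,
            patch_length_range = patch_length_range,
            K_core = K_core, K_edge = K_edge,
            central_patch = central_patch, end_ramp = end_ramp,
            seed = as.integer(seed))
  class(s) <- "fragmentation_spec"
  s
}

## half-cosine bump along one axis: 0 at the patch edges, rising smoothly to
## 1 at distance `ramp` from them, flat in between. With `ramp` equal to the
## half-width this is a pure cosine bump; with a shorter ramp the patch
## carries a flat-topped ridge at full capacity along its long axis.
patch_bump <- function(X, lo, hi, ramp = NULL) {
  if (is.null(ramp)) ramp <- (hi - lo) / 2
  ramp <- min(ramp, (hi - lo) / 2)
  d <- pmin(X - lo, hi - X)
  b <- matrix(0, nrow(X), ncol(X))
  inside <- d >= 0
  b[inside] <- 1
  sel <- inside & d < ramp
  b[sel] <- sin(pi * d[sel] / (2 * ramp))^2
  b
}

## partition [lo, hi] into segments with lengths drawn from len_range;
## the final segment is truncated to fit
draw_segments <- function(lo, hi, len_range) {
  lens <- numeric(0)
  pos <- lo
  while (pos < hi - 1e-9) {
    choices <- seq(len_range[1], len_range[2])
    l <- choices[sample.int(length(choices), 1L)]
    l <- min(l, hi - pos)
    lens <- c(lens, l)
    pos <- pos + l
  }
  cbind(start = lo + cumsum(c(0, lens[-length(lens)])),
        end = lo + cumsum(lens))
}

#' Fragmented carrying-capacity landscape
#'
#' Tiles the right half of a 2D habitat with gradient-aligned (horizontal)
#' patches and the left half with gradient-perpendicular (vertical) patches.
#' Within each patch the carrying capacity rises smoothly from `K_edge` at
#' the patch boundary to `K_core` at its centre: a half-cosine bump across
#' the narrow dimension, and along the long dimension either a matching
#' full bump (the default tensor profile) or a flat-topped ridge with short
#' end ramps (see the `end_ramp` argument of [fragmentation_spec]); the
#' patch edges stay barely habitable in either case. A large central
#' patch spans the seeding region; where it overlaps the tiling the larger
#' capacity wins. The patch-length draw is deterministic given the seed.
#'
#' @param grid a 2D [habitat_grid].
#' @param spec a [fragmentation_spec].
#' @return list with the capacity field `K` and the patch bookkeeping
#'   (`central_box`, the central-patch rectangle).
#' @export
fragmented_carrying_capacity <- function(grid, spec = fragmentation_spec()) {
  if (grid$m != 2L) stop("fragmented landscapes require a 2D habitat")
  ex1 <- grid$extents[[1]]; ex2 <- grid$extents[[2]]
  w <- spec$patch_width
  if (abs(diff(ex1)) / 2 < spec$patch_length_range[1] ||
      abs(diff(ex2)) %% w > 1e-9)
    stop("fragmentation spec does not tile the domain")
  X1 <- grid$X1; X2 <- grid$X2
  bump <- matrix(0, grid$nx[1], grid$nx[2])

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  mid1 <- mean(ex1)
  ## right half: horizontal patches (long axis = x1, width bands in x2)
  bands2 <- seq(ex2[1], ex2[2], by = w)
  for (j in seq_len(length(bands2) - 1L)) {
    segs <- draw_segments(mid1, ex1[2], spec$patch_length_range)
    band <- patch_bump(X2, bands2[j], bands2[j + 1L])
    for (k in seq_len(nrow(segs))) {
      bump <- pmax(bump, band *
                     patch_bump(X1, segs[k, 1], segs[k, 2], spec$end_ramp))
    }
  }
  ## left half: vertical patches (long axis = x2, width bands in x1)
  bands1 <- seq(ex1[1], mid1, by = w)
  for (j in seq_len(length(bands1) - 1L)) {
    segs <- draw_segments(ex2[1], ex2[2], spec$patch_length_range)
    band <- patch_bump(X1, bands1[j], bands1[j + 1L])
    for (k in seq_len(nrow(segs))) {
      bump <- pmax(bump, band *
                     patch_bump(X2, segs[k, 1], segs[k, 2], spec$end_ramp))
    }
  }
  ## enlarged central seeding patch (flat-topped in both directions)
  half <- spec$central_patch / 2
  c1 <- mean(ex1); c2 <- mean(ex2)
  central <- patch_bump(X1, c1 - half, c1 + half, spec$end_ramp) *
    patch_bump(X2, c2 - half, c2 + half, spec$end_ramp)
  bump <- pmax(bump, central)

  K <- spec$K_edge + (spec$K_core - spec$K_edge) * bump
  list(K = K, central_box = c(c1 - half, c1 + half, c2 - half, c2 + half))
}

#' Fragmented-habitat scenario
#'
#' Assembles the full 2D fragmented-habitat experiment: a `(-50, 50)^2`
#' habitat with a steep linear optimum (gradient 1 `Q/X` along axis 1,
#' constant along axis 2), patchy carrying capacity, and a population
#' seeded in the central patch: a sech density pulse, perfectly adapted at
#' the habitat centre with a trait-mean gradient of 0.6 of the
#' environmental gradient (as in the 1D expansion seed), and unit trait
#' variance.
#'
#' @param params a [model_params].
#' @param nx cells per axis.
#' @param spec a [fragmentation_spec].
#' @param slope optimum gradient along axis 1, `Q/X`.
#' @return list with `grid`, `env`, `state0` and `central_box`.
#' @export
fragmented_scenario <- function(params = model_params(), nx = 200,
                                spec = fragmentation_spec(), slope = 1) {
  grid <- habitat_grid(list(c(-50, 50), c(-50, 50)), nx = nx)
  frag <- fragmented_carrying_capacity(grid, spec)
  env <- linear_optimum(grid, slope = slope, K = frag$K, params = params)
  state0 <- expansion_initial_state(grid, env)
  list(grid = grid, env = env, state0 = state0,
       central_box = frag$central_box)
}

#' Mask of in-patch cells outside the central patch
#'
#' @param grid a 2D [habitat_grid].
#' @param central_box rectangle `c(x1lo, x1hi, x2lo, x2hi)` to exclude.
#' @param side `"both"`, `"left"` (gradient-perpendicular patches) or
#'   `"right"` (gradient-aligned patches).
#' @return logical field selecting the fragmented region.
#' @export
fragmented_region_mask <- function(grid, central_box, side = c("both", "left", "right")) {
  side <- match.arg(side)
  inside_central <- grid$X1 >= central_box[1] & grid$X1 <= central_box[2] &
    grid$X2 >= central_box[3] & grid$X2 <= central_box[4]
  mask <- !inside_central
  mid <- mean(grid$extents[[1]])
  if (side == "left") mask <- mask & grid$X1 < mid
  if (side == "right") mask <- mask & grid$X1 > mid
  mask
}
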