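## Right-hand sides of the three coupled PDEs, assembled term by term.
##
## Term labels in the registry follow the structure of the model:
##   density:        14 diffusion, 15 directed advection, 16 reaction
##   trait mean:     17 diffusion, 18 asymmetric random gene flow,
##                   19 divergence of directed flow, 20 asymmetric directed
##                   gene flow, 21 mismatch advection, 22 selection
##   trait variance: 23 diffusion, 24 asymmetric random gene flow,
##                   25 gradient inflation, 26 directed deflation,
##                   27 mismatch advection, 28 competition/selection/mutation

#' Mean directed-dispersal velocity
#'
#' The advection velocity of the population density under matching habitat
#' choice: the propensity `A` times the mean phenotypic potential
#' `(q - Q)/V` times the perceived environmental gradient. Populations whose
#' trait mean exceeds the local optimum move up the gradient, and vice
#' versa; a perfectly matched population does not move directionally.
#'
#' @param state a [population_state].
#' @param env an [environment_field].
#' @param params a [model_params].
#' @param grid a [habitat_grid].
#' @return list `list(u1, u2)` of velocity component fields, `X/T`.
#' @export
advection_velocity <- function(state, env, params, grid) {
  pg <- env_pg(env, grid, params)
  phi <- params$A * (state$q - env$Q) / params$V
  list(u1 = phi * pg$g1, u2 = phi * pg$g2)
}

env_pg <- function(env, grid, params) {
  if (is.null(env$pg)) perceived_gradient(env, grid, params) else env$pg
}

#' Full model right-hand side
#'
#' Evaluates the time derivatives of density, trait mean and trait variance
#' on the grid, together with a registry of every individually evaluated
#' term. The reaction terms are evaluated pointwise exactly; transport terms
#' use central second-order differences, except the advective transport
#' terms (density flux and the mismatch advection of `q` and `v`), which are
#' donor-cell upwinded when `scheme = "upwind"` (the default, which keeps
#' density nonnegative and suppresses oscillations outside the effective
#' range at steep gradients).
#'
#' @param state a [population_state].
#' @param env an [environment_field] (already shifted if a schedule applies).
#' @param params a [model_params].
#' @param grid a [habitat_grid].
#' @param scheme `"upwind"` or `"central"` for advective transport.
#' @param eps regularisation floor for `grad(log n)`.
#' @return list with fields `dn`, `dq`, `dv` and `terms`, a named list
#'   `t14 ... t28` of the individual contributions.
#' @export
model_rhs <- function(state, env, params, grid, scheme = c("upwind", "central"),
                      eps = 1e-10) {
  scheme <- match.arg(scheme)
  n <- state$n
  q <- state$q
  v <- pmax(state$v, 0)
  D <- params$D
  A <- params$A
  V <- params$V
  S <- params$S
  R <- params$R
  K <- env$K
  pg <- env_pg(env, grid, params)
  mis <- q - env$Q

  u1 <- A * mis / V * pg$g1
  u2 <- A * mis / V * pg$g2
  w1 <- A * v / V * pg$g1          # directed gene-flow velocity (v-weighted)
  w2 <- A * v / V * pg$g2

  gq1 <- grad_axis(q, grid, 1L); gq2 <- grad_axis(q, grid, 2L)
  gv1 <- grad_axis(v, grid, 1L); gv2 <- grad_axis(v, grid, 2L)
  gl1 <- grad_log_field(n, grid, 1L, eps)
  gl2 <- grad_log_field(n, grid, 2L, eps)

  comp <- sqrt(V / (v + V))        # phenotype-dependent competition factor

  terms <- list(
    t14 = diffusion_term(n, grid, D),
    t15 = -advective_divergence(n, u1, u2, grid, scheme),
    t16 = (R - (R / K) * comp * n - (S / 2) * (mis^2 + v)) * n,

    t17 = diffusion_term(q, grid, D),
    t18 = 2 * (gl1 * D[1] * gq1 + gl2 * D[2] * gq2),
    t19 = -div_vector(w1, w2, grid),
    t20 = -(gl1 * w1 + gl2 * w2),
    t21 = -advection_of(q, u1, u2, grid, scheme),
    t22 = -S * mis * v,

    t23 = diffusion_term(v, grid, D),
    t24 = 2 * (gl1 * D[1] * gv1 + gl2 * D[2] * gv2),
    t25 = 2 * (D[1] * gq1^2 + D[2] * gq2^2),
    t26 = -2 * (gq1 * w1 + gq2 * w2),
    t27 = -advection_of(v, u1, u2, grid, scheme),
    t28 = (R / K) * comp * n * v^2 / (2 * (v + V)) - S * v^2 + params$U
  )

  for (nm in names(terms)) {
    if (!all(is.finite(terms[[nm]])))
      stop("non-finite right-hand side in term ", sub("t", "", nm))
  }

  list(dn = terms$t14 + terms$t15 + terms$t16,
       dq = terms$t17 + terms$t18 + terms$t19 + terms$t20 + terms$t21 + terms$t22,
       dv = terms$t23 + terms$t24 + terms$t25 + terms$t26 + terms$t27 + terms$t28,
       terms = terms)
}

#' Density equation right-hand side
#'
#' Diffusive transport, directed advection and the reaction term
#' (logistic growth with phenotype-dependent competition, stabilising
#' selection on the mean mismatch, and phenotypic load).
#'
#' @inheritParams model_rhs
#' @return list with `field` (the full `dn`) and `terms` (`t14`-`t16`).
#' @export
density_rhs <- function(state, env, params, grid, scheme = "upwind") {
  r <- model_rhs(state, env, params, grid, scheme)
  list(field = r$dn, terms = r$terms[c("t14", "t15", "t16")])
}

#' Trait-mean equation right-hand side
#'
#' @inheritParams model_rhs
#' @return list with `field` (the full `dq`) and `terms` (`t17`-`t22`).
#' @export
trait_mean_rhs <- function(state, env, params, grid, scheme = "upwind") {
  r <- model_rhs(state, env, params, grid, scheme)
  list(field = r$dq, terms = r$terms[paste0("t", 17:22)])
}

#' Trait-variance equation right-hand side
#'
#' @inheritParams model_rhs
#' @return list with `field` (the full `dv`) and `terms` (`t23`-`t28`).
#' @export
trait_variance_rhs <- function(state, env, params, grid, scheme = "upwind") {
  r <- model_rhs(state, env, params, grid, scheme)
  list(field = r$dv, terms = r$terms[paste0("t", 23:28)])
}

#' Decompose gene flow into random and directed contributions
#'
#' Splits the dispersal-driven part of the trait-mean rate of change into
#' the contribution of random gene flow (diffusive transport plus the
#' asymmetric core-to-edge term) and of directed gene flow (the three
#' optimal-dispersal terms). Optionally also reports the product-rule split
#' of the divergence term into its variance-gradient and
#' gradient-divergence components.
#'
#' @inheritParams model_rhs
#' @param split19 if `TRUE`, also return the two product-rule components of
#'   the directed-flow divergence term.
#' @return list with fields `random`, `directed`, `total` (and, when
#'   requested, `div_split`, a list of the two components).
#' @export
gene_flow_decomposition <- function(state, env, params, grid,
                                    scheme = "upwind", split19 = FALSE) {
  r <- model_rhs(state, env, params, grid, scheme)
  tm <- r$terms
  out <- list(random = tm$t17 + tm$t18,
              directed = tm$t19 + tm$t20 + tm$t21)
  out$total <- out$random + out$directed
  if (split19) {
    pg <- env_pg(env, grid, params)
    v <- pmax(state$v, 0)
    gv1 <- grad_axis(v, grid, 1L); gv2 <- grad_axis(v, grid, 2L)
    a1 <- params$A * pg$g1; a2 <- params$A * pg$g2
    out$div_split <- list(
      variance_gradient = -(gv1 * a1 + gv2 * a2) / params$V,
      gradient_divergence = -(v / params$V) * div_vector(a1, a2, grid))
  }
  out
}
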