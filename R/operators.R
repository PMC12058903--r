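## Cell-centred finite-difference operators with boundary handling.
##
## All operators act on field matrices (n1 x n2; n2 = 1 in 1D). Ghost values
## are realised by index shifts: reflecting boundaries clamp (even extension,
## giving zero normal flux), periodic boundaries wrap. A single-column axis
## behaves as constant along that axis, so 1D fields need no special-casing.

shift_field <- function(f, axis, step, bc) {
  n <- if (axis == 1L) nrow(f) else ncol(f)
  if (n == 1L) return(f)
  idx <- seq_len(n) + step
  if (bc == "periodic") {
    idx <- ((idx - 1L) %% n) + 1L
  } else {
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
  }
  if (axis == 1L) f[idx, , drop = FALSE] else f[, idx, drop = FALSE]
}

## second-order central gradient along one axis
grad_axis <- function(f, grid, axis) {
  if (grid$nx[axis] == 1L) return(f * 0)
  bc <- grid$boundary[axis]
  (shift_field(f, axis, 1L, bc) - shift_field(f, axis, -1L, bc)) /
    (2 * grid$dx[axis])
}

## div(D grad f) with diagonal constant D (per-axis coefficients)
diffusion_term <- function(f, grid, D) {
  out <- f * 0
  for (axis in 1:2) {
    if (grid$nx[axis] == 1L || D[axis] == 0) next
    bc <- grid$boundary[axis]
    out <- out + D[axis] *
      (shift_field(f, axis, 1L, bc) - 2 * f + shift_field(f, axis, -1L, bc)) /
      grid$dx[axis]^2
  }
  out
}

## central divergence of a vector field (a1, a2)
div_vector <- function(a1, a2, grid) {
  grad_axis(a1, grid, 1L) + grad_axis(a2, grid, 2L)
}

## divergence of the advective flux div(n u), conservative flux form.
## Face velocities are interpolated; upwind (donor-cell) or central face
## values for n are selectable. Advective flux through reflecting faces is
## identically zero (the perceived gradient has no normal component there).
advective_divergence <- function(n, u1, u2, grid, scheme = "upwind") {
  out <- n * 0
  us <- list(u1, u2)
  for (axis in 1:2) {
    if (grid$nx[axis] == 1L) next
    u <- us[[axis]]
    bc <- grid$boundary[axis]
    u_p <- shift_field(u, axis, 1L, bc)
    n_p <- shift_field(n, axis, 1L, bc)
    uf <- 0.5 * (u + u_p)                       # flux at face i+1/2
    if (scheme == "upwind") {
      Fp <- uf * n_p
      sel <- uf > 0
      Fp[sel] <- (uf * n)[sel]
    } else {
      Fp <- uf * 0.5 * (n + n_p)
    }
    if (bc == "reflecting") {
      if (axis == 1L) Fp[nrow(n), ] <- 0 else Fp[, ncol(n)] <- 0
    }
    Fm <- shift_field(Fp, axis, -1L, bc)
    if (bc == "reflecting") {
      if (axis == 1L) Fm[1L, ] <- 0 else Fm[, 1L] <- 0
    }
    out <- out + (Fp - Fm) / grid$dx[axis]
  }
  out
}

## gradient of f biased against the local transport direction u
upwind_grad_axis <- function(f, u, grid, axis) {
  if (grid$nx[axis] == 1L) return(f * 0)
  bc <- grid$boundary[axis]
  dx <- grid$dx[axis]
  fwd <- (shift_field(f, axis, 1L, bc) - f) / dx
  bwd <- (f - shift_field(f, axis, -1L, bc)) / dx
  out <- fwd
  sel <- u > 0
  out[sel] <- bwd[sel]
  out
}

## <u, grad f> with scheme-dependent differencing of grad f
advection_of <- function(f, u1, u2, grid, scheme = "upwind") {
  if (scheme == "upwind") {
    u1 * upwind_grad_axis(f, u1, grid, 1L) +
      u2 * upwind_grad_axis(f, u2, grid, 2L)
  } else {
    u1 * grad_axis(f, grid, 1L) + u2 * grad_axis(f, grid, 2L)
  }
}

## grad(log n), regularised as grad(n)/max(n, eps)
grad_log_field <- function(n, grid, axis, eps = 1e-10) {
  grad_axis(n, grid, axis) / pmax(n, eps)
}
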