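#' One explicit 1D finite-difference diffusion step
#'
#' Advances a field on a periodic ring by one time step of the explicit
#' scheme `u_i' = u_i + d_x (u_{i-1} - 2 u_i + u_{i+1})`. This is the naive
#' reduced-dimension solver: molecules are confined to the focal plane, so
#' the spatial mean is exactly conserved.
#'
#' @param field a [field1d()].
#' @param params a [diffusion_params()] whose `dx` matches the mesh.
#' @param override if `TRUE`, step even when the stability condition
#'   `d_x <= 1/2` is violated (used to verify divergence numerically).
#' @return The field after one step, with `tau` incremented.
#' @export
step_explicit_1d <- function(field, params, override = FALSE) {
  if (!inherits(field, "field1d")) stop_invalid("field must be a field1d")
  check_params_mesh(params, field$mesh)
  assert_stable("explicit_1d", params, override)
  v <- kernel_explicit_1d(field$values, params$d_x)
  structure(list(values = v, mesh = field$mesh, tau = field$tau + 1L),
            class = "field1d")
}

#' One explicit 2D finite-difference diffusion step
#'
#' Advances a field on a periodic torus by one step of the explicit 2D
#' scheme: separate second-difference stencils along x (coefficient `d_x`)
#' and y (coefficient `d_y`). Total mass is conserved exactly on the
#' periodic domain.
#'
#' @param field a [field2d()].
#' @param params a [diffusion_params()] whose `dx`, `dy` match the mesh.
#' @param override if `TRUE`, ignore the stability condition
#'   `d_x + d_y <= 1/2`.
#' @return The field after one step, with `tau` incremented.
#' @export
step_explicit_2d <- function(field, params, override = FALSE) {
  if (!inherits(field, "field2d")) stop_invalid("field must be a field2d")
  check_params_mesh(params, field$mesh)
  assert_stable("explicit_2d", params, override)
  v <- kernel_explicit_2d(field$values, params$d_x, params$d_y)
  structure(list(values = v, mesh = field$mesh, tau = field$tau + 1L),
            class = "field2d")
}

#' One semi-implicit 2D diffusion step
#'
#' Movement along x is treated implicitly (evaluated at the new time level)
#' and movement along y explicitly, so each step requires one
#' cyclic-tridiagonal solve per mesh column. The system matrix is circulant
#' and is solved exactly by FFT diagonalisation.
#'
#' @inheritParams step_explicit_2d
#' @return The field after one step, with `tau` incremented.
#' @export
step_semi_implicit_2d <- function(field, params, override = FALSE) {
  if (!inherits(field, "field2d")) stop_invalid("field must be a field2d")
  check_params_mesh(params, field$mesh)
  eigs <- circulant_eigenvalues_C(params, field$mesh$N)
  stopifnot(all(eigs >= 1))  # C is SPD for d_x >= 0; cannot be singular
  v <- kernel_semi_implicit_2d(field$values, params$d_x, params$d_y, eigs)
  structure(list(values = v, mesh = field$mesh, tau = field$tau + 1L),
            class = "field2d")
}

#' Zero-flux residual through the focal plane
#'
#' The reduced-dimension (1D) diffusion model implicitly assumes that the
#' y-stencil across the focal plane vanishes:
#' `u_{i,J-1} - 2 u_{i,J} + u_{i,J+1} = 0` for every `i` — molecules leaving
#' the plane are exactly balanced by molecules entering it. This function
#' evaluates that residual per focal-plane point; an all-zero result means
#' the zero-flux assumption holds exactly on this field.
#'
#' @param field a [field2d()].
#' @return Numeric vector of length `N` with the per-point residual.
#' @export
zero_flux_residual <- function(field) {
  if (!inherits(field, "field2d")) stop_invalid("field must be a field2d")
  m <- field$mesh
  jm <- if (m$J == 1L) m$M else m$J - 1L
  jp <- if (m$J == m$M) 1L else m$J + 1L
  field$values[, jm] - 2 * field$values[, m$J] + field$values[, jp]
}
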