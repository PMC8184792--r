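#' Phantom-point mesh for off-plane interpolation
#'
#' The 1D-uFDM estimates the concentrations one mesh row either side of the
#' focal plane ("phantom points") from the in-plane profile. For a radially
#' symmetric patch centred at index `N/2`, the phantom point above/below
#' in-plane point `n` lies at radial distance `sqrt((n*dx)^2 + dy^2)` from the
#' patch centre (Pythagoras), so its concentration can be read off the radial
#' profile by interpolation.
#'
#' @param mesh a [mesh1d()].
#' @param dy off-plane mesh spacing in micrometres (> 0); by convention
#'   `dy = dx` unless the full-system mesh is anisotropic.
#' @return An object of class `phantom_mesh` with elements `mesh`, `dy`,
#'   `n` (transformed indices `i - N/2`), `source_r` (radii `0..(N/2)*dx` of
#'   the non-negative half-profile interpolated *from*) and `target`
#'   (distances `sqrt((n*dx)^2 + dy^2)` interpolated *to*, one per mesh point).
#' @examples
#' pm <- build_phantom_mesh(mesh1d(8, 0.1), dy = 0.1)
#' pm$target[pm$n == 0]  # 0.1: directly above the centre
#' @export
build_phantom_mesh <- function(mesh, dy = mesh$dx) {
  if (!inherits(mesh, "mesh1d")) stop_invalid("mesh must be a mesh1d")
  if (length(dy) != 1L || !is.finite(dy) || dy <= 0)
    stop_invalid("dy must be a single positive number")
  n <- seq_len(mesh$N) - mesh$centre
  structure(list(mesh = mesh, dy = dy, n = n,
                 source_r = (0:(mesh$N %/% 2L)) * mesh$dx,
                 target = sqrt((n * mesh$dx)^2 + dy^2)),
            class = "phantom_mesh")
}

#' @export
print.phantom_mesh <- function(x, ...) {
  cat(sprintf("<phantom_mesh> N=%d, dx=%g, dy=%g; target distances %.4g..%.4g um\n",
              x$mesh$N, x$mesh$dx, x$dy, min(x$target), max(x$target)))
  invisible(x)
}

#' Interpolate off-plane concentrations from the focal-plane profile
#'
#' Evaluates the estimated concentrations at the phantom points. By radial
#' symmetry only the non-negative half of the profile (`n = 0..N/2`) is used
#' as interpolation source, and the estimate at `n` equals the estimate at
#' `-n`. Target distances beyond the farthest source radius (only the
#' antipodal point `n = N/2`, whose phantom distance exceeds `N*dx/2` by less
#' than `dy^2/(N*dx)`) receive the value at the farthest point (constant
#' extension).
#'
#' @param field a [field1d()], expected radially symmetric about the centre
#'   index; asymmetry beyond `tol` triggers a warning but the computation
#'   proceeds (reaction-diffusion trajectories can drift slightly asymmetric
#'   through rounding).
#' @param pm a [build_phantom_mesh()] built on the same mesh.
#' @param method `"cubic"` (default) for a monotonicity-limited cubic
#'   Hermite spline in radial distance, or `"linear"` for piecewise-linear
#'   interpolation (cheaper, but its chord error on convex profiles biases
#'   the off-plane estimate high).
#' @param tol symmetry tolerance relative to `max(abs(u))`.
#' @return Numeric vector of length `N`: the estimated off-plane
#'   concentrations, one per in-plane mesh point.
#' @export
interpolate_offplane <- function(field, pm, method = c("cubic", "linear"),
                                 tol = 1e-6) {
  method <- match.arg(method)
  if (!inherits(field, "field1d")) stop_invalid("field must be a field1d")
  if (!inherits(pm, "phantom_mesh")) stop_invalid("pm must be a phantom_mesh")
  if (pm$mesh$N != field$mesh$N || abs(pm$mesh$dx - field$mesh$dx) > 1e-12)
    stop_invalid("phantom mesh does not match the field's mesh")
  u <- field$values
  N <- length(u)
  c0 <- N %/% 2L
  k <- seq_len(c0 - 1L)
  asym <- max(abs(u[c0 + k] - u[c0 - k]))
  if (asym > tol * max(abs(u), 1e-300))
    warn_redudim(sprintf(
      "field is not radially symmetric about the centre (max|u_n - u_-n| = %.3g); proceeding",
      asym), "redudim_asymmetry_warning")
  kernel_interp_offplane(u, pm, method)
}

#' One explicit 1D-uFDM step
#'
#' The 1D scheme with unrestricted molecular movement: the usual in-plane
#' stencil is augmented by a flux term `2 d_y (utilde_n - u_n)` estimating
#' exchange with the mesh rows either side of the focal plane, where
#' `utilde_n` is the off-plane concentration interpolated from the current
#' profile at radial distance `sqrt((n*dx)^2 + dy^2)`. Unlike the plain 1D
#' scheme, the spatial mean is *not* conserved: the flux term models
#' molecules genuinely leaving or entering the focal plane.
#'
#' @param field a [field1d()].
#' @param params a [diffusion_params()]; `dy` must match the phantom mesh.
#' @param pm a [build_phantom_mesh()]; built on the fly from `params$dy` when
#'   omitted (prefer passing one in loops).
#' @param method interpolation method, see [interpolate_offplane()].
#' @param override if `TRUE`, ignore the stability condition
#'   `2 d_x + d_y <= 1`.
#' @return The field after one step, with `tau` incremented.
#' @export
step_explicit_ufdm <- function(field, params, pm = NULL,
                               method = c("cubic", "linear"), override = FALSE) {
  method <- match.arg(method)
  if (!inherits(field, "field1d")) stop_invalid("field must be a field1d")
  check_params_mesh(params, field$mesh)
  if (is.null(pm)) pm <- build_phantom_mesh(field$mesh, params$dy)
  if (abs(pm$dy - params$dy) > 1e-12)
    stop_invalid("phantom mesh dy does not match params$dy")
  assert_stable("explicit_ufdm", params, override)
  v <- kernel_explicit_ufdm(field$values, params$d_x, params$d_y, pm, method)
  structure(list(values = v, mesh = field$mesh, tau = field$tau + 1L),
            class = "field1d")
}

#' One semi-implicit 1D-uFDM step
#'
#' Movement *through* the focal plane (the interpolated flux term) is solved
#' explicitly and movement *on* the focal plane implicitly:
#' `u' = C^{-1} ((1 - 2 d_y) u + 2 d_y utilde)` with `C` the circulant matrix
#' with diagonal `1 + 2 d_x` and off-diagonals `-d_x`. The off-plane estimate
#' must come from the current time level — a fully implicit variant is ill
#' defined because the off-plane concentrations are themselves inferred from
#' the unknown new profile; requesting one raises an unsupported-scheme error.
#'
#' @inheritParams step_explicit_ufdm
#' @param override if `TRUE`, ignore the stability condition `d_y <= 1`.
#' @return The field after one step, with `tau` incremented.
#' @export
step_semi_implicit_ufdm <- function(field, params, pm = NULL,
                                    method = c("cubic", "linear"),
                                    override = FALSE) {
  method <- match.arg(method)
  if (!inherits(field, "field1d")) stop_invalid("field must be a field1d")
  check_params_mesh(params, field$mesh)
  if (is.null(pm)) pm <- build_phantom_mesh(field$mesh, params$dy)
  if (abs(pm$dy - params$dy) > 1e-12)
    stop_invalid("phantom mesh dy does not match params$dy")
  assert_stable("semi_implicit_ufdm", params, override)
  eigs <- circulant_eigenvalues_C(params, field$mesh$N)
  v <- kernel_semi_implicit_ufdm(field$values, params$d_y, eigs, pm, method)
  structure(list(values = v, mesh = field$mesh, tau = field$tau + 1L),
            class = "field1d")
}

#' Explicit 1D-uFDM stability condition
#'
#' Returns the [stability_report()] for the explicit scheme: condition value
#' `2 d_x + d_y`, threshold 1. Derived from the Gerschgorin bound on the
#' propagator eigenvalues, see [gerschgorin_bounds_A()].
#'
#' @param params a [diffusion_params()].
#' @export
stability_explicit_ufdm <- function(params) stability_report("explicit_ufdm", params)

#' Explicit uFDM propagator matrix
#'
#' The dense `N x N` circulant matrix with diagonal `1 - 2 (d_x + d_y)`,
#' off-diagonals `d_x` and periodic corner entries `d_x`, so that one
#' explicit step is `u' = A u + 2 d_y utilde`.
#'
#' @param params a [diffusion_params()].
#' @param N mesh-point count.
#' @return An `N x N` numeric matrix.
#' @export
propagator_A <- function(params, N) {
  A <- matrix(0, N, N)
  diag(A) <- 1 - 2 * (params$d_x + params$d_y)
  idx <- seq_len(N - 1L)
  A[cbind(idx, idx + 1L)] <- params$d_x
  A[cbind(idx + 1L, idx)] <- params$d_x
  A[1L, N] <- A[N, 1L] <- params$d_x
  A
}

#' Semi-implicit uFDM system matrix
#'
#' The dense `N x N` circulant matrix with diagonal `1 + 2 d_x`,
#' off-diagonals and periodic corners `-d_x`; symmetric positive definite
#' for `d_x >= 0`, with unit row sums.
#'
#' @inheritParams propagator_A
#' @return An `N x N` numeric matrix.
#' @export
propagator_C <- function(params, N) {
  C <- matrix(0, N, N)
  diag(C) <- 1 + 2 * params$d_x
  idx <- seq_len(N - 1L)
  C[cbind(idx, idx + 1L)] <- -params$d_x
  C[cbind(idx + 1L, idx)] <- -params$d_x
  C[1L, N] <- C[N, 1L] <- -params$d_x
  C
}

#' Gerschgorin eigenvalue bounds for the explicit uFDM propagator
#'
#' Every eigenvalue of the propagator `A` lies in
#' `[1 - 4 d_x - 2 d_y, 1 - 2 d_y]` by Gerschgorin's circle theorem (the
#' bound on row diagonal dominance simplifies because all off-diagonal
#' entries are `d_x`). Requiring `|lambda| <= 1` yields the explicit
#' stability condition `2 d_x + d_y <= 1`. The exact circulant spectrum is
#' `1 - 2 (d_x + d_y) + 2 d_x cos(2 pi k / N)`; the lower bound is attained
#' at the Nyquist wavenumber `k = N/2`.
#'
#' @param params a [diffusion_params()].
#' @return Named numeric vector `c(lower, upper)`.
#' @export
gerschgorin_bounds_A <- function(params) {
  if (!inherits(params, "diffusion_params"))
    stop_invalid("params must be a diffusion_params object")
  c(lower = 1 - 4 * params$d_x - 2 * params$d_y,
    upper = 1 - 2 * params$d_y)
}

#' Propagate the explicit 1D-uFDM via its matrix-form solution
#'
#' Iterates `u^{tau+1} = A u^tau + 2 d_y utilde^tau` using the dense
#' propagator matrix — the matrix-form solution
#' `u^tau = A^tau u^0 + 2 d_y sum_k A^{tau-k} utilde^{k-1}` evaluated
#' iteratively. This is an independent code path from
#' [step_explicit_ufdm()] (dense matrix product vs stencil kernel), kept for
#' cross-validation; the two agree to roundoff.
#'
#' @param u0 initial [field1d()].
#' @param params a [diffusion_params()].
#' @param pm a [build_phantom_mesh()]; default built from `params$dy`.
#' @param steps number of time steps (>= 0).
#' @param method interpolation method.
#' @param override ignore the stability condition if `TRUE`.
#' @return The field after `steps` steps.
#' @export
propagate_explicit <- function(u0, params, pm = NULL, steps,
                               method = c("cubic", "linear"), override = FALSE) {
  method <- match.arg(method)
  if (!inherits(u0, "field1d")) stop_invalid("u0 must be a field1d")
  if (steps < 0 || steps != round(steps)) stop_invalid("steps must be a non-negative integer")
  check_params_mesh(params, u0$mesh)
  if (is.null(pm)) pm <- build_phantom_mesh(u0$mesh, params$dy)
  assert_stable("explicit_ufdm", params, override)
  A <- propagator_A(params, u0$mesh$N)
  u <- u0$values
  for (k in seq_len(steps)) {
    ut <- kernel_interp_offplane(u, pm, method)
    u <- drop(A %*% u) + 2 * params$d_y * ut
  }
  structure(list(values = u, mesh = u0$mesh, tau = u0$tau + as.integer(steps)),
            class = "field1d")
}

#' Propagate the semi-implicit 1D-uFDM via its matrix-form solution
#'
#' Iterates `u^{tau+1} = C^{-1} ((1 - 2 d_y) u^tau + 2 d_y utilde^tau)` with
#' a dense inverse of the system matrix `C`, as an independent
#' cross-validation path for [step_semi_implicit_ufdm()] (which uses an FFT
#' circulant solve).
#'
#' @inheritParams propagate_explicit
#' @export
propagate_semi_implicit <- function(u0, params, pm = NULL, steps,
                                    method = c("cubic", "linear"),
                                    override = FALSE) {
  method <- match.arg(method)
  if (!inherits(u0, "field1d")) stop_invalid("u0 must be a field1d")
  if (steps < 0 || steps != round(steps)) stop_invalid("steps must be a non-negative integer")
  check_params_mesh(params, u0$mesh)
  if (is.null(pm)) pm <- build_phantom_mesh(u0$mesh, params$dy)
  assert_stable("semi_implicit_ufdm", params, override)
  Cinv <- solve(propagator_C(params, u0$mesh$N))
  u <- u0$values
  for (k in seq_len(steps)) {
    ut <- kernel_interp_offplane(u, pm, method)
    u <- drop(Cinv %*% ((1 - 2 * params$d_y) * u + 2 * params$d_y * ut))
  }
  structure(list(values = u, mesh = u0$mesh, tau = u0$tau + as.integer(steps)),
            class = "field1d")
}
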