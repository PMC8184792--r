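#' Run a diffusion simulation and record a trajectory
#'
#' Integrates the diffusion equation with the chosen solver from one of the
#' closed-form initial conditions and records periodic snapshots of the
#' (focal-plane) profile. For the 2D solver the recorded profiles are the
#' central slice through the patch; the full final field is also kept.
#'
#' @param solver `"fdm1d"` (plain 1D scheme), `"fdm2d"` (full 2D scheme) or
#'   `"ufdm"` (1D scheme with unrestricted movement).
#' @param scheme `"explicit"` or `"semi-implicit"`. A fully `"implicit"`
#'   uFDM is ill defined (the off-plane estimate would depend on the unknown
#'   new profile) and raises an unsupported-scheme error.
#' @param ic `"gaussian"` (patch `alpha * exp(-r^2)`) or `"bleach"`
#'   (`1 - exp(-r^2)`).
#' @param D diffusion coefficient, um^2/s.
#' @param dx,dy mesh spacings, um.
#' @param dt time step, s.
#' @param N,M mesh-point counts (x and, for 2D, y).
#' @param t_end simulated end time, s.
#' @param alpha Gaussian patch amplitude.
#' @param snapshot_every snapshot interval in seconds of simulated time.
#' @param method interpolation method for the uFDM flux term.
#' @param override ignore stability conditions if `TRUE`.
#' @return An object of class `trajectory`: list with `times` (snapshot
#'   times, s), `profiles` (`N x` snapshots matrix of focal-plane
#'   concentrations), `solver`, `scheme`, `params`, `stability`, `mesh` (the
#'   1D slice mesh) and, for the 2D solver, `final_field`.
#' @export
run_diffusion <- function(solver = c("ufdm", "fdm1d", "fdm2d"),
                          scheme = c("explicit", "semi-implicit", "implicit"),
                          ic = c("gaussian", "bleach"),
                          D = 0.1, dx = 0.1, dy = dx, dt = 0.01,
                          N = 200, M = N, t_end = 10, alpha = 1,
                          snapshot_every = 0.1,
                          method = c("cubic", "linear"), override = FALSE) {
  solver <- match.arg(solver)
  scheme <- match.arg(scheme)
  ic <- match.arg(ic)
  method <- match.arg(method)
  if (scheme == "implicit")
    stop_unsupported(paste0(
      "a fully implicit 1D-uFDM is ill defined: off-plane concentrations are ",
      "interpolated from the focal-plane profile, which is unknown at the new ",
      "time level; use scheme = \"semi-implicit\""))
  if (solver == "fdm1d" && scheme != "explicit")
    stop_unsupported("the plain 1D solver is provided in explicit form only")
  params <- diffusion_params(D, dt, dx, dy)
  nsteps <- as.integer(round(t_end / dt))
  stride <- max(1L, as.integer(round(snapshot_every / dt)))
  snaps <- seq(0L, nsteps, by = stride)

  mesh1 <- mesh1d(N, dx)
  centre <- mesh1$centre
  scheme_id <- switch(solver,
    fdm1d = "explicit_1d",
    fdm2d = if (scheme == "explicit") "explicit_2d" else "semi_implicit_2d",
    ufdm  = if (scheme == "explicit") "explicit_ufdm" else "semi_implicit_ufdm")
  report <- assert_stable(scheme_id, params, override)

  profiles <- matrix(NA_real_, N, length(snaps))
  si <- 1L
  final_field <- NULL

  if (solver == "fdm2d") {
    mesh2 <- mesh2d(N, M, dx, dy)
    f <- if (ic == "gaussian") make_gaussian_patch(mesh2, alpha) else make_bleach_profile(mesh2)
    u <- f$values
    eigsCx <- if (scheme == "semi-implicit") circulant_eigenvalues_C(params, N)
    profiles[, si] <- u[, mesh2$J]; si <- si + 1L
    for (s in seq_len(nsteps)) {
      u <- if (scheme == "explicit") kernel_explicit_2d(u, params$d_x, params$d_y)
           else kernel_semi_implicit_2d(u, params$d_x, params$d_y, eigsCx)
      if (s %% stride == 0L) { profiles[, si] <- u[, mesh2$J]; si <- si + 1L }
    }
    final_field <- field2d(u, mesh2, tau = nsteps)
  } else {
    f <- if (ic == "gaussian") make_gaussian_patch(mesh1, alpha) else make_bleach_profile(mesh1)
    u <- f$values
    pm <- if (solver == "ufdm") build_phantom_mesh(mesh1, dy)
    eigsC <- if (solver == "ufdm" && scheme == "semi-implicit")
      circulant_eigenvalues_C(params, N)
    profiles[, si] <- u; si <- si + 1L
    for (s in seq_len(nsteps)) {
      u <- if (solver == "fdm1d") kernel_explicit_1d(u, params$d_x)
           else if (scheme == "explicit")
             kernel_explicit_ufdm(u, params$d_x, params$d_y, pm, method)
           else kernel_semi_implicit_ufdm(u, params$d_y, eigsC, pm, method)
      if (s %% stride == 0L) { profiles[, si] <- u; si <- si + 1L }
    }
    final_field <- field1d(u, mesh1, tau = nsteps)
  }

  structure(list(times = snaps * dt, profiles = profiles, solver = solver,
                 scheme = scheme, ic = ic, alpha = alpha, params = params,
                 stability = report, mesh = mesh1, centre = centre,
                 final_field = final_field),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s), %d snapshots over %g s, N=%d\n",
              x$solver, x$scheme, length(x$times), max(x$times), x$mesh$N))
  invisible(x)
}
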