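#' Region of interest for FRAP analysis
#'
#' Either a disk (2D fields) or a line segment along the focal plane (1D
#' fields, or the central slice of a 2D field). The default radius /
#' half-length of 0.55 um corresponds to the benchmark bleach-spot geometry
#' (disk diameter and line length 1.1 um). A mesh point belongs to the ROI
#' when its centre lies inside it, with `<=` on the boundary, so ROI
#' membership is reproducible bit-for-bit for a given mesh.
#'
#' @param kind `"disk"` or `"segment"`.
#' @param radius disk radius or segment half-length, um.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(kind = c("disk", "segment"), radius = 0.55) {
  kind <- match.arg(kind)
  if (!is.finite(radius) || radius <= 0) stop_invalid("radius must be positive")
  structure(list(kind = kind, radius = radius), class = "roi_spec")
}

# Logical membership mask, centred on the patch centre.
roi_mask <- function(mesh, roi) {
  if (roi$kind == "disk") {
    if (!inherits(mesh, "mesh2d")) stop_invalid("a disk ROI requires a 2D mesh")
    x <- coords(mesh, "x"); y <- coords(mesh, "y")
    outer(x^2, y^2, `+`) <= roi$radius^2
  } else {
    x <- if (inherits(mesh, "mesh1d")) coords(mesh) else coords(mesh, "x")
    abs(x) <= roi$radius
  }
}

#' Mean concentration inside a region of interest
#'
#' Arithmetic mean of the field values at mesh points whose centres lie in
#' the ROI. A segment ROI applied to a 2D field is evaluated along the focal
#' plane (row `J`).
#'
#' @param field a `field1d` or `field2d`.
#' @param roi a [roi_spec()].
#' @return A single number.
#' @export
roi_mean <- function(field, roi) {
  if (!inherits(roi, "roi_spec")) stop_invalid("roi must be a roi_spec")
  if (inherits(field, "field1d")) {
    if (roi$kind == "disk") stop_invalid("a disk ROI requires a 2D field")
    mask <- roi_mask(field$mesh, roi)
    if (!any(mask)) stop_invalid("ROI contains no mesh points")
    return(mean(field$values[mask]))
  }
  if (inherits(field, "field2d")) {
    if (roi$kind == "segment") return(roi_mean(central_slice(field), roi))
    mask <- roi_mask(field$mesh, roi)
    if (!any(mask)) stop_invalid("ROI contains no mesh points")
    return(mean(field$values[mask]))
  }
  stop_invalid("field must be a field1d or field2d")
}

#' FRAP recovery curve
#'
#' Container for a mean-ROI fluorescence time series with its derived
#' quantities: `F0 = F(0)`, the plateau estimate `Finf` (the last sampled
#' value), the half time `t_half` and, when requested, the diffusion
#' coefficient estimated from `t_half`.
#'
#' @param times sampling times, s.
#' @param values mean ROI fluorescence at each time.
#' @param solver,roi optional labels.
#' @return An object of class `recovery_curve`.
#' @export
recovery_curve <- function(times, values, solver = NA_character_,
                           roi = NA_character_) {
  if (length(times) != length(values) || length(times) < 2L)
    stop_invalid("times and values must have equal length >= 2")
  structure(list(times = times, values = values,
                 F0 = values[1L], Finf = values[length(values)],
                 solver = solver, roi = roi),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %s/%s: F0=%.4g, Finf=%.4g, %d samples over %g s\n",
              x$solver, x$roi, x$F0, x$Finf, length(x$times), max(x$times)))
  invisible(x)
}

#' Half time of a FRAP recovery curve
#'
#' The time at which the mean ROI fluorescence reaches half of its maximum
#' recovery, `F0 + (Finf - F0) / 2`, located by linear interpolation between
#' the two bracketing samples. `Finf` is the final sampled value (the
#' empirical plateau), so `t_half` depends on the simulated end time for
#' solvers whose plateau is domain-limited.
#'
#' @param curve a [recovery_curve()].
#' @return `t_half` in seconds.
#' @export
half_time <- function(curve) {
  if (!inherits(curve, "recovery_curve")) stop_invalid("curve must be a recovery_curve")
  F <- curve$values; t <- curve$times
  target <- curve$F0 + (curve$Finf - curve$F0) / 2
  if (!(curve$Finf > curve$F0))
    stop_not_converged("no recovery: plateau does not exceed the initial value (increase t_end or check D)")
  above <- which(F >= target)
  above <- above[above > 1L]
  if (length(above) == 0L)
    stop_not_converged("half-recovery level never reached; increase t_end")
  k <- above[1L]
  # linear interpolation on the bracketing segment
  t[k - 1L] + (target - F[k - 1L]) / (F[k] - F[k - 1L]) * (t[k] - t[k - 1L])
}

#' Estimate a diffusion coefficient from a FRAP half time
#'
#' The standard spot-photobleaching estimator
#' `D = (r_n^2 + r_e^2) / (8 * t_half)`, where `r_n` is the nominal (laser)
#' radius and `r_e` the effective radius of the bleach profile. For the
#' Gaussian bleach `1 - exp(-r^2)` used here, `r_n = 0.55` um and
#' `r_e = sqrt(2)` um.
#'
#' @param t_half half time, s (> 0).
#' @param r_n nominal laser radius, um.
#' @param r_e effective bleach radius, um.
#' @return Estimated diffusion coefficient, um^2/s.
#' @examples
#' estimate_D(2.711)  # ~0.106
#' @export
estimate_D <- function(t_half, r_n = 0.55, r_e = sqrt(2)) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop_invalid("t_half must be positive")
  (r_n^2 + r_e^2) / (8 * t_half)
}

#' Simulate a FRAP experiment and analyse the recovery
#'
#' Starts from the Gaussian-bleach initial condition, integrates with the
#' chosen solver, samples the mean ROI fluorescence at every solver step,
#' and derives `t_half` and the estimated diffusion coefficient. For the 2D
#' solver both ROI kinds are measured in one pass (a disk on the full field
#' and a segment along the central slice); the 1D solvers use the segment
#' ROI.
#'
#' @inheritParams run_diffusion
#' @param roi_radius disk radius / segment half-length, um.
#' @return For 1D solvers a single analysed `recovery_curve` (with fields
#'   `t_half` and `D_est` filled in); for `"fdm2d"` a named list
#'   `list(disk = ..., segment = ...)` of two analysed curves.
#' @export
run_frap <- function(solver = c("ufdm", "fdm1d", "fdm2d"),
                     scheme = c("explicit", "semi-implicit"),
                     D = 0.1, dx = 0.1, dy = dx, dt = 0.01,
                     N = 200, M = N, t_end = 60, roi_radius = 0.55,
                     method = c("cubic", "linear"), override = FALSE) {
  solver <- match.arg(solver)
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  params <- diffusion_params(D, dt, dx, dy)
  nsteps <- as.integer(round(t_end / dt))
  times <- (0:nsteps) * dt

  analyse <- function(curve) {
    curve$t_half <- half_time(curve)
    curve$D_est <- estimate_D(curve$t_half)
    curve
  }

  if (solver == "fdm2d") {
    scheme_id <- if (scheme == "explicit") "explicit_2d" else "semi_implicit_2d"
    assert_stable(scheme_id, params, override)
    mesh2 <- mesh2d(N, M, dx, dy)
    u <- make_bleach_profile(mesh2)$values
    disk_idx <- which(roi_mask(mesh2, roi_spec("disk", roi_radius)))
    seg_idx <- which(roi_mask(mesh1d(N, dx), roi_spec("segment", roi_radius)))
    eigsCx <- if (scheme == "semi-implicit") circulant_eigenvalues_C(params, N)
    Fd <- Fs <- numeric(nsteps + 1L)
    Fd[1L] <- mean(u[disk_idx]); Fs[1L] <- mean(u[seg_idx, mesh2$J])
    for (s in seq_len(nsteps)) {
      u <- if (scheme == "explicit") kernel_explicit_2d(u, params$d_x, params$d_y)
           else kernel_semi_implicit_2d(u, params$d_x, params$d_y, eigsCx)
      Fd[s + 1L] <- mean(u[disk_idx])
      Fs[s + 1L] <- mean(u[seg_idx, mesh2$J])
    }
    return(list(disk = analyse(recovery_curve(times, Fd, solver, "disk")),
                segment = analyse(recovery_curve(times, Fs, solver, "segment"))))
  }

  scheme_id <- if (solver == "fdm1d") "explicit_1d"
               else if (scheme == "explicit") "explicit_ufdm" else "semi_implicit_ufdm"
  if (solver == "fdm1d" && scheme != "explicit")
    stop_unsupported("the plain 1D solver is provided in explicit form only")
  assert_stable(scheme_id, params, override)
  mesh1 <- mesh1d(N, dx)
  u <- make_bleach_profile(mesh1)$values
  seg_idx <- which(roi_mask(mesh1, roi_spec("segment", roi_radius)))
  pm <- if (solver == "ufdm") build_phantom_mesh(mesh1, dy)
  eigsC <- if (solver == "ufdm" && scheme == "semi-implicit")
    circulant_eigenvalues_C(params, N)
  F <- numeric(nsteps + 1L)
  F[1L] <- mean(u[seg_idx])
  for (s in seq_len(nsteps)) {
    u <- if (solver == "fdm1d") kernel_explicit_1d(u, params$d_x)
         else if (scheme == "explicit")
           kernel_explicit_ufdm(u, params$d_x, params$d_y, pm, method)
         else kernel_semi_implicit_ufdm(u, params$d_y, eigsC, pm, method)
    F[s + 1L] <- mean(u[seg_idx])
  }
  analyse(recovery_curve(times, F, solver, "segment"))
}
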