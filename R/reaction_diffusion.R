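#' Substrate-depletion reaction rate
#'
#' The conversion rate `f = u1^2 * u2 - u1` of the two-species
#' mass-conserved substrate-depletion model: an active, slowly diffusing
#' form `u1` autocatalytically recruits from a fast-diffusing substrate pool
#' `u2` (`+f` for `u1`, `-f` for `u2`), so reactions change molecular
#' identity but never create or destroy molecules.
#'
#' @param u1,u2 concentrations (numbers, vectors or matrices).
#' @return The rate `f`, same shape as the inputs.
#' @export
reaction_rate <- function(u1, u2) u1^2 * u2 - u1

#' Reaction-diffusion state
#'
#' Pairs the two species fields (on a shared mesh) with their diffusion
#' coefficients. Defaults are the polarity-model values: `D1 = 0.01` um^2/s
#' for the membrane-bound active form, `D2 = 1` um^2/s for the substrate.
#'
#' @param u1,u2 `field1d` or `field2d` objects on the same mesh.
#' @param D1,D2 diffusion coefficients, um^2/s.
#' @return An object of class `rd_state`.
#' @export
rd_state <- function(u1, u2, D1 = 0.01, D2 = 1) {
  if (!identical(class(u1), class(u2))) stop_invalid("u1 and u2 must be fields of the same class")
  if (!identical(unclass(u1$mesh), unclass(u2$mesh)))
    stop_invalid("u1 and u2 must share a mesh")
  if (!is.finite(D1) || D1 < 0 || !is.finite(D2) || D2 < 0)
    stop_invalid("diffusion coefficients must be non-negative")
  structure(list(u1 = u1, u2 = u2, D1 = D1, D2 = D2), class = "rd_state")
}

#' Initial condition after a signalling pulse
#'
#' A pulse conversion of molecules to `u1` from the `u2` pool:
#' `u1 = alpha * exp(-r^2)` and `u2 = m - u1` pointwise, so the pointwise
#' total — and hence the system mass — equals `m` exactly.
#'
#' @param mesh a `mesh1d` or `mesh2d`.
#' @param alpha pulse amplitude (peak `u1`), `0 < alpha <= m` so `u2 >= 0`.
#' @param m system mass (mean total concentration); default 3, large enough
#'   for saturation by substrate depletion.
#' @param D1,D2 passed to [rd_state()].
#' @return An `rd_state`.
#' @export
rd_initial_condition <- function(mesh, alpha, m = 3, D1 = 0.01, D2 = 1) {
  if (!is.finite(m) || m <= 0) stop_invalid("m must be positive")
  if (!is.finite(alpha) || alpha <= 0 || alpha > m)
    stop_invalid("alpha must satisfy 0 < alpha <= m so that u2 >= 0")
  u1 <- make_gaussian_patch(mesh, alpha)
  u2 <- u1
  u2$values <- m - u1$values
  rd_state(u1, u2, D1, D2)
}

#' System mass (mean total concentration)
#'
#' `m = <u1> + <u2>`, where `<.>` is the mesh mean (`1/N` sum on a ring,
#' `1/(N M)` double sum on a torus). Conserved exactly by the reactions
#' (pointwise `+f`/`-f`) and by the conservative diffusion stencils
#' (plain 1D and 2D schemes on periodic domains). The uFDM flux term models
#' genuine exchange with off-plane rows, so mass in a uFDM
#' reduced-dimension model tracks the 2D central slice instead of being
#' constant.
#'
#' @param state an [rd_state()].
#' @return A single number.
#' @export
mass <- function(state) {
  if (!inherits(state, "rd_state")) stop_invalid("state must be an rd_state")
  mean(state$u1$values) + mean(state$u2$values)
}

#' One Euler reaction substep
#'
#' Pointwise forward-Euler update `u1 <- u1 + dt_R * f`,
#' `u2 <- u2 - dt_R * f`; the pointwise sum `u1 + u2` is unchanged exactly.
#'
#' @param state an [rd_state()].
#' @param dt_R reaction time step, s.
#' @return The updated state.
#' @export
euler_reaction_substep <- function(state, dt_R) {
  if (!inherits(state, "rd_state")) stop_invalid("state must be an rd_state")
  if (!is.finite(dt_R) || dt_R <= 0) stop_invalid("dt_R must be positive")
  f <- reaction_rate(state$u1$values, state$u2$values)
  state$u1$values <- state$u1$values + dt_R * f
  state$u2$values <- state$u2$values - dt_R * f
  state
}

#' Operator-splitting schedule
#'
#' Reactions are advanced with Euler substeps of `dt_R` seconds; each
#' diffusion step of `dt_D` seconds (which must be an integer multiple of
#' `dt_R`) is preceded by `dt_D / dt_R` reaction substeps (Lie splitting).
#' Defaults: `dt_R = 1e-5` s, `dt_D = 0.002` s — the latter keeps the
#' explicit 2D scheme stable for the fast species (`D2 = 1` gives
#' `d = 0.2` per axis at `dx = 0.1`).
#'
#' @param dt_R reaction substep, s.
#' @param dt_D diffusion step, s.
#' @return An object of class `splitting_schedule` with `n_sub = dt_D/dt_R`.
#' @export
splitting_schedule <- function(dt_R = 1e-5, dt_D = 0.002) {
  if (!is.finite(dt_R) || dt_R <= 0 || !is.finite(dt_D) || dt_D <= 0)
    stop_invalid("dt_R and dt_D must be positive")
  n_sub <- dt_D / dt_R
  if (abs(n_sub - round(n_sub)) > 1e-8 * n_sub)
    stop_invalid("dt_D must be an integer multiple of dt_R")
  structure(list(dt_R = dt_R, dt_D = dt_D, n_sub = as.integer(round(n_sub))),
            class = "splitting_schedule")
}

#' Integrate the reaction-diffusion model
#'
#' Two-step operator splitting: per diffusion step, `dt_D / dt_R` Euler
#' reaction substeps followed by one diffusion step per species with its
#' own coefficient. Diffusion uses the chosen solver; for the 2D solver the
#' recorded profiles are the central slice of `u1`. Transient negative
#' concentrations (possible with forward Euler) are warned about, not
#' clipped, to preserve mass exactly.
#'
#' @param state an [rd_state()] (1D fields for `"fdm1d"`/`"ufdm"`, 2D for
#'   `"fdm2d"`).
#' @param schedule a [splitting_schedule()].
#' @param solver `"fdm1d"`, `"fdm2d"` or `"ufdm"` (explicit schemes).
#' @param t_end simulated end time, s.
#' @param snapshot_every snapshot interval, s.
#' @param steady_tol if non-`NULL`, stop early once the sup-norm change of
#'   `u1` per unit simulated time falls below this value (checked every
#'   simulated second).
#' @param method uFDM interpolation method.
#' @return An object of class `rd_trajectory`: `times`, `profiles` (u1 on
#'   the focal plane), `centre` (u1 centre-value trace), `mass_trace`,
#'   `final` (final `rd_state`), `solver`, plus the schedule and end time
#'   actually reached.
#' @export
rd_integrate <- function(state, schedule, solver = c("fdm1d", "fdm2d", "ufdm"),
                         t_end, snapshot_every = 0.5, steady_tol = NULL,
                         method = c("cubic", "linear")) {
  solver <- match.arg(solver)
  method <- match.arg(method)
  if (!inherits(state, "rd_state")) stop_invalid("state must be an rd_state")
  if (!inherits(schedule, "splitting_schedule"))
    stop_invalid("schedule must be a splitting_schedule")
  is2d <- inherits(state$u1, "field2d")
  if (is2d != (solver == "fdm2d"))
    stop_invalid("solver dimensionality does not match the state's fields")
  mesh <- state$u1$mesh
  dx <- mesh$dx
  dy <- if (is2d) mesh$dy else dx
  p1 <- diffusion_params(state$D1, schedule$dt_D, dx, dy)
  p2 <- diffusion_params(state$D2, schedule$dt_D, dx, dy)
  scheme_id <- switch(solver, fdm1d = "explicit_1d", fdm2d = "explicit_2d",
                      ufdm = "explicit_ufdm")
  for (sp in c("u1", "u2")) {
    p <- if (sp == "u1") p1 else p2
    rep <- stability_report(scheme_id, p)
    if (!rep$satisfied)
      stop_stability(sprintf(
        "diffusion of species %s violates the %s stability condition (value %.4g > %.4g)",
        sp, scheme_id, rep$value, rep$threshold), rep)
  }

  nsteps <- as.integer(round(t_end / schedule$dt_D))
  stride <- max(1L, as.integer(round(snapshot_every / schedule$dt_D)))
  check_stride <- max(1L, as.integer(round(1 / schedule$dt_D)))  # every ~1 s
  u1 <- state$u1$values; u2 <- state$u2$values
  dtR <- schedule$dt_R; n_sub <- schedule$n_sub
  slice_mesh <- if (is2d) mesh1d(mesh$N, dx) else mesh
  centre <- slice_mesh$centre
  J <- if (is2d) mesh$J else NA_integer_
  pm <- if (solver == "ufdm") build_phantom_mesh(mesh, dy)

  n_snap_max <- length(seq(0L, nsteps, by = stride)) + 1L
  profiles <- matrix(NA_real_, mesh$N, n_snap_max)
  times <- numeric(n_snap_max)
  mass_tr <- numeric(n_snap_max)
  take <- function(u) if (is2d) u[, J] else u
  si <- 1L
  profiles[, si] <- take(u1); times[si] <- 0; mass_tr[si] <- mean(u1) + mean(u2)
  neg_warned <- FALSE
  prev_check <- take(u1)
  steps_done <- 0L

  # The hot loop runs in the compiled core except for the monotone-cubic
  # uFDM path, which stays with the R kernels; both are advanced in chunks
  # between snapshot and steady-check boundaries.
  use_compiled <- !(solver == "ufdm" && method == "cubic")
  solver_code <- switch(solver, fdm1d = 0L, fdm2d = 1L, ufdm = 2L)
  if (solver == "ufdm") {
    iw <- phantom_linear_weights(pm)
  } else {
    iw <- list(lo = integer(0), w = numeric(0))
  }
  advance <- if (use_compiled) {
    function(k) {
      res <- .rd_advance(u1, u2, mesh$N, if (is2d) mesh$M else 1L,
                         solver_code, p1$d_x, p1$d_y, p2$d_x, p2$d_y,
                         dtR, n_sub, k, iw$lo, iw$w)
      if (is2d) {
        u1 <<- matrix(res$u1, mesh$N, mesh$M)
        u2 <<- matrix(res$u2, mesh$N, mesh$M)
      } else {
        u1 <<- res$u1; u2 <<- res$u2
      }
    }
  } else {
    function(k) {
      for (s in seq_len(k)) {
        for (r in seq_len(n_sub)) {
          f <- u1 * u1 * u2 - u1
          u1 <<- u1 + dtR * f
          u2 <<- u2 - dtR * f
        }
        u1 <<- kernel_explicit_ufdm(u1, p1$d_x, p1$d_y, pm, method)
        u2 <<- kernel_explicit_ufdm(u2, p2$d_x, p2$d_y, pm, method)
      }
    }
  }

  s <- 0L
  while (s < nsteps) {
    s_next <- min(nsteps,
                  (s %/% stride + 1L) * stride,
                  (s %/% check_stride + 1L) * check_stride)
    advance(s_next - s)
    s <- s_next
    steps_done <- s
    if (s %% stride == 0L || s == nsteps) {
      si <- si + 1L
      profiles[, si] <- take(u1)
      times[si] <- s * schedule$dt_D
      mass_tr[si] <- mean(u1) + mean(u2)
      if (!neg_warned && (min(u1) < 0 || min(u2) < 0)) {
        warn_redudim("transient negative concentrations encountered (not clipped, mass preserved)",
                     "redudim_negativity_warning")
        neg_warned <- TRUE
      }
    }
    if (!is.null(steady_tol) && s %% check_stride == 0L) {
      cur <- take(u1)
      rate <- max(abs(cur - prev_check)) / (check_stride * schedule$dt_D)
      prev_check <- cur
      if (rate < steady_tol) break
    }
  }

  keep <- seq_len(si)
  state$u1$values <- u1; state$u2$values <- u2
  state$u1$tau <- state$u1$tau + steps_done
  state$u2$tau <- state$u2$tau + steps_done
  structure(list(times = times[keep], profiles = profiles[, keep, drop = FALSE],
                 centre = profiles[centre, keep], mass_trace = mass_tr[keep],
                 final = state, solver = solver, schedule = schedule,
                 t_reached = steps_done * schedule$dt_D,
                 mesh = slice_mesh, centre_index = centre),
            class = c("rd_trajectory", "trajectory"))
}

#' Classify a steady-state profile
#'
#' Distinguishes the qualitative outcomes of the polarity model: a single
#' peak, two peaks flanking a central trough (formed when replenishment into
#' a depleted centre is too slow), or a spatially uniform profile. The
#' profile is first smoothed by one pass of periodic nearest-neighbour
#' averaging to suppress rounding ripples; strict local maxima rising more
#' than a small fraction of the profile range above the mean are counted.
#'
#' @param u1 a `field1d` or numeric vector (the u1 profile).
#' @param eps_frac maxima must exceed `mean + eps_frac * range`.
#' @param uniform_tol profiles with relative range below this are uniform.
#' @return `"single-peak"`, `"double-peak"` or `"uniform"`.
#' @export
classify_profile <- function(u1, eps_frac = 0.02, uniform_tol = 1e-4) {
  if (inherits(u1, "field1d")) u1 <- u1$values
  N <- length(u1)
  v <- (u1[c(N, seq_len(N - 1L))] + u1 + u1[c(seq_len(N - 1L) + 1L, 1L)]) / 3
  rng <- max(v) - min(v)
  if (rng <= uniform_tol * max(abs(v), 1e-300)) return("uniform")
  vm <- v[c(N, seq_len(N - 1L))]; vp <- v[c(seq_len(N - 1L) + 1L, 1L)]
  peaks <- which(v > vm & v > vp & v > mean(v) + eps_frac * rng)
  if (length(peaks) >= 2L) "double-peak" else if (length(peaks) == 1L) "single-peak"
  else "uniform"
}
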