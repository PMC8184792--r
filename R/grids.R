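#' Periodic 1D mesh (ring)
#'
#' A uniform mesh of `N` points, spacing `dx` micrometres, with periodic
#' boundary conditions (the reduced-dimension model is a ring). The centre of
#' the patch sits on the mesh point with index `N/2`, so the transformed index
#' `n = i - N/2` spans `{1 - N/2, ..., N/2}` and the physical coordinate of
#' point `i` is `x = (i - N/2) * dx`.
#'
#' @param N number of mesh points; must be an even integer >= 4 so the patch
#'   centre falls exactly on a mesh point.
#' @param dx mesh spacing in micrometres (> 0).
#' @return An object of class `mesh1d` with elements `N`, `dx` and `centre`
#'   (the index of the patch centre).
#' @examples
#' m <- mesh1d(200, 0.1)   # 20 um ring
#' range(coords(m))
#' @export
mesh1d <- function(N, dx = 0.1) {
  if (length(N) != 1L || !is.finite(N) || N < 4 || N != round(N))
    stop_invalid("N must be a single integer >= 4")
  if (N %% 2 != 0)
    stop_invalid("N must be even so the patch centre lies on a mesh point")
  if (length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop_invalid("dx must be a single positive number")
  structure(list(N = as.integer(N), dx = dx, centre = as.integer(N / 2)),
            class = "mesh1d")
}

#' Periodic 2D mesh (torus)
#'
#' A uniform `N x M` mesh, spacing `dx` along x and `dy` along y, periodic in
#' both directions. Row `J` is the focal plane: the 1D slice through the axis
#' of symmetry that the reduced-dimension model represents. The patch centre
#' is at `(i, j) = (N/2, J)`.
#'
#' @param N,M mesh-point counts along x and y (`N` even, both >= 4).
#' @param dx,dy spacings in micrometres; `dy` defaults to `dx`.
#' @param J focal-plane row index, defaulting to `M %/% 2`.
#' @return An object of class `mesh2d`.
#' @export
mesh2d <- function(N, M = N, dx = 0.1, dy = dx, J = M %/% 2) {
  if (length(N) != 1L || !is.finite(N) || N < 4 || N != round(N) || N %% 2 != 0)
    stop_invalid("N must be a single even integer >= 4")
  if (length(M) != 1L || !is.finite(M) || M < 4 || M != round(M))
    stop_invalid("M must be a single integer >= 4")
  if (!is.finite(dx) || dx <= 0 || !is.finite(dy) || dy <= 0)
    stop_invalid("dx and dy must be positive")
  if (J < 1 || J > M || J != round(J))
    stop_invalid("J must be a row index in 1..M")
  structure(list(N = as.integer(N), M = as.integer(M), dx = dx, dy = dy,
                 J = as.integer(J), centre = as.integer(N / 2)),
            class = "mesh2d")
}

#' Physical coordinates of mesh points
#'
#' @param mesh a `mesh1d` or `mesh2d`.
#' @param axis for 2D meshes, `"x"` or `"y"`.
#' @return Numeric vector of coordinates in micrometres, zero at the patch
#'   centre (index `N/2` along x, the focal row `J` along y).
#' @export
coords <- function(mesh, axis = "x") {
  if (inherits(mesh, "mesh1d")) return((seq_len(mesh$N) - mesh$centre) * mesh$dx)
  if (inherits(mesh, "mesh2d")) {
    if (axis == "x") return((seq_len(mesh$N) - mesh$centre) * mesh$dx)
    if (axis == "y") return((seq_len(mesh$M) - mesh$J) * mesh$dy)
    stop_invalid("axis must be \"x\" or \"y\"")
  }
  stop_invalid("mesh must be a mesh1d or mesh2d")
}

#' Concentration field on a 1D ring
#'
#' @param values numeric vector of concentrations, length `mesh$N`, all finite.
#' @param mesh a [mesh1d()].
#' @param tau non-negative integer time index (time is `tau * dt` seconds).
#' @return An object of class `field1d`.
#' @export
field1d <- function(values, mesh, tau = 0L) {
  if (!inherits(mesh, "mesh1d")) stop_invalid("mesh must be a mesh1d")
  if (length(values) != mesh$N) stop_invalid("length(values) must equal mesh$N")
  if (!all(is.finite(values))) stop_invalid("all field values must be finite")
  if (tau < 0 || tau != round(tau)) stop_invalid("tau must be a non-negative integer")
  structure(list(values = as.numeric(values), mesh = mesh, tau = as.integer(tau)),
            class = "field1d")
}

#' Concentration field on a 2D torus
#'
#' @param values numeric `N x M` matrix (rows index x, columns index y).
#' @param mesh a [mesh2d()].
#' @param tau non-negative integer time index.
#' @return An object of class `field2d`.
#' @export
field2d <- function(values, mesh, tau = 0L) {
  if (!inherits(mesh, "mesh2d")) stop_invalid("mesh must be a mesh2d")
  if (!is.matrix(values) || nrow(values) != mesh$N || ncol(values) != mesh$M)
    stop_invalid("values must be an N x M matrix matching the mesh")
  if (!all(is.finite(values))) stop_invalid("all field values must be finite")
  if (tau < 0 || tau != round(tau)) stop_invalid("tau must be a non-negative integer")
  structure(list(values = values, mesh = mesh, tau = as.integer(tau)),
            class = "field2d")
}

#' Gaussian concentration patch
#'
#' Initial condition for the diffusion examples: `alpha * exp(-x^2)` on a ring,
#' `alpha * exp(-(x^2 + y^2))` on a torus, centred on the patch centre. The
#' Gaussian has unit 1/e radius (1 micrometre).
#'
#' @param mesh a `mesh1d` or `mesh2d`.
#' @param alpha peak amplitude (> 0), the maximum concentration at the centre.
#' @return A `field1d` or `field2d` at `tau = 0`.
#' @export
make_gaussian_patch <- function(mesh, alpha = 1) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop_invalid("alpha must be a single positive number")
  if (inherits(mesh, "mesh1d")) {
    x <- coords(mesh)
    return(field1d(alpha * exp(-x^2), mesh))
  }
  if (inherits(mesh, "mesh2d")) {
    gx <- exp(-coords(mesh, "x")^2)
    gy <- exp(-coords(mesh, "y")^2)
    return(field2d(alpha * (gx %o% gy), mesh))
  }
  stop_invalid("mesh must be a mesh1d or mesh2d")
}

#' Gaussian photobleach profile
#'
#' Initial condition for FRAP simulations: a uniformly labelled membrane after
#' bleaching with a Gaussian laser, `1 - exp(-x^2)` (ring) or
#' `1 - exp(-(x^2 + y^2))` (torus). Zero at the bleach centre, approaching 1
#' far from it.
#'
#' @inheritParams make_gaussian_patch
#' @return A `field1d` or `field2d` at `tau = 0`.
#' @export
make_bleach_profile <- function(mesh) {
  g <- make_gaussian_patch(mesh, alpha = 1)
  g$values <- 1 - g$values
  g
}

#' Extract the focal-plane slice of a 2D field
#'
#' Returns row `J` (the focal plane) of a 2D field as a 1D field on a matching
#' ring mesh. For a radially symmetric field this is the radial profile.
#'
#' @param field a `field2d`.
#' @return A `field1d` with the same `N`, `dx` and `tau`.
#' @export
central_slice <- function(field) {
  if (!inherits(field, "field2d")) stop_invalid("field must be a field2d")
  m <- field$mesh
  field1d(field$values[, m$J], mesh1d(m$N, m$dx), tau = field$tau)
}

#' @export
print.mesh1d <- function(x, ...) {
  cat(sprintf("<mesh1d> N=%d, dx=%g um (ring length %g um), centre index %d\n",
              x$N, x$dx, x$N * x$dx, x$centre))
  invisible(x)
}

#' @export
print.mesh2d <- function(x, ...) {
  cat(sprintf("<mesh2d> %d x %d, dx=%g, dy=%g um, focal row J=%d\n",
              x$N, x$M, x$dx, x$dy, x$J))
  invisible(x)
}

#' @export
print.field1d <- function(x, ...) {
  cat(sprintf("<field1d> N=%d, tau=%d, range [%.4g, %.4g], mean %.4g\n",
              x$mesh$N, x$tau, min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
print.field2d <- function(x, ...) {
  cat(sprintf("<field2d> %d x %d, tau=%d, range [%.4g, %.4g], mean %.4g\n",
              x$mesh$N, x$mesh$M, x$tau, min(x$values), max(x$values),
              mean(x$values)))
  invisible(x)
}

#' Write a field as delimited text
#'
#' One row per mesh point: index, coordinate(s) in micrometres, concentration.
#'
#' @param field a `field1d` or `field2d`.
#' @param path output file path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (inherits(field, "field1d")) {
    df <- data.frame(i = seq_len(field$mesh$N), x = coords(field$mesh),
                     value = field$values)
  } else if (inherits(field, "field2d")) {
    m <- field$mesh
    df <- data.frame(i = rep(seq_len(m$N), times = m$M),
                     j = rep(seq_len(m$M), each = m$N),
                     x = rep(coords(m, "x"), times = m$M),
                     y = rep(coords(m, "y"), each = m$N),
                     value = as.vector(field$values))
  } else stop_invalid("field must be a field1d or field2d")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
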