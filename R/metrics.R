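#' Mean squared distance between two profiles
#'
#' `(1/N) * sum_i (a_i - b_i)^2`, the comparison statistic used throughout to
#' quantify how far a reduced-dimension solution is from the central slice of
#' the full 2D solution.
#'
#' @param a,b `field1d` objects or numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
msd <- function(a, b) {
  if (inherits(a, "field1d")) a <- a$values
  if (inherits(b, "field1d")) b <- b$values
  if (length(a) != length(b)) stop_invalid("profiles must have equal length")
  mean((a - b)^2)
}

#' Spatial-mean trace of a trajectory
#'
#' The mean concentration of each recorded profile over time. For the plain
#' 1D solver this is exactly constant; for the 2D central slice and the uFDM
#' it decays (Gaussian patch) or rises (bleach) as molecules cross the focal
#' plane.
#'
#' @param traj a [run_diffusion()] trajectory (or any object with `times`
#'   and `profiles`).
#' @return `data.frame` with columns `time` and `value`.
#' @export
mean_trace <- function(traj) {
  if (is.null(traj$profiles) || length(traj$times) == 0L)
    stop_invalid("trajectory has no recorded profiles")
  data.frame(time = traj$times, value = colMeans(traj$profiles))
}

#' Centre-value trace of a trajectory
#'
#' The concentration at the patch centre (index `N/2`) over time.
#'
#' @inheritParams mean_trace
#' @return `data.frame` with columns `time` and `value`.
#' @export
centre_trace <- function(traj) {
  if (is.null(traj$profiles)) stop_invalid("trajectory has no recorded profiles")
  data.frame(time = traj$times, value = traj$profiles[traj$centre, ])
}

#' MSD trace between two trajectories
#'
#' Per-snapshot mean squared distance between the recorded profiles of two
#' runs on the same mesh and snapshot grid (e.g. a reduced-dimension solution
#' vs the 2D central slice).
#'
#' @param a,b trajectories from [run_diffusion()].
#' @return `data.frame` with columns `time` and `msd`.
#' @export
msd_trace <- function(a, b) {
  if (!identical(dim(a$profiles), dim(b$profiles)))
    stop_invalid("trajectories have different profile dimensions")
  if (max(abs(a$times - b$times)) > 1e-9)
    stop_invalid("trajectories have different snapshot times")
  data.frame(time = a$times,
             msd = colMeans((a$profiles - b$profiles)^2))
}

#' Kymograph of a trajectory
#'
#' Space x time array of the recorded focal-plane concentrations, with the
#' spatial coordinate and snapshot times attached.
#'
#' @inheritParams mean_trace
#' @return An object of class `kymograph`: the `N x` snapshots matrix with
#'   attributes `x` (coordinates, um), `times` (s) and `solver`.
#' @export
kymograph <- function(traj) {
  structure(traj$profiles, x = coords(traj$mesh), times = traj$times,
            solver = traj$solver, class = c("kymograph", "matrix", "array"))
}

#' Write a kymograph as delimited text
#'
#' Header row of snapshot times; first column the spatial coordinate; one row
#' per mesh point.
#'
#' @param kym a [kymograph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kym, path) {
  df <- data.frame(x = attr(kym, "x"), unclass(kym))
  names(df) <- c("x", sprintf("t%g", attr(kym, "times")))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path file path.
#' @return A `kymograph` object.
#' @export
read_kymograph <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  structure(as.matrix(df[, -1, drop = FALSE]), x = df$x, times = times,
            solver = NA_character_, class = c("kymograph", "matrix", "array"))
}
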