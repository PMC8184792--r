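# Internal vectorised stencil kernels operating on raw arrays. The exported
# steppers wrap these with field objects and stability checks; the long
# integration loops (FRAP, reaction-diffusion) call them directly.

kernel_explicit_1d <- function(u, d) {
  N <- length(u)
  u + d * (u[c(N, seq_len(N - 1L))] - 2 * u + u[c(seq_len(N - 1L) + 1L, 1L)])
}

kernel_explicit_2d <- function(u, dxc, dyc) {
  N <- nrow(u); M <- ncol(u)
  ix_m <- c(N, seq_len(N - 1L)); ix_p <- c(seq_len(N - 1L) + 1L, 1L)
  iy_m <- c(M, seq_len(M - 1L)); iy_p <- c(seq_len(M - 1L) + 1L, 1L)
  u + dxc * (u[ix_m, ] - 2 * u + u[ix_p, ]) +
      dyc * (u[, iy_m] - 2 * u + u[, iy_p])
}

# Eigenvalues of the N x N circulant propagators (first row determines all):
# A: diag 1 - 2(d_x + d_y), off-diagonal and periodic corners d_x.
# C: diag 1 + 2 d_x, off-diagonal and corners -d_x.
circulant_eigenvalues_A <- function(params, N) {
  k <- 0:(N - 1L)
  1 - 2 * (params$d_x + params$d_y) + 2 * params$d_x * cos(2 * pi * k / N)
}

circulant_eigenvalues_C <- function(params, N) {
  k <- 0:(N - 1L)
  1 + 2 * params$d_x - 2 * params$d_x * cos(2 * pi * k / N)
}

# Exact direct solve of a symmetric circulant system via FFT diagonalisation.
# `eigs` are the circulant eigenvalues in FFT order; works for a vector b or
# column-wise for a matrix b.
circulant_solve <- function(eigs, b) {
  if (is.matrix(b)) {
    Re(stats::mvfft(stats::mvfft(b) / eigs, inverse = TRUE)) / nrow(b)
  } else {
    Re(stats::fft(stats::fft(b) / eigs, inverse = TRUE)) / length(b)
  }
}

# Precomputed linear-interpolation brackets for the phantom targets on the
# uniform radius grid: 0-based index `lo` into the half profile and weight
# `w` toward lo + 1, with constant extension clamped at the far end. Used by
# the compiled reaction-diffusion core.
phantom_linear_weights <- function(pm) {
  half_n <- length(pm$source_r) - 1L        # largest radius index N/2
  pos <- pmin(pm$target, pm$source_r[half_n + 1L]) / pm$mesh$dx
  lo <- pmin(as.integer(floor(pos)), half_n - 1L)
  list(lo = lo, w = pos - lo)
}

# uFDM kernels on raw vectors. `half` interpolation inputs are rebuilt each
# call from the current field; `pm` carries precomputed target distances.
kernel_interp_offplane <- function(u, pm, method = "cubic") {
  N <- length(u)
  half_r <- pm$source_r
  half_v <- u[(N %/% 2L):N]          # n = 0 .. N/2, centre at index N/2
  tgt <- pmin(pm$target, half_r[length(half_r)])  # constant far-end extension
  if (method == "linear") {
    stats::approx(half_r, half_v, xout = tgt, rule = 2)$y
  } else {
    f <- stats::splinefun(half_r, half_v, method = "monoH.FC")
    f(tgt)
  }
}

kernel_explicit_ufdm <- function(u, d_x, d_y, pm, method = "cubic") {
  ut <- kernel_interp_offplane(u, pm, method)
  N <- length(u)
  u + d_x * (u[c(N, seq_len(N - 1L))] - 2 * u + u[c(seq_len(N - 1L) + 1L, 1L)]) +
    2 * d_y * (ut - u)
}

kernel_semi_implicit_ufdm <- function(u, d_y, eigsC, pm, method = "cubic") {
  ut <- kernel_interp_offplane(u, pm, method)
  circulant_solve(eigsC, (1 - 2 * d_y) * u + 2 * d_y * ut)
}

kernel_semi_implicit_2d <- function(u, dxc, dyc, eigsCx) {
  M <- ncol(u)
  iy_m <- c(M, seq_len(M - 1L)); iy_p <- c(seq_len(M - 1L) + 1L, 1L)
  rhs <- u + dyc * (u[, iy_m] - 2 * u + u[, iy_p])
  circulant_solve(eigsCx, rhs)
}
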