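test_that("phantom distances follow Pythagoras and are symmetric in n", {
  m <- mesh1d(200, 0.1)
  pm <- build_phantom_mesh(m, dy = 0.1)
  expect_equal(pm$target[pm$n == 0], 0.1)               # directly off-plane
  expect_equal(pm$target[pm$n == 3], sqrt(0.09 + 0.01)) # ~0.3162
  k <- 1:99
  expect_equal(pm$target[m$centre + k], pm$target[m$centre - k])
  expect_true(all(pm$target >= 0.1))
  expect_true(all(pm$target >= abs(pm$n) * 0.1))
  # degenerate dy -> 0 limit collapses onto the in-plane radii
  pm0 <- build_phantom_mesh(m, dy = 1e-12)
  expect_equal(pm0$target, abs(pm$n) * 0.1, tolerance = 1e-9)
  expect_invalid(build_phantom_mesh(m, dy = 0))
})

test_that("off-plane interpolation reproduces known profiles", {
  m <- mesh1d(200, 0.1)
  pm <- build_phantom_mesh(m, 0.1)
  # constant profile: interpolant is the constant, both methods
  uc <- field1d(rep(3, 200), m)
  for (meth in c("linear", "cubic"))
    expect_equal(interpolate_offplane(uc, pm, meth), rep(3, 200))
  # linear-in-r half profile: interpolant exact, value = target distance
  fr <- field1d(abs(coords(m)), m)
  ut <- interpolate_offplane(fr, pm, "linear")
  expect_equal(ut[m$centre + 3], sqrt(0.10), tolerance = 1e-12)
  # gaussian: estimate at n = 0 is the closed form at r = dy
  ug <- interpolate_offplane(make_gaussian_patch(m), pm)
  expect_equal(ug[m$centre], exp(-0.01), tolerance = 2e-4)
  # the estimate inherits the radial symmetry of the source profile
  k <- 1:99
  expect_equal(ug[m$centre + k], ug[m$centre - k])
})

test_that("asymmetric fields trigger a warning but still interpolate", {
  m <- mesh1d(64, 0.1)
  pm <- build_phantom_mesh(m, 0.1)
  v <- exp(-coords(m)^2); v[10] <- v[10] + 0.1
  expect_warning(interpolate_offplane(field1d(v, m), pm),
                 class = "redudim_asymmetry_warning")
  expect_invalid(interpolate_offplane(make_gaussian_patch(mesh1d(32, 0.1)), pm))
})

test_that("uniform fields are exact fixed points of both uFDM steppers", {
  m <- mesh1d(32, 0.1)
  pm <- build_phantom_mesh(m, 0.1)
  p <- bench_params()
  u <- field1d(rep(1.7, 32), m)
  expect_equal(step_explicit_ufdm(u, p, pm)$values, u$values)
  expect_equal(step_semi_implicit_ufdm(u, p, pm)$values, u$values,
               tolerance = 1e-14)
})

test_that("the flux term drains a gaussian peak and is not mass conserving", {
  m <- mesh1d(200, 0.1)
  pm <- build_phantom_mesh(m, 0.1)
  p <- bench_params()
  g <- make_gaussian_patch(m)
  g1 <- step_explicit_ufdm(g, p, pm)
  expect_lt(mean(g1$values), mean(g$values))
  # centre decreases monotonically toward uniform (gaussian patch) ...
  f <- g
  centres <- numeric(200)
  for (i in 1:200) { f <- step_explicit_ufdm(f, p, pm); centres[i] <- f$values[m$centre] }
  expect_true(all(diff(c(g$values[m$centre], centres)) < 0))
  # ... and rises monotonically for the bleach trough
  b <- make_bleach_profile(m)
  centres <- numeric(200)
  for (i in 1:200) { b <- step_explicit_ufdm(b, p, pm); centres[i] <- b$values[m$centre] }
  expect_true(all(diff(c(0, centres)) > 0))
})

test_that("one uFDM step matches row J of one 2D step to interpolation error", {
  p <- bench_params()
  g2 <- make_gaussian_patch(mesh2d(200, 200, 0.1))
  g1 <- central_slice(g2)
  pm <- build_phantom_mesh(g1$mesh, 0.1)
  row_j <- central_slice(step_explicit_2d(g2, p))
  expect_lt(max(abs(step_explicit_ufdm(g1, p, pm)$values - row_j$values)),
            1e-4)                                  # cubic: ~1e-5
  expect_lt(max(abs(step_explicit_ufdm(g1, p, pm, method = "linear")$values -
                    row_j$values)), 1e-3)          # linear: ~5e-4
})

test_that("explicit stability condition and Gerschgorin bounds are correct", {
  p <- bench_params()                               # the benchmark parameter set
  r <- stability_explicit_ufdm(p)
  expect_equal(r$value, 0.3)
  expect_equal(r$threshold, 1)
  expect_true(r$satisfied)
  expect_equal(unname(gerschgorin_bounds_A(p)), c(0.4, 0.8))
  # d_x = 0: diagonal matrix, bounds coincide
  p0 <- diffusion_params(1, 1e-12, dx = 1, dy = 1e-5)
  b <- gerschgorin_bounds_A(params_with_d(1e-15, 0.2))
  expect_equal(unname(b), c(1 - 2 * 0.2, 1 - 2 * 0.2), tolerance = 1e-12)
})

test_that("propagator spectra lie within the Gerschgorin bounds", {
  set.seed(7)
  N <- 32
  for (i in 1:100) {
    p <- params_with_d(runif(1, 0.01, 0.5), runif(1, 0.01, 0.5))
    b <- gerschgorin_bounds_A(p)
    # closed-form circulant spectrum as oracle
    k <- 0:(N - 1)
    lam_closed <- 1 - 2 * (p$d_x + p$d_y) + 2 * p$d_x * cos(2 * pi * k / N)
    lam <- eigen(propagator_A(p, N), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(lam), sort(lam_closed), tolerance = 1e-10)
    expect_true(all(lam >= b["lower"] - 1e-12 & lam <= b["upper"] + 1e-12))
    # the lower bound is attained at the Nyquist wavenumber k = N/2
    expect_equal(min(lam), 1 - 4 * p$d_x - 2 * p$d_y, tolerance = 1e-12)
  }
})

test_that("propagator matrices have the stated structure", {
  p <- bench_params()
  A <- propagator_A(p, 8)
  C <- propagator_C(p, 8)
  expect_equal(rowSums(A), rep(1 - 2 * p$d_y, 8))
  expect_equal(rowSums(C), rep(1, 8))
  expect_identical(A, t(A))
  expect_identical(C, t(C))
  expect_equal(A[1, 8], p$d_x)                      # periodic corners
  expect_equal(C[8, 1], -p$d_x)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("matrix-form propagation matches repeated stepping", {
  m <- mesh1d(64, 0.1)
  pm <- build_phantom_mesh(m, 0.1)
  p <- bench_params()
  g <- make_gaussian_patch(m)
  expect_identical(propagate_explicit(g, p, pm, 0)$values, g$values)
  u <- field1d(rep(2, 64), m)
  expect_equal(propagate_explicit(u, p, pm, 1)$values, u$values)
  f <- g
  for (i in 1:50) f <- step_explicit_ufdm(f, p, pm)
  expect_equal(propagate_explicit(g, p, pm, 50)$values, f$values,
               tolerance = 1e-10)
  f <- g
  for (i in 1:50) f <- step_semi_implicit_ufdm(f, p, pm)
  expect_equal(propagate_semi_implicit(g, p, pm, 50)$values, f$values,
               tolerance = 1e-10)
})

test_that("semi-implicit uFDM agrees with explicit to O(dt^2) per step", {
  m <- mesh1d(200, 0.1)
  pm <- build_phantom_mesh(m, 0.1)
  g <- make_gaussian_patch(m)
  dif <- function(dt) {
    p <- diffusion_params(0.1, dt, 0.1)
    max(abs(step_explicit_ufdm(g, p, pm)$values -
            step_semi_implicit_ufdm(g, p, pm)$values))
  }
  ratio <- dif(0.01) / dif(0.005)
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.6)
})

test_that("semi-implicit uFDM is stable far beyond the explicit limit", {
  # d_x = 10 (explicit limit is 2 d_x + d_y <= 1), d_y = 0.5
  p <- params_with_d(10, 0.5)
  m <- mesh1d(64, p$dx)
  pm <- build_phantom_mesh(m, p$dy)
  f <- make_gaussian_patch(m)
  for (i in 1:1000) f <- step_semi_implicit_ufdm(f, p, pm)
  expect_true(all(is.finite(f$values)))
  expect_lt(max(abs(f$values)), 1)                  # relaxing, not growing
})

test_that("a fully implicit uFDM is rejected as ill defined", {
  expect_error(run_diffusion("ufdm", scheme = "implicit", t_end = 1),
               class = "redudim_unsupported_scheme")
})

test_that("reduced-dimension solutions rank as expected against the 2D slice", {
  # gaussian patch, benchmark parameters: the uFDM tracks the 2D central
  # slice far better than the plain 1D scheme at all times past 1 s
  t2 <- run_diffusion("fdm2d", t_end = 10, N = 200)
  t1 <- run_diffusion("fdm1d", t_end = 10, N = 200)
  tu <- run_diffusion("ufdm", t_end = 10, N = 200)
  m1 <- msd_trace(t2, t1)
  mu <- msd_trace(t2, tu)
  sel <- m1$time > 1
  expect_true(all(m1$msd[sel] > 10 * mu$msd[sel]))
  # the uFDM mean follows the slice mean; the 1D-FDM mean cannot move
  expect_equal(mean_trace(t1)$value, rep(mean_trace(t1)$value[1], sum(sel) +
               sum(!sel)), tolerance = 1e-12)
  end_means <- c(mean_trace(t2)$value[101], mean_trace(tu)$value[101],
                 mean_trace(t1)$value[101])
  expect_lt(abs(end_means[2] - end_means[1]), abs(end_means[3] - end_means[1]))
})
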