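test_that("stencil coefficients and stability reports are computed correctly", {
  p <- bench_params()
  expect_equal(p$d_x, 0.1)
  expect_equal(p$d_y, 0.1)
  expect_invalid(diffusion_params(-1, 0.01, 0.1))
  expect_invalid(diffusion_params(0.1, 0, 0.1))

  r <- stability_report("explicit_ufdm", p)
  expect_equal(r$value, 0.3)
  expect_true(r$satisfied)
  r <- stability_report("explicit_ufdm", params_with_d(0.5, 1e-16))
  expect_equal(r$value, 1.0)
  expect_true(r$satisfied)                        # boundary case counts
  r <- stability_report("explicit_ufdm", params_with_d(0.5, 0.1))
  expect_equal(r$value, 1.1)
  expect_false(r$satisfied)
})

test_that("unstable parameters raise a classed error carrying the report", {
  f <- make_gaussian_patch(mesh1d(16, sqrt(1 / 0.6)))
  p <- params_with_d(0.6)                          # d_x = 0.6 > 1/2
  err <- tryCatch(step_explicit_1d(f, p), condition = identity)
  expect_s3_class(err, "redudim_stability_error")
  expect_s3_class(err$report, "stability_report")
  expect_false(err$report$satisfied)
  # override steps anyway
  expect_s3_class(step_explicit_1d(f, p, override = TRUE), "field1d")
})

test_that("one explicit step reproduces the hand-evaluated stencils", {
  # 4x4 torus, unit point mass, d_x = d_y = 0.1
  u <- matrix(0, 4, 4); u[2, 2] <- 1
  f <- step_explicit_2d(field2d(u, mesh2d(4, 4, 0.1)), bench_params())
  expect_equal(f$values[2, 2], 0.6)
  expect_equal(f$values[c(1, 3), 2], c(0.1, 0.1))
  expect_equal(f$values[2, c(1, 3)], c(0.1, 0.1))
  expect_equal(sum(f$values), 1)
  expect_identical(f$tau, 1L)
  # 4-point ring, d_x = 0.25
  f1 <- step_explicit_1d(field1d(c(0, 1, 0, 0), mesh1d(4, 0.1)),
                         diffusion_params(0.25, 0.01, 0.1))
  expect_equal(f1$values, c(0.25, 0.5, 0.25, 0))
})

test_that("uniform fields are exact fixed points of all reference steppers", {
  p <- bench_params()
  u1 <- field1d(rep(2.5, 16), mesh1d(16, 0.1))
  u2 <- field2d(matrix(2.5, 16, 8), mesh2d(16, 8, 0.1))
  expect_identical(step_explicit_1d(u1, p)$values, u1$values)
  expect_identical(step_explicit_2d(u2, p)$values, u2$values)
  expect_equal(step_semi_implicit_2d(u2, p)$values, u2$values,
               tolerance = 1e-14)
})

test_that("periodic steppers conserve total mass for arbitrary fields", {
  set.seed(42)
  p <- bench_params()
  for (i in 1:5) {
    v <- runif(32)
    f <- field1d(v, mesh1d(32, 0.1))
    expect_equal(mean(step_explicit_1d(f, p)$values), mean(v),
                 tolerance = 1e-13)
    w <- matrix(runif(32 * 16), 32, 16)
    g <- field2d(w, mesh2d(32, 16, 0.1))
    expect_equal(mean(step_explicit_2d(g, p)$values), mean(w),
                 tolerance = 1e-13)
    expect_equal(mean(step_semi_implicit_2d(g, p)$values), mean(w),
                 tolerance = 1e-13)
  }
})

test_that("radial symmetry is preserved by the explicit 2D stepper", {
  g <- make_gaussian_patch(mesh2d(64, 64, 0.1))
  p <- bench_params()
  for (i in 1:20) g <- step_explicit_2d(g, p)
  v <- g$values
  # mirror about the centre row/column (index 32 + k <-> 32 - k), axis swap
  k <- 1:31
  expect_equal(v[32 + k, ], v[32 - k, ], tolerance = 1e-14)
  expect_equal(v[, 32 + k], v[, 32 - k], tolerance = 1e-14)
  expect_equal(v, t(v), tolerance = 1e-14)
})

test_that("semi-implicit 2D agrees with explicit to O(dt^2) per step", {
  g <- make_gaussian_patch(mesh2d(64, 64, 0.1))
  dif <- function(dt) {
    p <- diffusion_params(0.1, dt, 0.1)
    max(abs(step_explicit_2d(g, p)$values -
            step_semi_implicit_2d(g, p)$values))
  }
  ratio <- dif(0.01) / dif(0.005)
  expect_gt(ratio, 3.4)                            # ~4 for a dt^2 difference
  expect_lt(ratio, 4.6)
})

test_that("2D centre value tracks the unbounded-plane closed form", {
  tr <- run_diffusion("fdm2d", t_end = 10, N = 200)
  ct <- centre_trace(tr)
  closed <- 1 / (1 + 4 * 0.1 * ct$time)
  expect_lt(max(abs(ct$value - closed) / closed), 0.01)
})

test_that("zero-flux residual diagnoses the reduced-model assumption", {
  m2 <- mesh2d(32, 32, 0.1)
  # constant along y: assumption holds exactly
  v <- matrix(rep(runif(32), 32), 32, 32)
  expect_equal(zero_flux_residual(field2d(v, m2)), rep(0, 32))
  expect_equal(zero_flux_residual(field2d(matrix(1, 32, 32), m2)), rep(0, 32))
  # radially symmetric gaussian: negative curvature across the plane at the peak
  g <- make_gaussian_patch(m2)
  r <- zero_flux_residual(g)
  expect_lt(r[m2$centre], 0)
})
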