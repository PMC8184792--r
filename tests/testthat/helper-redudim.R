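# Shared helpers: parameter constructors used across test files.

# diffusion_params with prescribed dimensionless stencil coefficients
# (D = dt = 1; spacings back-solved), for stability/spectral tests where
# only d_x, d_y matter.
params_with_d <- function(d_x, d_y = d_x) {
  diffusion_params(D = 1, dt = 1, dx = sqrt(1 / d_x), dy = sqrt(1 / d_y))
}

# The benchmark discretisation used throughout the examples.
bench_params <- function(D = 0.1, dt = 0.01, dx = 0.1, dy = dx) {
  diffusion_params(D, dt, dx, dy)
}

expect_invalid <- function(expr) {
  expect_error(expr, class = "redudim_invalid_parameter")
}
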