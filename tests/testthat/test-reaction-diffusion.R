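test_that("the substrate-depletion reaction rate has its fixed points", {
  expect_equal(reaction_rate(1, 1), 0)              # u1 u2 = 1 balance
  expect_equal(reaction_rate(0, 5), 0)              # absorbing state
  expect_equal(reaction_rate(1, 2), 1)
  expect_equal(reaction_rate(c(1, 0), c(2, 3)), c(1, 0))
})

test_that("Euler reaction substeps convert without creating mass", {
  m <- mesh1d(16, 0.1)
  st <- rd_state(field1d(rep(1, 16), m), field1d(rep(2, 16), m))
  st1 <- euler_reaction_substep(st, 1e-5)
  expect_equal(st1$u1$values, rep(1.00001, 16))
  expect_equal(st1$u2$values, rep(1.99999, 16))
  # pointwise sum is invariant exactly, for arbitrary states
  set.seed(3)
  stR <- rd_state(field1d(runif(16, 0, 2), m), field1d(runif(16, 0, 2), m))
  tot <- stR$u1$values + stR$u2$values
  stR1 <- euler_reaction_substep(stR, 1e-3)
  expect_identical(stR1$u1$values + stR1$u2$values, tot)
  # the balanced uniform state does not move
  stF <- rd_state(field1d(rep(1, 16), m), field1d(rep(1, 16), m))
  expect_equal(euler_reaction_substep(stF, 1e-5)$u1$values, rep(1, 16))
})

test_that("the signalling-pulse initial condition carries mass m exactly", {
  m <- mesh1d(64, 0.1)
  st <- rd_initial_condition(m, alpha = 3, m = 3)
  expect_equal(st$u1$values[m$centre], 3)
  expect_equal(st$u2$values[m$centre], 0)
  st5 <- rd_initial_condition(m, alpha = 0.5)
  expect_equal(st5$u1$values[m$centre], 0.5)
  expect_equal(st5$u2$values[m$centre], 2.5)
  for (a in c(0.5, 1.7, 3)) expect_equal(mass(rd_initial_condition(m, a)), 3)
  expect_invalid(rd_initial_condition(m, alpha = 3.5, m = 3))
  m2 <- mesh2d(32, 16, 0.1)
  expect_equal(mass(rd_initial_condition(m2, 2)), 3)
})

test_that("mass is the mean total concentration", {
  m <- mesh1d(16, 0.1)
  st <- rd_state(field1d(rep(1, 16), m), field1d(rep(2, 16), m))
  expect_equal(mass(st), 3)
})

test_that("splitting schedules require commensurate steps", {
  s <- splitting_schedule(1e-5, 0.002)
  expect_equal(s$n_sub, 200L)
  expect_equal(splitting_schedule(1e-3, 0.002)$n_sub, 2L)
  expect_invalid(splitting_schedule(3e-5, 1e-4))
  expect_invalid(splitting_schedule(-1e-5, 0.002))
})

test_that("homogeneous balanced states are fixed points of the integrator", {
  m <- mesh1d(32, 0.1)
  sch <- splitting_schedule(1e-3, 0.002)
  # u1 = u2 = 1 (u1 u2 = 1), no spatial structure: nothing moves
  st <- rd_state(field1d(rep(1, 32), m), field1d(rep(1, 32), m))
  tr <- rd_integrate(st, sch, solver = "fdm1d", t_end = 0.2)
  expect_equal(tr$final$u1$values, rep(1, 32), tolerance = 1e-12)
  # u1 = 0 everywhere is absorbing: the state is constant
  st0 <- rd_state(field1d(rep(0, 32), m), field1d(rep(3, 32), m))
  tr0 <- rd_integrate(st0, sch, solver = "ufdm", t_end = 0.2)
  expect_equal(tr0$final$u1$values, rep(0, 32))
  expect_equal(tr0$final$u2$values, rep(3, 32), tolerance = 1e-12)
})

test_that("conservative solvers hold the system mass along trajectories", {
  sch <- splitting_schedule(1e-3, 0.002)
  st1 <- rd_initial_condition(mesh1d(64, 0.1), 1.5)
  tr1 <- rd_integrate(st1, sch, solver = "fdm1d", t_end = 20)  # 1e4 steps
  expect_lt(max(abs(tr1$mass_trace - 3)) / 3, 1e-9)
  st2 <- rd_initial_condition(mesh2d(32, 24, 0.1), 1.5)
  tr2 <- rd_integrate(st2, sch, solver = "fdm2d", t_end = 4)
  expect_lt(max(abs(tr2$mass_trace - 3)) / 3, 1e-9)
})

test_that("stability violations name the offending species", {
  st <- rd_initial_condition(mesh1d(32, 0.1), 1, D2 = 5)  # d = 1 for u2
  err <- tryCatch(
    rd_integrate(st, splitting_schedule(1e-3, 0.002), solver = "fdm1d",
                 t_end = 0.1),
    condition = identity)
  expect_s3_class(err, "redudim_stability_error")
  expect_match(conditionMessage(err), "u2")
})

test_that("profile classification separates the qualitative outcomes", {
  m <- mesh1d(100, 0.1)
  x <- coords(m)
  expect_equal(classify_profile(field1d(exp(-x^2), m)), "single-peak")
  expect_equal(classify_profile(rep(2, 100)), "uniform")
  expect_equal(classify_profile(exp(-(x - 2)^2) + exp(-(x + 2)^2)),
               "double-peak")
})

test_that("coarsening the reaction substep leaves the solution unchanged", {
  # mild pulse: halving dt_R from 2e-5 to 1e-5 moves the t = 10 s profile
  # by under 1e-4 in relative sup-norm
  run <- function(dtR) {
    st <- rd_initial_condition(mesh1d(100, 0.1), 0.5)
    tr <- rd_integrate(st, splitting_schedule(dtR, 0.002), solver = "ufdm",
                       t_end = 10, snapshot_every = 10)
    tr$profiles[, ncol(tr$profiles)]
  }
  pa <- run(2e-5); pb <- run(1e-5)
  expect_lt(max(abs(pa - pb)) / max(abs(pb)), 1e-4)
})
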