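test_that("periodic Laplacian annihilates constants and sums to zero", {
  expect_equal(laplacian_periodic(rep(3.7, 17), 0.1), rep(0, 17))
  set.seed(3)
  f <- rnorm(40)
  expect_equal(sum(laplacian_periodic(f, 0.05)), 0, tolerance = 1e-10)
})

test_that("discrete Fourier modes are Laplacian eigenvectors", {
  n <- 64; dx <- 0.1
  for (m in c(1, 3, 7)) {
    f <- cos(2 * pi * m * (0:(n - 1)) / n)
    lam <- -(2 - 2 * cos(2 * pi * m / n)) / dx^2
    expect_equal(laplacian_periodic(f, dx), lam * f, tolerance = 1e-9)
  }
})

test_that("the homogeneous equilibrium is invariant under integration", {
  ic <- make_initial_condition("homog_eq", fig4, small_grid)
  f <- simulate_rde(actin_network(fig4), small_grid, ic, T = 20)
  expect_lt(max(abs(f$u - f$u[1, 1])), 1e-8)
  expect_lt(max(abs(f$v - f$v[1, 1])), 1e-8)
})

test_that("integration is deterministic and bit-stable", {
  ic <- make_initial_condition("gaussian_bump", fig4, small_grid)
  f1 <- simulate_rde(actin_network(fig4), small_grid, ic, T = 1)
  f2 <- simulate_rde(actin_network(fig4), small_grid, ic, T = 1)
  expect_identical(f1$u, f2$u)
})

test_that("halving dt changes the endpoint at first order", {
  ic <- make_initial_condition("gaussian_bump", fig4, small_grid)
  net <- actin_network(fig4)
  dt0 <- 2e-4
  ref <- simulate_rde(net, small_grid, ic, T = 0.5, dt = dt0 / 4,
                      save_every = 10000L)
  e1 <- max(abs(simulate_rde(net, small_grid, ic, T = 0.5, dt = dt0,
                             save_every = 2500L)$u[2, ] -
                ref$u[nrow(ref$u), ]))
  e2 <- max(abs(simulate_rde(net, small_grid, ic, T = 0.5, dt = dt0 / 2,
                             save_every = 5000L)$u[2, ] -
                ref$u[nrow(ref$u), ]))
  expect_lt(e2, e1)
  # first-order stepper: halving dt roughly halves the error
  expect_equal(e1 / e2, 2, tolerance = 0.5)
})

test_that("without diffusion the solver matches a stiff ODE reference", {
  skip_if_not_installed("deSolve")
  p <- actin_params(c1 = 0.1, Du = 1e-12, Dv = 1e-12)
  g <- wave_grid(-1, 1, 16)
  x0 <- c(0.4, 2.5)
  ic <- list(u = rep(x0[1], g$n), v = rep(x0[2], g$n))
  f <- simulate_rde(actin_network(p), g, ic, T = 5, dt = 5e-7,
                    save_every = 1000000L)
  ref <- deSolve::ode(y = x0, times = c(0, 5),
                      func = function(t, y, parms) list(kinetics_rhs(y[1], y[2], p)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(f$u[nrow(f$u), 1] - ref[2, 2]), 1e-6)
  expect_lt(abs(f$v[nrow(f$v), 1] - ref[2, 3]), 1e-6)
})

test_that("generic R stepper agrees with the compiled actin fast path", {
  net <- actin_network(fig4)
  slow <- net
  slow$kinetics <- NULL  # force the generic path
  ic <- make_initial_condition("gaussian_bump", fig4, small_grid)
  f_fast <- simulate_rde(net, small_grid, ic, T = 0.2)
  f_slow <- simulate_rde(slow, small_grid, ic, T = 0.2)
  expect_equal(f_slow$u, f_fast$u, tolerance = 1e-12)
  expect_equal(f_slow$v, f_fast$v, tolerance = 1e-12)
})

test_that("unstable step sizes and bad initial data are rejected", {
  ic <- make_initial_condition("homog_eq", fig4, small_grid)
  expect_error(simulate_rde(actin_network(fig4), small_grid, ic, T = 1, dt = 1),
               "stability")
  ic$u[3] <- NaN
  expect_error(simulate_rde(actin_network(fig4), small_grid, ic, T = 1),
               "finite")
})

test_that("two standing pulses repel and the inhibitor stays elevated between them", {
  p <- fig4
  g <- wave_grid(-60, 60, 1200)  # dx = 0.1 keeps this test quick
  ic <- make_initial_condition("gaussian_bump", p, g)
  f <- simulate_rde(actin_network(p), g, ic, T = 40, dt = 1e-3)
  bg <- background_states(p)
  sep <- function(ti) {
    i <- which.min(abs(f$times - ti))
    u <- f$u[i, ]
    right <- which(g$x > 0)
    left <- which(g$x < 0)
    g$x[right[which.max(u[right])]] - g$x[left[which.max(u[left])]]
  }
  seps <- vapply(seq(10, 40, by = 5), sep, numeric(1))
  # separation is non-decreasing after formation (slow repulsion)
  expect_true(all(diff(seps) > -1e-9))
  # v does not return to background between the pulses
  i <- length(f$times)
  mid <- which.min(abs(g$x))
  expect_gt(f$v[i, mid], bg$v_star[1] + 0.1)
})
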