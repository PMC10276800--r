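net4 <- actin_network(fig4)

test_that("from the empty state the first reaction is basal production", {
  omega <- 50
  # waiting time ~ Exp(a5 * omega); average the first-event time over seeds
  first <- vapply(1:400, function(s) {
    tr <- simulate_ssa_wellmixed(net4, omega, c(0, 0), T = 2, seed = s,
                                 n_save = 3L)
    tr$first_event_time
  }, numeric(1))
  rate <- fig4$a5 * omega
  se <- (1 / rate) / sqrt(length(first))
  expect_lt(abs(mean(first) - 1 / rate), 3.5 * se)
})

test_that("counts stay non-negative integers for any seed", {
  for (s in c(1, 17, 99)) {
    tr <- simulate_ssa_wellmixed(net4, 20, c(3, 1), T = 10, seed = s)
    expect_true(all(tr$u_counts >= 0) && all(tr$v_counts >= 0))
    expect_true(all(tr$u_counts == round(tr$u_counts)))
  }
})

test_that("SSA propensity scaling has the macroscopic limit", {
  # count-rates divided by omega converge to the concentration propensities
  conc <- c(0.7, 1.9)
  R_conc <- propensities(net4, conc)
  for (omega in c(1e2, 1e4, 1e6)) {
    counts <- conc * omega
    p <- fig4
    count_rates <- c(p$a1 * counts[1],
                     p$a2 * counts[1] * counts[2] / omega,
                     omega * p$a3 * (counts[1] / omega)^2 /
                       (p$a4 + (counts[1] / omega)^2),
                     p$a5 * omega,
                     p$eps * p$c1 * counts[2],
                     p$eps * p$c2 * counts[1])
    expect_equal(count_rates / omega, unname(R_conc), tolerance = 1e-12)
  }
})

test_that("SSA first moments converge to the kinetics ODE as omega grows", {
  skip_if_not_installed("deSolve")
  x0 <- c(0.4, 2.5)
  Tend <- 3
  ref <- deSolve::ode(y = x0, times = c(0, Tend),
                      func = function(t, y, parms)
                        list(kinetics_rhs(y[1], y[2], fig4)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)[2, 2:3]
  err <- vapply(c(100, 1000, 10000), function(omega) {
    runs <- vapply(1:40, function(s) {
      tr <- simulate_ssa_wellmixed(net4, omega, round(x0 * omega), T = Tend,
                                   seed = s, n_save = 2L)
      c(tr$u[2], tr$v[2])
    }, numeric(2))
    sqrt(sum((rowMeans(runs) - ref)^2))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2] + 0.01)  # allow Monte-Carlo noise at large omega
  expect_lt(err[3], 0.05)
})

test_that("diffusion-only spatial SSA conserves molecules exactly", {
  g <- wave_grid(-2, 2, 32)
  set.seed(12)
  icu <- rpois(g$n, 20); icv <- rpois(g$n, 10)
  f <- simulate_rdme(net4, g, omega = 100, ic_counts = list(u = icu, v = icv),
                     T = 2, seed = 4, n_save = 21L, reactions_on = FALSE)
  tot_u <- rowSums(f$u_counts)
  tot_v <- rowSums(f$v_counts)
  expect_true(all(tot_u == sum(icu)))
  expect_true(all(tot_v == sum(icv)))
  expect_gt(f$n_events, 0)
})

test_that("a single diffusing molecule spreads like a random walk", {
  g <- wave_grid(-5, 5, 100)
  mid <- 50
  Tend <- 0.5  # keep displacements well below the half-domain
  msd <- vapply(1:300, function(s) {
    icu <- integer(g$n); icu[mid] <- 1L
    f <- simulate_rdme(net4, g, omega = 10,
                       ic_counts = list(u = icu, v = integer(g$n)),
                       T = Tend, seed = s, n_save = 2L, reactions_on = FALSE)
    pos <- which(f$u_counts[2, ] == 1)
    d <- (pos - mid) * g$dx
    (d - g$length * round(d / g$length))^2
  }, numeric(1))
  expected <- 2 * fig4$Du * Tend
  se <- stats::sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - expected), 4 * se)
})

test_that("RDME fronts approach the deterministic wave speed at large omega", {
  g <- wave_grid(-20, 20, 400)  # dx = 0.1 keeps event counts manageable
  ic <- make_initial_condition("gaussian_bump", fig11, g)
  f <- simulate_rdme(actin_network(fig11), g, omega = 5000, ic_conc = ic,
                     T = 6, seed = 2, n_save = 61L)
  sp <- measure_speed(f, window = c(1.5, 5), x_range = c(-19, -0.1))
  det <- simulate_rde(actin_network(fig11), g,
                      make_initial_condition("gaussian_bump", fig11, g), T = 6)
  sp_det <- measure_speed(det, window = c(1.5, 5), x_range = c(-19, -0.1))
  expect_equal(sp, sp_det, tolerance = 0.15)
})
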