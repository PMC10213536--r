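test_that("derivatives match the hand-evaluated dynamics and conserve N", {
  p <- sirs_params(alpha = 1, beta = 0.2, lam = 0.3, delta = 0.1, N = 1)
  d <- sirs_derivatives(c(0.5, 0.3, 0.2), p)
  expect_equal(unname(d), c(-0.06, 0.06, 0), tolerance = 1e-12)
  # diffusion-free state is a fixed point
  expect_equal(unname(sirs_derivatives(c(1, 0, 0), p)), c(0, 0, 0))
  # conservation holds algebraically at random states
  set.seed(6)
  for (i in 1:25) {
    st <- runif(3)
    expect_equal(sum(sirs_derivatives(st, p)), 0, tolerance = 1e-14)
  }
  expect_error(sirs_derivatives(c(-0.1, 0.5, 0.6), p), ">= 0")
})

test_that("parameter validation enforces strict positivity", {
  expect_error(sirs_params(0, 0.2, 0.3, 0.1), "> 0")
  expect_error(sirs_params(1, -0.2, 0.3, 0.1), "> 0")
  expect_error(sirs_params(1, 0.2, 0.3, 0.1, N = 0), "N must be > 0")
})

test_that("closed-form steady state matches the worked example", {
  p <- sirs_params(1, 0.2, 0.3, 0.1, N = 1)
  eq <- sirs_steady_state(p)
  expect_true(eq$endemic)
  expect_equal(eq$S_star, 0.30, tolerance = 1e-12)
  expect_equal(eq$I_star, 0.42, tolerance = 1e-12)
  expect_equal(eq$R_star, 0.28, tolerance = 1e-12)
  expect_equal(eq$S_star + eq$I_star + eq$R_star, p$N, tolerance = 1e-12)
  # derivatives vanish at the equilibrium
  d <- sirs_derivatives(c(eq$S_star, eq$I_star, eq$R_star), p)
  expect_lt(sqrt(sum(d^2)), 1e-10)
})

test_that("threshold behaviour of the equilibrium", {
  # alpha N = beta + delta exactly: boundary, diffusion-free
  p0 <- sirs_params(0.3, 0.2, 0.3, 0.1, N = 1)
  eq0 <- sirs_steady_state(p0)
  expect_false(eq0$endemic)
  expect_equal(c(eq0$S_star, eq0$I_star, eq0$R_star), c(1, 0, 0))
  # below threshold
  eqb <- sirs_steady_state(sirs_params(0.25, 0.2, 0.3, 0.1, N = 1))
  expect_false(eqb$endemic)
  # the interior formula degenerates continuously to (N, 0, 0) at the boundary
  eps <- 1e-10
  eqa <- sirs_steady_state(sirs_params(0.3 + eps, 0.2, 0.3, 0.1, N = 1))
  expect_lt(eqa$I_star, 1e-9)
})

test_that("trajectories conserve population and converge to the equilibrium", {
  p <- sirs_params(1, 0.2, 0.3, 0.1, N = 1)
  tr <- sirs_simulate(p, c(0.98, 0.02, 0), t_end = 300, dt = 0.05)
  expect_true(all(abs(rowSums(tr[, c("S", "I", "R")]) - 1) <= 1e-8))
  terminal <- unlist(tr[nrow(tr), c("S", "I", "R")])
  expect_equal(unname(terminal), c(0.30, 0.42, 0.28), tolerance = 1e-6)
  # no contagion without initial risk-aware individuals
  tr0 <- sirs_simulate(p, c(0.7, 0, 0.3), t_end = 60, dt = 0.05)
  expect_true(all(tr0$I == 0))
  t_terminal <- unlist(tr0[nrow(tr0), c("S", "I", "R")])
  expect_equal(unname(t_terminal), c(1, 0, 0), tolerance = 1e-6)
  # R decays into S like exp(-lam t) when I = 0
  expect_lt(max(abs(tr0$R - 0.3 * exp(-0.3 * tr0$time))), 1e-8)
  expect_error(sirs_simulate(p, c(0.5, 0.2, 0.2), 10), "sum to N")
  expect_error(sirs_simulate(p, c(-0.1, 0.4, 0.7), 10), ">= 0")
})

test_that("integrator accuracy: halving the step barely moves the endpoint", {
  p <- sirs_params(1, 0.2, 0.3, 0.1, N = 1)
  t1 <- sirs_simulate(p, c(0.98, 0.02, 0), t_end = 50, dt = 0.05)
  t2 <- sirs_simulate(p, c(0.98, 0.02, 0), t_end = 50, dt = 0.025)
  d <- max(abs(unlist(t1[nrow(t1), -1]) - unlist(t2[nrow(t2), -1])))
  expect_lt(d, 1e-8)
  # built-in step-halving verification passes at this step size
  expect_silent(sirs_simulate(p, c(0.98, 0.02, 0), t_end = 10, dt = 0.05,
                              verify = TRUE, check_tol = 1e-8))
})

test_that("trajectory matches an independent adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- sirs_params(0.8, 0.15, 0.25, 0.05, N = 1)
  rhs <- function(t, y, parms) list(unname(sirs_derivatives(y, p)))
  ref <- deSolve::ode(c(S = 0.9, I = 0.1, R = 0), seq(0, 40, 1), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  mine <- sirs_simulate(p, c(0.9, 0.1, 0), t_end = 40, dt = 0.02)
  at <- seq(1, nrow(mine), by = 50)      # rows at integer times
  expect_equal(mine$S[at], unname(ref[, "S"]), tolerance = 1e-7)
  expect_equal(mine$I[at], unname(ref[, "I"]), tolerance = 1e-7)
})

test_that("random endemic draws converge to the closed form", {
  set.seed(14)
  for (i in 1:50) {
    repeat {
      a <- runif(1, 0.3, 2); b <- runif(1, 0.05, 0.4)
      l <- runif(1, 0.05, 0.5); dl <- runif(1, 0.02, 0.3)
      if (a * 1 > b + dl + 0.05) break   # clearly endemic
    }
    p <- sirs_params(a, b, l, dl, N = 1)
    eq <- sirs_steady_state(p)
    d <- sirs_derivatives(c(eq$S_star, eq$I_star, eq$R_star), p)
    expect_lt(sqrt(sum(d^2)), 1e-10)
    tr <- sirs_simulate(p, c(0.97, 0.03, 0), t_end = 400, dt = 0.1)
    terminal <- unlist(tr[nrow(tr), c("S", "I", "R")])
    expect_lt(max(abs(terminal - c(eq$S_star, eq$I_star, eq$R_star))) /
                max(abs(c(eq$S_star, eq$I_star, eq$R_star))), 1e-5)
  }
})

test_that("risk awareness decays below threshold and grows above it", {
  below <- sirs_params(0.25, 0.2, 0.3, 0.1, N = 1)
  tr_b <- sirs_simulate(below, c(1 - 1e-3, 1e-3, 0), t_end = 200, dt = 0.05)
  expect_lt(tr_b$I[nrow(tr_b)], 1e-6)
  above <- sirs_params(0.6, 0.2, 0.3, 0.1, N = 1)
  tr_a <- sirs_simulate(above, c(1 - 1e-3, 1e-3, 0), t_end = 200, dt = 0.05)
  eq_a <- sirs_steady_state(above)
  expect_gt(tr_a$I[nrow(tr_a)], 0.5 * eq_a$I_star)
})

test_that("comparative statics: undecided pool shrinks as ties strengthen", {
  p <- sirs_params(1, 0.2, 0.3, 0.1, N = 1)
  grid <- seq(0.1, 2, by = 0.05)
  cs <- sirs_comparative_statics(p, grid)
  expect_identical(names(cs), c("alpha", "S_star", "I_star", "R_star",
                                "endemic"))
  # endemic flag flips exactly once along a grid spanning the threshold
  expect_equal(sum(diff(cs$endemic) != 0), 1)
  en <- cs[cs$endemic, ]
  expect_true(all(diff(en$S_star) < 0))
  expect_true(all(diff(en$I_star) >= 0))
  expect_true(all(diff(en$R_star) >= 0))
  # exact inverse proportionality: doubling alpha halves S*
  eq_half <- sirs_steady_state(sirs_params(0.5, 0.2, 0.3, 0.1, N = 1))
  eq_full <- sirs_steady_state(sirs_params(1.0, 0.2, 0.3, 0.1, N = 1))
  expect_equal(eq_full$S_star, eq_half$S_star / 2, tolerance = 1e-12)
  # finite-difference slope matches the analytic derivative within 1%
  i <- which(en$alpha >= 0.8)[1]
  h <- en$alpha[i + 1] - en$alpha[i]
  fd <- (en$S_star[i + 1] - en$S_star[i]) / h
  a_mid <- (en$alpha[i] + en$alpha[i + 1]) / 2
  expect_lt(abs(fd - (-(p$beta + p$delta) / a_mid^2)) /
              ((p$beta + p$delta) / a_mid^2), 0.01)
  # S* does not depend on the abandonment rate lam
  cs2 <- sirs_comparative_statics(sirs_params(1, 0.2, 0.45, 0.1, N = 1), grid)
  expect_equal(cs$S_star, cs2$S_star, tolerance = 1e-12)
  expect_error(sirs_comparative_statics(p, c(0.5, 0.4)), "increasing")
})
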