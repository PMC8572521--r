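test_that("Type-2 growth rate matches its closed form and saturates", {
  p <- ref_params()
  expect_identical(growth_rate(0, 7.5, p), 0)
  # hand evaluation: x * y * N / (N + N_H) = 0.0206 * 7.5 * 1/2
  expect_equal(growth_rate(1, 7.5, p), 0.077250, tolerance = 1e-12)
  expect_equal(growth_rate(1e9, 7.5, p), p$x * 7.5, tolerance = 1e-6)
  # strictly increasing, bounded by the saturation level
  g <- growth_rate(seq(0, 50, length.out = 200), 4, p)
  expect_true(all(diff(g) > 0))
  expect_true(all(g < p$x * 4))
  expect_error(growth_rate(-0.1, 7.5, p), "non-negative")
})

test_that("lysis laws reproduce the switching points and their limits", {
  p <- ref_params()
  # the tabulated switch densities give the 0.0033/h switching rate
  expect_equal(lysis_rate("ptl", 0.2010076, 0, p), 0.0033,
               tolerance = 1e-6)
  expect_equal(lysis_rate("ptw", 19.8997500, 0, p), 0.0033,
               tolerance = 1e-6)
  # and inverting the laws recovers the tabulated densities
  expect_equal(switch_density("ptl", p), 0.2010076, tolerance = 1e-6)
  expect_equal(switch_density("ptw", p), 19.8997500, tolerance = 1e-6)
  # limits at zero host density
  expect_identical(lysis_rate("ptl", 0, 0, p), 0)
  expect_equal(lysis_rate("ptw", 0, 0, p), p$s_max / p$H)
  # constant and absent strategies
  expect_equal(lysis_rate("lytic", 123.4, 5, p), 0.33)
  expect_identical(lysis_rate("none", 1, 1, p), 0)
  # the split between B and I is irrelevant, only the total counts
  expect_equal(lysis_rate("ptl", 0.3, 0.7, p), lysis_rate("ptl", 1, 0, p))
})

test_that("lysis rates are monotone in host density and bounded", {
  p <- ref_params()
  h <- seq(0, 100, length.out = 250)
  s_ptl <- lysis_rate("ptl", h, 0, p)
  s_ptw <- lysis_rate("ptw", h, 0, p)
  expect_true(all(diff(s_ptl) > 0))
  expect_true(all(diff(s_ptw) < 0))
  bound <- p$s_max / min(1, p$H)
  for (s in list(s_ptl, s_ptw, lysis_rate("lytic", h, 0, p)))
    expect_true(all(s >= 0 & s <= bound + 1e-12))
  # PtL never reaches s_max, PtW tops out at s_max / H
  expect_true(all(s_ptl < p$s_max))
  expect_true(max(s_ptw) <= p$s_max / p$H)
})

test_that("rate-based growth switch equals the density-threshold form", {
  p <- ref_params()
  set.seed(42)
  h <- c(runif(500, 0, 1), runif(500, 0, 50))  # dense near the PtL switch
  for (strat in c("ptl", "ptw")) {
    s <- lysis_rate(strat, h, 0, p)
    by_rate <- growth_enabled(strat, s, p)
    thr <- switch_density(strat, p)
    by_density <- if (strat == "ptl") h <= thr else h >= thr
    expect_identical(by_rate, by_density)
  }
  expect_false(any(growth_enabled("lytic", c(0, 0.001, 0.33), p)))
})

test_that("turnover forcing has mean D, stays positive, and validates a", {
  p0 <- ref_params(a = 0)
  expect_equal(turnover_rate(c(0, 17, 1e5), p0), rep(p0$D, 3))
  p <- ref_params(a = 0.5, T = 24)
  expect_equal(turnover_rate(0, p), p$D)
  expect_equal(turnover_rate(6, p), 1.5 / 24, tolerance = 1e-12)  # t = T/4
  tt <- seq(0, 24, length.out = 1e4 + 1)
  expect_equal(mean(turnover_rate(tt[-1], p)), p$D, tolerance = 1e-4)
  p9 <- ref_params(a = 0.99, T = 24)
  expect_true(all(turnover_rate(tt, p9) > 0))
  expect_error(phage_params(a = 1), "amplitude")
  expect_error(phage_params(a = 1.2), "amplitude")
})

test_that("washout and single-species chemostat fixed points annihilate the RHS", {
  p <- ref_params()
  washout <- phage_state(0, 0, 0, 0, 0, 0, N = p$N0)
  for (strat in PHAGE_STRATEGIES) {
    f <- phage_derivs(0, washout, list(params = p, strategy = strat))[[1]]
    expect_identical(max(abs(f)), 0)
  }
  eq <- chemostat_equilibrium(p)
  st <- phage_state(eq$B, 0, 0, 0, 0, 0, N = eq$N)
  f <- phage_derivs(0, st, list(params = p, strategy = "none"))[[1]]
  expect_lt(max(abs(f)), 1e-12)
})

test_that("derivative bookkeeping: shunt at n = 1, c = 0 infection terms, forcing identity", {
  set.seed(7)
  st <- phage_state(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 1),
                    runif(1, 0, 1), runif(1, 0, 0.1), runif(1, 0, 0.1),
                    N = runif(1, 0.5, 5))
  # n = 1: the viral shunt contributes exactly nothing to the nutrient
  for (strat in c("lytic", "ptw", "ptl")) {
    f_on <- phage_derivs(0, st, list(params = ref_params(n = 1),
                                     strategy = strat))[[1]]
    f_off <- phage_derivs(0, st,
                          list(params = ref_params(n = 1,
                                                   shunt_enabled = FALSE),
                               strategy = strat))[[1]]
    expect_equal(f_on, f_off, tolerance = 1e-15)
  }
  # c = 0: no phage loss via infection; infected gain is exactly i*B*P
  p0 <- ref_params(c = 0)
  f <- phage_derivs(0, st, list(params = p0, strategy = "lytic"))[[1]]
  s <- pmax(st, 0)
  expect_equal(unname(f[5]), p0$n * p0$s_max * s[["I1"]] - p0$d * s[["P1"]],
               tolerance = 1e-15)
  gain <- p0$i_norm * s[["B1"]] * s[["P1"]]
  expect_equal(unname(f[3]), gain + 0 - p0$x * s[["I1"]] - p0$s_max * s[["I1"]],
               tolerance = 1e-15)
  # a = 0: the RHS is autonomous
  p <- ref_params(a = 0)
  for (strat in PHAGE_STRATEGIES)
    expect_identical(
      phage_derivs(0, st, list(params = p, strategy = strat)),
      phage_derivs(9876.5, st, list(params = p, strategy = strat)))
  # none: infected and phage compartments are inert
  f_none <- phage_derivs(0, st, list(params = p, strategy = "none"))[[1]]
  expect_identical(unname(f_none[3:6]), rep(0, 4))
})

test_that("compiled and R right-hand sides produce the same trajectories", {
  cases <- list(
    list(strategy = "lytic", params = phage_params(N0 = 2)),
    list(strategy = "ptw", params = phage_params(N0 = 5)),
    list(strategy = "ptl", params = phage_params(N0 = 3, a = 0.5, T = 168)),
    list(strategy = "none", params = phage_params(N0 = 2)))
  for (cs in cases) {
    spec <- simulation_spec(cs$strategy, cs$params,
                            initial_state = phage_state(N = cs$params$N0),
                            t_end = 400, rel_tol = 1e-10, abs_tol = 1e-10)
    traj_c <- run_simulation(spec)
    init <- spec$initial_state
    if (cs$strategy == "none") init[c("I1", "I2", "P1", "P2")] <- 0
    traj_r <- deSolve::ode(init, seq(0, 400, 1), phage_derivs,
                           parms = list(params = cs$params,
                                        strategy = cs$strategy),
                           method = deSolve::rkMethod("rk45ck"),
                           rtol = 1e-10, atol = 1e-10)
    fin_c <- unlist(tail(as.data.frame(traj_c), 1)[-1])
    fin_r <- unname(tail(as.data.frame(traj_r), 1))[-1]
    expect_equal(unname(fin_c), as.numeric(fin_r), tolerance = 1e-6,
                 label = paste("final state,", cs$strategy))
  }
})
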