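test_that("extrema detector separates steady, oscillating and damped series", {
  ext <- detect_extrema(rep(3.2, 50))
  expect_false(ext$oscillating)
  expect_equal(ext$maxima, 3.2)
  # three periods of a sine: extrema near +1 and -1
  s <- 2 + sin(seq(0, 6 * pi, by = 0.01))
  ext <- detect_extrema(s)
  expect_true(ext$oscillating)
  expect_equal(unique(round(ext$maxima, 4)), 3)
  expect_equal(unique(round(ext$minima, 4)), 1)
  expect_length(ext$maxima, 3)
  # damped oscillation sampled after the transient has died away
  tt <- seq(200, 300, by = 0.1)
  damped <- 1 + exp(-tt / 10) * cos(tt)
  expect_false(detect_extrema(damped)$oscillating)
  # ... but flagged oscillating while the amplitude is still large
  tt0 <- seq(0, 50, by = 0.1)
  expect_true(detect_extrema(1 + exp(-tt0 / 10) * cos(tt0))$oscillating)
  expect_error(detect_extrema(c(1, 2)), "3 samples")
})

test_that("persistence codes follow the state-count ladder", {
  base <- list(B1 = 1, B2 = 1, I1 = 0.2, I2 = 0.2, P1 = 0.01, P2 = 0.01,
               N = 1)
  expect_identical(classify_persistence(synthetic_trajectory(base))$code, 4L)
  # slow grower and its infection extinct -> fast grower + infection
  lv <- base; lv$B2 <- 1e-9; lv$I2 <- 0; lv$P2 <- 0
  ps <- classify_persistence(synthetic_trajectory(lv))
  expect_identical(ps$code, 2L)
  expect_identical(unname(ps$survived), c(TRUE, TRUE, FALSE, FALSE))
  # an infection needs BOTH infected cells and free phage
  lv <- base; lv$P1 <- 1e-12
  ps <- classify_persistence(synthetic_trajectory(lv))
  expect_false(ps$survived[["inf1"]])
  expect_identical(ps$code, 3L)
  # everything extinct
  lv <- lapply(base, function(x) 0); lv$N <- 1
  expect_identical(classify_persistence(synthetic_trajectory(lv))$code, 0L)
})

test_that("raising the extinction threshold never raises the code", {
  traj <- run_simulation(quick_spec("ptl", N0 = 2, t_end = 4000))
  thr <- 10^seq(-10, 0, length.out = 40)
  codes <- vapply(thr, function(th) classify_persistence(traj, th)$code,
                  integer(1))
  expect_true(all(diff(codes) <= 0))
})

test_that("survival uses the post-transient maximum, not the final value", {
  # oscillating component that ends low but peaks high inside the window
  tt <- seq(0, 100, length.out = 401)
  df <- data.frame(time_h = tt, B1 = 0.5 + 0.5 * sin(tt / 3), B2 = 1,
                   I1 = 0.1, I2 = 0.1, P1 = 0.01, P2 = 0.01, N = 1)
  df$B1[length(tt)] <- 1e-9
  spec <- simulation_spec("lytic", phage_params(), t_end = 100,
                          transient_fraction = 0)
  traj <- structure(df, spec = spec,
                    class = c("phage_trajectory", "data.frame"))
  expect_true(classify_persistence(traj)$survived[["B1"]])
})

test_that("bisection recovers a known transition and rejects flat brackets", {
  # monotone synthetic predicate: survive iff N0 < 10
  pred <- function(N0) N0 < 10
  est <- find_critical_N0("lytic", component = "B1", bracket = c(5, 30),
                          tolerance = 0.01, survives = pred)
  expect_equal(est, 10, tolerance = 0.011)
  expect_error(
    find_critical_N0("lytic", bracket = c(1, 5), tolerance = 0.1,
                     survives = pred),
    "straddle")
  expect_error(
    find_critical_N0("lytic", component = "Z9", bracket = c(1, 5)),
    "unknown component")
})

test_that("bifurcation scans classify, record extrema, and tolerate failures", {
  bd <- bifurcation_scan("lytic", phage_params(), N0_grid = c(2, 20),
                         t_end = 20000, output_step = 1)
  expect_identical(bd$codes, c(4L, 4L))
  # N0 = 2 settles; N0 = 20 cycles (paradox of enrichment)
  expect_false(bd$extrema[[1]]$B1$oscillating)
  expect_true(bd$extrema[[2]]$B1$oscillating)
  expect_true(all(bd$extrema[[2]]$B1$minima <= min(bd$extrema[[2]]$B1$maxima)))
  expect_identical(coexistence_onset(bd), 2)
  td <- withr::local_tempdir()
  write_bifurcation(bd, file.path(td, "bif.csv"))
  long <- utils::read.csv(file.path(td, "bif.csv"))
  expect_setequal(names(long), c("N0", "variable", "extremum_type", "value"))
  expect_setequal(unique(long$variable),
                  c("B1", "B2", "I1", "I2", "P1", "P2", "N"))
})

test_that("sweeps are deterministic and serialize to TSV + flags CSV", {
  grid_a <- c(0, 0.9); grid_n <- c(1, 4)
  run <- function() sweep_2d("ptw", phage_params(), "amplitude",
                             grid_a, grid_n, t_end = 6000, output_step = 4)
  s1 <- run(); s2 <- run()
  expect_identical(s1$codes, s2$codes)
  expect_identical(s1$survived, s2$survived)
  expect_identical(dim(s1$codes), c(2L, 2L))
  td <- withr::local_tempdir()
  write_sweep(s1, file.path(td, "sweep.tsv"))
  m <- utils::read.delim(file.path(td, "sweep.tsv"), check.names = FALSE)
  expect_identical(dim(m), c(2L, 3L))  # axis column + one per N0
  expect_identical(as.integer(as.matrix(m[, -1])), as.integer(s1$codes))
  fl <- utils::read.csv(file.path(td, "sweep_flags.csv"))
  expect_identical(nrow(fl), 4L)
  expect_true(all(c("amplitude", "N0", "code", "B1", "inf1", "B2", "inf2")
                  %in% names(fl)))
})
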