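test_that("no doses and a drug-free start give identically zero concentrations", {
  p <- pk_params(cl = 5, v1 = 50)
  tc <- rk4_solve(p, NULL, horizon_h = 6)
  expect_identical(max(abs(tc$conc_mg_l)), 0)
  expect_length(tc$times_h, 6 * 60 + 1)
  expect_equal(diff(tc$times_h), rep(1 / 60, 6 * 60), tolerance = 1e-12)
  p2 <- pk_params(cl = 5, v1 = 30, q = 6, v2 = 40)
  tc2 <- rk4_solve(p2, NULL, horizon_h = 3)
  expect_identical(max(abs(tc2$conc_mg_l)), 0)
})

test_that("RK4 at 1-minute steps matches the one-compartment closed form", {
  p <- pk_params(cl = 4.58, v1 = 107.1)
  ev <- regular_events(1000, 12, 4, infusion_min = 60)
  tc <- rk4_solve(p, ev, horizon_h = 48)
  cf <- closed_form_one_compartment(p, ev, tc$times_h)
  expect_lt(max(abs(tc$conc_mg_l - cf)), 1e-3)
  expect_lt(median(abs(tc$conc_mg_l - cf)), 1e-3)
})

test_that("halving the step shrinks the RK4 error about 16-fold (4th order)", {
  # a fast-eliminating test problem so the discretization error is
  # measurable above double precision
  p <- pk_params(cl = 40, v1 = 10)
  ev <- dose_events(1000, 0, 30)
  err_at <- function(step_min) {
    tc <- rk4_solve(p, ev, horizon_h = 2, step_min = step_min)
    max(abs(tc$conc_mg_l - closed_form_one_compartment(p, ev, tc$times_h)))
  }
  ratio <- err_at(1) / err_at(0.5)
  expect_gt(ratio, 10)
  expect_lt(ratio, 25)
})

test_that("the system is linear: doubling doses doubles concentrations, superposition holds", {
  p <- pk_params(cl = 6, v1 = 40, q = 8, v2 = 60)
  ev1 <- dose_events(c(500, 750), c(0, 8), c(30, 60))
  ev2 <- dose_events(c(250), c(4), c(120))
  both <- dose_events(c(500, 750, 250), c(0, 8, 4), c(30, 60, 120))
  tc1 <- rk4_solve(p, ev1, 24)
  tc2 <- rk4_solve(p, ev2, 24)
  tc_both <- rk4_solve(p, both, 24)
  expect_equal(tc_both$conc_mg_l, tc1$conc_mg_l + tc2$conc_mg_l,
               tolerance = 1e-9)
  doubled <- ev1
  doubled$amount_mg <- 2 * doubled$amount_mg
  tc_d <- rk4_solve(p, doubled, 24)
  expect_equal(tc_d$conc_mg_l, 2 * tc1$conc_mg_l, tolerance = 1e-12)
})

test_that("mass is conserved when there is no elimination", {
  p1 <- pk_params(cl = 0, v1 = 50)
  ev <- dose_events(c(400, 600), c(0, 3), c(60, 30))
  tc <- rk4_solve(p1, ev, 8)
  expect_equal(sum(tc$amounts_mg[nrow(tc$amounts_mg), ]), 1000,
               tolerance = 1e-9)
  p2 <- pk_params(cl = 0, v1 = 30, q = 5, v2 = 60)
  tc2 <- rk4_solve(p2, ev, 8)
  expect_equal(sum(tc2$amounts_mg[nrow(tc2$amounts_mg), ]), 1000,
               tolerance = 1e-9)
})

test_that("concentrations stay non-negative for non-negative inputs", {
  set.seed(11)
  for (i in 1:10) {
    p <- pk_params(cl = runif(1, 0.5, 30), v1 = runif(1, 10, 150),
                   q = runif(1, 1, 60), v2 = runif(1, 10, 150))
    ev <- dose_events(runif(3, 100, 2000), c(0, 6, 12), sample(30:120, 3, TRUE))
    tc <- rk4_solve(p, ev, 36)
    expect_gte(min(tc$conc_mg_l), 0)
    expect_gte(min(tc$amounts_mg), 0)
  }
})

test_that("RK4 agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- pk_params(cl = 10, v1 = 25, q = 15, v2 = 80)
  ev <- dose_events(1000, 0, 60)
  tc <- rk4_solve(p, ev, 12)
  rhs <- function(t, A, parms) {
    u <- if (t < 1) 1000 else 0
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    list(c(u - (k10 + k12) * A[1] + k21 * A[2], k12 * A[1] - k21 * A[2]))
  }
  ref <- deSolve::lsoda(c(0, 0), times = tc$times_h, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tc$conc_mg_l - ref[, 2] / p$v1)), 1e-5)
})

test_that("closed form handles bolus limit, zero start and washout", {
  p <- pk_params(cl = 5, v1 = 100)
  ev <- dose_events(1000, 0, 1)
  expect_identical(closed_form_one_compartment(p, ev, 0), 0)
  c_end <- closed_form_one_compartment(p, ev, 1 / 60)
  expect_equal(c_end, 10, tolerance = 0.01)   # D/V with 1-min decay slack
  expect_lt(closed_form_one_compartment(p, ev, 1e4), 1e-12)
  p2 <- pk_params(cl = 5, v1 = 50, q = 5, v2 = 20)
  expect_error(closed_form_one_compartment(p2, ev, 1), "one-compartment")
})

test_that("dose events are validated against the horizon and sign constraints", {
  p <- pk_params(cl = 5, v1 = 50)
  expect_error(rk4_solve(p, dose_events(500, 30, 60), horizon_h = 24),
               "horizon")
  expect_error(dose_events(-5, 0, 60), ">= 0")
  expect_error(dose_events(500, 0, 0.5), "1 minute")
  expect_error(rk4_solve(p, NULL, horizon_h = 0), "> 0")
  expect_error(rk4_solve(p, NULL, 5, initial_amounts = c(1, 2)),
               "per compartment")
})

test_that("exposure summary: rectangle AUC, %T>MIC bounds, window checks", {
  n <- 24 * 60
  tc <- conc_time_course(times_h = (0:n) / 60, conc_mg_l = rep(5, n + 1),
                         amounts_mg = matrix(5 * 40, n + 1, 1), step_min = 1)
  s <- summarize_exposure(tc, window = c(0, 24), mic_mg_l = 1)
  expect_equal(s$auc_mg_h_l, 120, tolerance = 1e-12)
  expect_identical(s$pct_time_above_mic, 100)
  expect_identical(s$cmin_mg_l, 5)
  expect_identical(s$cmax_mg_l, 5)
  expect_identical(summarize_exposure(tc, c(0, 24), mic_mg_l = 5)$pct_time_above_mic, 0)
  expect_error(summarize_exposure(tc, c(10, 10)), "empty")
  expect_error(summarize_exposure(tc, c(20, 30)), "span")
})

test_that("steady-state daily AUC equals daily dose over clearance", {
  p <- pk_params(cl = 4.58, v1 = 107.1)
  ss <- simulate_steady_state(p, 1000, 12, infusion_min = 60)
  expect_equal(ss$exposure$auc_mg_h_l, 2000 / 4.58, tolerance = 0.01)
})

test_that("terminal half-life and seven-half-life rule match direct formulas", {
  p <- pk_params(cl = 4.58, v1 = 107.1)
  expect_equal(terminal_half_life(p), log(2) * 107.1 / 4.58, tolerance = 1e-12)
  expect_equal(terminal_half_life(p), 16.21, tolerance = 1e-3)
  expect_equal(time_to_steady_state(p), 113.5, tolerance = 1e-3)
  p_unit <- pk_params(cl = 3, v1 = 3)   # k = 1 per hour
  expect_equal(terminal_half_life(p_unit), log(2), tolerance = 1e-12)
  expect_equal(time_to_steady_state(p_unit), 7 * log(2), tolerance = 1e-12)
})

test_that("two-compartment half-life uses the slow exponent (eigen oracle)", {
  set.seed(21)
  for (i in 1:5) {
    p <- pk_params(cl = runif(1, 1, 20), v1 = runif(1, 10, 80),
                   q = runif(1, 1, 50), v2 = runif(1, 10, 150))
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    M <- matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2)
    slow <- -max(Re(eigen(M)$values))
    expect_equal(terminal_half_life(p), log(2) / slow, tolerance = 1e-9)
    expect_gte(terminal_half_life(p) + 1e-12,
               terminal_half_life(pk_params(p$cl, p$v1)))
  }
})

test_that("time-course CSV export is two columns with optional ISO timestamps", {
  p <- pk_params(cl = 5, v1 = 50)
  tc <- rk4_solve(p, dose_events(500, 0, 60), 2)
  f <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f)
  d <- read.csv(f)
  expect_named(d, c("time_h", "conc_mg_l"))
  expect_equal(nrow(d), 121)
  write_timecourse_csv(tc, f, t0 = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"))
  d2 <- read.csv(f)
  expect_named(d2, c("time", "conc_mg_l"))
  expect_identical(d2$time[1], "2024-01-01T00:00:00Z")
})
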