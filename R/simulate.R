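#' Construct a dose-event table
#'
#' @param amount_mg Dose amounts (mg), >= 0.
#' @param time_h Infusion start times (hours), snapped to the simulation
#'   grid at solve time.
#' @param infusion_min Infusion durations in minutes (>= 1; a bolus is
#'   modeled as a 1-minute infusion).
#' @param drug Optional drug label.
#' @return A `data.frame` of class `dose_events`.
#' @export
dose_events <- function(amount_mg, time_h, infusion_min, drug = NA_character_) {
  n <- max(length(amount_mg), length(time_h), length(infusion_min))
  if (n == 0)
    return(structure(data.frame(drug = character(), amount_mg = numeric(),
                                time_h = numeric(), infusion_min = numeric()),
                     class = c("dose_events", "data.frame")))
  d <- data.frame(drug = rep_len(drug, n), amount_mg = rep_len(amount_mg, n),
                  time_h = rep_len(time_h, n),
                  infusion_min = rep_len(infusion_min, n))
  if (any(d$amount_mg < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  if (any(d$infusion_min < 1)) stop("infusion_min must be >= 1 minute", call. = FALSE)
  structure(d, class = c("dose_events", "data.frame"))
}

# Per-step infusion rate vector (mg/h) on a uniform grid. Step i covers
# [t_{i-1}, t_i); an event contributes its constant rate to every step whose
# start lies within the (grid-snapped) infusion window.
infusion_rate_vector <- function(events, n_steps, step_min) {
  rate <- numeric(n_steps)
  if (is.null(events) || nrow(events) == 0) return(rate)
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$time_h[i] * 60 / step_min)            # start step index (0-based)
    nd <- max(1L, round(events$infusion_min[i] / step_min))  # duration in steps
    r <- events$amount_mg[i] / (nd * step_min / 60)          # mg/h
    lo <- i0 + 1L
    hi <- min(i0 + nd, n_steps)
    if (lo <= hi) rate[lo:hi] <- rate[lo:hi] + r
  }
  rate
}

# Linear compartmental system matrix (amounts, mg):
#   dA1/dt = u(t) - (CL/V1) A1 - (Q/V1) A1 + (Q/V2) A2
#   dA2/dt =              (Q/V1) A1 - (Q/V2) A2
system_matrix <- function(params) {
  k10 <- params$cl / params$v1
  if (params$n_compartments == 1) return(matrix(-k10, 1, 1))
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2)
}

#' Simulate a concentration-time course with a fixed-step RK4 solver
#'
#' Integrates the one- or two-compartment linear ODE system with the
#' classical Runge-Kutta fourth-order method on a uniform grid (1-minute
#' steps by default). Infusions enter as a piecewise-constant forcing term
#' aligned to the grid: event start times are snapped to the nearest grid
#' point and the rate active at a step's start is held through the step, so
#' the forcing is exactly constant within every step and the RK4 update
#' reduces to a precomputed affine map.
#'
#' @param params A `pk_params` object (see [pk_params()],
#'   [compute_individual_parameters()]).
#' @param events A [dose_events()] table (may be empty).
#' @param horizon_h Simulation horizon in hours (> 0).
#' @param initial_amounts Optional vector of initial compartment amounts
#'   (mg), length = number of compartments; defaults to zero.
#' @param step_min Grid step in minutes (default 1).
#' @return A `conc_time_course`: list with `times_h` (grid, hours),
#'   `conc_mg_l` (central concentration) and `amounts_mg` (matrix, one
#'   column per compartment).
#' @export
rk4_solve <- function(params, events = NULL, horizon_h, initial_amounts = NULL,
                      step_min = 1) {
  if (horizon_h <= 0) stop("horizon_h must be > 0", call. = FALSE)
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$time_h < 0 | events$time_h > horizon_h))
      stop("dose event outside the simulation horizon", call. = FALSE)
    if (any(events$amount_mg < 0)) stop("dose amounts must be >= 0", call. = FALSE)
  }
  ncmt <- params$n_compartments
  n <- round(horizon_h * 60 / step_min)
  h <- step_min / 60
  M <- system_matrix(params)
  A0 <- initial_amounts %||% numeric(ncmt)
  if (length(A0) != ncmt) stop("initial_amounts must have one entry per compartment",
                               call. = FALSE)
  if (any(A0 < 0)) stop("initial amounts must be >= 0", call. = FALSE)
  rate <- infusion_rate_vector(events, n, step_min)

  # RK4 for dA/dt = M A + u e1 with u constant over the step is the affine
  # map A <- P A + q u, with P and q the degree-4 Taylor truncations below.
  I <- diag(ncmt)
  M2 <- M %*% M; M3 <- M2 %*% M; M4 <- M3 %*% M
  P <- I + h * M + h^2 / 2 * M2 + h^3 / 6 * M3 + h^4 / 24 * M4
  Qv <- (h * I + h^2 / 2 * M + h^3 / 6 * M2 + h^4 / 24 * M3)[, 1]

  amounts <- matrix(0, n + 1, ncmt)
  amounts[1, ] <- A0
  A <- A0
  if (ncmt == 1) {
    p11 <- P[1, 1]; q1 <- Qv[1]
    for (i in seq_len(n)) {
      A <- p11 * A + q1 * rate[i]
      amounts[i + 1, 1] <- A
    }
  } else {
    p11 <- P[1, 1]; p12 <- P[1, 2]; p21 <- P[2, 1]; p22 <- P[2, 2]
    q1 <- Qv[1]; q2 <- Qv[2]
    a1 <- A[1]; a2 <- A[2]
    for (i in seq_len(n)) {
      u <- rate[i]
      t1 <- p11 * a1 + p12 * a2 + q1 * u
      a2 <- p21 * a1 + p22 * a2 + q2 * u
      a1 <- t1
      amounts[i + 1, 1] <- a1
      amounts[i + 1, 2] <- a2
    }
  }
  conc_time_course(times_h = (0:n) * h, conc_mg_l = amounts[, 1] / params$v1,
                   amounts_mg = amounts, step_min = step_min)
}

#' Concentration-time course container
#'
#' @param times_h Uniform, strictly increasing time grid (hours).
#' @param conc_mg_l Central-compartment concentration at each grid point.
#' @param amounts_mg Matrix of compartment amounts (one column per
#'   compartment).
#' @param step_min Grid step (minutes).
#' @return Object of class `conc_time_course`.
#' @export
conc_time_course <- function(times_h, conc_mg_l, amounts_mg, step_min) {
  stopifnot(length(times_h) == length(conc_mg_l),
            nrow(amounts_mg) == length(times_h))
  structure(list(times_h = times_h, conc_mg_l = conc_mg_l,
                 amounts_mg = amounts_mg, step_min = step_min),
            class = "conc_time_course")
}

#' @export
print.conc_time_course <- function(x, ...) {
  cat(sprintf("<conc_time_course> %d points, %.3g-%.3g h (step %g min)\n",
              length(x$times_h), min(x$times_h), max(x$times_h), x$step_min))
  cat(sprintf("  Cmax %.4g mg/L, C(end) %.4g mg/L\n",
              max(x$conc_mg_l), x$conc_mg_l[length(x$conc_mg_l)]))
  invisible(x)
}

#' @export
as.data.frame.conc_time_course <- function(x, ...) {
  data.frame(time_h = x$times_h, conc_mg_l = x$conc_mg_l)
}

#' Closed-form one-compartment solution
#'
#' Exact superposed infusion/washout solution for a one-compartment model
#' with first-order elimination `k = CL/V1`: during an infusion at rate R,
#' the event contributes `R/CL * (1 - exp(-k (t - t0)))`; afterwards the
#' end-of-infusion concentration decays exponentially. Contributions of all
#' events and of any initial amount are summed (linearity).
#'
#' @inheritParams rk4_solve
#' @param times_h Times (hours) at which to evaluate the solution.
#' @param initial_amount_mg Initial central amount (mg).
#' @return Numeric vector of concentrations (mg/L) at `times_h`.
#' @export
closed_form_one_compartment <- function(params, events = NULL, times_h,
                                        initial_amount_mg = 0) {
  if (params$n_compartments != 1)
    stop("closed form covers one-compartment models only; use rk4_solve()",
         call. = FALSE)
  if (params$cl <= 0)
    stop("closed form requires cl > 0", call. = FALSE)
  k <- params$cl / params$v1
  conc <- (initial_amount_mg / params$v1) * exp(-k * pmax(times_h, 0))
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      t0 <- events$time_h[i]
      dur <- events$infusion_min[i] / 60
      R <- events$amount_mg[i] / dur
      dt <- times_h - t0
      during <- dt >= 0 & dt <= dur
      after <- dt > dur
      contrib <- numeric(length(times_h))
      contrib[during] <- R / params$cl * (1 - exp(-k * dt[during]))
      contrib[after] <- R / params$cl * (1 - exp(-k * dur)) *
        exp(-k * (dt[after] - dur))
      conc <- conc + contrib
    }
  }
  conc
}

#' Terminal half-life and time to steady state
#'
#' Steady state under repeated dosing is approximated as reached after seven
#' terminal half-lives. For one-compartment models the half-life is
#' `ln 2 * V1 / CL`; for two-compartment models it derives from the slow
#' (beta) exponent of the disposition matrix.
#'
#' @param params A `pk_params` object.
#' @return `terminal_half_life()`: hours; `time_to_steady_state()`: hours
#'   (seven half-lives).
#' @export
terminal_half_life <- function(params) {
  k10 <- params$cl / params$v1
  if (params$n_compartments == 1) return(log(2) / k10)
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  beta <- 0.5 * (s - sqrt(s^2 - 4 * k10 * k21))
  log(2) / beta
}

#' @rdname terminal_half_life
#' @export
time_to_steady_state <- function(params) 7 * terminal_half_life(params)

#' Summarize PK exposure over a window
#'
#' AUC by the trapezoidal rule on the simulation grid, trough/peak, and the
#' percentage of grid points in the window with concentration above the MIC.
#'
#' @param tc A `conc_time_course`.
#' @param window Numeric `c(start_h, end_h)`, within the simulated span;
#'   defaults to the last 24 h of the grid (or the whole grid if shorter).
#' @param mic_mg_l Minimum inhibitory concentration (mg/L), >= 0.
#' @return List of class `exposure_summary`: `auc_mg_h_l`, `cmin_mg_l`,
#'   `cmax_mg_l`, `pct_time_above_mic`, `window`.
#' @export
summarize_exposure <- function(tc, window = NULL, mic_mg_l = 0) {
  span <- range(tc$times_h)
  window <- window %||% c(max(span[1], span[2] - 24), span[2])
  if (mic_mg_l < 0) stop("mic_mg_l must be >= 0", call. = FALSE)
  if (window[2] <= window[1]) stop("empty exposure window", call. = FALSE)
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9)
    stop("window outside the simulated span", call. = FALSE)
  idx <- which(tc$times_h >= window[1] - 1e-9 & tc$times_h <= window[2] + 1e-9)
  if (length(idx) < 2) stop("window too narrow for the grid", call. = FALSE)
  cc <- tc$conc_mg_l[idx]
  tt <- tc$times_h[idx]
  auc <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  structure(list(auc_mg_h_l = auc, cmin_mg_l = min(cc), cmax_mg_l = max(cc),
                 pct_time_above_mic = 100 * mean(cc > mic_mg_l),
                 window = window),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("<exposure> window %.4g-%.4g h: AUC %.4g mg*h/L, Cmin %.4g, Cmax %.4g mg/L, %%T>MIC %.1f\n",
              x$window[1], x$window[2], x$auc_mg_h_l, x$cmin_mg_l, x$cmax_mg_l,
              x$pct_time_above_mic))
  invisible(x)
}

#' Export a time course as a two-column CSV
#'
#' @param tc A `conc_time_course`.
#' @param path Output file path.
#' @param t0 Optional POSIXct origin; when given, times are written as
#'   ISO-8601 UTC timestamps, otherwise as numeric hours.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, t0 = NULL) {
  d <- as.data.frame(tc)
  if (!is.null(t0)) {
    d$time <- format(t0 + d$time_h * 3600, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    d <- d[, c("time", "conc_mg_l")]
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
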