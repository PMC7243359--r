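#' Dose scaling under PK linearity
#'
#' The linearity premise: exposure is proportional to dose, so the dose that
#' reaches a target exposure is
#' `MD_target = exposure_target / exposure_test * MD_test`.
#'
#' @param md_test_mg Test maintenance dose (mg).
#' @param exposure_test Exposure simulated for the test dose (same units as
#'   `exposure_target`; trough mg/L or AUC mg*h/L).
#' @param exposure_target Target exposure.
#' @return Scaled dose (mg).
#' @export
scale_dose <- function(md_test_mg, exposure_test, exposure_target) {
  if (exposure_test <= 0)
    stop("test exposure is zero; no dose can be derived by scaling", call. = FALSE)
  exposure_target / exposure_test * md_test_mg
}

# Steady-state settling horizon: seven terminal half-lives, rounded up to a
# whole number of dosing intervals so the evaluation window starts on an
# administration; capped so settle + window never exceeds cap_h (14 days).
ss_horizon <- function(params, interval_h, eval_window_h, cap_h = 336) {
  tss <- time_to_steady_state(params)
  settle <- ceiling(tss / interval_h) * interval_h
  if (settle + eval_window_h > cap_h)
    settle <- max(interval_h, floor((cap_h - eval_window_h) / interval_h) * interval_h)
  list(settle_h = settle, total_h = settle + eval_window_h)
}

#' Simulate a maintenance regimen to steady state
#'
#' Runs the regimen until steady state (seven terminal half-lives, rounded
#' up to whole dosing intervals; hard cap 14 days) and evaluates exposure
#' over the following window (default 24 h, dosed throughout).
#'
#' @param params A `pk_params` object.
#' @param md_mg Maintenance dose per administration (mg).
#' @param interval_h Dosing interval (hours).
#' @param infusion_min Infusion duration (minutes).
#' @param eval_window_h Evaluation window appended after settling (hours).
#' @param mic_mg_l MIC used for the %T>MIC summary.
#' @param step_min Grid step (minutes).
#' @return List with the `conc_time_course` (`tc`), the evaluation `window`,
#'   the [summarize_exposure()] result (`exposure`) and `trough_mg_l`, the
#'   concentration at the end of the final interval.
#' @export
simulate_steady_state <- function(params, md_mg, interval_h, infusion_min = 60,
                                  eval_window_h = 24, mic_mg_l = 0, step_min = 1) {
  hz <- ss_horizon(params, interval_h, eval_window_h)
  times <- seq(0, hz$total_h - interval_h + 1e-9, by = interval_h)
  ev <- dose_events(amount_mg = md_mg, time_h = times, infusion_min = infusion_min)
  tc <- rk4_solve(params, ev, horizon_h = hz$total_h, step_min = step_min)
  window <- c(hz$settle_h, hz$total_h)
  exp_sum <- summarize_exposure(tc, window = window, mic_mg_l = mic_mg_l)
  list(tc = tc, window = window, exposure = exp_sum,
       trough_mg_l = tc$conc_mg_l[length(tc$conc_mg_l)])
}

resolve_params <- function(model, patient, corr = NULL, at_h = NULL) {
  if (inherits(patient, "pk_params")) return(patient)
  cov <- if (inherits(patient, "covariate_set")) patient
         else latest_covariates(patient, at_h = at_h)
  compute_individual_parameters(model, cov, corr)
}

#' Maintenance dose by exposure scaling
#'
#' Simulates a test maintenance dose at the requested interval to steady
#' state, reads the simulated trough, and scales the test dose by the ratio
#' of target to simulated trough ([scale_dose()]). Used for
#' time-above-MIC targets, where the target trough (a multiple of the MIC)
#' guarantees 100 %T>MIC at steady state.
#'
#' @param model A [pk_model()].
#' @param patient A `patient_record`, [covariate_set()] or `pk_params`.
#' @param interval_h Dosing interval (hours).
#' @param target An [exposure_target()] of kind `T_ABOVE_MIC`.
#' @param test_md_mg Test dose (mg); the result is test-dose independent
#'   under linearity. Defaults to 1000 mg.
#' @param infusion_min Infusion duration (minutes).
#' @param corr Optional [correction_factors()].
#' @param step_min Grid step (minutes).
#' @return Maintenance dose per administration (mg), with the simulated
#'   test trough attached as attribute `test_trough_mg_l`.
#' @export
maintenance_dose_by_scaling <- function(model, patient, interval_h, target,
                                        test_md_mg = 1000, infusion_min = 60,
                                        corr = NULL, step_min = 1) {
  stopifnot(inherits(target, "exposure_target"))
  if (target$kind != "T_ABOVE_MIC")
    stop("maintenance_dose_by_scaling expects a T_ABOVE_MIC target; use ",
         "maintenance_dose_by_auc for AUC targets", call. = FALSE)
  params <- resolve_params(model, patient, corr)
  ss <- simulate_steady_state(params, test_md_mg, interval_h, infusion_min,
                              eval_window_h = interval_h, step_min = step_min)
  md <- scale_dose(test_md_mg, ss$trough_mg_l, target$target_cmin_mg_l)
  structure(md, test_trough_mg_l = ss$trough_mg_l)
}

#' Maintenance dose from a target daily AUC
#'
#' Analytic dose calculation for linear PK: the total daily dose that
#' yields a steady-state AUC over 24 h of `AUC_target` is
#' `AUC_target * CL`. Splitting across administrations is the caller's
#' concern (daily AUC is frequency-invariant under linear PK).
#'
#' @param cl_l_h Individual clearance (L/h), > 0.
#' @param target_auc24_mg_h_l Target AUC over 24 h (mg*h/L), >= 0.
#' @return Total daily dose (mg per 24 h).
#' @export
maintenance_dose_by_auc <- function(cl_l_h, target_auc24_mg_h_l) {
  if (cl_l_h <= 0) stop("clearance must be > 0", call. = FALSE)
  if (target_auc24_mg_h_l < 0) stop("target AUC must be >= 0", call. = FALSE)
  target_auc24_mg_h_l * cl_l_h
}

# Concentration reached at the end of an infusion of `amount_mg` over
# `infusion_min`, starting from a drug-free state.
end_of_infusion_conc <- function(params, amount_mg, infusion_min, step_min = 1) {
  ev <- dose_events(amount_mg = amount_mg, time_h = 0, infusion_min = infusion_min)
  tc <- rk4_solve(params, ev, horizon_h = infusion_min / 60, step_min = step_min)
  tc$conc_mg_l[length(tc$conc_mg_l)]
}

# Residual concentration from past doses at `at_h` on the history's own
# time axis (events may lie at negative times relative to "now"; the
# simulation is shifted so it starts at the earliest event).
residual_conc_at <- function(params, dose_history, at_h, step_min = 1) {
  if (is.null(dose_history) || nrow(dose_history) == 0) return(0)
  t0 <- min(dose_history$time_h, at_h)
  if (at_h <= t0) return(0)
  ev <- dose_events(amount_mg = dose_history$amount_mg,
                    time_h = dose_history$time_h - t0,
                    infusion_min = dose_history$infusion_min)
  tc <- rk4_solve(params, ev, horizon_h = at_h - t0, step_min = step_min)
  tc$conc_mg_l[length(tc$conc_mg_l)]
}

#' Loading dose via superposition
#'
#' Derives the loading dose (LD) that brings the concentration at the end
#' of the LD infusion to the target peak of the maintenance-dose steady
#' state. By superposition, the concentration at that moment decomposes
#' into the washout of any residual drug from past doses (`Ct_res`) plus
#' the net increase due to the LD itself, so a test LD simulated from a
#' drug-free state is scaled to cover `Cmax_ss - Ct_res`. Never negative:
#' if the residual already reaches the target peak, the LD is 0.
#'
#' @inheritParams maintenance_dose_by_scaling
#' @param md_mg The (pre-calculated) maintenance dose per administration.
#' @param dose_history Optional [dose_events()] of past administrations, on
#'   the same time axis as `ld_start_h`.
#' @param ld_start_h Start time of the LD infusion (default 0 = now); past
#'   doses lie at earlier times on the same axis.
#' @return Loading dose (mg), with attributes `cmax_ss_mg_l` (the target
#'   peak) and `ct_res_mg_l` (residual concentration at the end of the LD
#'   infusion).
#' @export
loading_dose <- function(model, patient, md_mg, interval_h, dose_history = NULL,
                         infusion_min = 60, corr = NULL, ld_start_h = 0,
                         step_min = 1) {
  if (md_mg <= 0) stop("md_mg must be > 0", call. = FALSE)
  params <- resolve_params(model, patient, corr)
  ss <- simulate_steady_state(params, md_mg, interval_h, infusion_min,
                              eval_window_h = interval_h, step_min = step_min)
  cmax_ss <- ss$exposure$cmax_mg_l
  ct_res <- residual_conc_at(params, dose_history,
                             at_h = ld_start_h + infusion_min / 60,
                             step_min = step_min)
  if (ct_res >= cmax_ss)
    return(structure(0, cmax_ss_mg_l = cmax_ss, ct_res_mg_l = ct_res))
  test_ld <- md_mg
  cmax_test <- end_of_infusion_conc(params, test_ld, infusion_min, step_min)
  if (cmax_test <= 0)
    stop("test loading dose produced no concentration; check parameters",
         call. = FALSE)
  ld <- scale_dose(test_ld, cmax_test, cmax_ss - ct_res)
  structure(ld, cmax_ss_mg_l = cmax_ss, ct_res_mg_l = ct_res)
}
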