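#' @title Synthetic ICU cohort generation
#' @description Emulates the data an EHR extraction would provide: ICU
#'   patient demographics and covariate trajectories, dose histories, and
#'   noisy plasma levels drawn with the statistical structure the PK models
#'   assume (lognormal IIV, additive/proportional residual error).
#' @name cohort
NULL

default_patient_ranges <- function() {
  list(weight_kg = c(40, 150), scr_mg_dl = c(0.3, 5), age_years = c(18, 90))
}

rtrunc <- function(n, rfun, lo, hi, ...) {
  x <- rfun(n, ...)
  pmin(pmax(x, lo), hi)
}

#' Generate one synthetic ICU patient
#'
#' Seeded draws of demographics (age uniform on its range; weight normal
#' around 80 kg, SD 20; serum creatinine lognormal around 1 mg/dL), all
#' clipped to the configured ranges, plus a covariate trajectory sampled
#' every `cov_interval_h` hours with an optional multiplicative lognormal
#' random walk on creatinine (drift SD per step on the log scale).
#'
#' @param seed Integer seed.
#' @param ranges List of `c(low, high)` ranges for `weight_kg`,
#'   `scr_mg_dl`, `age_years`.
#' @param n_cov_times Number of covariate time points.
#' @param cov_interval_h Spacing of covariate measurements (hours).
#' @param scr_drift_sd Log-scale SD of the per-step creatinine random walk
#'   (0 disables drift).
#' @param id Patient identifier (default derived from the seed).
#' @return A [patient_record()] (no doses or observations yet).
#' @export
generate_patient <- function(seed, ranges = default_patient_ranges(),
                             n_cov_times = 3, cov_interval_h = 24,
                             scr_drift_sd = 0.1, id = NULL) {
  for (nm in c("weight_kg", "scr_mg_dl", "age_years")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] <= 0 && nm != "age_years" ||
        r[1] >= r[2])
      stop("invalid range for ", nm, call. = FALSE)
  }
  with_seed(seed, {
    age <- stats::runif(1, ranges$age_years[1], ranges$age_years[2])
    weight <- rtrunc(1, stats::rnorm, ranges$weight_kg[1], ranges$weight_kg[2],
                     mean = 80, sd = 20)
    scr0 <- rtrunc(1, function(n) stats::rlnorm(n, log(1.0), 0.5),
                   ranges$scr_mg_dl[1], ranges$scr_mg_dl[2])
    sex <- sample(c("male", "female"), 1)
    scr <- numeric(n_cov_times)
    scr[1] <- scr0
    if (n_cov_times > 1)
      for (i in 2:n_cov_times)
        scr[i] <- min(max(scr[i - 1] * stats::rlnorm(1, 0, scr_drift_sd),
                          ranges$scr_mg_dl[1]), ranges$scr_mg_dl[2])
    covariates <- data.frame(
      time_h = (seq_len(n_cov_times) - 1) * cov_interval_h,
      weight_kg = weight, scr_mg_dl = scr, age_years = age, sex = sex)
    patient_record(id = id %||% sprintf("synth-%06d", seed),
                   covariates = covariates)
  })
}

#' Generate a synthetic cohort
#'
#' @param n Number of patients.
#' @param seed Base seed; patient i uses `seed + i - 1`.
#' @param ... Passed to [generate_patient()].
#' @return List of [patient_record()]s.
#' @export
generate_cohort <- function(n, seed, ...) {
  lapply(seq_len(n), function(i) generate_patient(seed + i - 1, ...))
}

#' Simulate noisy observed plasma levels
#'
#' Draws per-patient correction factors from the model's lognormal IIV
#' (unless supplied), simulates the individual's true curve under the given
#' regimen, and adds residual noise according to the model's error kind
#' (additive, proportional, or combined), truncating at zero.
#'
#' @param model A [pk_model()].
#' @param patient A [patient_record()].
#' @param regimen A [dose_events()] table.
#' @param sampling_times_h Observation times (hours).
#' @param seed Integer seed.
#' @param factors Optional true [correction_factors()]; default drawn from
#'   the IIV.
#' @return List with `observations` (`data.frame`: `time_h`, `conc_mg_l`),
#'   `factors` (the simulated truth) and `truth` (noise-free
#'   concentrations).
#' @export
simulate_observed_levels <- function(model, patient, regimen, sampling_times_h,
                                     seed, factors = NULL) {
  with_seed(seed, {
    if (is.null(factors)) {
      draw <- function(p) if (!is.null(model$iiv[[p]]))
        stats::rlnorm(1, 0, model$iiv[[p]]) else 1
      factors <- correction_factors(cl = draw("cl"), v1 = draw("v1"))
    }
    params <- apply_factors(model, patient, factors)
    truth <- predict_conc(model, params, regimen, sampling_times_h)
    re <- model$residual_error
    n <- length(truth)
    y <- switch(re$kind,
      additive = truth + stats::rnorm(n, 0, re$sigma_add),
      proportional = truth * (1 + stats::rnorm(n, 0, re$sigma_prop)),
      combined = truth * (1 + stats::rnorm(n, 0, re$sigma_prop)) +
        stats::rnorm(n, 0, re$sigma_add)
    )
    list(observations = data.frame(time_h = sampling_times_h,
                                   conc_mg_l = pmax(y, 0)),
         factors = factors, truth = truth)
  })
}

#' Evaluate two dosing strategies on a cohort
#'
#' For each patient and each strategy, builds a maintenance regimen,
#' simulates it to steady state with the patient's individual parameters
#' (including any `true_factors` the synthetic patient carries) and
#' evaluates a 24-h window: percentage of time within the acceptable
#' concentration range and the AUC over 24 h with its in-range flag.
#'
#' A strategy is a function `function(model, patient)` returning a list
#' with `md_mg`, `interval_h` and optionally `infusion_min`. A failing
#' strategy yields `NA` for that patient rather than aborting the
#' evaluation.
#'
#' @param model A [pk_model()].
#' @param cohort List of [patient_record()]s.
#' @param strategy_a,strategy_b Regimen-builder functions.
#' @param conc_range Acceptable concentration window (mg/L), default
#'   `c(10, 30)`.
#' @param auc_range Desirable AUC0-24 window (mg*h/L), default
#'   `c(400, 600)`.
#' @param step_min Grid step (minutes).
#' @return List of class `regimen_evaluation`: `per_patient`
#'   (`data.frame` with both strategies' `pct_in_range`, `auc24` and
#'   in-range flags) and `summary` (medians and in-range proportions).
#' @export
evaluate_regimens <- function(model, cohort, strategy_a, strategy_b,
                              conc_range = c(10, 30), auc_range = c(400, 600),
                              step_min = 1) {
  stopifnot(length(cohort) >= 1)
  eval_one <- function(patient, strategy) {
    tryCatch({
      reg <- strategy(model, patient)
      params <- apply_factors(model, patient,
                              patient$true_factors %||% correction_factors())
      ss <- simulate_steady_state(params, reg$md_mg, reg$interval_h,
                                  reg$infusion_min %||% 60,
                                  eval_window_h = 24, step_min = step_min)
      idx <- which(ss$tc$times_h >= ss$window[1] & ss$tc$times_h <= ss$window[2])
      cc <- ss$tc$conc_mg_l[idx]
      c(pct_in_range = 100 * mean(cc >= conc_range[1] & cc <= conc_range[2]),
        auc24 = ss$exposure$auc_mg_h_l)
    }, error = function(e) c(pct_in_range = NA_real_, auc24 = NA_real_))
  }
  a <- t(vapply(cohort, eval_one, numeric(2), strategy = strategy_a))
  b <- t(vapply(cohort, eval_one, numeric(2), strategy = strategy_b))
  per_patient <- data.frame(
    id = vapply(cohort, function(p) p$id, character(1)),
    pct_in_range_a = a[, "pct_in_range"], auc24_a = a[, "auc24"],
    auc_in_range_a = a[, "auc24"] >= auc_range[1] & a[, "auc24"] <= auc_range[2],
    pct_in_range_b = b[, "pct_in_range"], auc24_b = b[, "auc24"],
    auc_in_range_b = b[, "auc24"] >= auc_range[1] & b[, "auc24"] <= auc_range[2])
  summary <- list(
    median_pct_in_range_a = stats::median(per_patient$pct_in_range_a, na.rm = TRUE),
    median_pct_in_range_b = stats::median(per_patient$pct_in_range_b, na.rm = TRUE),
    median_auc24_a = stats::median(per_patient$auc24_a, na.rm = TRUE),
    median_auc24_b = stats::median(per_patient$auc24_b, na.rm = TRUE),
    prop_auc_in_range_a = mean(per_patient$auc_in_range_a, na.rm = TRUE),
    prop_auc_in_range_b = mean(per_patient$auc_in_range_b, na.rm = TRUE))
  structure(list(per_patient = per_patient, summary = summary,
                 conc_range = conc_range, auc_range = auc_range),
            class = "regimen_evaluation")
}

#' @export
print.regimen_evaluation <- function(x, ...) {
  s <- x$summary
  cat("<regimen_evaluation>\n")
  cat(sprintf("  median %%time in %g-%g mg/L:  A %.1f  B %.1f\n",
              x$conc_range[1], x$conc_range[2],
              s$median_pct_in_range_a, s$median_pct_in_range_b))
  cat(sprintf("  median AUC0-24 (mg*h/L):     A %.0f  B %.0f\n",
              s$median_auc24_a, s$median_auc24_b))
  cat(sprintf("  AUC in %g-%g:                A %.0f%%  B %.0f%%\n",
              x$auc_range[1], x$auc_range[2],
              100 * s$prop_auc_in_range_a, 100 * s$prop_auc_in_range_b))
  invisible(x)
}
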