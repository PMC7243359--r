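#' Clinical dosing advice
#'
#' Implements the deterministic advice algorithm: starting at the drug's
#' baseline dosing frequency and moving up the allowed ladder (1, 2, 3, 4,
#' 6 administrations/day, up to six times daily), compute a maintenance
#' dose (MD) for each frequency — by the analytic AUC relation for AUC/MIC
#' targets, by trough-ratio scaling for time-above-MIC targets — and accept
#' the first frequency whose MD respects all safety limits (single dose,
#' daily total, and predicted steady-state peak below the minimal toxic
#' concentration). A loading dose (LD) is then derived so steady state is
#' reached immediately; if the residual concentration from past doses
#' already covers the steady-state peak, only the MD is advised together
#' with an estimated ideal start time. When no intermittent regimen is
#' safe, a continuous infusion is advised if enabled; otherwise no advice
#' is given and the user is referred to the pharmacist.
#'
#' Safety warnings are attached rather than silently resolved: a daily dose
#' above twice or below half the standard daily dose, stale covariates
#' (see [staleness_warnings()]), and a capped loading dose. The advice is
#' always stated in absolute terms, never relative to a prior order.
#'
#' @param model A [pk_model()] (or a drug name resolvable via [get_model()]).
#' @param patient A `patient_record`.
#' @param target An [exposure_target()]; defaults to the drug configuration.
#' @param limits A [safety_limits()]; defaults to the drug configuration.
#' @param options List of optional settings: `infusion_min`,
#'   `continuous_enabled`, `now_h` (advice/reference time; default = newest
#'   timestamp in the record), `corr` (MAP [correction_factors()]),
#'   `freshness_h`, `test_md_mg`, `step_min`, `config_path`.
#' @return Object of class `dose_advice`: `status`
#'   (`LOADING_PLUS_MAINTENANCE`, `MAINTENANCE_ONLY`, `CONTINUOUS`,
#'   `NO_ADVICE`), `regimen` (dose, interval, LD, infusion duration,
#'   predicted steady-state exposure, residual concentration), `start_h`,
#'   `warnings` (list of `code`/`text`), `inputs_snapshot`.
#' @export
advise <- function(model, patient, target = NULL, limits = NULL,
                   options = list()) {
  if (is.character(model)) model <- get_model(model)
  stopifnot(inherits(model, "pk_model"), inherits(patient, "patient_record"))
  cfg <- tryCatch(get_drug_config(model$drug, path = options$config_path),
                  error = function(e) NULL)
  target <- target %||% cfg$target
  limits <- limits %||% cfg$limits
  if (is.null(target) || is.null(limits))
    stop("no exposure target / safety limits available for '", model$drug, "'",
         call. = FALSE)
  infusion_min <- options$infusion_min %||% cfg$infusion_min %||% 60
  continuous_enabled <- options$continuous_enabled %||%
    (cfg$continuous_enabled %||% FALSE)
  freshness <- options$freshness_h %||% cfg$freshness_h %||% list(scr_mg_dl = 24)
  step_min <- options$step_min %||% 1
  now_h <- options$now_h %||% newest_time(patient)
  corr <- options$corr

  cov <- latest_covariates(patient, at_h = now_h)
  params <- compute_individual_parameters(model, cov, corr)
  snapshot <- list(covariates = cov, params = unclass(params)[c("cl", "v1", "q", "v2")],
                   correction = corr, now_h = now_h)

  warn <- staleness_warnings(patient, freshness, now_h = now_h)

  ladder <- c(1L, 2L, 3L, 4L, 6L)
  baseline_freq <- max(1L, as.integer(round(24 / model$baseline_interval_h)))
  freqs <- ladder[ladder >= baseline_freq & ladder <= model$max_daily_frequency]
  if (!length(freqs)) freqs <- baseline_freq

  chosen <- NULL
  for (f in freqs) {
    interval_h <- 24 / f
    md <- if (target$kind == "AUC_OVER_MIC") {
      maintenance_dose_by_auc(params$cl, target$target_auc24_mg_h_l) / f
    } else {
      as.numeric(maintenance_dose_by_scaling(
        model, params, interval_h, target,
        test_md_mg = options$test_md_mg %||% (limits$standard_daily_dose_mg / f),
        infusion_min = infusion_min, step_min = step_min))
    }
    if (!is.finite(md) || md <= 0) next
    if (md > limits$max_dose_mg) next
    if (md * f > limits$max_daily_dose_mg) next
    ss <- simulate_steady_state(params, md, interval_h, infusion_min,
                                eval_window_h = 24, mic_mg_l = target$mic_mg_l,
                                step_min = step_min)
    if (ss$exposure$cmax_mg_l >= limits$minimal_toxic_conc_mg_l) next
    chosen <- list(freq = f, interval_h = interval_h, md_mg = md, ss = ss)
    break
  }

  if (!is.null(chosen)) {
    history <- past_doses(patient, model$drug, now_h)
    ld <- loading_dose(model, params, chosen$md_mg, chosen$interval_h,
                       dose_history = history, infusion_min = infusion_min,
                       ld_start_h = now_h, step_min = step_min)
    ld_mg <- as.numeric(ld)
    if (ld_mg > limits$max_dose_mg) {
      ld_mg <- limits$max_dose_mg
      warn <- c(warn, list(warning_entry("LD_CAPPED", sprintf(
        "Calculated loading dose exceeded the maximum single dose and was capped at %.0f mg.",
        limits$max_dose_mg))))
    }
    if (ld_mg > 0) {
      status <- "LOADING_PLUS_MAINTENANCE"
      start_h <- now_h
    } else {
      status <- "MAINTENANCE_ONLY"
      start_h <- ideal_dosing_time(params, history, now_h,
                                   trough_mg_l = chosen$ss$trough_mg_l,
                                   step_min = step_min)
    }
    regimen <- list(maintenance_dose_mg = chosen$md_mg,
                    interval_h = chosen$interval_h,
                    loading_dose_mg = if (ld_mg > 0) ld_mg else NULL,
                    infusion_min = infusion_min,
                    predicted = chosen$ss$exposure,
                    residual_conc_at_start_mg_l = attr(ld, "ct_res_mg_l"))
    warn <- c(warn, dose_range_warnings(chosen$md_mg * chosen$freq, limits))
    return(new_dose_advice(status, model$drug, regimen, start_h, warn, snapshot))
  }

  if (continuous_enabled) {
    rate <- if (target$kind == "AUC_OVER_MIC")
      target$target_auc24_mg_h_l * params$cl / 24
    else target$target_cmin_mg_l * params$cl
    css <- rate / params$cl
    if (rate * 24 <= limits$max_daily_dose_mg &&
        css < limits$minimal_toxic_conc_mg_l) {
      history <- past_doses(patient, model$drug, now_h)
      ct_res <- residual_conc_at(params, history, now_h + infusion_min / 60,
                                 step_min = step_min)
      ld_mg <- 0
      if (ct_res < css) {
        cmax_test <- end_of_infusion_conc(params, 1000, infusion_min, step_min)
        ld_mg <- min(scale_dose(1000, cmax_test, css - ct_res),
                     limits$max_dose_mg)
      }
      regimen <- list(rate_mg_h = rate, daily_dose_mg = rate * 24,
                      loading_dose_mg = if (ld_mg > 0) ld_mg else NULL,
                      infusion_min = infusion_min,
                      predicted = list(css_mg_l = css, auc24_mg_h_l = css * 24),
                      residual_conc_at_start_mg_l = ct_res)
      warn <- c(warn, dose_range_warnings(rate * 24, limits))
      return(new_dose_advice("CONTINUOUS", model$drug, regimen, now_h, warn,
                             snapshot))
    }
  }

  new_dose_advice("NO_ADVICE", model$drug, NULL, now_h, warn, snapshot)
}

newest_time <- function(patient) {
  max(c(patient$covariates$time_h, patient$doses$time_h,
        patient$observations$time_h, 0))
}

past_doses <- function(patient, drug, now_h) {
  d <- patient$doses
  if (nrow(d) == 0) return(d)
  keep <- d$time_h <= now_h & (is.na(d$drug) | tolower(d$drug) == tolower(drug))
  d[keep, , drop = FALSE]
}

# Earliest time >= now at which the residual concentration has decayed to
# the regimen's steady-state trough, found on the simulation grid.
ideal_dosing_time <- function(params, history, now_h, trough_mg_l,
                              step_min = 1, max_wait_h = 72) {
  if (is.null(history) || nrow(history) == 0) return(now_h)
  t0 <- min(history$time_h, now_h)
  ev <- dose_events(amount_mg = history$amount_mg, time_h = history$time_h - t0,
                    infusion_min = history$infusion_min)
  tc <- rk4_solve(params, ev, horizon_h = (now_h - t0) + max_wait_h,
                  step_min = step_min)
  tt <- tc$times_h + t0
  ok <- which(tt >= now_h & tc$conc_mg_l <= trough_mg_l)
  if (!length(ok)) return(now_h + max_wait_h)
  tt[ok[1]]
}

dose_range_warnings <- function(daily_dose_mg, limits) {
  out <- list()
  if (daily_dose_mg > 2 * limits$standard_daily_dose_mg)
    out <- c(out, list(warning_entry("DAILY_DOSE_HIGH", sprintf(
      "Advised total of %.0f mg over 24 h is more than twice the standard daily dose (%.0f mg); review advised.",
      daily_dose_mg, limits$standard_daily_dose_mg))))
  if (daily_dose_mg < 0.5 * limits$standard_daily_dose_mg)
    out <- c(out, list(warning_entry("DAILY_DOSE_LOW", sprintf(
      "Advised total of %.0f mg over 24 h is less than half the standard daily dose (%.0f mg); review advised.",
      daily_dose_mg, limits$standard_daily_dose_mg))))
  out
}

warning_entry <- function(code, text, covariate = NULL) {
  w <- list(code = code, text = text)
  if (!is.null(covariate)) w$covariate <- covariate
  w
}

new_dose_advice <- function(status, drug, regimen, start_h, warnings, snapshot) {
  structure(list(status = status, drug = drug, regimen = regimen,
                 start_h = start_h, warnings = warnings,
                 inputs_snapshot = snapshot),
            class = "dose_advice")
}

#' @export
print.dose_advice <- function(x, ...) {
  cat(render_advice_text(x))
  invisible(x)
}

#' Stale-covariate warnings
#'
#' One warning per covariate whose newest measurement is older than its
#' configured maximum age (default: serum creatinine every 24 h), ordered
#' deterministically by covariate name.
#'
#' @param patient A `patient_record`.
#' @param freshness_h Named list of maximum ages in hours, e.g.
#'   `list(scr_mg_dl = 24)`.
#' @param now_h Reference time (hours); default = newest timestamp in the
#'   record.
#' @return List of warnings (`code`, `covariate`, `text`).
#' @export
staleness_warnings <- function(patient, freshness_h = list(scr_mg_dl = 24),
                               now_h = NULL) {
  now_h <- now_h %||% newest_time(patient)
  cv <- patient$covariates
  out <- list()
  for (name in sort(names(freshness_h))) {
    if (!name %in% names(cv)) next
    t_meas <- cv$time_h[!is.na(cv[[name]])]
    if (!length(t_meas)) next
    age <- now_h - max(t_meas)
    if (age > freshness_h[[name]])
      out <- c(out, list(warning_entry("STALE_COVARIATE", sprintf(
        "Covariate '%s' is %.1f h old (recommended at most %.0f h); older than recommended data is being used.",
        name, age, freshness_h[[name]]), covariate = name)))
  }
  out
}

#' Render a dosing advice as plain text
#'
#' Advice is always stated in absolute doses (never as a change relative
#' to a prior order); a no-advice outcome refers the user to the support
#' team or pharmacist.
#'
#' @param advice A `dose_advice`.
#' @return A single character string.
#' @export
render_advice_text <- function(advice) {
  lines <- sprintf("Dosing advice for %s:", advice$drug)
  r <- advice$regimen
  if (advice$status == "NO_ADVICE") {
    lines <- c(lines,
      "  No safe dose advice could be generated for this patient.",
      "  Please contact the support team or the pharmacist.")
  } else if (advice$status == "CONTINUOUS") {
    if (!is.null(r$loading_dose_mg))
      lines <- c(lines, sprintf("  Loading dose: %.0f mg infused over %.0f min.",
                                r$loading_dose_mg, r$infusion_min))
    lines <- c(lines, sprintf(
      "  Continuous infusion at %.1f mg/h (%.0f mg per 24 h), starting at t = %.1f h.",
      r$rate_mg_h, r$daily_dose_mg, advice$start_h))
    lines <- c(lines, sprintf("  Predicted steady-state concentration: %.1f mg/L.",
                              r$predicted$css_mg_l))
  } else {
    if (!is.null(r$loading_dose_mg))
      lines <- c(lines, sprintf("  Loading dose: %.0f mg infused over %.0f min, starting at t = %.1f h.",
                                r$loading_dose_mg, r$infusion_min, advice$start_h))
    lines <- c(lines, sprintf(
      "  Maintenance dose: %.0f mg every %g h (infused over %.0f min), %s at t = %.1f h.",
      r$maintenance_dose_mg, r$interval_h, r$infusion_min,
      if (is.null(r$loading_dose_mg)) "first dose" else "starting one interval after the loading dose,",
      advice$start_h))
    p <- r$predicted
    lines <- c(lines, sprintf(
      "  Predicted steady state: AUC0-24 %.0f mg*h/L, Cmin %.1f mg/L, Cmax %.1f mg/L, %%T>MIC %.0f%%.",
      p$auc_mg_h_l, p$cmin_mg_l, p$cmax_mg_l, p$pct_time_above_mic))
  }
  for (w in advice$warnings)
    lines <- c(lines, sprintf("  WARNING [%s]: %s", w$code, w$text))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Convert a dosing advice to its JSON representation
#'
#' @param advice A `dose_advice`.
#' @return JSON string (schema: status, drug, md_mg, interval_h, ld_mg,
#'   start_h, predicted, warnings).
#' @export
advice_to_json <- function(advice) {
  r <- advice$regimen
  pred <- NULL
  if (!is.null(r$predicted)) {
    p <- r$predicted
    pred <- if (!is.null(p$auc_mg_h_l))
      list(auc24 = p$auc_mg_h_l, cmin = p$cmin_mg_l, cmax = p$cmax_mg_l,
           pct_t_above_mic = p$pct_time_above_mic)
    else list(css = p$css_mg_l, auc24 = p$auc24_mg_h_l)
  }
  obj <- list(status = advice$status, drug = advice$drug,
              md_mg = r$maintenance_dose_mg, interval_h = r$interval_h,
              rate_mg_h = r$rate_mg_h, ld_mg = r$loading_dose_mg,
              infusion_min = r$infusion_min, start_h = advice$start_h,
              predicted = pred,
              warnings = lapply(advice$warnings, function(w)
                list(code = w$code, text = w$text)))
  jsonlite::toJSON(obj[!vapply(obj, is.null, logical(1))], auto_unbox = TRUE,
                   digits = NA, null = "null")
}
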