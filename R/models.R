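#' Construct a population PK model specification
#'
#' A `pk_model` bundles the structural model (one or two compartments),
#' typical parameter values, the covariate equations that individualize
#' clearance (and, for weight-scaled drugs, central volume), lognormal
#' inter-individual variability (IIV) and the residual-error model.
#'
#' @param drug Drug name (lower-case canonical key).
#' @param n_compartments 1 or 2.
#' @param typical Named list of typical values: `cl` (L/h), `v1` (L, or L/kg
#'   when the covariate model declares `per_kg`), and for two-compartment
#'   models `q` (L/h) and `v2` (L).
#' @param covariate_model Named list of per-parameter covariate equations,
#'   each a list with a `form` and its coefficients. Supported forms:
#'   `linear_clcr` (`theta * CLcr / ref_clcr`), `power_clcr`
#'   (`theta * (CLcr / ref_clcr)^exponent`), `power_scr`
#'   (`theta * (max(SCR, scr_floor) / ref_scr)^exponent`), `intercept_clcr`
#'   (`theta + theta_clcr * CLcr / ref_clcr`), and `per_kg`
#'   (`theta * weight`).
#' @param iiv Named numeric vector/list of log-scale IIV standard deviations
#'   (omega) for a subset of the typical parameters.
#' @param residual_error List with `kind` (`"additive"`, `"proportional"` or
#'   `"combined"`) and `sigma_add` (mg/L) and/or `sigma_prop` (fraction).
#' @param source_id Identifier of the source publication (e.g. PubMed ID).
#' @param source Free-text citation label.
#' @param baseline_interval_h The drug's standard dosing interval in hours.
#' @param max_daily_frequency Maximum administrations per day (default 6).
#'
#' @return An object of class `pk_model`.
#' @export
pk_model <- function(drug, n_compartments, typical, covariate_model = list(),
                     iiv = list(), residual_error = list(kind = "additive", sigma_add = 1),
                     source_id = "", source = "", baseline_interval_h = 12,
                     max_daily_frequency = 6L) {
  if (!n_compartments %in% c(1L, 2L))
    stop("n_compartments must be 1 or 2", call. = FALSE)
  typical <- lapply(typical, as.numeric)
  needed <- if (n_compartments == 2) c("cl", "v1", "q", "v2") else c("cl", "v1")
  missing_p <- setdiff(needed, names(typical))
  if (length(missing_p))
    stop("typical values missing for: ", paste(missing_p, collapse = ", "), call. = FALSE)
  if (n_compartments == 1 && any(c("q", "v2") %in% names(typical)))
    stop("q/v2 only allowed for two-compartment models", call. = FALSE)
  if (any(unlist(typical) <= 0))
    stop("all typical parameter values must be strictly positive", call. = FALSE)
  iiv <- lapply(iiv, as.numeric)
  bad_iiv <- setdiff(names(iiv), names(typical))
  if (length(bad_iiv))
    stop("iiv names not in typical parameters: ", paste(bad_iiv, collapse = ", "),
         call. = FALSE)
  stopifnot(residual_error$kind %in% c("additive", "proportional", "combined"))
  structure(list(
    drug = tolower(drug),
    n_compartments = as.integer(n_compartments),
    typical = typical,
    covariate_model = covariate_model,
    iiv = iiv,
    residual_error = residual_error,
    source_id = as.character(source_id),
    source = source,
    baseline_interval_h = as.numeric(baseline_interval_h),
    max_daily_frequency = as.integer(max_daily_frequency)
  ), class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("<pk_model> %s (%s, PMID %s)\n", x$drug, x$source, x$source_id))
  cat(sprintf("  compartments: %d\n", x$n_compartments))
  tv <- vapply(x$typical, identity, numeric(1))
  cat("  typical:", paste(sprintf("%s=%g", names(tv), tv), collapse = ", "), "\n")
  if (length(x$iiv))
    cat("  iiv (omega):", paste(sprintf("%s=%g", names(x$iiv), unlist(x$iiv)),
                                collapse = ", "), "\n")
  cat(sprintf("  residual error: %s\n", x$residual_error$kind))
  invisible(x)
}

#' Construct a covariate set
#'
#' Time-stamped patient covariates used by the model covariate equations.
#' Times are numeric hours on the patient's time axis.
#'
#' @param weight_kg Body weight (kg), > 0.
#' @param scr_mg_dl Serum creatinine (mg/dL), > 0.
#' @param age_years Age in years, >= 0.
#' @param sex `"male"` or `"female"`.
#' @param clcr_ml_min Optional measured creatinine clearance (mL/min); when
#'   present it takes precedence over the Cockcroft-Gault derivation.
#' @param albumin_g_l Optional serum albumin (g/L).
#' @param sofa Optional SOFA score.
#' @param time_h Timestamp (hours) of the measurements.
#' @return An object of class `covariate_set`.
#' @export
covariate_set <- function(weight_kg, scr_mg_dl, age_years, sex,
                          clcr_ml_min = NULL, albumin_g_l = NULL, sofa = NULL,
                          time_h = 0) {
  sex <- match.arg(sex, c("male", "female"))
  if (weight_kg <= 0) stop("weight_kg must be > 0", call. = FALSE)
  if (scr_mg_dl <= 0) stop("scr_mg_dl must be > 0", call. = FALSE)
  if (age_years < 0) stop("age_years must be >= 0", call. = FALSE)
  structure(list(time_h = time_h, weight_kg = weight_kg, scr_mg_dl = scr_mg_dl,
                 age_years = age_years, sex = sex, clcr_ml_min = clcr_ml_min,
                 albumin_g_l = albumin_g_l, sofa = sofa),
            class = "covariate_set")
}

#' Cockcroft-Gault creatinine clearance
#'
#' Estimates creatinine clearance (mL/min) from age, weight, sex and serum
#' creatinine: `(140 - age) * weight / (72 * SCR)`, multiplied by 0.85 for
#' female patients, floored at zero.
#'
#' @param cov A [covariate_set()].
#' @return Creatinine clearance in mL/min.
#' @export
cockcroft_gault <- function(cov) {
  for (f in c("age_years", "weight_kg", "scr_mg_dl", "sex"))
    if (is.null(cov[[f]]) || (f != "sex" && is.na(cov[[f]])))
      stop("Cockcroft-Gault requires covariate: ", f, call. = FALSE)
  if (cov$scr_mg_dl <= 0) stop("serum creatinine must be > 0", call. = FALSE)
  clcr <- (140 - cov$age_years) * cov$weight_kg / (72 * cov$scr_mg_dl)
  if (identical(cov$sex, "female")) clcr <- clcr * 0.85
  max(clcr, 0)
}

# CLcr used by covariate equations: measured value wins over the derived one.
effective_clcr <- function(cov) {
  if (!is.null(cov$clcr_ml_min) && !is.na(cov$clcr_ml_min)) return(cov$clcr_ml_min)
  cockcroft_gault(cov)
}

eval_covariate_form <- function(spec, cov, param) {
  switch(spec$form,
    linear_clcr = spec$theta * effective_clcr(cov) / spec$ref_clcr,
    power_clcr = {
      expo <- if (is.null(spec$exponent)) 1 else spec$exponent
      spec$theta * (effective_clcr(cov) / spec$ref_clcr)^expo
    },
    power_scr = {
      if (is.null(cov$scr_mg_dl)) stop("missing covariate: scr_mg_dl", call. = FALSE)
      mscr <- max(cov$scr_mg_dl, spec$scr_floor %||% 0)
      spec$theta * (mscr / spec$ref_scr)^spec$exponent
    },
    intercept_clcr = spec$theta + spec$theta_clcr * effective_clcr(cov) / spec$ref_clcr,
    per_kg = {
      if (is.null(cov$weight_kg)) stop("missing covariate: weight_kg", call. = FALSE)
      spec$theta * cov$weight_kg
    },
    stop("unknown covariate form: ", spec$form, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute individual PK parameters from covariates
#'
#' Evaluates the model's covariate equations at a patient's covariates, then
#' multiplies the parameters elementwise by MAP correction factors (default
#' 1, i.e. the population prediction).
#'
#' @param model A [pk_model()].
#' @param cov A [covariate_set()].
#' @param corr Optional [correction_factors()] (or named list with `cl`, `v1`).
#' @return An object of class `pk_params` with fields `cl`, `v1` and, for
#'   two-compartment models, `q` and `v2` (all L or L/h), plus a
#'   `provenance` attribute describing what was applied.
#' @export
compute_individual_parameters <- function(model, cov, corr = NULL) {
  stopifnot(inherits(model, "pk_model"))
  pars <- model$typical
  applied <- character(0)
  for (p in names(model$covariate_model)) {
    pars[[p]] <- eval_covariate_form(model$covariate_model[[p]], cov, p)
    applied <- c(applied, paste0(p, ":", model$covariate_model[[p]]$form))
  }
  corr <- corr %||% correction_factors()
  for (p in intersect(names(corr), names(pars))) {
    f <- corr[[p]]
    if (!is.null(f) && !is.na(f) && f != 1) applied <- c(applied, paste0(p, ":x", f))
    pars[[p]] <- pars[[p]] * (corr[[p]] %||% 1)
  }
  vals <- unlist(pars)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("individual parameters must be strictly positive; got ",
         paste(sprintf("%s=%g", names(vals), vals), collapse = ", "), call. = FALSE)
  structure(c(pars, list(n_compartments = model$n_compartments)),
            provenance = applied, class = "pk_params")
}

#' Construct a set of pure PK parameters
#'
#' Used directly when no covariate model is involved (e.g. simulation tests).
#' Clearance may be zero (no elimination, useful for mass-balance checks);
#' volumes and inter-compartmental clearance must be strictly positive.
#' @param cl Clearance (L/h), >= 0. @param v1 Central volume (L).
#' @param q Inter-compartmental clearance (L/h), two-compartment only.
#' @param v2 Peripheral volume (L), two-compartment only.
#' @return A `pk_params` object.
#' @export
pk_params <- function(cl, v1, q = NULL, v2 = NULL) {
  ncmt <- if (is.null(q)) 1L else 2L
  if (ncmt == 2L && is.null(v2)) stop("v2 required with q", call. = FALSE)
  if (cl < 0) stop("cl must be >= 0", call. = FALSE)
  if (any(c(v1, q, v2) <= 0))
    stop("volumes and inter-compartmental clearance must be strictly positive",
         call. = FALSE)
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2, n_compartments = ncmt),
            class = "pk_params")
}

#' MAP correction factors
#'
#' Multiplicative adjustments applied to the random-effect-bearing
#' parameters (clearance and central volume). Defaults of exactly 1
#' reproduce the population covariate-model prediction.
#'
#' @param cl Clearance factor (> 0). @param v1 Central-volume factor (> 0).
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(cl = 1, v1 = 1) {
  if (cl <= 0 || v1 <= 0)
    stop("correction factors must be strictly positive", call. = FALSE)
  structure(list(cl = cl, v1 = v1), class = "correction_factors")
}
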