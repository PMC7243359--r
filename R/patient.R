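#' Construct a patient record
#'
#' Bundles a patient's time-stamped covariate series, dose-event history
#' and measured plasma concentrations on a single numeric time axis
#' (hours; an optional POSIXct origin `t0` anchors it to wall-clock time).
#'
#' @param id Patient identifier.
#' @param covariates `data.frame` with columns `time_h`, `weight_kg`,
#'   `scr_mg_dl`, `age_years`, `sex` and optionally `clcr_ml_min`,
#'   `albumin_g_l`, `sofa`; rows sorted by time. At least one row.
#' @param doses Optional [dose_events()] history.
#' @param observations Optional `data.frame` with `time_h`, `conc_mg_l`.
#' @param t0 Optional POSIXct origin of the time axis (UTC).
#' @param true_factors Optional [correction_factors()] carried by synthetic
#'   patients (the simulated truth; not visible to the estimators).
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(id, covariates, doses = NULL, observations = NULL,
                           t0 = NULL, true_factors = NULL) {
  stopifnot(is.data.frame(covariates), nrow(covariates) >= 1)
  need <- c("time_h", "weight_kg", "scr_mg_dl", "age_years", "sex")
  missing_c <- setdiff(need, names(covariates))
  if (length(missing_c))
    stop("covariates missing columns: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(covariates$time_h))
    stop("covariate timestamps must be sorted", call. = FALSE)
  doses <- doses %||% dose_events(numeric(0), numeric(0), numeric(0))
  observations <- observations %||%
    data.frame(time_h = numeric(0), conc_mg_l = numeric(0))
  if (nrow(observations) > 0 && any(observations$conc_mg_l < 0))
    stop("observed concentrations must be >= 0", call. = FALSE)
  structure(list(id = as.character(id), covariates = covariates, doses = doses,
                 observations = observations, t0 = t0,
                 true_factors = true_factors),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %d covariate set(s), %d dose(s), %d level(s)\n",
              x$id, nrow(x$covariates), nrow(x$doses), nrow(x$observations)))
  invisible(x)
}

#' Most recent covariate set
#'
#' @param patient A `patient_record`.
#' @param at_h Reference time (hours); the newest covariate row at or
#'   before it is used (the first row if none precedes it). Default: the
#'   newest row.
#' @return A [covariate_set()].
#' @export
latest_covariates <- function(patient, at_h = NULL) {
  cv <- patient$covariates
  i <- if (is.null(at_h)) nrow(cv) else max(1, max(c(0, which(cv$time_h <= at_h))))
  row <- cv[i, ]
  covariate_set(weight_kg = row$weight_kg, scr_mg_dl = row$scr_mg_dl,
                age_years = row$age_years, sex = as.character(row$sex),
                clcr_ml_min = if ("clcr_ml_min" %in% names(cv)) row$clcr_ml_min else NULL,
                albumin_g_l = if ("albumin_g_l" %in% names(cv)) row$albumin_g_l else NULL,
                sofa = if ("sofa" %in% names(cv)) row$sofa else NULL,
                time_h = row$time_h)
}
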