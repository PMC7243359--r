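#' @title Patient and cohort file formats
#' @description Patients are exchanged as JSON (one object) or JSON-lines
#'   (one patient per line for cohorts). Timestamps may be ISO-8601 UTC
#'   strings or numeric hours; internally everything lives on a numeric
#'   hour axis anchored at the record's `t0`.
#' @name io
NULL

parse_time_h <- function(x, t0) {
  if (is.numeric(x)) return(as.numeric(x))
  tt <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (any(is.na(tt)))
    tt[is.na(tt)] <- as.POSIXct(x[is.na(tt)], tz = "UTC")
  if (any(is.na(tt))) stop("unparseable timestamp(s): ",
                           paste(x[is.na(tt)], collapse = ", "), call. = FALSE)
  as.numeric(difftime(tt, t0, units = "hours"))
}

find_t0 <- function(obj) {
  if (!is.null(obj$t0)) return(as.POSIXct(obj$t0, tz = "UTC"))
  times <- c(obj$covariates$time, obj$doses$time, obj$observations$time)
  if (is.character(times) && length(times))
    return(min(as.POSIXct(times, tz = "UTC")))
  NULL
}

patient_from_list <- function(obj) {
  t0 <- find_t0(obj)
  cv <- as.data.frame(obj$covariates)
  cv$time_h <- parse_time_h(cv$time %||% cv$time_h, t0)
  cv$time <- NULL
  doses <- NULL
  if (!is.null(obj$doses) && NROW(obj$doses) > 0) {
    d <- as.data.frame(obj$doses)
    doses <- dose_events(amount_mg = d$amount_mg,
                         time_h = parse_time_h(d$time %||% d$time_h, t0),
                         infusion_min = d$infusion_min,
                         drug = d$drug %||% NA_character_)
  }
  observations <- NULL
  if (!is.null(obj$observations) && NROW(obj$observations) > 0) {
    o <- as.data.frame(obj$observations)
    observations <- data.frame(time_h = parse_time_h(o$time %||% o$time_h, t0),
                               conc_mg_l = o$conc_mg_l)
  }
  tf <- NULL
  if (!is.null(obj$true_factors))
    tf <- correction_factors(cl = obj$true_factors$cl %||% 1,
                             v1 = obj$true_factors$v1 %||% 1)
  patient_record(id = obj$id %||% "patient", covariates = cv, doses = doses,
                 observations = observations, t0 = t0, true_factors = tf)
}

patient_to_list <- function(patient) {
  cv <- patient$covariates
  out <- list(id = patient$id, covariates = cv)
  if (!is.null(patient$t0))
    out$t0 <- format(patient$t0, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (nrow(patient$doses) > 0) out$doses <- as.data.frame(patient$doses)
  if (nrow(patient$observations) > 0) out$observations <- patient$observations
  if (!is.null(patient$true_factors))
    out$true_factors <- list(cl = patient$true_factors$cl,
                             v1 = patient$true_factors$v1)
  out
}

#' Read / write a patient record as JSON
#'
#' @param path File path.
#' @return `read_patient_json()`: a [patient_record()];
#'   `write_patient_json()`: `path`, invisibly.
#' @export
read_patient_json <- function(path) {
  patient_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_patient_json
#' @param patient A [patient_record()].
#' @export
write_patient_json <- function(patient, path) {
  jsonlite::write_json(patient_to_list(patient), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read / write a cohort as JSON-lines
#'
#' One patient JSON object per line.
#'
#' @param cohort List of [patient_record()]s.
#' @param path File path.
#' @return `read_cohort_jsonl()`: list of patients;
#'   `write_cohort_jsonl()`: `path`, invisibly.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  lines <- vapply(cohort, function(p)
    as.character(jsonlite::toJSON(patient_to_list(p), auto_unbox = TRUE,
                                  digits = NA, dataframe = "rows")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lapply(readLines(path), function(l)
    patient_from_list(jsonlite::fromJSON(l, simplifyVector = TRUE)))
}

#' Read observations from a two-column CSV
#'
#' Expects columns `time` (ISO-8601 or numeric hours) and `conc_mg_l`.
#'
#' @param path File path.
#' @param t0 Optional POSIXct origin for ISO timestamps.
#' @return `data.frame` with `time_h`, `conc_mg_l`.
#' @export
read_observations_csv <- function(path, t0 = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- if ("time" %in% names(d)) d$time else d$time_h
  data.frame(time_h = parse_time_h(tcol, t0), conc_mg_l = d$conc_mg_l)
}
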