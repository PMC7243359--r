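#' Load per-drug clinical configuration
#'
#' Reads the drug configuration catalogue (exposure-target defaults, safety
#' limits, infusion duration, continuous-advice flag, covariate freshness
#' limits) and returns the entry for one drug as ready-to-use objects.
#'
#' @param drug Drug name (case-insensitive).
#' @param path Optional path to a YAML configuration; defaults to the file
#'   shipped with the package.
#' @return A list of class `drug_config` with elements `target`
#'   ([exposure_target()]), `limits` ([safety_limits()]), `infusion_min`,
#'   `continuous_enabled` and `freshness_h`.
#' @export
get_drug_config <- function(drug, path = NULL) {
  path <- path %||% system.file("extdata", "drug_config.yaml",
                                package = "icudose", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  key <- tolower(trimws(drug))
  if (!key %in% names(raw))
    stop("no configuration for drug '", drug, "'; configured: ",
         paste(sort(names(raw)), collapse = ", "), call. = FALSE)
  e <- raw[[key]]
  tgt <- e$target
  target <- exposure_target(
    kind = tgt$kind,
    mic_mg_l = tgt$mic_mg_l,
    cmin_mic_multiplier = tgt$cmin_mic_multiplier %||% 1,
    target_auc24_mg_h_l = tgt$target_auc24_mg_h_l,
    acceptable_conc_range = unlist(tgt$acceptable_conc_range),
    acceptable_auc_range = unlist(tgt$acceptable_auc_range)
  )
  lim <- e$limits
  limits <- safety_limits(
    max_dose_mg = lim$max_dose_mg,
    max_daily_dose_mg = lim$max_daily_dose_mg,
    minimal_toxic_conc_mg_l = lim$minimal_toxic_conc_mg_l,
    standard_daily_dose_mg = lim$standard_daily_dose_mg
  )
  structure(list(drug = key, target = target, limits = limits,
                 infusion_min = e$infusion_min %||% 60,
                 continuous_enabled = isTRUE(e$continuous_enabled),
                 freshness_h = e$freshness_h %||% list(scr_mg_dl = 24)),
            class = "drug_config")
}

#' Exposure target definition
#'
#' Defines the PK/PD target driving dose selection. For time-above-MIC
#' drugs (beta-lactams) the target is operationalized as a steady-state
#' trough of `cmin_mic_multiplier * MIC`, which guarantees 100 %T>MIC; for
#' AUC/MIC drugs (vancomycin, ciprofloxacin) the target is a daily AUC.
#'
#' @param kind `"T_ABOVE_MIC"` or `"AUC_OVER_MIC"`.
#' @param mic_mg_l MIC of the pathogen (mg/L).
#' @param target_cmin_mg_l Explicit target trough (mg/L); defaults to
#'   `cmin_mic_multiplier * mic_mg_l` for `T_ABOVE_MIC`.
#' @param cmin_mic_multiplier Trough target as a multiple of the MIC.
#' @param target_auc24_mg_h_l Target AUC over 24 h (mg*h/L), for
#'   `AUC_OVER_MIC`.
#' @param acceptable_conc_range Optional clinically acceptable concentration
#'   window, e.g. `c(10, 30)` mg/L for vancomycin.
#' @param acceptable_auc_range Optional desirable AUC window, e.g.
#'   `c(400, 600)` mg*h/L.
#' @return Object of class `exposure_target`.
#' @export
exposure_target <- function(kind = c("T_ABOVE_MIC", "AUC_OVER_MIC"),
                            mic_mg_l = 1, target_cmin_mg_l = NULL,
                            cmin_mic_multiplier = 1,
                            target_auc24_mg_h_l = NULL,
                            acceptable_conc_range = NULL,
                            acceptable_auc_range = NULL) {
  kind <- match.arg(kind)
  if (mic_mg_l < 0) stop("mic_mg_l must be >= 0", call. = FALSE)
  if (kind == "T_ABOVE_MIC") {
    target_cmin_mg_l <- target_cmin_mg_l %||% (cmin_mic_multiplier * mic_mg_l)
    if (target_cmin_mg_l <= 0)
      stop("T_ABOVE_MIC target requires a positive target trough", call. = FALSE)
    target_auc24_mg_h_l <- NULL
  } else {
    if (is.null(target_auc24_mg_h_l) || target_auc24_mg_h_l < 0)
      stop("AUC_OVER_MIC target requires target_auc24_mg_h_l >= 0", call. = FALSE)
    target_cmin_mg_l <- NULL
  }
  for (r in list(acceptable_conc_range, acceptable_auc_range))
    if (!is.null(r) && (length(r) != 2 || r[1] >= r[2]))
      stop("ranges must be c(low, high) with low < high", call. = FALSE)
  structure(list(kind = kind, mic_mg_l = mic_mg_l,
                 target_cmin_mg_l = target_cmin_mg_l,
                 target_auc24_mg_h_l = target_auc24_mg_h_l,
                 acceptable_conc_range = acceptable_conc_range,
                 acceptable_auc_range = acceptable_auc_range),
            class = "exposure_target")
}

#' Safety limits for dose advice
#'
#' Upper limits enforced by the advisor: maximum dose per administration,
#' maximum total daily dose, and the minimal toxic (peak) concentration.
#' The standard daily dose anchors the out-of-range warning (advice above
#' twice or below half of it is flagged).
#'
#' @param max_dose_mg Maximum single dose (mg).
#' @param max_daily_dose_mg Maximum total dose per 24 h (mg).
#' @param minimal_toxic_conc_mg_l Peak concentration that must not be
#'   reached (mg/L).
#' @param standard_daily_dose_mg The drug's standard total daily dose (mg).
#' @return Object of class `safety_limits`.
#' @export
safety_limits <- function(max_dose_mg, max_daily_dose_mg,
                          minimal_toxic_conc_mg_l, standard_daily_dose_mg) {
  vals <- c(max_dose_mg, max_daily_dose_mg, minimal_toxic_conc_mg_l,
            standard_daily_dose_mg)
  if (any(vals <= 0)) stop("safety limits must be positive", call. = FALSE)
  if (max_dose_mg > max_daily_dose_mg)
    stop("max_dose_mg cannot exceed max_daily_dose_mg", call. = FALSE)
  structure(list(max_dose_mg = max_dose_mg,
                 max_daily_dose_mg = max_daily_dose_mg,
                 minimal_toxic_conc_mg_l = minimal_toxic_conc_mg_l,
                 standard_daily_dose_mg = standard_daily_dose_mg),
            class = "safety_limits")
}
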