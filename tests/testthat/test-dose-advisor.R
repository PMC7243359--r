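test_that("a typical vancomycin patient gets feasible advice hitting the AUC target", {
  pat <- ref_patient(clcr_ml_min = 100)
  adv <- advise("vancomycin", pat)
  expect_true(adv$status %in% c("LOADING_PLUS_MAINTENANCE", "MAINTENANCE_ONLY"))
  r <- adv$regimen
  # verify safety predicates independently of the advisor's own checks
  cfg <- get_drug_config("vancomycin")
  expect_lte(r$maintenance_dose_mg, cfg$limits$max_dose_mg)
  expect_lte(r$maintenance_dose_mg * 24 / r$interval_h,
             cfg$limits$max_daily_dose_mg)
  expect_lt(r$predicted$cmax_mg_l, cfg$limits$minimal_toxic_conc_mg_l)
  # re-simulate the advised regimen from scratch: AUC0-24 within 5% of 500
  params <- compute_individual_parameters(get_model("vancomycin"),
                                          latest_covariates(pat))
  ss <- simulate_steady_state(params, r$maintenance_dose_mg, r$interval_h,
                              r$infusion_min)
  expect_equal(ss$exposure$auc_mg_h_l, 500, tolerance = 0.05)
})

test_that("an unreachable toxicity limit yields NO_ADVICE when continuous is off", {
  pat <- ref_patient()
  limits <- safety_limits(max_dose_mg = 3000, max_daily_dose_mg = 6000,
                          minimal_toxic_conc_mg_l = 0.001,
                          standard_daily_dose_mg = 2000)
  adv <- advise("vancomycin", pat, limits = limits,
                options = list(continuous_enabled = FALSE))
  expect_identical(adv$status, "NO_ADVICE")
  expect_null(adv$regimen)
  txt <- render_advice_text(adv)
  expect_match(txt, "pharmacist")
})

test_that("continuous infusion is the fallback when no intermittent regimen is safe", {
  pat <- ref_patient(clcr_ml_min = 100)
  # single-dose cap so low that every intermittent frequency fails, but a
  # continuous infusion stays within the daily limit
  limits <- safety_limits(max_dose_mg = 100, max_daily_dose_mg = 6000,
                          minimal_toxic_conc_mg_l = 60,
                          standard_daily_dose_mg = 2000)
  adv <- advise("vancomycin", pat, limits = limits,
                options = list(continuous_enabled = TRUE))
  expect_identical(adv$status, "CONTINUOUS")
  params <- compute_individual_parameters(get_model("vancomycin"),
                                          latest_covariates(pat))
  expect_equal(adv$regimen$rate_mg_h, 500 * params$cl / 24, tolerance = 1e-9)
  adv_off <- advise("vancomycin", pat, limits = limits,
                    options = list(continuous_enabled = FALSE))
  expect_identical(adv_off$status, "NO_ADVICE")
})

test_that("the first feasible (lowest) frequency wins and iteration is monotone", {
  pat <- ref_patient(clcr_ml_min = 100)
  # generous single-dose cap: baseline q12h is feasible
  adv_base <- advise("vancomycin", pat)
  expect_identical(adv_base$regimen$interval_h, 12)
  # cap below the q12h dose but above the q6h dose: advisor must move on
  md_q12 <- adv_base$regimen$maintenance_dose_mg
  limits <- safety_limits(max_dose_mg = md_q12 * 0.6,
                          max_daily_dose_mg = 6000,
                          minimal_toxic_conc_mg_l = 60,
                          standard_daily_dose_mg = 2000)
  adv <- advise("vancomycin", pat, limits = limits)
  expect_lt(adv$regimen$interval_h, 12)
  expect_lte(adv$regimen$maintenance_dose_mg, limits$max_dose_mg)
})

test_that("advice is deterministic for identical inputs", {
  pat <- ref_patient()
  a1 <- advise("meropenem", pat)
  a2 <- advise("meropenem", pat)
  expect_identical(a1, a2)
})

test_that("a daily dose beyond twice the standard carries the out-of-range warning", {
  pat <- ref_patient(clcr_ml_min = 100)
  target <- exposure_target("AUC_OVER_MIC", mic_mg_l = 1,
                            target_auc24_mg_h_l = 1200)
  limits <- safety_limits(max_dose_mg = 4000, max_daily_dose_mg = 12000,
                          minimal_toxic_conc_mg_l = 500,
                          standard_daily_dose_mg = 2000)
  adv <- advise("vancomycin", pat, target = target, limits = limits)
  codes <- vapply(adv$warnings, `[[`, character(1), "code")
  expect_true("DAILY_DOSE_HIGH" %in% codes)
  # and a low dose carries the low warning
  target_lo <- exposure_target("AUC_OVER_MIC", mic_mg_l = 1,
                               target_auc24_mg_h_l = 100)
  adv_lo <- advise("vancomycin", pat, target = target_lo, limits = limits)
  codes_lo <- vapply(adv_lo$warnings, `[[`, character(1), "code")
  expect_true("DAILY_DOSE_LOW" %in% codes_lo)
})

test_that("stale covariates are flagged, fresh ones are not, order is deterministic", {
  fresh <- patient_record("f", data.frame(
    time_h = 10, weight_kg = 70, scr_mg_dl = 1, age_years = 40, sex = "male"))
  expect_length(staleness_warnings(fresh, list(scr_mg_dl = 24), now_h = 20), 0)
  stale <- patient_record("s", data.frame(
    time_h = 0, weight_kg = 70, scr_mg_dl = 1, age_years = 40, sex = "male"))
  w <- staleness_warnings(stale, list(scr_mg_dl = 24), now_h = 30)
  expect_length(w, 1)
  expect_identical(w[[1]]$covariate, "scr_mg_dl")
  expect_match(w[[1]]$text, "older than recommended")
  w2 <- staleness_warnings(stale, list(weight_kg = 12, scr_mg_dl = 24),
                           now_h = 30)
  expect_length(w2, 2)
  expect_identical(vapply(w2, `[[`, character(1), "covariate"),
                   c("scr_mg_dl", "weight_kg"))
})

test_that("advice text is absolute, complete, and refers NO_ADVICE to support", {
  pat <- ref_patient()
  adv <- advise("vancomycin", pat)
  txt <- render_advice_text(adv)
  expect_match(txt, sprintf("%.0f mg every %g h",
                            adv$regimen$maintenance_dose_mg,
                            adv$regimen$interval_h))
  if (!is.null(adv$regimen$loading_dose_mg))
    expect_match(txt, "Loading dose")
  expect_false(grepl("increase|decrease", txt, ignore.case = TRUE))
  json <- jsonlite::fromJSON(advice_to_json(adv))
  expect_identical(json$status, adv$status)
  expect_equal(json$md_mg, adv$regimen$maintenance_dose_mg)
})

test_that("returned regimens always satisfy the safety limits (randomized patients)", {
  set.seed(41)
  cohort <- generate_cohort(40, seed = 500)
  for (drug in c("vancomycin", "meropenem")) {
    cfg <- get_drug_config(drug)
    for (pat in cohort[1:20]) {
      adv <- advise(drug, pat)
      if (adv$status %in% c("LOADING_PLUS_MAINTENANCE", "MAINTENANCE_ONLY")) {
        r <- adv$regimen
        expect_lte(r$maintenance_dose_mg, cfg$limits$max_dose_mg)
        expect_lte(r$maintenance_dose_mg * 24 / r$interval_h,
                   cfg$limits$max_daily_dose_mg + 1e-9)
        expect_lt(r$predicted$cmax_mg_l, cfg$limits$minimal_toxic_conc_mg_l)
        if (!is.null(r$loading_dose_mg))
          expect_lte(r$loading_dose_mg, cfg$limits$max_dose_mg)
      } else if (adv$status == "CONTINUOUS") {
        expect_lte(adv$regimen$daily_dose_mg, cfg$limits$max_daily_dose_mg)
      }
    }
  }
})
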