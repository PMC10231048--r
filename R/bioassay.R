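#' Control-corrected bioassay mortality
#'
#' Observed mortality in the treated arm, corrected for natural mortality in
#' the untreated control by Abbott's formula following WHO test-procedure
#' conventions: if control mortality exceeds 20% the test is discarded
#' (`valid = FALSE`); between 5% and 20% the treated mortality is corrected,
#' \deqn{M' = 100 (M - C) / (100 - C)}{M' = 100 (M - C) / (100 - C)}
#' with M the raw treated and C the control mortality (both in percent);
#' below 5% the raw mortality is used as-is. The corrected value is clamped
#' to \[0, 100\].
#'
#' @param n_dead,n_exposed treated-arm counts (`n_exposed > 0`).
#' @param n_control_dead,n_control_exposed control-arm counts
#'   (`n_control_exposed > 0`).
#' @return A `mortality_result` list: `raw_mortality`, `control_mortality`,
#'   `corrected_mortality` (percent), `valid`, `correction_applied`.
#' @examples
#' corrected_mortality(90, 100, 10, 100)  # Abbott: 100*(90-10)/(100-10)
#' @export
corrected_mortality <- function(n_dead, n_exposed,
                                n_control_dead, n_control_exposed) {
  if (!is_scalar_number(n_exposed) || n_exposed <= 0 ||
      !is_scalar_number(n_control_exposed) || n_control_exposed <= 0) {
    stop_psir("corrected_mortality: exposed counts must be positive",
              class = "psir_undefined_rate")
  }
  if (n_dead < 0 || n_dead > n_exposed ||
      n_control_dead < 0 || n_control_dead > n_control_exposed) {
    stop_psir("corrected_mortality: dead counts outside [0, exposed]")
  }
  raw <- 100 * n_dead / n_exposed
  ctrl <- 100 * n_control_dead / n_control_exposed
  valid <- ctrl <= 20
  applied <- FALSE
  corrected <- raw
  if (valid && ctrl >= 5) {
    corrected <- 100 * (raw - ctrl) / (100 - ctrl)
    applied <- TRUE
  }
  corrected <- clamp(corrected, 0, 100)
  structure(list(raw_mortality = raw, control_mortality = ctrl,
                 corrected_mortality = if (valid) corrected else NA_real_,
                 valid = valid, correction_applied = applied),
            class = "mortality_result")
}

#' @export
print.mortality_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<mortality_result> %.2f%% (raw %.2f%%, control %.2f%%%s)\n",
                x$corrected_mortality, x$raw_mortality, x$control_mortality,
                if (x$correction_applied) ", Abbott-corrected" else ""))
  } else {
    cat(sprintf("<mortality_result> INVALID: control mortality %.2f%% > 20%%\n",
                x$control_mortality))
  }
  invisible(x)
}

#' Adult emergence inhibition (EI%)
#'
#' Endpoint for insect growth regulators in larval bioassays: the
#' percentage of exposed larvae that fail to emerge as adults relative to
#' the control,
#' \deqn{EI = 100 (1 - E_T / E_C)}{EI = 100 (1 - E_T/E_C)}
#' where \eqn{E_T} and \eqn{E_C} are the treated and control emergence
#' rates. Clamped to \[0, 100\] (treated emergence can exceed control by
#' sampling noise).
#'
#' @param n_exposed,n_emerged treated-arm counts.
#' @param control_n_exposed,control_n_emerged control-arm counts; the
#'   control emergence rate must be positive.
#' @return EI as a percent scalar.
#' @examples
#' emergence_inhibition(100, 47, 100, 94)  # 50%
#' @export
emergence_inhibition <- function(n_exposed, n_emerged,
                                 control_n_exposed, control_n_emerged) {
  if (n_exposed <= 0 || control_n_exposed <= 0) {
    stop_psir("emergence_inhibition: exposed counts must be positive",
              class = "psir_undefined_rate")
  }
  if (n_emerged < 0 || n_emerged > n_exposed ||
      control_n_emerged < 0 || control_n_emerged > control_n_exposed) {
    stop_psir("emergence_inhibition: emerged counts outside [0, exposed]")
  }
  e_c <- control_n_emerged / control_n_exposed
  if (e_c == 0) {
    stop_psir("emergence_inhibition: control emergence rate is zero",
              class = "psir_undefined_baseline")
  }
  e_t <- n_emerged / n_exposed
  clamp(100 * (1 - e_t / e_c), 0, 100)
}

#' Interpret a synergist (enzyme-inhibitor) bioassay
#'
#' Pre-exposure to a synergist such as PBO blocks detoxification enzymes;
#' comparing mortality with and without it reveals how much of a resistance
#' phenotype is metabolic. Synergist testing is only informative when the
#' population is resistant at the diagnostic concentration, so a DC-test
#' mortality >= 90% returns `not_applicable`. Otherwise:
#' \itemize{
#'   \item combined mortality >= 98%: `full_restoration` — metabolic
#'     resistance alone explains the phenotype;
#'   \item combined < 98% but more than 10 percentage points above the
#'     insecticide-alone arm: `partial_restoration` — detoxification
#'     contributes, other mechanisms are also present;
#'   \item otherwise `no_restoration` — detoxification enzymes are not
#'     involved.
#' }
#' "10% higher" is read as 10 percentage points, strictly greater, matching
#' the complementary "not more than 10% higher" wording of the
#' no-restoration class.
#'
#' @param mortality_alone percent mortality with the insecticide alone.
#' @param mortality_combined percent mortality with synergist + insecticide.
#' @param dc_mortality percent mortality of the population in the
#'   diagnostic-concentration test (eligibility gate). Corrected mortalities
#'   should be supplied for all three arms.
#' @param full_threshold,delta_threshold,eligibility_threshold rule
#'   thresholds in percent / percentage points; defaults 98, 10, 90.
#' @return A `synergist_outcome` list: `category` (one of
#'   `full_restoration`, `partial_restoration`, `no_restoration`,
#'   `not_applicable`) and `delta_mortality` (combined minus alone, points).
#' @examples
#' interpret_synergist(60, 99, 70)  # full_restoration
#' interpret_synergist(60, 75, 70)  # partial_restoration (delta 15)
#' @export
interpret_synergist <- function(mortality_alone, mortality_combined,
                                dc_mortality,
                                full_threshold = 98, delta_threshold = 10,
                                eligibility_threshold = 90) {
  for (m in c(mortality_alone, mortality_combined, dc_mortality)) {
    if (!is_scalar_number(m) || m < 0 || m > 100) {
      stop_psir("interpret_synergist: mortalities must be in [0, 100]")
    }
  }
  delta <- mortality_combined - mortality_alone
  category <-
    if (dc_mortality >= eligibility_threshold) "not_applicable"
    else if (mortality_combined >= full_threshold) "full_restoration"
    else if (delta > delta_threshold) "partial_restoration"
    else "no_restoration"
  structure(list(category = category, delta_mortality = delta),
            class = "synergist_outcome")
}

#' @export
print.synergist_outcome <- function(x, ...) {
  cat(sprintf("<synergist_outcome> %s (delta %+.1f points)\n",
              x$category, x$delta_mortality))
  invisible(x)
}
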