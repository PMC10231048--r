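#' Log-probit dose-response fit (LC50 / IE50)
#'
#' Fits the classical log-probit model to a larval dose-response series:
#' the response probability at concentration c is
#' \deqn{P(c) = \Phi(\alpha + \beta \log_{10} c)}{P(c) = Phi(alpha + beta log10 c)}
#' and the median lethal (or emergence-inhibiting) concentration is
#' \eqn{LC_{50} = 10^{-\alpha/\beta}}. Estimation is maximum likelihood by
#' iteratively reweighted least squares (`stats::glm` with a probit link on
#' control-corrected response proportions, binomial weights equal to the
#' exposed counts; log-likelihood tolerance 1e-8, up to 100 iterations).
#'
#' Control handling follows the bioassay conventions: control response above
#' 20% invalidates the series; between 5% and 20% every treated proportion
#' is Abbott-corrected before fitting; below 5% raw proportions are used.
#'
#' The 95% CI on LC50 is computed by the delta method on
#' \eqn{\log_{10} LC_{50} = -\alpha/\beta} and back-transformed. When the
#' fit is over-dispersed (Pearson chi-square / df > 1) the variance is
#' inflated by the heterogeneity factor and a t quantile on `n_points - 2`
#' degrees of freedom replaces the normal quantile, as in standard probit
#' analysis.
#'
#' @param series a [larval_series()].
#' @return A `probit_fit` with fields `alpha`, `beta` (slope per log10
#'   concentration unit), `lc50`, `lc50_ci95` (length-2 vector), `se_log10_lc50`,
#'   `heterogeneity`, `n_points`, `converged`, `endpoint`, plus the series
#'   identity. A series carrying no information about the median (all-0 or
#'   all-100 responses) returns `converged = FALSE` with `NA` estimates. A
#'   significantly negative fitted slope raises an error, since it usually
#'   means mislabelled concentrations.
#' @examples
#' s <- larval_series("pop1", "Aedes aegypti", "temephos",
#'   concentration = c(0.01, 0.02, 0.05, 0.1, 0.2),
#'   n_exposed = rep(100, 5), n_responded = c(4, 17, 52, 88, 99),
#'   control_n_exposed = 100, control_n_responded = 1)
#' fit_probit(s)
#' @export
fit_probit <- function(series) {
  stopifnot(inherits(series, "larval_series"))
  pts <- series$points
  ctrl_rate <- series$control$n_responded / series$control$n_exposed
  if (ctrl_rate > 0.20) {
    stop_psir(sprintf(
      "fit_probit: control response %.1f%% > 20%%; series invalid", 100 * ctrl_rate))
  }
  p_raw <- pts$n_responded / pts$n_exposed
  p <- if (ctrl_rate >= 0.05) clamp((p_raw - ctrl_rate) / (1 - ctrl_rate), 0, 1)
       else p_raw

  base <- structure(list(
    site_id = series$site_id, species = series$species,
    insecticide = series$insecticide, endpoint = series$endpoint,
    conc_units = series$conc_units,
    alpha = NA_real_, beta = NA_real_, lc50 = NA_real_,
    lc50_ci95 = c(NA_real_, NA_real_), se_log10_lc50 = NA_real_,
    heterogeneity = NA_real_, n_points = nrow(pts), converged = FALSE),
    class = "probit_fit")

  # no partial response anywhere: the data say nothing about the median
  if (all(p <= 0) || all(p >= 1) ||
      (!any(p > 0 & p < 1) && length(unique(p)) == 1L)) {
    return(base)
  }

  x <- log10(pts$concentration)
  fit <- tryCatch(
    suppressWarnings(stats::glm(p ~ x, family = stats::binomial(link = "probit"),
                                weights = pts$n_exposed,
                                control = stats::glm.control(epsilon = 1e-8,
                                                             maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(base)

  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  if (!is.finite(beta) || beta <= 0) {
    stop_psir("fit_probit: fitted slope is not positive; check that concentrations are labelled correctly")
  }
  V <- stats::vcov(fit)
  df_resid <- nrow(pts) - 2L
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  h <- if (df_resid > 0) max(1, pearson / df_resid) else 1

  log10_lc50 <- -alpha / beta
  grad <- c(-1 / beta, alpha / beta^2)
  var_log10 <- h * drop(t(grad) %*% V %*% grad)
  q <- if (h > 1 && df_resid > 0) stats::qt(0.975, df_resid) else stats::qnorm(0.975)
  ci <- 10^(log10_lc50 + c(-1, 1) * q * sqrt(var_log10))

  base$alpha <- alpha
  base$beta <- beta
  base$lc50 <- 10^log10_lc50
  base$lc50_ci95 <- ci
  base$se_log10_lc50 <- sqrt(var_log10)
  base$heterogeneity <- h
  base$converged <- TRUE
  base
}

#' @export
print.probit_fit <- function(x, ...) {
  lab <- if (identical(x$endpoint, "emergence_inhibition")) "IE50" else "LC50"
  if (x$converged) {
    cat(sprintf("<probit_fit> %s / %s / %s\n", x$site_id, x$species, x$insecticide))
    cat(sprintf("  slope %.3f, %s = %.4g %s (95%% CI %.4g-%.4g), heterogeneity %.2f\n",
                x$beta, lab, x$lc50, x$conc_units,
                x$lc50_ci95[1], x$lc50_ci95[2], x$heterogeneity))
  } else {
    cat(sprintf("<probit_fit> %s: not converged (no %s estimate)\n", x$site_id, lab))
  }
  invisible(x)
}

#' Resistance ratio (RR50)
#'
#' Strength of resistance of a field population to a larvicide: the LC50
#' (or IE50) of the tested population divided by that of the susceptible
#' reference strain assayed in parallel with the same insecticide and
#' endpoint.
#'
#' @param test,reference converged [fit_probit()] results for the field
#'   population and the susceptible reference strain.
#' @return A `resistance_ratio` with fields `rr50`, `test_fit`,
#'   `reference_fit`.
#' @export
resistance_ratio <- function(test, reference) {
  stopifnot(inherits(test, "probit_fit"), inherits(reference, "probit_fit"))
  if (!test$converged || !reference$converged) {
    stop_psir("resistance_ratio: both fits must have converged")
  }
  if (!identical(test$insecticide, reference$insecticide) ||
      !identical(test$endpoint, reference$endpoint)) {
    stop_psir("resistance_ratio: test and reference must share insecticide and endpoint")
  }
  structure(list(rr50 = test$lc50 / reference$lc50,
                 test_fit = test, reference_fit = reference),
            class = "resistance_ratio")
}

#' @export
print.resistance_ratio <- function(x, ...) {
  cat(sprintf("<resistance_ratio> RR50 = %.3g (%s vs reference %s)\n",
              x$rr50, x$test_fit$site_id, x$reference_fit$site_id))
  invisible(x)
}

#' Export probit fits as a flat table
#'
#' @param fits list of `probit_fit` objects.
#' @return data.frame, one row per fit.
#' @export
probit_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    site_id = f$site_id, species = f$species, insecticide = f$insecticide,
    endpoint = f$endpoint, converged = f$converged,
    slope = f$beta, lc50 = f$lc50,
    lc50_lo = f$lc50_ci95[1], lc50_hi = f$lc50_ci95[2],
    heterogeneity = f$heterogeneity, n_points = f$n_points,
    stringsAsFactors = FALSE)))
}
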