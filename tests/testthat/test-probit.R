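test_that("noiseless probit-line data are recovered almost exactly", {
  conc <- 10^seq(0.5, 2.1, length.out = 5)
  s <- make_exact_series(alpha = -3.9, beta = 3.0, conc = conc)
  f <- fit_probit(s)
  expect_true(f$converged)
  expect_equal(f$lc50, 10^(3.9 / 3.0), tolerance = 0.01)
  expect_equal(f$beta, 3.0, tolerance = 0.02)
  # fitted LC50 is the exact median of the fitted curve
  expect_equal(pnorm(f$alpha + f$beta * log10(f$lc50)), 0.5, tolerance = 1e-8)
  expect_true(f$lc50_ci95[1] <= f$lc50 && f$lc50 <= f$lc50_ci95[2])
})

test_that("glm-based fit agrees with direct maximum-likelihood optimisation", {
  s <- make_probit_series(lc50 = 0.05, slope = 3, n = 100, seed = 42)
  f <- fit_probit(s)
  # independent oracle: direct binomial log-likelihood, Nelder-Mead
  x <- log10(s$points$concentration)
  d <- s$points$n_responded
  n <- s$points$n_exposed
  nll <- function(par) {
    p <- pnorm(par[1] + par[2] * x)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(d * log(p) + (n - d) * log(1 - p))
  }
  o <- optim(c(0, 1), nll, control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(f$alpha, o$par[1], tolerance = 1e-3)
  expect_equal(f$beta, o$par[2], tolerance = 1e-3)
  expect_equal(f$lc50, 10^(-o$par[1] / o$par[2]), tolerance = 1e-3)
})

test_that("LC50 is scale-equivariant and RR50 scale-invariant", {
  s1 <- make_probit_series(lc50 = 0.05, slope = 3, n = 200, seed = 11)
  s2 <- make_probit_series(lc50 = 0.5, slope = 3, n = 200, seed = 12,
                           site_id = "pop2")
  k <- 7.3
  scale_series <- function(s, k) {
    larval_series(s$site_id, s$species, s$insecticide,
                  s$points$concentration * k, s$points$n_exposed,
                  s$points$n_responded, s$control$n_exposed,
                  s$control$n_responded)
  }
  f1 <- fit_probit(s1); f1k <- fit_probit(scale_series(s1, k))
  f2 <- fit_probit(s2); f2k <- fit_probit(scale_series(s2, k))
  expect_equal(f1k$lc50, k * f1$lc50, tolerance = 1e-6)
  expect_equal(f2k$lc50, k * f2$lc50, tolerance = 1e-6)
  expect_equal(resistance_ratio(f2k, f1k)$rr50,
               resistance_ratio(f2, f1)$rr50, tolerance = 1e-6)
})

test_that("uninformative series are flagged unconverged, not guessed", {
  conc <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  dead0 <- larval_series("p", "sp", "i", conc, rep(100, 5), rep(0L, 5), 100, 0)
  expect_false(fit_probit(dead0)$converged)
  expect_true(is.na(fit_probit(dead0)$lc50))
  all100 <- larval_series("p", "sp", "i", conc, rep(100, 5), rep(100L, 5), 100, 0)
  expect_false(fit_probit(all100)$converged)
})

test_that("a decreasing dose-response raises an error instead of a fit", {
  conc <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  s <- larval_series("p", "sp", "i", conc, rep(100, 5),
                     c(95L, 80L, 50L, 20L, 5L), 100, 0)
  expect_error(fit_probit(s), "slope")
})

test_that("series with high control response are rejected", {
  conc <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  s <- larval_series("p", "sp", "i", conc, rep(100, 5),
                     c(5L, 20L, 50L, 80L, 95L), 100, 25)
  expect_error(fit_probit(s), "control")
})

test_that("resistance ratio contracts hold", {
  f <- fit_probit(make_probit_series(lc50 = 0.05, seed = 5))
  expect_equal(resistance_ratio(f, f)$rr50, 1.0)
  f2 <- fit_probit(make_probit_series(lc50 = 0.5, seed = 6, site_id = "p2"))
  expect_equal(resistance_ratio(f2, f)$rr50, f2$lc50 / f$lc50)
  other <- fit_probit(make_probit_series(lc50 = 0.05, seed = 7,
                                         insecticide = "Bti"))
  expect_error(resistance_ratio(other, f), "insecticide")
  bad <- fit_probit(larval_series("p", "sp", "temephos",
                                  c(0.01, 0.02, 0.05, 0.1), rep(50, 4),
                                  rep(0L, 4), 50, 0))
  expect_error(resistance_ratio(bad, f), "converged")
})

test_that("a simulated 20-fold LC50 shift is recovered in the RR50", {
  set.seed(2026)
  ref <- fit_probit(make_probit_series(lc50 = 0.05, slope = 3, n = 200, seed = 21))
  tst <- fit_probit(make_probit_series(lc50 = 1.0, slope = 3, n = 200, seed = 22,
                                       site_id = "field"))
  rr <- resistance_ratio(tst, ref)$rr50
  expect_gt(rr, 15); expect_lt(rr, 25)
})

test_that("parameter recovery over seeded replicates is unbiased and calibrated", {
  # kept small here; the full 200-replicate calibration runs in the
  # acceptance suite
  true_lc50 <- 0.05
  errs <- numeric(40); covered <- logical(40)
  for (i in seq_len(40)) {
    f <- fit_probit(make_probit_series(true_lc50, slope = 3, n = 100,
                                       seed = 1000 + i))
    errs[i] <- abs(log(f$lc50 / true_lc50))
    covered[i] <- f$lc50_ci95[1] <= true_lc50 && true_lc50 <= f$lc50_ci95[2]
  }
  expect_lt(median(errs), 0.07)
  expect_gte(mean(covered), 0.85)
})
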