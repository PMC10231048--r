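geno <- function(n, rr, rs, ss, marker = "kdr") {
  list(marker_id = marker, n_individuals = n, n_hom_resistant = rr,
       n_het = rs, n_hom_susceptible = ss)
}

test_that("allele frequency counts resistant chromosomes over 2N", {
  expect_equal(allele_frequency(geno(50, 0, 0, 50))$estimated_frequency, 0)
  m <- allele_frequency(geno(50, 0, 1, 49))
  expect_equal(m$estimated_frequency, 0.01)
  expect_equal(m$n_chromosomes, 100L)
  expect_equal(allele_frequency(geno(50, 50, 0, 0))$estimated_frequency, 1)
  expect_equal(allele_frequency(geno(10, 2, 3, 5))$estimated_frequency, 7 / 20)
  expect_error(allele_frequency(geno(0, 0, 0, 0)), "positive")
  expect_error(allele_frequency(geno(10, 5, 5, 5)), "sum")
})

test_that("adult classification reproduces the level table", {
  expect_equal(classify_adult(dc = 99)$level, 0L)
  # susceptible but resistance alleles present: tipping point, level 1
  mk <- list(allele_frequency(geno(50, 0, 2, 48)))
  cl <- classify_adult(dc = 99, markers = mk)
  expect_equal(cl$level, 1L)
  expect_equal(cl$status_label, "susceptible_with_alleles")
  # moderate: resistant at DC and 5x but controlled at 10x
  cl <- classify_adult(dc = 70, dc5x = 80, dc10x = 99)
  expect_equal(cl$level, 2L)
  expect_false(cl$unresolved)
  # strong: survives even 10x
  expect_equal(classify_adult(dc = 60, dc10x = 90)$level, 3L)
  # low: resistant at DC, already dead at 5x
  cl <- classify_adult(dc = 90, dc5x = 99, dc10x = 100)
  expect_equal(cl$level, 1L)
  expect_equal(cl$status_label, "low_resistance")
})

test_that("boundaries sit exactly at 98% as printed", {
  expect_equal(classify_adult(dc = 98)$level, 0L)
  expect_equal(classify_adult(dc = 97.999, dc5x = 98, dc10x = 98)$level, 1L)
  expect_equal(classify_adult(dc = 0, dc5x = 97.999, dc10x = 98)$level, 2L)
  expect_equal(classify_adult(dc = 0, dc5x = 0, dc10x = 97.999)$level, 3L)
})

test_that("missing intensity data yields an explicit unresolved state", {
  cl <- classify_adult(dc = 92)
  expect_true(cl$unresolved)
  expect_equal(cl$level, 1L)  # provisional
  expect_true("confirm_with_intensity_tests" %in% cl$flags)
  # the 90-98% band is additionally flagged as suspected resistance
  expect_true("resistance_suspected_confirm" %in% cl$flags)
  expect_false("resistance_suspected_confirm" %in% classify_adult(dc = 85)$flags)
  # 5x known resistant but 10x missing: provisionally moderate, unresolved
  cl <- classify_adult(dc = 70, dc5x = 80)
  expect_true(cl$unresolved)
  expect_equal(cl$level, 2L)
})

test_that("mortality results feed classification and invalid tests refuse it", {
  cl <- classify_adult(dc = corrected_mortality(99, 100, 1, 100))
  expect_equal(cl$level, 0L)
  expect_error(
    classify_adult(dc = corrected_mortality(50, 100, 25, 100)),
    "refused")
})

test_that("larval RR50 thresholds partition (0, Inf) with closed moderate interval", {
  expect_equal(classify_larval(3)$level, 0L)
  expect_equal(classify_larval(7)$level, 2L)
  expect_equal(classify_larval(12)$level, 3L)
  # both printed boundaries belong to the moderate class: 5 <= RR50 <= 10
  expect_equal(classify_larval(5)$level, 2L)
  expect_equal(classify_larval(10)$level, 2L)
  expect_equal(classify_larval(10.0001)$level, 3L)
  expect_equal(classify_larval(4.9999)$level, 0L)
  # markers upgrade a susceptible call to level 1
  mk <- list(allele_frequency(geno(50, 0, 1, 49)))
  expect_equal(classify_larval(3, markers = mk)$level, 1L)
  expect_equal(classify_larval(7, markers = mk)$level, 2L)
  expect_error(classify_larval(-1), "positive")
})

test_that("every mortality combination gets exactly one well-formed outcome", {
  g <- expand.grid(dc = seq(0, 100, by = 4), m5 = c(NA, seq(0, 100, by = 10)),
                   m10 = c(NA, seq(0, 100, by = 10)), mk = c(FALSE, TRUE))
  r <- adult_resistance_level(g$dc, g$m5, g$m10, g$mk)
  expect_equal(nrow(r), nrow(g))
  expect_true(all(r$level %in% 0:3))
  expect_true(all(r$status_label %in% c(
    "susceptible", "susceptible_with_alleles", "low_resistance",
    "moderate_resistance", "strong_resistance")))
  # unresolved only ever arises below the susceptibility threshold
  expect_true(all(!r$unresolved[g$dc >= 98]))
})

test_that("killing fewer mosquitoes never lowers the assigned level", {
  grid <- seq(0, 100, by = 7)
  for (mk in c(FALSE, TRUE)) {
    g <- expand.grid(dc = grid, m5 = grid, m10 = grid)
    lv <- adult_resistance_level(g$dc, g$m5, g$m10, mk)$level
    dim(lv) <- c(length(grid), length(grid), length(grid))
    # decreasing along each mortality axis must be non-decreasing in level
    expect_true(all(apply(lv, c(2, 3), function(v) all(diff(rev(v)) >= 0))))
    expect_true(all(apply(lv, c(1, 3), function(v) all(diff(rev(v)) >= 0))))
    expect_true(all(apply(lv, c(1, 2), function(v) all(diff(rev(v)) >= 0))))
  }
})

test_that("adult and larval evidence merge to the definitive maximum", {
  a0 <- make_cls(0); l2 <- make_cls(2)
  expect_equal(merge_evidence(a0, l2)$level, 2L)
  expect_equal(merge_evidence(NULL, l2)$level, 2L)
  expect_equal(merge_evidence(a0, NULL)$level, 0L)
  expect_error(merge_evidence(NULL, NULL), "at least one")
  # definitive larval evidence overrides a provisional adult call
  a_unres <- classify_adult(dc = 92)     # unresolved provisional 1
  m <- merge_evidence(a_unres, make_cls(3))
  expect_equal(m$level, 3L)
  expect_false(m$unresolved)
  expect_false("confirm_with_intensity_tests" %in% m$flags)
  # but a resolved lower level does not resolve a higher provisional one
  m2 <- merge_evidence(classify_adult(dc = 70, dc5x = 80), make_cls(0))
  expect_equal(m2$level, 2L)
  expect_true(m2$unresolved)
})
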