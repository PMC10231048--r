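test_that("detection probability has the closed form and its limits", {
  expect_equal(detection_probability(50, 0), 0)
  expect_equal(detection_probability(1, 1), 1)
  expect_equal(detection_probability(0, 0.5), 0)
  expect_equal(detection_probability(50, 0.01), 1 - 0.99^100)
  expect_equal(round(detection_probability(50, 0.01), 4), 0.6340)
})

test_that("detection probability is monotone in sample size and frequency", {
  p_n <- detection_probability(1:200, 0.01)
  expect_true(all(diff(p_n) > 0))
  p_f <- detection_probability(50, seq(0, 1, by = 0.01))
  expect_true(all(diff(p_f) >= 0))
  expect_error(detection_probability(-1, 0.5), "n >= 0")
  expect_error(detection_probability(10, 1.5), "p in")
})

test_that("tipping-point generations match the geometric-growth model", {
  expect_equal(generations_to_fixation(0.02, 2), 6L)
  expect_equal(generations_to_fixation(1, 2), 0L)
  expect_equal(generations_to_fixation(0.01, 2), 7L)
  expect_equal(generations_to_fixation(0.5, 2), 1L)
  # exact powers must not be off by one through floating point
  expect_equal(generations_to_fixation(0.25, 2), 2L)
  expect_equal(generations_to_fixation(1 / 1024, 2), 10L)
  expect_error(generations_to_fixation(0.02, 1), "exceed 1|never")
  expect_error(generations_to_fixation(0, 2), "p0")
})

test_that("projection and fixation time are mutually consistent", {
  expect_equal(project_frequency(0.1, 2, 2), c(0.1, 0.2, 0.4))
  expect_equal(project_frequency(0.5, 1, 5), rep(0.5, 6))
  traj <- project_frequency(0.02, 2, 6)
  expect_equal(traj[7], 1)  # capped at fixation
  set.seed(31)
  for (i in 1:50) {
    p0 <- runif(1, 0.001, 0.5)
    r <- runif(1, 1.05, 4)
    g <- generations_to_fixation(p0, r)
    traj <- project_frequency(p0, r, g)
    expect_equal(traj[g + 1], 1)
    if (g > 0) expect_lt(traj[g], 1)
  }
})

test_that("a compliant territory passes every design rule", {
  sites <- compliant_territory(12)
  genotypes <- data.frame(record_id = paste0(sites$site_id, "-G"),
                          site_id = sites$site_id,
                          species = "Aedes albopictus", marker_id = "kdr",
                          n_individuals = 60L, n_hom_resistant = 0L,
                          n_het = 0L, n_hom_susceptible = 60L)
  rep <- validate_design(sites, genotypes, as_of = as.Date("2026-09-01"))
  expect_true(all(rep$passed))
  expect_true("territory_min_sites" %in% rep$rule_id)
  expect_true("genotype_sample_size" %in% rep$rule_id)
})

test_that("each design shortfall is reported with observed vs required", {
  sites <- compliant_territory(9)  # one site short of ten
  rep <- validate_design(sites, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "territory_min_sites", ]
  expect_false(r$passed); expect_equal(r$observed, 9); expect_equal(r$required, 10)

  # 9 breeding sites: count rule fails with observed 9
  s <- compliant_territory(10)
  bs <- unpack_coords(s$breeding_site_coords[1])[1:9, ]
  s$breeding_site_coords[1] <- pack_coords(bs)
  rep <- validate_design(s, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "breeding_site_count" & rep$scope == "s01", ]
  expect_false(r$passed); expect_equal(r$observed, 9)

  # two breeding points 0.00036 degrees apart (~40 m): spacing rule fails
  s <- compliant_territory(10)
  near <- rbind(c(45, 5), c(45.00036, 5),
                cbind(45.01 + 0.002 * (0:7), 5))
  colnames(near) <- c("lat", "lon")
  s$breeding_site_coords[1] <- pack_coords(near)
  rep <- validate_design(s, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "breeding_site_spacing" & rep$scope == "s01", ]
  expect_false(r$passed)
  expect_equal(r$observed, 40, tolerance = 0.02)

  # too few females behind an F1 colony
  s <- compliant_territory(10); s$females_collected[2] <- 20L
  rep <- validate_design(s, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "females_collected" & rep$scope == "s02", ]
  expect_false(r$passed); expect_equal(r$observed, 20)

  # stale survey
  s <- compliant_territory(10); s$last_survey_date[3] <- "2024-01-01"
  rep <- validate_design(s, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "survey_recency" & rep$scope == "s03", ]
  expect_false(r$passed)
})

test_that("missing coordinates make spacing not-assessable, not failed", {
  s <- compliant_territory(10)
  s$breeding_site_coords[1] <- ""
  rep <- validate_design(s, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "breeding_site_spacing" & rep$scope == "s01", ]
  expect_true(is.na(r$passed))
  # count rule still fails (0 observed)
  r <- rep[rep$rule_id == "breeding_site_count" & rep$scope == "s01", ]
  expect_false(r$passed)
})

test_that("genotyping below 50 individuals fails the molecular rule", {
  s <- compliant_territory(10)
  genotypes <- data.frame(record_id = "g1", site_id = "s01",
                          species = "Aedes albopictus", marker_id = "kdr",
                          n_individuals = 49L, n_hom_resistant = 0L,
                          n_het = 0L, n_hom_susceptible = 49L)
  rep <- validate_design(s, genotypes, as_of = as.Date("2026-09-01"))
  r <- rep[rep$rule_id == "genotype_sample_size" & rep$scope == "s01", ]
  expect_false(r$passed); expect_equal(r$observed, 49)
  genotypes$n_individuals <- 50L; genotypes$n_hom_susceptible <- 50L
  rep <- validate_design(s, genotypes, as_of = as.Date("2026-09-01"))
  expect_true(rep[rep$rule_id == "genotype_sample_size" & rep$scope == "s01", ]$passed)
})
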