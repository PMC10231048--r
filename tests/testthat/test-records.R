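test_that("record tables round-trip through CSV field-by-field", {
  ds <- generate_dataset(scenario_config(seed = 3, sites_per_territory = 4))
  d <- withr::local_tempdir()
  pairs <- list(
    list(ds$sites, write_sites, read_sites, "sites.csv"),
    list(ds$adult_bioassays, write_adult_bioassays, read_adult_bioassays,
         "adult.csv"),
    list(ds$larval_assays, write_larval_assays, read_larval_assays,
         "larval.csv"),
    list(ds$genotypes, write_genotypes, read_genotypes, "geno.csv"),
    list(ds$synergist_assays, write_synergist_assays, read_synergist_assays,
         "syn.csv"))
  for (p in pairs) {
    f <- file.path(d, p[[4]])
    p[[2]](p[[1]], f)
    back <- p[[3]](f)
    expect_equal(back, p[[1]], ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("sites round-trip through GeoJSON", {
  ds <- generate_dataset(scenario_config(seed = 3, sites_per_territory = 3))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_sites_geojson(ds$sites, f)
  back <- read_sites_geojson(f)
  expect_equal(back, ds$sites, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("the DC registry round-trips through YAML and rejects bad entries", {
  reg <- data.frame(species = c("Aedes albopictus", "Aedes albopictus"),
                    insecticide = c("deltamethrin", "chlorfenapyr"),
                    diagnostic_concentration = c(0.03, 100),
                    units = c("%", "ug/bottle"),
                    assay_type = c("tube", "bottle"),
                    readout_hours = c(24L, 72L),
                    source = c("a", "b"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_dc_registry(reg, f)
  back <- read_dc_registry(f)
  expect_equal(as.data.frame(back), reg, ignore_attr = TRUE)
  # chlorfenapyr-style 72 h readout is preserved
  expect_equal(back$readout_hours[back$insecticide == "chlorfenapyr"], 72L)
  writeLines(c("sp:", "  ins:", "    diagnostic_concentration: -1"), f)
  expect_error(read_dc_registry(f), "> 0")
})

test_that("the shipped registry template parses", {
  f <- system.file("extdata", "dc_registry_template.yaml", package = "psir")
  reg <- read_dc_registry(f)
  expect_gt(nrow(reg), 0)
  expect_true(all(reg$diagnostic_concentration > 0))
})

test_that("malformed CSV input names the offending row and column", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- adult_row(); df$n_dead <- "twenty"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_adult_bioassays(f), "n_dead.*row 1",
               class = "psir_parse_error")
  writeLines("a,b\n1,2", f)
  expect_error(read_adult_bioassays(f), "missing column",
               class = "psir_parse_error")
  expect_error(read_adult_bioassays(file.path(tempdir(), "nope.csv")),
               "not found", class = "psir_parse_error")
})

test_that("validation flags impossible counts with the record id", {
  rep <- validate_records(adult_row(record_id = "bad1", n_dead = 26L,
                                    n_exposed = 25L), "adult_bioassays")
  v <- rep[rep$severity == "violation", ]
  expect_equal(nrow(v), 1L)
  expect_equal(v$record_id, "bad1")
  expect_match(v$message, "n_dead")
})

test_that("F0 provenance draws a comparability warning, F1 does not", {
  s <- sites_row(generation_tested = "F0")
  rep <- validate_records(s, "sites")
  w <- rep[rep$rule == "f0_provenance", ]
  expect_equal(nrow(w), 1L)
  expect_equal(w$severity, "warning")
  expect_match(w$message, "variability")
  expect_equal(nrow(validate_records(sites_row(), "sites")), 0L)
})

test_that("an empty table yields an empty report with a warning, not an error", {
  empty <- adult_row()[0, ]
  rep <- validate_records(empty, "adult_bioassays")
  expect_equal(attr(rep, "n_records"), 0L)
  expect_equal(sum(rep$severity == "violation"), 0L)
  expect_equal(rep$rule, "empty_input")
})

test_that("unknown species-insecticide pairs are flagged against the registry", {
  reg <- structure(data.frame(species = "Aedes albopictus",
                              insecticide = "deltamethrin",
                              diagnostic_concentration = 0.03, units = "%",
                              assay_type = "tube", readout_hours = 24L,
                              source = "", stringsAsFactors = FALSE),
                   class = c("dc_registry", "data.frame"))
  rep <- validate_records(adult_row(insecticide = "malathion"),
                          "adult_bioassays", registry = reg)
  expect_true(any(rep$rule == "registry" & rep$severity == "warning"))
  rep <- validate_records(adult_row(), "adult_bioassays", registry = reg)
  expect_false(any(rep$rule == "registry"))
})

test_that("validation is total over arbitrary imperfect tables", {
  set.seed(5)
  for (i in 1:25) {
    df <- adult_row()[rep(1, 4), ]
    df$record_id <- paste0("r", 1:4)
    # random corruption
    df$n_dead <- sample(c(-5L, 0L, 50L, 200L), 4, replace = TRUE)
    df$dc_multiplier <- sample(c(1L, 3L, 5L, 10L), 4, replace = TRUE)
    df$assay_type <- sample(c("tube", "bottle", "cup"), 4, replace = TRUE)
    rep <- expect_no_error(validate_records(df, "adult_bioassays"))
    bad <- rep[rep$severity == "violation", ]
    expect_true(all(!is.na(bad$record_id)))
  }
})

test_that("larval series invariants are enforced per series", {
  ds <- generate_dataset(scenario_config(seed = 4, sites_per_territory = 1))
  tab <- ds$larval_assays
  rep <- validate_records(tab, "larval_assays")
  expect_equal(sum(rep$severity == "violation"), 0L)
  # drop the control row of one series
  rep <- validate_records(tab[tab$concentration > 0, ], "larval_assays")
  expect_true(any(rep$rule == "series_control"))
  # series with too few concentrations
  short <- tab[tab$series_id == tab$series_id[1], ][1:4, ]
  short$concentration[4] <- 0
  rep <- validate_records(short, "larval_assays")
  expect_true(any(rep$rule == "series_concentrations"))
})

test_that("coordinate packing round-trips", {
  m <- cbind(lat = c(45.1, -12.5), lon = c(5.25, 45.166667))
  expect_equal(unpack_coords(pack_coords(m)), m, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(nrow(unpack_coords("")), 0L)
})
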