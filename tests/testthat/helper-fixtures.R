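# shared fixture builders (everything generated in code, nothing on disk)

# binomial dose-response draws on an exact probit curve
make_probit_series <- function(lc50, slope = 3, n = 100, seed = NULL,
                               span = 0.8, n_conc = 5, control_rate = 0.01,
                               site_id = "pop", insecticide = "temephos") {
  conc <- lc50 * 10^seq(-span, span, length.out = n_conc)
  p <- pnorm(slope * (log10(conc) - log10(lc50)))
  if (!is.null(seed)) set.seed(seed)
  responded <- rbinom(n_conc, n, p)
  ctrl <- if (!is.null(seed)) rbinom(1, n, control_rate) else 0L
  larval_series(site_id, "Aedes aegypti", insecticide,
                concentration = conc, n_exposed = rep(n, n_conc),
                n_responded = responded,
                control_n_exposed = n, control_n_responded = ctrl)
}

# noiseless series: expected counts rounded, huge n
make_exact_series <- function(alpha, beta, conc, n = 10000,
                              site_id = "exact") {
  p <- pnorm(alpha + beta * log10(conc))
  larval_series(site_id, "Aedes aegypti", "temephos",
                concentration = conc, n_exposed = rep(n, length(conc)),
                n_responded = round(n * p),
                control_n_exposed = n, control_n_responded = 0L)
}

# a bare population classification at a given level
make_cls <- function(level, site_id = "s1", unresolved = FALSE,
                     territory_id = NULL) {
  label <- c("susceptible", "low_resistance", "moderate_resistance",
             "strong_resistance")[level + 1]
  cl <- psir:::new_classification(site_id, "Aedes albopictus", "deltamethrin",
                                  level, label, unresolved, character(0),
                                  list(), "test")
  if (!is.null(territory_id)) cl$territory_id <- territory_id
  cl
}

make_cls_list <- function(levels, territory_id = NULL) {
  lapply(seq_along(levels), function(i)
    make_cls(levels[i], site_id = sprintf("s%02d", i),
             territory_id = territory_id))
}

# a minimal valid adult bioassay row
adult_row <- function(record_id = "a1", site_id = "s1",
                      species = "Aedes albopictus",
                      insecticide = "deltamethrin", dc_multiplier = 1L,
                      n_exposed = 100L, n_dead = 99L,
                      n_control_exposed = 100L, n_control_dead = 1L,
                      readout_hours = 24L, assay_type = "tube",
                      test_date = "2026-06-01") {
  data.frame(record_id = record_id, site_id = site_id, species = species,
             insecticide = insecticide, dc_multiplier = dc_multiplier,
             n_exposed = n_exposed, n_dead = n_dead,
             n_control_exposed = n_control_exposed,
             n_control_dead = n_control_dead, readout_hours = readout_hours,
             assay_type = assay_type, test_date = test_date,
             stringsAsFactors = FALSE)
}

sites_row <- function(site_id = "s1", territory_id = "T1", latitude = 45,
                      longitude = 5, breeding_site_coords = "",
                      ovitrap_count = 12L, surveyed_area_ha = 2.5,
                      females_collected = 40L, generation_tested = "F1",
                      last_survey_date = "2026-06-01") {
  data.frame(site_id = site_id, territory_id = territory_id,
             name = paste("site", site_id), latitude = latitude,
             longitude = longitude, species_monitored = "Aedes albopictus",
             breeding_site_coords = breeding_site_coords,
             ovitrap_count = ovitrap_count, surveyed_area_ha = surveyed_area_ha,
             females_collected = females_collected,
             generation_tested = generation_tested,
             last_survey_date = last_survey_date, stringsAsFactors = FALSE)
}

# a compliant sentinel site: 10 breeding points on a ~150 m grid
compliant_site <- function(site_id, territory_id = "T1", lat = 45, lon = 5) {
  bs <- cbind(lat = lat + 0.0015 * (0:9), lon = rep(lon, 10))
  sites_row(site_id, territory_id, lat, lon,
            breeding_site_coords = pack_coords(bs))
}

compliant_territory <- function(n_sites = 12, territory_id = "T1") {
  do.call(rbind, lapply(seq_len(n_sites), function(i)
    compliant_site(sprintf("s%02d", i), territory_id,
                   lat = 45 + 0.05 * i, lon = 5)))
}

# independent RiR oracle written directly from the attribution sentences,
# not from the lookup matrix
rir_oracle <- function(levels, t1 = 0.10, t2 = 0.50) {
  q <- vapply(1:3, function(l) mean(levels >= l), numeric(1))
  rir <- 0L
  if (q[1] >= t1) rir <- max(rir, 1L)          # multiple sites at level 1
  if (q[2] > 0) rir <- max(rir, 1L)            # isolated level-2 populations
  if (q[2] >= t1) rir <- max(rir, 2L)          # multiple sites at level 2
  if (q[3] > 0) rir <- max(rir, 2L)            # first detection of level 3
  if (q[3] > t2) rir <- max(rir, 3L)           # majority of sites at level 3
  rir
}
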