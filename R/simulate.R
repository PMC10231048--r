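#' Configure a synthetic surveillance scenario
#'
#' Describes a complete surveillance campaign with known ground truth: a set
#' of territories and sentinel sites, each site carrying a true resistance
#' level 0-3, and the level-conditional parameters from which every assay
#' outcome is drawn. Defaults emulate a deltamethrin-monitoring campaign on
#' an *Aedes* vector:
#' \itemize{
#'   \item level 0 (susceptible): expected DC/5x/10x mortalities
#'     99.8/99.9/100%, no resistance alleles, larval RR 1;
#'   \item level 1 (tipping point): susceptible bioassays but resistance
#'     allele at 2% frequency — the textbook tipping-point frequency;
#'   \item level 2 (moderate): 70/90/99.5% mortalities, allele at 20%,
#'     larval RR 7;
#'   \item level 3 (strong): 40/70/90% mortalities, allele at 50%, larval
#'     RR 20.
#' }
#' Larval series use a susceptible-reference LC50 of 0.05 mg/L and a probit
#' slope of 3 per decade of concentration; control response rates default
#' to 1%.
#'
#' @param seed master seed; it fans out into per-record substreams keyed by
#'   territory, site and assay, so adding a site leaves other sites' draws
#'   unchanged.
#' @param n_territories,sites_per_territory scenario dimensions.
#' @param species,insecticide,marker_id labels used throughout the dataset.
#' @param site_levels integer vector of true levels, recycled across each
#'   territory's sites; overrides `level_weights`.
#' @param level_weights sampling weights for levels 0-3 when `site_levels`
#'   is `NULL` (default: mostly susceptible).
#' @param n_exposed mosquitoes/larvae per assay arm; the `"high-n"` preset
#'   sets 500 (near-deterministic classification), the default 100.
#' @param n_genotyped individuals genotyped per site.
#' @param control_mortality control-arm death/response rate in \[0, 1).
#' @param reference_lc50,slope larval probit truth (reference strain).
#' @param preset `"default"` or `"high-n"`.
#' @return A `psir_scenario` list, validated for internal consistency (the
#'   level-conditional parameters must actually produce the level they
#'   label, e.g. a level-0 stratum with an RR above 5 is rejected).
#' @export
scenario_config <- function(seed, n_territories = 1L, sites_per_territory = 20L,
                            species = "Aedes albopictus",
                            insecticide = "deltamethrin",
                            marker_id = "kdr-L1014F",
                            site_levels = NULL,
                            level_weights = c(0.7, 0.1, 0.1, 0.1),
                            n_exposed = if (preset == "high-n") 500L else 100L,
                            n_genotyped = 50L,
                            control_mortality = 0.01,
                            reference_lc50 = 0.05, slope = 3,
                            preset = c("default", "high-n")) {
  preset <- match.arg(preset)
  stopifnot(is_scalar_number(seed), n_territories >= 1, sites_per_territory >= 1,
            n_exposed >= 1, n_genotyped >= 1,
            control_mortality >= 0, control_mortality < 1,
            reference_lc50 > 0, slope > 0)
  level_params <- data.frame(
    level = 0:3,
    p_dc  = c(0.998, 0.995, 0.70, 0.40),
    p_5x  = c(0.999, 0.999, 0.90, 0.70),
    p_10x = c(1.000, 1.000, 0.995, 0.90),
    allele_freq = c(0, 0.02, 0.20, 0.50),
    rr = c(1, 1, 7, 20))
  # internal consistency: the stratum parameters must map back to the level
  for (i in seq_len(nrow(level_params))) {
    lp <- level_params[i, ]
    expected <- adult_resistance_level(100 * lp$p_dc, 100 * lp$p_5x,
                                       100 * lp$p_10x, lp$allele_freq > 0)
    ok_adult <- expected$level == lp$level
    rr_level <- if (lp$rr < 5) 0L else if (lp$rr <= 10) 2L else 3L
    ok_larval <- lp$level %in% c(0L, 1L) && rr_level == 0L ||
                 lp$level == rr_level
    if (!(ok_adult && ok_larval)) {
      stop_psir(sprintf("scenario_config: stratum %d parameters map to level %d (adult rule)",
                        lp$level, expected$level))
    }
  }
  if (!is.null(site_levels)) {
    site_levels <- as.integer(site_levels)
    stopifnot(all(site_levels %in% 0:3))
  } else {
    stopifnot(length(level_weights) == 4, all(level_weights >= 0),
              sum(level_weights) > 0)
  }
  structure(list(seed = as.integer(seed), n_territories = as.integer(n_territories),
                 sites_per_territory = as.integer(sites_per_territory),
                 species = species, insecticide = insecticide,
                 marker_id = marker_id, site_levels = site_levels,
                 level_weights = level_weights, n_exposed = as.integer(n_exposed),
                 n_genotyped = as.integer(n_genotyped),
                 control_mortality = control_mortality,
                 reference_lc50 = reference_lc50, slope = slope,
                 level_params = level_params, preset = preset),
            class = "psir_scenario")
}

# evaluate expr under a per-record substream seed, restoring RNG state after
with_substream <- function(seed, labels, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(substream_seed(seed, labels))
  force(expr)
}

#' Generate a synthetic surveillance dataset
#'
#' Draws a complete dataset — sentinel sites, adult DC and intensity
#' bioassays, larval dose-response series (field populations plus one
#' susceptible reference strain), genotype samples and synergist assays —
#' from a [scenario_config()], together with a ground-truth table never
#' consumed by the analysis pipeline. All outcomes are binomial draws from
#' the level-conditional truth: treated-arm mortality combines the level's
#' insecticidal kill probability with the control death rate
#' (\eqn{p = 1 - (1 - p_{kill})(1 - c)}), larval responses follow the
#' probit curve at the level's true LC50, genotypes are Hardy-Weinberg
#' multinomial draws at the level's allele frequency. The same seed always
#' reproduces the same dataset byte-for-byte.
#'
#' @param config a `psir_scenario`.
#' @return A `psir_dataset` list: `sites`, `adult_bioassays`,
#'   `larval_assays`, `synergist_assays`, `genotypes`, `ground_truth`
#'   (data.frames in the package's CSV schemas) and `config`.
#' @examples
#' ds <- generate_dataset(scenario_config(seed = 7, sites_per_territory = 4))
#' table(ds$ground_truth$true_level)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "psir_scenario"))
  cfg <- config
  lp <- cfg$level_params
  ctrl <- cfg$control_mortality
  obs_p <- function(p_kill) 1 - (1 - p_kill) * (1 - ctrl)

  sites <- list(); adults <- list(); larvae <- list(); genos <- list()
  syner <- list(); truth <- list()

  # susceptible reference strain larval series (one per dataset)
  ref_conc <- cfg$reference_lc50 * 10^seq(-0.8, 0.8, length.out = 5)
  ref_resp <- with_substream(cfg$seed, c(0, 0, 1), {
    p <- stats::pnorm(cfg$slope * (log10(ref_conc) - log10(cfg$reference_lc50)))
    stats::rbinom(5, cfg$n_exposed, obs_p(p))
  })
  ref_ctrl <- with_substream(cfg$seed, c(0, 0, 2),
                             stats::rbinom(1, cfg$n_exposed, ctrl))
  larvae[[1]] <- data.frame(
    series_id = "REF-1", site_id = "REF", species = cfg$species,
    insecticide = cfg$insecticide, endpoint = "mortality", role = "reference",
    concentration = c(ref_conc, 0), conc_units = "mg/L",
    n_exposed = rep(cfg$n_exposed, 6L),
    n_responded = c(ref_resp, ref_ctrl), stringsAsFactors = FALSE)

  for (t in seq_len(cfg$n_territories)) {
    tid <- sprintf("T%02d", t)
    for (s in seq_len(cfg$sites_per_territory)) {
      sid <- sprintf("%s-S%03d", tid, s)
      level <- if (!is.null(cfg$site_levels)) {
        cfg$site_levels[((s - 1L) %% length(cfg$site_levels)) + 1L]
      } else {
        with_substream(cfg$seed, c(t, s, 10),
                       sample(0:3, 1, prob = cfg$level_weights))
      }
      pars <- lp[lp$level == level, ]

      lat <- 44 + t * 0.5 + (s %% 10) * 0.02
      lon <- 4 + t * 0.5 + (s %/% 10) * 0.02
      bs <- cbind(lat = lat + 0.0015 * (0:9), lon = rep(lon, 10))
      sites[[length(sites) + 1L]] <- data.frame(
        site_id = sid, territory_id = tid, name = paste("site", sid),
        latitude = lat, longitude = lon,
        species_monitored = cfg$species,
        breeding_site_coords = pack_coords(bs),
        ovitrap_count = 12L, surveyed_area_ha = 2.5,
        females_collected = 40L, generation_tested = "F1",
        last_survey_date = "2026-06-01", stringsAsFactors = FALSE)

      # adult bioassays at 1x, 5x, 10x DC
      p_arm <- c(pars$p_dc, pars$p_5x, pars$p_10x)
      mult <- c(1L, 5L, 10L)
      for (k in 1:3) {
        draws <- with_substream(cfg$seed, c(t, s, 20 + k), {
          c(stats::rbinom(1, cfg$n_exposed, obs_p(p_arm[k])),
            stats::rbinom(1, cfg$n_exposed, ctrl))
        })
        adults[[length(adults) + 1L]] <- data.frame(
          record_id = sprintf("%s-A%dx", sid, mult[k]), site_id = sid,
          species = cfg$species, insecticide = cfg$insecticide,
          dc_multiplier = mult[k], n_exposed = cfg$n_exposed,
          n_dead = draws[1], n_control_exposed = cfg$n_exposed,
          n_control_dead = draws[2], readout_hours = 24L,
          assay_type = "tube", test_date = "2026-06-01",
          stringsAsFactors = FALSE)
      }

      # larval dose-response at the level's true LC50
      true_lc50 <- cfg$reference_lc50 * pars$rr
      conc <- true_lc50 * 10^seq(-0.8, 0.8, length.out = 5)
      resp <- with_substream(cfg$seed, c(t, s, 30), {
        p <- stats::pnorm(cfg$slope * (log10(conc) - log10(true_lc50)))
        stats::rbinom(5, cfg$n_exposed, obs_p(p))
      })
      lctrl <- with_substream(cfg$seed, c(t, s, 31),
                              stats::rbinom(1, cfg$n_exposed, ctrl))
      larvae[[length(larvae) + 1L]] <- data.frame(
        series_id = paste0(sid, "-L"), site_id = sid, species = cfg$species,
        insecticide = cfg$insecticide, endpoint = "mortality", role = "test",
        concentration = c(conc, 0), conc_units = "mg/L",
        n_exposed = rep(cfg$n_exposed, 6L), n_responded = c(resp, lctrl),
        stringsAsFactors = FALSE)

      # genotypes: Hardy-Weinberg multinomial at the level's allele frequency
      g <- with_substream(cfg$seed, c(t, s, 40), {
        p <- pars$allele_freq
        stats::rmultinom(1, cfg$n_genotyped, c(p^2, 2 * p * (1 - p), (1 - p)^2))
      })
      genos[[length(genos) + 1L]] <- data.frame(
        record_id = paste0(sid, "-G"), site_id = sid, species = cfg$species,
        marker_id = cfg$marker_id, n_individuals = cfg$n_genotyped,
        n_hom_resistant = g[1], n_het = g[2], n_hom_susceptible = g[3],
        stringsAsFactors = FALSE)

      # synergist assay for resistant strata (metabolic component at level 2)
      if (level >= 2) {
        p_comb <- if (level == 2) 0.92 else 0.55
        draws <- with_substream(cfg$seed, c(t, s, 50), {
          c(stats::rbinom(1, cfg$n_exposed, obs_p(pars$p_dc)),
            stats::rbinom(1, cfg$n_exposed, obs_p(p_comb)))
        })
        syner[[length(syner) + 1L]] <- data.frame(
          record_id = paste0(sid, "-SY"), site_id = sid, species = cfg$species,
          insecticide = cfg$insecticide, synergist = "PBO",
          mortality_alone = 100 * draws[1] / cfg$n_exposed,
          mortality_combined = 100 * draws[2] / cfg$n_exposed,
          n_exposed_alone = cfg$n_exposed, n_exposed_combined = cfg$n_exposed,
          stringsAsFactors = FALSE)
      }

      truth[[length(truth) + 1L]] <- data.frame(
        site_id = sid, territory_id = tid, true_level = level,
        true_allele_freq = pars$allele_freq, true_lc50 = true_lc50,
        true_rr = pars$rr, stringsAsFactors = FALSE)
    }
  }

  empty_syn <- data.frame(record_id = character(), site_id = character(),
                          species = character(), insecticide = character(),
                          synergist = character(), mortality_alone = numeric(),
                          mortality_combined = numeric(),
                          n_exposed_alone = integer(),
                          n_exposed_combined = integer())
  structure(list(
    sites = do.call(rbind, sites),
    adult_bioassays = do.call(rbind, adults),
    larval_assays = do.call(rbind, larvae),
    synergist_assays = if (length(syner)) do.call(rbind, syner) else empty_syn,
    genotypes = do.call(rbind, genos),
    ground_truth = do.call(rbind, truth),
    config = cfg), class = "psir_dataset")
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' Emits `sites.csv`, `adult_bioassays.csv`, `larval_assays.csv`,
#' `synergist_assays.csv`, `genotypes.csv` and `ground_truth.csv` (the last
#' is never read by the pipeline), plus `sites.geojson` and a placeholder
#' DC registry `dc_registry.yaml` for the scenario's species x insecticide.
#'
#' @param dataset a `psir_dataset`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "psir_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sites(dataset$sites, file.path(dir, "sites.csv"))
  write_adult_bioassays(dataset$adult_bioassays, file.path(dir, "adult_bioassays.csv"))
  write_larval_assays(dataset$larval_assays, file.path(dir, "larval_assays.csv"))
  write_synergist_assays(dataset$synergist_assays, file.path(dir, "synergist_assays.csv"))
  write_genotypes(dataset$genotypes, file.path(dir, "genotypes.csv"))
  utils::write.csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  write_sites_geojson(dataset$sites, file.path(dir, "sites.geojson"))
  reg <- data.frame(species = dataset$config$species,
                    insecticide = dataset$config$insecticide,
                    diagnostic_concentration = 0.03, units = "%",
                    assay_type = "tube", readout_hours = 24L,
                    source = "synthetic placeholder", stringsAsFactors = FALSE)
  write_dc_registry(reg, file.path(dir, "dc_registry.yaml"))
  invisible(dir)
}

#' @export
print.psir_scenario <- function(x, ...) {
  cat(sprintf("<psir_scenario> seed %d: %d territories x %d sites, n = %d/arm (%s)\n",
              x$seed, x$n_territories, x$sites_per_territory, x$n_exposed,
              x$preset))
  invisible(x)
}

#' @export
print.psir_dataset <- function(x, ...) {
  cat(sprintf("<psir_dataset> %d sites, %d adult assays, %d larval rows, %d genotype samples\n",
              nrow(x$sites), nrow(x$adult_bioassays), nrow(x$larval_assays),
              nrow(x$genotypes)))
  invisible(x)
}
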