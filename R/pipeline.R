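#' Analysis configuration
#'
#' Collects every tunable threshold of the surveillance workflow with its
#' guideline default. The stratification bin cut points in particular are
#' explicitly adjustable per vector species and territory configuration;
#' every report echoes the effective values so assessments stay auditable.
#'
#' @param susceptible_threshold percent mortality at/above which a DC test
#'   calls a population susceptible (default 98).
#' @param suspected_threshold percent mortality below `susceptible_threshold`
#'   but at/above which resistance is only "suspected" and should be
#'   confirmed (default 90).
#' @param rr_thresholds larval RR50 cut points (default `c(5, 10)`).
#' @param bin_thresholds stratification proportions (default `c(0.10, 0.50)`).
#' @param synergist_full,synergist_delta,synergist_eligibility synergist
#'   rule constants (default 98 percent, 10 points, 90 percent).
#' @return A `psir_config` list.
#' @export
psir_config <- function(susceptible_threshold = 98, suspected_threshold = 90,
                        rr_thresholds = c(5, 10),
                        bin_thresholds = c(0.10, 0.50),
                        synergist_full = 98, synergist_delta = 10,
                        synergist_eligibility = 90) {
  stopifnot(suspected_threshold < susceptible_threshold,
            susceptible_threshold <= 100, suspected_threshold >= 0,
            length(rr_thresholds) == 2, rr_thresholds[1] < rr_thresholds[2],
            rr_thresholds[1] > 0,
            length(bin_thresholds) == 2, bin_thresholds[1] < bin_thresholds[2],
            bin_thresholds[1] > 0, bin_thresholds[2] < 1,
            synergist_full <= 100, synergist_delta >= 0,
            synergist_eligibility <= 100)
  structure(list(susceptible_threshold = susceptible_threshold,
                 suspected_threshold = suspected_threshold,
                 rr_thresholds = rr_thresholds,
                 bin_thresholds = bin_thresholds,
                 synergist_full = synergist_full,
                 synergist_delta = synergist_delta,
                 synergist_eligibility = synergist_eligibility),
            class = "psir_config")
}

#' Load a configuration from YAML
#'
#' Top-level keys mirror the arguments of [psir_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A `psir_config`.
#' @export
read_psir_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(psir_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_psir("read_psir_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(psir_config, raw)
}

sum_arm <- function(df) {
  list(n_exposed = sum(df$n_exposed), n_dead = sum(df$n_dead),
       n_control_exposed = sum(df$n_control_exposed),
       n_control_dead = sum(df$n_control_dead))
}

#' Run the full surveillance analysis pipeline
#'
#' Executes the whole chain on a directory (or explicit file paths) of
#' record tables: validation, per-assay mortality statistics, larval
#' log-probit fits and resistance ratios, population classification per
#' (site, species, insecticide), territory stratification into RiR classes
#' and the matched recommendations. Adult replicate tests of the same arm
#' are pooled by summing counts before correction.
#'
#' @param input_dir directory containing `sites.csv`, `adult_bioassays.csv`
#'   and optionally `larval_assays.csv`, `synergist_assays.csv`,
#'   `genotypes.csv`, `dc_registry.yaml`. Individual paths can be
#'   overridden via the `paths` argument.
#' @param output_dir where reports are written (created if needed): one
#'   JSON report per territory, `classifications.csv`,
#'   `territory_summary.csv`, and `probit_fits.csv` when larval data are
#'   present. `NULL` skips writing.
#' @param config a [psir_config()].
#' @param paths named list overriding individual input paths.
#' @param require_registry when `TRUE` (default if a registry file is
#'   present), every tested species x insecticide pair must have a
#'   diagnostic-concentration registry entry; a missing pair is an error.
#' @param generated_at metadata timestamp recorded in reports; fix it to a
#'   constant to make reports byte-reproducible.
#' @return Invisibly, a list with `classifications` (list of
#'   `population_classification`), `assessments` (list of
#'   `territory_assessment`), `fits`, `validation` (per-table reports) and
#'   `output_files`.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL, config = psir_config(),
                         paths = list(), require_registry = NULL,
                         generated_at = format(Sys.time(), tz = "UTC")) {
  p <- function(name, file) paths[[name]] %||% file.path(input_dir, file)
  f_sites <- p("sites", "sites.csv")
  f_adult <- p("adult_bioassays", "adult_bioassays.csv")
  f_larval <- p("larval_assays", "larval_assays.csv")
  f_syn <- p("synergist_assays", "synergist_assays.csv")
  f_geno <- p("genotypes", "genotypes.csv")
  f_reg <- p("registry", "dc_registry.yaml")

  sites <- read_sites(f_sites)
  adults <- read_adult_bioassays(f_adult)
  larval <- if (file.exists(f_larval)) read_larval_assays(f_larval) else NULL
  synergists <- if (file.exists(f_syn)) read_synergist_assays(f_syn) else NULL
  genotypes <- if (file.exists(f_geno)) read_genotypes(f_geno) else NULL
  registry <- if (file.exists(f_reg)) read_dc_registry(f_reg) else NULL
  if (is.null(require_registry)) require_registry <- !is.null(registry)

  validation <- list(
    sites = validate_records(sites, "sites"),
    adult_bioassays = validate_records(adults, "adult_bioassays", registry))
  if (!is.null(larval)) validation$larval_assays <- validate_records(larval, "larval_assays")
  if (!is.null(synergists)) validation$synergist_assays <- validate_records(synergists, "synergist_assays")
  if (!is.null(genotypes)) validation$genotypes <- validate_records(genotypes, "genotypes")
  for (tab in names(validation)) {
    v <- validation[[tab]]
    bad <- v[v$severity == "violation", , drop = FALSE]
    if (nrow(bad)) {
      stop_psir(sprintf("run_pipeline: validation failed for %s: %s (record %s)",
                        tab, bad$message[1], bad$record_id[1]))
    }
  }
  if (require_registry) {
    pairs <- unique(adults[c("species", "insecticide")])
    for (i in seq_len(nrow(pairs))) {
      hit <- registry$species == pairs$species[i] &
             registry$insecticide == pairs$insecticide[i]
      if (!any(hit)) {
        stop_psir(sprintf("run_pipeline: no diagnostic-concentration registry entry for %s / %s",
                          pairs$species[i], pairs$insecticide[i]))
      }
    }
  }

  # larval fits: reference strains first, then test populations
  fits <- list(); ratios <- list()
  if (!is.null(larval) && nrow(larval)) {
    series <- split_larval_series(larval)
    roles <- vapply(series, function(s) attr(s, "role"), "")
    refs <- series[roles == "reference"]
    ref_fit_for <- function(s) {
      for (r in refs) {
        if (identical(r$insecticide, s$insecticide) &&
            identical(r$endpoint, s$endpoint)) return(r)
      }
      NULL
    }
    ref_fits <- lapply(refs, fit_probit)
    fits <- ref_fits
    for (nm in names(series)[roles == "test"]) {
      s <- series[[nm]]
      fit <- fit_probit(s)
      fits[[nm]] <- fit
      r <- ref_fit_for(s)
      if (is.null(r)) {
        stop_psir(sprintf("run_pipeline: no susceptible reference series for %s / %s",
                          s$insecticide, s$endpoint))
      }
      rfit <- ref_fits[[which(vapply(refs, identical, TRUE, r))[1]]]
      if (fit$converged && rfit$converged) {
        ratios[[nm]] <- resistance_ratio(fit, rfit)
      }
    }
  }

  # population classification per (site, species, insecticide)
  classifications <- list()
  keys <- unique(adults[c("site_id", "species", "insecticide")])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- adults[adults$site_id == k$site_id & adults$species == k$species &
                    adults$insecticide == k$insecticide, , drop = FALSE]
    arm <- function(mult) {
      a <- sub[sub$dc_multiplier == mult, , drop = FALSE]
      if (!nrow(a)) return(NULL)
      do.call(corrected_mortality, unname(sum_arm(a)[
        c("n_dead", "n_exposed", "n_control_dead", "n_control_exposed")]))
    }
    markers <- list()
    if (!is.null(genotypes)) {
      g <- genotypes[genotypes$site_id == k$site_id & genotypes$species == k$species, ,
                     drop = FALSE]
      markers <- lapply(seq_len(nrow(g)), function(j) allele_frequency(g[j, ]))
    }
    syn_out <- NULL
    if (!is.null(synergists)) {
      sy <- synergists[synergists$site_id == k$site_id &
                         synergists$insecticide == k$insecticide, , drop = FALSE]
      if (nrow(sy)) {
        dc_res <- arm(1L)
        if (!is.null(dc_res) && dc_res$valid) {
          syn_out <- interpret_synergist(
            sy$mortality_alone[1], sy$mortality_combined[1],
            dc_res$corrected_mortality,
            full_threshold = config$synergist_full,
            delta_threshold = config$synergist_delta,
            eligibility_threshold = config$synergist_eligibility)
        }
      }
    }
    adult_cl <- classify_adult(
      dc = arm(1L), dc5x = arm(5L), dc10x = arm(10L), markers = markers,
      synergist = syn_out, site_id = k$site_id, species = k$species,
      insecticide = k$insecticide,
      susceptible_threshold = config$susceptible_threshold,
      suspected_threshold = config$suspected_threshold)

    larval_cl <- NULL
    key_ratio <- NULL
    for (r in ratios) {
      if (identical(r$test_fit$site_id, k$site_id) &&
          identical(r$test_fit$insecticide, k$insecticide)) key_ratio <- r
    }
    if (!is.null(key_ratio)) {
      larval_cl <- classify_larval(key_ratio, markers = markers,
                                   site_id = k$site_id, species = k$species,
                                   insecticide = k$insecticide,
                                   rr_thresholds = config$rr_thresholds)
    }
    cl <- merge_evidence(adult_cl, larval_cl)
    cl$territory_id <- sites$territory_id[match(k$site_id, sites$site_id)]
    classifications[[length(classifications) + 1L]] <- cl
  }

  # stratification per (territory, species, insecticide)
  assessments <- list()
  meta <- data.frame(
    territory_id = vapply(classifications, function(cl) cl$territory_id %||% NA_character_, ""),
    species = vapply(classifications, `[[`, "", "species"),
    insecticide = vapply(classifications, `[[`, "", "insecticide"),
    stringsAsFactors = FALSE)
  groups <- unique(meta)
  groups <- groups[!is.na(groups$territory_id), , drop = FALSE]
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sel <- meta$territory_id == g$territory_id & meta$species == g$species &
           meta$insecticide == g$insecticide
    a <- withCallingHandlers(
      stratify(classifications[sel], territory_id = g$territory_id,
               bin_thresholds = config$bin_thresholds),
      warning = function(w) invokeRestart("muffleWarning"))
    assessments[[length(assessments) + 1L]] <- a
  }

  output_files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    cls_tab <- classification_table(classifications)
    cls_tab$territory_id <- meta$territory_id
    f <- file.path(output_dir, "classifications.csv")
    utils::write.csv(cls_tab, f, row.names = FALSE, fileEncoding = "UTF-8")
    output_files <- c(output_files, f)

    summ <- do.call(rbind, lapply(assessments, function(a) data.frame(
      territory_id = a$territory_id, species = a$species,
      insecticide = a$insecticide, rir = a$rir,
      n_sites_assessed = a$n_sites_assessed,
      n_sites_excluded = a$n_sites_excluded,
      prop_ge1 = a$proportion_at_or_above[1],
      prop_ge2 = a$proportion_at_or_above[2],
      prop_ge3 = a$proportion_at_or_above[3],
      driver_level = a$driver_level, stringsAsFactors = FALSE)))
    f <- file.path(output_dir, "territory_summary.csv")
    utils::write.csv(summ, f, row.names = FALSE, fileEncoding = "UTF-8")
    output_files <- c(output_files, f)

    if (length(fits)) {
      f <- file.path(output_dir, "probit_fits.csv")
      utils::write.csv(probit_fits_table(fits), f, row.names = FALSE,
                       fileEncoding = "UTF-8")
      output_files <- c(output_files, f)
    }

    for (a in assessments) {
      f <- file.path(output_dir, sprintf("territory_%s_%s.json", a$territory_id,
                                         gsub("[^A-Za-z0-9]+", "_", a$insecticide)))
      report <- list(
        metadata = list(generated_at = generated_at, package = "psir",
                        thresholds = unclass(config)),
        territory_id = a$territory_id, species = a$species,
        insecticide = a$insecticide, rir = a$rir,
        n_sites_assessed = a$n_sites_assessed,
        n_sites_excluded = a$n_sites_excluded,
        proportion_at_or_above = as.list(a$proportion_at_or_above),
        driver_level = a$driver_level,
        site_levels = as.list(a$site_levels),
        recommendations = unclass(a$recommendations))
      jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
      output_files <- c(output_files, f)
    }
  }

  invisible(list(classifications = classifications, assessments = assessments,
                 fits = fits, ratios = ratios, validation = validation,
                 output_files = output_files))
}
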