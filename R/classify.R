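#' Resistance-allele frequency from genotype counts
#'
#' For a codominant diallelic marker scored in `n` diploid individuals
#' (`2n` chromosomes), the estimated resistance-allele frequency is
#' \deqn{\hat p = (2 n_{RR} + n_{RS}) / (2n)}{p = (2*hom_res + het)/(2n)}
#'
#' @param sample a one-row genotypes record (or list) with fields
#'   `n_individuals`, `n_hom_resistant`, `n_het`, `n_hom_susceptible` and
#'   optionally `marker_id`.
#' @return A `marker_evidence` list: `marker_id`, `estimated_frequency`,
#'   `n_chromosomes`.
#' @examples
#' allele_frequency(list(marker_id = "kdr-L1014F", n_individuals = 50,
#'                       n_hom_resistant = 0, n_het = 1, n_hom_susceptible = 49))
#' @export
allele_frequency <- function(sample) {
  sample <- as.list(sample)
  n <- as.integer(sample$n_individuals)
  counts <- c(as.integer(sample$n_hom_resistant), as.integer(sample$n_het),
              as.integer(sample$n_hom_susceptible))
  if (is.na(n) || n <= 0) {
    stop_psir("allele_frequency: n_individuals must be positive",
              class = "psir_undefined_rate")
  }
  if (any(counts < 0) || sum(counts) != n) {
    stop_psir("allele_frequency: genotype counts must be >= 0 and sum to n_individuals")
  }
  structure(list(marker_id = as.character(sample$marker_id %||% NA_character_),
                 estimated_frequency = (2 * counts[1] + counts[2]) / (2 * n),
                 n_chromosomes = 2L * n),
            class = "marker_evidence")
}

#' Vectorised adult resistance-level rule
#'
#' The decision cascade behind [classify_adult()], vectorised over corrected
#' mortalities so the whole rule surface can be swept. Inputs are percent
#' mortalities at the diagnostic concentration (DC) and at 5x / 10x DC
#' intensity tests (`NA` when not performed):
#' \itemize{
#'   \item DC >= 98: level 0 (susceptible), or level 1
#'     (`susceptible_with_alleles`) when resistance markers were detected;
#'   \item DC < 98 and 10x < 98: level 3 (`strong_resistance`);
#'   \item DC < 98, 5x < 98, 10x >= 98: level 2 (`moderate_resistance`);
#'   \item DC < 98 and 5x >= 98: level 1 (`low_resistance`) — resistance
#'     detectable at the DC but already broken at 5x;
#'   \item DC < 98 with the needed intensity arm(s) missing: `unresolved`,
#'     with a provisional level no higher than the available evidence
#'     supports (level 2 when 5x < 98 is known, else level 1) and a
#'     `confirm_with_intensity_tests` flag.
#' }
#' DC mortality in \[90, 98) additionally raises a
#' `resistance_suspected_confirm` flag (the WHO "suspected resistance" band:
#' repeat or confirm before acting).
#'
#' @param dc,m5,m10 numeric vectors of corrected percent mortalities
#'   (`m5`, `m10` may be `NA`).
#' @param markers_present logical vector: any resistance-marker frequency
#'   > 0 in the population.
#' @param susceptible_threshold,suspected_threshold percent thresholds
#'   (defaults 98 and 90).
#' @return data.frame with columns `level` (integer 0-3), `status_label`,
#'   `unresolved`, `suspected`.
#' @export
adult_resistance_level <- function(dc, m5 = NA_real_, m10 = NA_real_,
                                   markers_present = FALSE,
                                   susceptible_threshold = 98,
                                   suspected_threshold = 90) {
  n <- max(length(dc), length(m5), length(m10), length(markers_present))
  dc <- rep_len(as.numeric(dc), n)
  m5 <- rep_len(as.numeric(m5), n)
  m10 <- rep_len(as.numeric(m10), n)
  markers_present <- rep_len(as.logical(markers_present), n)
  S <- susceptible_threshold

  level <- integer(n)
  label <- character(n)
  unresolved <- logical(n)

  susceptible <- dc >= S
  level[susceptible] <- ifelse(markers_present[susceptible], 1L, 0L)
  label[susceptible] <- ifelse(markers_present[susceptible],
                               "susceptible_with_alleles", "susceptible")

  res <- !susceptible
  strong <- res & !is.na(m10) & m10 < S
  level[strong] <- 3L; label[strong] <- "strong_resistance"

  moderate <- res & !strong & !is.na(m5) & m5 < S & !is.na(m10) & m10 >= S
  level[moderate] <- 2L; label[moderate] <- "moderate_resistance"

  low <- res & !strong & !moderate & !is.na(m5) & m5 >= S
  level[low] <- 1L; label[low] <- "low_resistance"

  open <- res & !strong & !moderate & !low
  # 5x < 98 known but 10x missing: at least moderate; otherwise provisional low
  open2 <- open & !is.na(m5) & m5 < S
  level[open2] <- 2L; label[open2] <- "moderate_resistance"
  open1 <- open & !open2
  level[open1] <- 1L; label[open1] <- "low_resistance"
  unresolved[open] <- TRUE

  data.frame(level = level, status_label = label, unresolved = unresolved,
             suspected = res & dc >= suspected_threshold,
             stringsAsFactors = FALSE)
}

new_classification <- function(site_id, species, insecticide, level, label,
                               unresolved, flags, evidence, route) {
  structure(list(site_id = site_id, species = species,
                 insecticide = insecticide, level = as.integer(level),
                 status_label = label, unresolved = unresolved,
                 flags = flags, evidence = evidence, route = route),
            class = "population_classification")
}

#' Classify an adult population from DC and intensity bioassays
#'
#' Assigns the population-level resistance status 0-3 for one (site,
#' species, insecticide) from the diagnostic-concentration test, optional
#' 5x / 10x intensity tests, optional resistance-marker frequencies, and an
#' optional synergist-test outcome (recorded as evidence; it does not move
#' the level). The decision rules are those of [adult_resistance_level()].
#'
#' @param dc a [corrected_mortality()] result (or a bare corrected percent)
#'   for the 1x diagnostic-concentration test; an invalid test (control
#'   mortality > 20%) refuses classification.
#' @param dc5x,dc10x optional intensity-test results at 5x and 10x DC.
#' @param markers optional list of `marker_evidence` ([allele_frequency()]).
#' @param synergist optional `synergist_outcome` ([interpret_synergist()]).
#' @param site_id,species,insecticide identity carried into the result.
#' @param susceptible_threshold,suspected_threshold see
#'   [adult_resistance_level()].
#' @return A `population_classification`: `level` (0-3), `status_label`,
#'   `unresolved`, `flags` (character vector; may include
#'   `confirm_with_intensity_tests` and `resistance_suspected_confirm`),
#'   and an `evidence` list retaining every input quantity.
#' @examples
#' classify_adult(dc = 70, dc5x = 80, dc10x = 99)   # level 2
#' classify_adult(dc = 99, markers = list(allele_frequency(list(
#'   marker_id = "kdr", n_individuals = 50, n_hom_resistant = 0,
#'   n_het = 2, n_hom_susceptible = 48))))          # level 1, tipping point
#' @export
classify_adult <- function(dc, dc5x = NULL, dc10x = NULL, markers = list(),
                           synergist = NULL, site_id = NA_character_,
                           species = NA_character_, insecticide = NA_character_,
                           susceptible_threshold = 98, suspected_threshold = 90) {
  get_m <- function(x, arm) {
    if (is.null(x)) return(NA_real_)
    if (inherits(x, "mortality_result")) {
      if (!x$valid) {
        stop_psir(sprintf(
          "classify_adult: %s test invalid (control mortality %.1f%% > 20%%); classification refused",
          arm, x$control_mortality))
      }
      return(x$corrected_mortality)
    }
    as.numeric(x)
  }
  m_dc <- get_m(dc, "DC")
  if (is.na(m_dc)) stop_psir("classify_adult: a DC-test result is required")
  m5 <- get_m(dc5x, "5x DC")
  m10 <- get_m(dc10x, "10x DC")
  freqs <- vapply(markers, function(m) m$estimated_frequency, numeric(1))
  markers_present <- length(freqs) > 0 && any(freqs > 0)

  r <- adult_resistance_level(m_dc, m5, m10, markers_present,
                              susceptible_threshold, suspected_threshold)
  flags <- character(0)
  if (r$unresolved) flags <- c(flags, "confirm_with_intensity_tests")
  if (r$suspected) flags <- c(flags, "resistance_suspected_confirm")

  new_classification(
    site_id, species, insecticide, r$level, r$status_label, r$unresolved,
    flags,
    evidence = list(route = "adult",
                    dc_mortality = m_dc, dc5x_mortality = m5,
                    dc10x_mortality = m10,
                    marker_frequencies = as.list(stats::setNames(
                      freqs, vapply(markers, `[[`, "", "marker_id"))),
                    synergist = if (!is.null(synergist))
                      list(category = synergist$category,
                           delta_mortality = synergist$delta_mortality)),
    route = "adult")
}

#' Classify a population from a larval resistance ratio
#'
#' RR50 thresholds: below 5 the population is susceptible (level 0, or 1 if
#' resistance markers were detected); between 5 and 10 inclusive, moderate
#' resistance (level 2); above 10, strong resistance (level 3).
#'
#' @param rr a [resistance_ratio()] (or bare positive number).
#' @param markers optional list of `marker_evidence`.
#' @param site_id,species,insecticide identity carried into the result.
#' @param rr_thresholds length-2 numeric: the susceptible/moderate and
#'   moderate/strong cut points (default `c(5, 10)`; boundaries belong to
#'   the moderate class).
#' @return A `population_classification` (always resolved).
#' @export
classify_larval <- function(rr, markers = list(), site_id = NA_character_,
                            species = NA_character_,
                            insecticide = NA_character_,
                            rr_thresholds = c(5, 10)) {
  if (inherits(rr, "resistance_ratio")) {
    site_id <- if (is.na(site_id)) rr$test_fit$site_id else site_id
    species <- if (is.na(species)) rr$test_fit$species else species
    insecticide <- if (is.na(insecticide)) rr$test_fit$insecticide else insecticide
    rr50 <- rr$rr50
  } else {
    rr50 <- as.numeric(rr)
  }
  if (!is_scalar_number(rr50) || rr50 <= 0) {
    stop_psir("classify_larval: RR50 must be a positive number (converged fits required)")
  }
  freqs <- vapply(markers, function(m) m$estimated_frequency, numeric(1))
  markers_present <- length(freqs) > 0 && any(freqs > 0)

  if (rr50 < rr_thresholds[1]) {
    level <- if (markers_present) 1L else 0L
    label <- if (markers_present) "susceptible_with_alleles" else "susceptible"
  } else if (rr50 <= rr_thresholds[2]) {
    level <- 2L; label <- "moderate_resistance"
  } else {
    level <- 3L; label <- "strong_resistance"
  }
  new_classification(
    site_id, species, insecticide, level, label, unresolved = FALSE,
    flags = character(0),
    evidence = list(route = "larval", rr50 = rr50,
                    marker_frequencies = as.list(stats::setNames(
                      freqs, vapply(markers, `[[`, "", "marker_id")))),
    route = "larval")
}

#' Merge adult and larval classifications for one population
#'
#' Adult DC/intensity testing and larval RR50 are alternative routes to the
#' same 0-3 scale; when both are available the population is assigned the
#' maximum level, and the result is definitive as soon as the maximum is
#' backed by resolved evidence (a provisional, unresolved adult call is
#' superseded by a resolved larval call at or above it, and vice versa).
#'
#' @param adult,larval `population_classification` objects (either may be
#'   `NULL`, not both).
#' @return A merged `population_classification` with concatenated evidence.
#' @export
merge_evidence <- function(adult = NULL, larval = NULL) {
  if (is.null(adult) && is.null(larval)) {
    stop_psir("merge_evidence: at least one classification required")
  }
  if (is.null(adult)) return(larval)
  if (is.null(larval)) return(adult)
  lev <- max(adult$level, larval$level)
  from <- if (larval$level >= adult$level) larval else adult
  resolved_at_max <- (!adult$unresolved && adult$level == lev) ||
                     (!larval$unresolved && larval$level == lev)
  new_classification(
    adult$site_id %||% larval$site_id, adult$species, adult$insecticide,
    lev, from$status_label, unresolved = !resolved_at_max,
    flags = unique(c(
      if (resolved_at_max) setdiff(adult$flags, "confirm_with_intensity_tests")
      else adult$flags,
      larval$flags)),
    evidence = list(adult = adult$evidence, larval = larval$evidence),
    route = "merged")
}

#' @export
print.population_classification <- function(x, ...) {
  cat(sprintf("<population_classification> %s / %s / %s\n",
              x$site_id, x$species, x$insecticide))
  cat(sprintf("  level %d (%s)%s%s\n", x$level, x$status_label,
              if (x$unresolved) " [UNRESOLVED]" else "",
              if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Flatten classifications to a table
#'
#' @param classifications list of `population_classification` objects.
#' @return data.frame, one row per classification, with the evidence list
#'   serialised to a JSON column.
#' @export
classification_table <- function(classifications) {
  do.call(rbind, lapply(classifications, function(cl) data.frame(
    site_id = cl$site_id, species = cl$species, insecticide = cl$insecticide,
    level = cl$level, status_label = cl$status_label,
    unresolved = cl$unresolved,
    flags = paste(cl$flags, collapse = ";"),
    evidence = as.character(jsonlite::toJSON(cl$evidence, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
    stringsAsFactors = FALSE)))
}
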