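#' Probability of detecting a resistance allele in a genotyped sample
#'
#' Probability that at least one copy of an allele at population frequency
#' `p` appears among the `2n` chromosomes of `n` genotyped diploid
#' individuals, assuming independent chromosome draws
#' (Hardy-Weinberg-style sampling):
#' \deqn{P = 1 - (1 - p)^{2n}}{P = 1 - (1 - p)^(2n)}
#' This is the calculation behind the "genotype at least 50 individuals for
#' a marker at 1% frequency" rule of thumb (50 individuals give a detection
#' probability of about 0.63 at p = 0.01). Relatedness among field-caught
#' individuals reduces the effective number of chromosomes and is not
#' modelled; spacing collection points is the field mitigation.
#'
#' @param n_individuals number of diploid individuals genotyped (>= 0).
#' @param allele_freq allele frequency in \[0, 1\]. Both arguments are
#'   vectorised.
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_probability(50, 0.01)  # 1 - 0.99^100 = 0.6340
#' @export
detection_probability <- function(n_individuals, allele_freq) {
  if (any(n_individuals < 0) || any(allele_freq < 0) || any(allele_freq > 1)) {
    stop_psir("detection_probability: need n >= 0 and p in [0, 1]")
  }
  1 - (1 - allele_freq)^(2 * n_individuals)
}

#' Generations for a resistance allele to reach fixation
#'
#' Under uncapped geometric growth (frequency multiplied by a constant
#' factor each generation, the "tipping point" dynamic: an allele at low
#' frequency under strong selection), the smallest integer g with
#' \eqn{p_0 r^g \ge 1}, i.e. \eqn{\lceil \log(1/p_0)/\log r \rceil}.
#' An allele at 2% that doubles each generation is fixed in 6 generations.
#'
#' @param p0 starting allele frequency, 0 < p0 <= 1.
#' @param growth_factor per-generation multiplier r > 1.
#' @return Integer number of generations (0 if already fixed).
#' @examples
#' generations_to_fixation(0.02, 2)  # 6
#' @export
generations_to_fixation <- function(p0, growth_factor) {
  if (!is_scalar_number(p0) || p0 <= 0 || p0 > 1) {
    stop_psir("generations_to_fixation: need 0 < p0 <= 1")
  }
  if (!is_scalar_number(growth_factor) || growth_factor <= 1) {
    stop_psir("generations_to_fixation: growth_factor must exceed 1 (frequency never reaches 1)",
              class = "psir_never_fixes")
  }
  g <- ceiling(log(1 / p0) / log(growth_factor) - 1e-12)
  # guard against floating-point undershoot at exact powers
  while (p0 * growth_factor^g < 1) g <- g + 1
  while (g > 0 && p0 * growth_factor^(g - 1) >= 1) g <- g - 1
  as.integer(g)
}

#' Project an allele-frequency trajectory
#'
#' Geometric growth capped at fixation: `min(1, p0 * r^t)` for
#' t = 0, ..., `generations`. Companion to [generations_to_fixation()] for
#' plotting and reports.
#'
#' @param p0 starting frequency, 0 < p0 <= 1.
#' @param growth_factor per-generation multiplier (>= 0; 1 holds the
#'   frequency constant).
#' @param generations non-negative integer horizon.
#' @return Numeric vector of length `generations + 1` (index 1 is t = 0).
#' @examples
#' project_frequency(0.02, 2, 6)  # reaches 1 at the last generation
#' @export
project_frequency <- function(p0, growth_factor, generations) {
  if (!is_scalar_number(p0) || p0 <= 0 || p0 > 1) {
    stop_psir("project_frequency: need 0 < p0 <= 1")
  }
  if (!is_scalar_number(growth_factor) || growth_factor < 0) {
    stop_psir("project_frequency: growth_factor must be >= 0")
  }
  generations <- as.integer(generations)
  if (generations < 0) stop_psir("project_frequency: generations must be >= 0")
  pmin(1, p0 * growth_factor^(0:generations))
}

# pairwise haversine distances (metres) between rows of a lat/lon matrix
pairwise_haversine <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(numeric(0))
  idx <- utils::combn(n, 2)
  geosphere::distHaversine(
    cbind(coords[idx[1, ], "lon"], coords[idx[1, ], "lat"]),
    cbind(coords[idx[2, ], "lon"], coords[idx[2, ], "lat"]))
}

#' Validate the sampling design of a surveillance territory
#'
#' Checks a territory's sentinel-site network and per-site collection
#' metadata against the design prescriptions for resistance surveillance:
#' \itemize{
#'   \item `territory_min_sites`: at least 10 sentinel sites per territory;
#'   \item `ovitrap_density`: at least 4 oviposition traps per hectare;
#'   \item `breeding_site_count`: at least 10 prospected breeding-site
#'     locations per site;
#'   \item `breeding_site_spacing`: all pairwise distances between
#'     breeding-site locations at least 100 m (haversine on WGS84);
#'   \item `females_collected`: at least 30 wild-caught females when F1
#'     progeny are tested;
#'   \item `genotype_sample_size`: at least 50 genotyped individuals per
#'     marker and site (the sample size needed to detect a 1%-frequency
#'     allele with reasonable probability, see [detection_probability()]);
#'   \item `survey_recency`: last survey within 365 days (susceptibility
#'     should be tested at least once a year).
#' }
#' Sites without breeding-site coordinates have the spacing rule reported
#' as not assessable (`NA`) rather than failed.
#'
#' @param sites a sites table (one territory; see [read_sites()]).
#' @param genotypes optional genotypes table for the same sites.
#' @param as_of reference date for the survey-recency rule (default today).
#' @param rules named list overriding rule constants: `min_sites` (10),
#'   `ovitraps_per_ha` (4), `min_breeding_sites` (10), `min_spacing_m`
#'   (100), `min_females` (30), `min_genotyped` (50), `max_survey_age_days`
#'   (365).
#' @return A `design_report`: data.frame with columns `scope`
#'   (`"territory"` or a site id), `rule_id`, `passed` (logical, `NA` when
#'   not assessable), `observed`, `required`.
#' @export
validate_design <- function(sites, genotypes = NULL, as_of = Sys.Date(),
                            rules = list()) {
  defaults <- list(min_sites = 10, ovitraps_per_ha = 4, min_breeding_sites = 10,
                   min_spacing_m = 100, min_females = 30, min_genotyped = 50,
                   max_survey_age_days = 365)
  rules <- utils::modifyList(defaults, rules)
  as_of <- as.Date(as_of)
  tid <- unique(sites$territory_id)
  if (length(tid) != 1) {
    stop_psir("validate_design: sites table must cover exactly one territory")
  }
  if (anyDuplicated(sites$site_id)) {
    stop_psir("validate_design: duplicated site_id within territory")
  }
  rows <- list()
  add <- function(scope, rule_id, passed, observed, required) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, rule_id = rule_id, passed = passed,
      observed = as.numeric(observed), required = as.numeric(required),
      stringsAsFactors = FALSE)
  }

  add("territory", "territory_min_sites", nrow(sites) >= rules$min_sites,
      nrow(sites), rules$min_sites)

  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    density <- if (!is.na(s$ovitrap_count) && !is.na(s$surveyed_area_ha) &&
                   s$surveyed_area_ha > 0) s$ovitrap_count / s$surveyed_area_ha
               else NA_real_
    add(s$site_id, "ovitrap_density",
        if (is.na(density)) NA else density >= rules$ovitraps_per_ha,
        density, rules$ovitraps_per_ha)

    bs <- unpack_coords(s$breeding_site_coords)
    add(s$site_id, "breeding_site_count", nrow(bs) >= rules$min_breeding_sites,
        nrow(bs), rules$min_breeding_sites)
    if (nrow(bs) >= 2) {
      dmin <- min(pairwise_haversine(bs))
      add(s$site_id, "breeding_site_spacing", dmin >= rules$min_spacing_m,
          dmin, rules$min_spacing_m)
    } else {
      add(s$site_id, "breeding_site_spacing", NA, NA_real_, rules$min_spacing_m)
    }

    if (identical(s$generation_tested, "F1")) {
      add(s$site_id, "females_collected",
          if (is.na(s$females_collected)) NA
          else s$females_collected >= rules$min_females,
          s$females_collected, rules$min_females)
    }

    if (!is.null(genotypes)) {
      g <- genotypes[genotypes$site_id == s$site_id, , drop = FALSE]
      if (nrow(g)) {
        for (mk in unique(g$marker_id)) {
          ni <- sum(g$n_individuals[g$marker_id == mk])
          add(s$site_id, "genotype_sample_size", ni >= rules$min_genotyped,
              ni, rules$min_genotyped)
        }
      } else {
        add(s$site_id, "genotype_sample_size", FALSE, 0, rules$min_genotyped)
      }
    }

    d <- suppressWarnings(as.Date(s$last_survey_date))
    age <- as.numeric(as_of - d)
    add(s$site_id, "survey_recency",
        if (is.na(age)) NA else age <= rules$max_survey_age_days,
        age, rules$max_survey_age_days)
  }

  rep <- do.call(rbind, rows)
  attr(rep, "territory_id") <- tid
  attr(rep, "rules") <- rules
  class(rep) <- c("design_report", "data.frame")
  rep
}

#' @export
print.design_report <- function(x, ...) {
  npass <- sum(x$passed, na.rm = TRUE)
  nfail <- sum(!x$passed, na.rm = TRUE)
  nna <- sum(is.na(x$passed))
  cat(sprintf("<design_report> territory %s: %d pass, %d fail, %d not assessable\n",
              attr(x, "territory_id"), npass, nfail, nna))
  bad <- x[is.na(x$passed) | !x$passed, , drop = FALSE]
  if (nrow(bad)) print.data.frame(bad, row.names = FALSE)
  invisible(x)
}

#' Serialise a design report to JSON
#'
#' @param report a `design_report`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(
    list(territory_id = attr(report, "territory_id"),
         rules = attr(report, "rules"),
         checks = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
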