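#' Risk-of-Resistance lookup matrix
#'
#' The 4 x 3 territory-stratification matrix: rows are population resistance
#' levels 0-3, columns the prevalence bin of sentinel sites at or above that
#' level — isolated sites (< 10%), multiple sites (10-50%), majority of
#' sites (> 50%). Cell values are candidate RiR scores; a territory takes
#' the maximum candidate over levels 1-3 (see [stratify()]).
#'
#' @return Integer matrix with dimnames `level` (0-3) and `bin`.
#' @export
rir_matrix <- function() {
  m <- matrix(c(0L, 0L, 0L,
                0L, 1L, 1L,
                1L, 2L, 2L,
                2L, 2L, 3L),
              nrow = 4, byrow = TRUE,
              dimnames = list(level = 0:3,
                              bin = c("isolated", "multiple", "majority")))
  m
}

bin_proportion <- function(q, thresholds) {
  if (q < thresholds[1]) "isolated" else if (q <= thresholds[2]) "multiple" else "majority"
}

#' RiR score from a vector of site resistance levels
#'
#' The arithmetic core of [stratify()], usable directly when only the
#' per-site levels are at hand (e.g. against simulation ground truth).
#'
#' @param levels integer vector of site resistance levels (0-3).
#' @param bin_thresholds see [stratify()].
#' @return List with `rir`, `driver_level`, `proportion_at_or_above`.
#' @export
rir_from_levels <- function(levels, bin_thresholds = c(0.10, 0.50)) {
  stopifnot(length(levels) > 0, all(levels %in% 0:3))
  q <- vapply(1:3, function(l) mean(levels >= l), numeric(1))
  names(q) <- as.character(1:3)
  M <- rir_matrix()
  candidates <- rep(NA_integer_, 3)
  for (l in 1:3) {
    if (q[l] > 0) {
      candidates[l] <- M[as.character(l), bin_proportion(q[l], bin_thresholds)]
    }
  }
  if (all(is.na(candidates))) {
    list(rir = 0L, driver_level = 0L, proportion_at_or_above = q)
  } else {
    rir <- max(candidates, na.rm = TRUE)
    list(rir = as.integer(rir),
         driver_level = as.integer(max(which(candidates == rir))),
         proportion_at_or_above = q)
  }
}

#' Stratify a territory into a Risk-of-Resistance (RiR) class
#'
#' Combines the population-level classifications of a territory's sentinel
#' sites into a single RiR score 0-3 for one species x insecticide pair.
#' For each resistance level l in \{1, 2, 3\} the cumulative proportion
#' \eqn{q_l} of assessed sites with level >= l is computed and binned as
#' isolated (< 10% of sites), multiple (10-50%) or majority (> 50%); row l
#' of [rir_matrix()] then yields a candidate score (only for levels
#' actually observed, \eqn{q_l > 0}), and the territory's RiR is the
#' maximum candidate. A territory where every site is level 0 is RiR 0.
#'
#' The cumulative-proportion, max-over-rows reading is the only one that
#' simultaneously reproduces the matrix and the textual attribution rules
#' (e.g. a single strong-resistance site among otherwise susceptible ones
#' is RiR 2; more than half the sites at level 3 is RiR 3).
#'
#' Unresolved classifications (provisional levels awaiting intensity tests)
#' are excluded from the denominator rather than imputed; the report says
#' how many were excluded.
#'
#' @param classifications list of `population_classification` for one
#'   territory, one per sentinel site, all for the same species and
#'   insecticide.
#' @param territory_id identifier recorded in the result; if the
#'   classifications carry `territory_id` fields themselves they must all
#'   agree (mixing territories in one call is an error).
#' @param bin_thresholds length-2 proportions, default `c(0.10, 0.50)`.
#'   The lower bound is inclusive for the "multiple" bin (a territory with
#'   exactly 10% of sites at a level falls in the 10-50% bin). These cut
#'   points are guidance values; they may be adjusted per vector species or
#'   territory configuration, and every report echoes the values used.
#' @return A `territory_assessment`: `rir`, `n_sites_assessed`,
#'   `n_sites_excluded`, `proportion_at_or_above` (named vector for levels
#'   1-3), `driver_level`, `has_level3_site`, `bin_thresholds`, and the
#'   matched `recommendations` (see [recommend()]).
#' @examples
#' sites <- c(rep(0, 14), rep(2, 6))  # 30% of sites at moderate resistance
#' cls <- lapply(seq_along(sites), function(i)
#'   classify_larval(c(2, 7, 12)[sites[i] / 2 + 1], site_id = paste0("s", i)))
#' stratify(cls, territory_id = "T1")$rir  # 2
#' @export
stratify <- function(classifications, territory_id = NA_character_,
                     bin_thresholds = c(0.10, 0.50)) {
  if (!length(classifications)) {
    stop_psir("stratify: at least one classification required")
  }
  stopifnot(length(bin_thresholds) == 2, bin_thresholds[1] < bin_thresholds[2],
            all(bin_thresholds > 0), all(bin_thresholds < 1))
  tids <- unlist(lapply(classifications, function(cl) cl$territory_id))
  tids <- unique(tids[!is.na(tids)])
  if (length(tids) > 1) {
    stop_psir("stratify: classifications span multiple territories: ",
              paste(tids, collapse = ", "))
  }
  if (is.na(territory_id) && length(tids) == 1) territory_id <- tids
  sp <- unique(stats::na.omit(vapply(classifications, `[[`, "", "species")))
  ins <- unique(stats::na.omit(vapply(classifications, `[[`, "", "insecticide")))
  if (length(sp) > 1 || length(ins) > 1) {
    stop_psir("stratify: one species x insecticide pair per call")
  }

  unres <- vapply(classifications, `[[`, TRUE, "unresolved")
  resolved <- classifications[!unres]
  if (!length(resolved)) {
    stop_psir("stratify: no resolved classifications (all sites awaiting intensity tests)")
  }
  if (any(unres)) {
    warning(sprintf("stratify: %d unresolved site(s) excluded from the denominator",
                    sum(unres)), call. = FALSE)
  }
  levels <- vapply(resolved, `[[`, 0L, "level")
  n <- length(levels)
  core <- rir_from_levels(levels, bin_thresholds)
  rir <- core$rir
  driver <- core$driver_level
  q <- core$proportion_at_or_above

  out <- structure(list(
    territory_id = territory_id,
    species = if (length(sp)) sp else NA_character_,
    insecticide = if (length(ins)) ins else NA_character_,
    rir = as.integer(rir), n_sites_assessed = n,
    n_sites_excluded = sum(unres),
    proportion_at_or_above = q, driver_level = as.integer(driver),
    has_level3_site = any(levels == 3L),
    bin_thresholds = bin_thresholds,
    site_levels = stats::setNames(levels, vapply(resolved, `[[`, "", "site_id"))),
    class = "territory_assessment")
  out$recommendations <- recommend(out)
  out
}

.rir_actions <- list(
  `0` = list(
    monitoring = "routine resistance monitoring maintained",
    vca = "vector control actions unchanged"),
  `1` = list(
    monitoring = c("strengthen resistance monitoring: increase number of sites and sampling frequency"),
    vca = c("vector control actions unchanged",
            "conceptualise a locally adapted resistance management plan")),
  `2` = list(
    monitoring = c("continued monitoring of resistance",
                   "select and integrate alternative molecules (authorised and/or usable on a derogatory basis) in the monitoring",
                   "targeted sensitivity tests on the populations showing the strongest resistance"),
    vca = c("moderate modifications of vector control: reduce treatments, alternate authorised insecticides in space/time, use complementary methods (trapping, physical control)",
            "efficiency trials under semi-operational conditions with alternative molecules")),
  `3` = list(
    monitoring = c("continued monitoring of resistance",
                   "integrate alternative molecules (authorised and/or usable on a derogatory basis) in the territorial monitoring"),
    vca = c("significant changes in vector control: cessation of treatment with the insecticide concerned",
            "use alternative insecticides that are authorised and/or usable on a derogatory basis",
            "innovative control strategies where a proof of concept exists")))

#' Surveillance and vector-control recommendations for a RiR score
#'
#' Deterministic lookup of the action bundle for a territory assessment.
#' Identification of substances usable by derogatory procedure is flagged
#' from RiR 2 (so alternatives are vetted before they are needed); their
#' operational use is only recommended at RiR 3. Whenever any single
#' sentinel site is at level 3, a local-hotspot note is appended regardless
#' of the territory score: strong resistance in a site warrants increased
#' attention there and, where possible, local cessation of the insecticide
#' concerned.
#'
#' @param assessment a `territory_assessment` (see [stratify()]), or a bare
#'   RiR score 0-3 (no hotspot note in that case).
#' @return A `recommendation_bundle`: `rir`, `monitoring_actions`,
#'   `vector_control_actions`, `derogatory_substances_flag` (identify
#'   candidates, RiR >= 2), `derogatory_use_recommended` (RiR 3),
#'   `local_hotspot_note` (character or `NULL`).
#' @export
recommend <- function(assessment) {
  if (inherits(assessment, "territory_assessment")) {
    rir <- assessment$rir
    hotspot <- isTRUE(assessment$has_level3_site)
  } else {
    rir <- as.integer(assessment)
    hotspot <- FALSE
  }
  if (!rir %in% 0:3) stop_psir("recommend: RiR must be 0, 1, 2 or 3")
  acts <- .rir_actions[[as.character(rir)]]
  structure(list(
    rir = rir,
    monitoring_actions = acts$monitoring,
    vector_control_actions = acts$vca,
    derogatory_substances_flag = rir >= 2L,
    derogatory_use_recommended = rir == 3L,
    local_hotspot_note = if (hotspot)
      paste("strong resistance (level 3) detected in at least one sentinel site:",
            "increase local surveillance and, if possible, cease use of the",
            "insecticide concerned in that area") else NULL),
    class = "recommendation_bundle")
}

#' @export
print.territory_assessment <- function(x, ...) {
  cat(sprintf("<territory_assessment> %s / %s / %s\n",
              x$territory_id, x$species, x$insecticide))
  cat(sprintf("  RiR %d (driver level %d); %d site(s) assessed, %d excluded\n",
              x$rir, x$driver_level, x$n_sites_assessed, x$n_sites_excluded))
  cat(sprintf("  sites at level >= 1/2/3: %s\n",
              paste(sprintf("%.0f%%", 100 * x$proportion_at_or_above), collapse = " / ")))
  invisible(x)
}

#' @export
print.recommendation_bundle <- function(x, ...) {
  cat(sprintf("<recommendation_bundle> RiR %d\n", x$rir))
  cat("  monitoring:\n"); for (a in x$monitoring_actions) cat("   -", a, "\n")
  cat("  vector control:\n"); for (a in x$vector_control_actions) cat("   -", a, "\n")
  if (x$derogatory_substances_flag)
    cat("  derogatory substances: identify candidates",
        if (x$derogatory_use_recommended) "(use recommended)" else "(use not yet recommended)", "\n")
  if (!is.null(x$local_hotspot_note)) cat("  note:", x$local_hotspot_note, "\n")
  invisible(x)
}
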