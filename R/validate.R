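#' Validate a table of surveillance records
#'
#' Applies the domain invariants of one record type to every row and returns
#' a tidy report instead of failing: validation is total, so any table that
#' parses yields a report, and every violation or warning carries the row
#' number and record id it refers to.
#'
#' Checks per type:
#' \describe{
#'   \item{adult_bioassays}{counts consistent (`n_dead <= n_exposed`, same
#'     for controls, all non-negative, exposed > 0); `dc_multiplier` in
#'     \{1, 5, 10\}; `assay_type` tube/bottle; unknown species x insecticide
#'     pairs flagged against the DC registry when one is supplied.}
#'   \item{larval_assays}{concentrations >= 0 (0 marks the control row),
#'     `n_responded <= n_exposed`, >= 4 distinct positive concentrations and
#'     exactly one control row per series, endpoint recognised.}
#'   \item{synergist_assays}{both mortalities within \[0, 100\].}
#'   \item{genotypes}{genotype counts non-negative and summing to
#'     `n_individuals`.}
#'   \item{sites}{latitude/longitude (and every breeding-site coordinate)
#'     within range; `ovitrap_count >= 0`, `surveyed_area_ha > 0`,
#'     `females_collected >= 0`; duplicate `site_id` within a territory is a
#'     violation; `generation_tested = F0` draws a warning because wild
#'     females of unknown age and exposure history increase test variability
#'     and limit comparability across sites and years.}
#' }
#'
#' @param records a record table (possibly with zero rows).
#' @param type one of `"adult_bioassays"`, `"larval_assays"`,
#'   `"synergist_assays"`, `"genotypes"`, `"sites"`.
#' @param registry optional `dc_registry` for species/insecticide lookups.
#' @return A `validation_report`: data.frame with columns `row`,
#'   `record_id`, `severity` (`"violation"`/`"warning"`), `rule`, `message`;
#'   attribute `n_records` holds the number of rows examined. An empty table
#'   yields a zero-violation report with an `empty_input` warning.
#' @examples
#' bad <- data.frame(record_id = "x", site_id = "s", species = "sp",
#'   insecticide = "delta", dc_multiplier = 1L, n_exposed = 25L,
#'   n_dead = 26L, n_control_exposed = 50L, n_control_dead = 0L,
#'   readout_hours = 24L, assay_type = "tube", test_date = "2025-01-01")
#' validate_records(bad, "adult_bioassays")
#' @export
validate_records <- function(records, type = names(.psir_schemas),
                             registry = NULL) {
  type <- match.arg(type)
  findings <- list()
  note <- function(row, id, severity, rule, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      row = row, record_id = as.character(id), severity = severity,
      rule = rule, message = message, stringsAsFactors = FALSE)
  }
  records <- coerce_schema(as.data.frame(records), .psir_schemas[[type]], type)
  n <- nrow(records)
  if (n == 0L) {
    note(NA_integer_, NA_character_, "warning", "empty_input",
         "no records found")
    return(finish_report(findings, 0L))
  }

  id_col <- if ("record_id" %in% names(records)) "record_id"
            else if ("series_id" %in% names(records)) "series_id"
            else "site_id"
  for (i in seq_len(n)) {
    r <- records[i, ]
    id <- r[[id_col]]
    chk <- function(ok, rule, msg) if (!isTRUE(ok)) note(i, id, "violation", rule, msg)

    if (type == "adult_bioassays") {
      chk(r$n_exposed > 0, "counts", "n_exposed must be > 0")
      chk(r$n_control_exposed > 0, "counts", "n_control_exposed must be > 0")
      chk(r$n_dead >= 0 && r$n_dead <= r$n_exposed, "counts",
          sprintf("n_dead (%d) outside [0, n_exposed = %d]", r$n_dead, r$n_exposed))
      chk(r$n_control_dead >= 0 && r$n_control_dead <= r$n_control_exposed,
          "counts", "control deaths outside [0, n_control_exposed]")
      chk(r$dc_multiplier %in% c(1L, 5L, 10L), "dc_multiplier",
          sprintf("dc_multiplier %s not in {1, 5, 10}", r$dc_multiplier))
      chk(r$assay_type %in% c("tube", "bottle"), "assay_type",
          sprintf("assay_type '%s' not tube/bottle", r$assay_type))
      chk(is.na(r$readout_hours) || r$readout_hours > 0, "readout_hours",
          "readout_hours must be positive")
      if (!is.null(registry)) {
        hit <- registry$species == r$species & registry$insecticide == r$insecticide
        if (!any(hit)) {
          note(i, id, "warning", "registry",
               sprintf("no DC registry entry for %s / %s", r$species, r$insecticide))
        }
      }
    } else if (type == "larval_assays") {
      chk(!is.na(r$concentration) && r$concentration >= 0, "concentration",
          "concentration must be >= 0 (0 marks the control row)")
      chk(r$n_exposed > 0, "counts", "n_exposed must be > 0")
      chk(r$n_responded >= 0 && r$n_responded <= r$n_exposed, "counts",
          sprintf("n_responded (%d) outside [0, n_exposed = %d]",
                  r$n_responded, r$n_exposed))
      chk(r$endpoint %in% c("mortality", "emergence_inhibition"), "endpoint",
          sprintf("endpoint '%s' unknown", r$endpoint))
    } else if (type == "synergist_assays") {
      chk(is.finite(r$mortality_alone) && r$mortality_alone >= 0 &&
            r$mortality_alone <= 100, "mortality_range",
          "mortality_alone outside [0, 100]")
      chk(is.finite(r$mortality_combined) && r$mortality_combined >= 0 &&
            r$mortality_combined <= 100, "mortality_range",
          "mortality_combined outside [0, 100]")
    } else if (type == "genotypes") {
      counts <- c(r$n_hom_resistant, r$n_het, r$n_hom_susceptible)
      chk(all(counts >= 0), "counts", "genotype counts must be >= 0")
      chk(r$n_individuals >= 0, "counts", "n_individuals must be >= 0")
      chk(sum(counts) == r$n_individuals, "counts",
          sprintf("genotype counts sum to %d, n_individuals is %d",
                  sum(counts), r$n_individuals))
    } else if (type == "sites") {
      chk(is.finite(r$latitude) && abs(r$latitude) <= 90, "coordinates",
          "latitude outside [-90, 90]")
      chk(is.finite(r$longitude) && abs(r$longitude) <= 180, "coordinates",
          "longitude outside [-180, 180]")
      bs <- tryCatch(unpack_coords(r$breeding_site_coords), error = function(e) NULL)
      if (is.null(bs)) {
        note(i, id, "violation", "coordinates", "breeding_site_coords unparseable")
      } else if (nrow(bs) > 0) {
        chk(all(abs(bs[, "lat"]) <= 90) && all(abs(bs[, "lon"]) <= 180),
            "coordinates", "breeding-site coordinate out of range")
      }
      chk(is.na(r$ovitrap_count) || r$ovitrap_count >= 0, "design",
          "ovitrap_count must be >= 0")
      chk(is.na(r$surveyed_area_ha) || r$surveyed_area_ha > 0, "design",
          "surveyed_area_ha must be > 0")
      chk(is.na(r$females_collected) || r$females_collected >= 0, "design",
          "females_collected must be >= 0")
      chk(is.na(r$generation_tested) ||
            r$generation_tested %in% c("F0", "F1"), "generation",
          sprintf("generation_tested '%s' not F0/F1", r$generation_tested))
      if (identical(r$generation_tested, "F0")) {
        note(i, id, "warning", "f0_provenance",
             paste("F0 (wild-caught) test material: unknown age and physiological",
                   "status increase test variability and limit the comparison of",
                   "results; prefer F1 progeny reared under standard conditions"))
      }
    }
  }

  if (type == "larval_assays") {
    for (sid in unique(records$series_id)) {
      sub <- records[records$series_id == sid, , drop = FALSE]
      n_ctrl <- sum(sub$concentration == 0, na.rm = TRUE)
      n_conc <- length(unique(sub$concentration[sub$concentration > 0]))
      if (n_ctrl != 1L) {
        note(NA_integer_, sid, "violation", "series_control",
             sprintf("series %s has %d control rows; exactly 1 required", sid, n_ctrl))
      }
      if (n_conc < 4L) {
        note(NA_integer_, sid, "violation", "series_concentrations",
             sprintf("series %s has %d distinct concentrations; >= 4 required",
                     sid, n_conc))
      }
    }
  }
  if (type == "sites") {
    dup <- records[duplicated(records[c("territory_id", "site_id")]), , drop = FALSE]
    for (j in seq_len(nrow(dup))) {
      note(NA_integer_, dup$site_id[j], "violation", "unique_site_id",
           sprintf("site_id '%s' duplicated within territory '%s'",
                   dup$site_id[j], dup$territory_id[j]))
    }
  }
  finish_report(findings, n)
}

finish_report <- function(findings, n_records) {
  rep <- if (length(findings)) do.call(rbind, findings) else
    data.frame(row = integer(), record_id = character(),
               severity = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  attr(rep, "n_records") <- n_records
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  nv <- sum(x$severity == "violation")
  nw <- sum(x$severity == "warning")
  cat(sprintf("<validation_report> %d record(s): %d violation(s), %d warning(s)\n",
              attr(x, "n_records"), nv, nw))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
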