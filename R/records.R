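#' Record tables and their file formats
#'
#' Surveillance data enter the package as flat tables, one record type per
#' CSV file (UTF-8, comma separated, mandatory header). The readers below
#' parse and type-check each schema; [validate_records()] applies the domain
#' invariants. Sentinel sites can alternatively be exchanged as a GeoJSON
#' FeatureCollection of Point features.
#'
#' @name psir-records
NULL

# ---- schemas ----------------------------------------------------------------

.psir_schemas <- list(
  adult_bioassays = c(
    record_id = "character", site_id = "character", species = "character",
    insecticide = "character", dc_multiplier = "integer",
    n_exposed = "integer", n_dead = "integer",
    n_control_exposed = "integer", n_control_dead = "integer",
    readout_hours = "integer", assay_type = "character",
    test_date = "character"),
  larval_assays = c(
    series_id = "character", site_id = "character", species = "character",
    insecticide = "character", endpoint = "character", role = "character",
    concentration = "numeric", conc_units = "character",
    n_exposed = "integer", n_responded = "integer"),
  synergist_assays = c(
    record_id = "character", site_id = "character", species = "character",
    insecticide = "character", synergist = "character",
    mortality_alone = "numeric", mortality_combined = "numeric",
    n_exposed_alone = "integer", n_exposed_combined = "integer"),
  genotypes = c(
    record_id = "character", site_id = "character", species = "character",
    marker_id = "character", n_individuals = "integer",
    n_hom_resistant = "integer", n_het = "integer",
    n_hom_susceptible = "integer"),
  sites = c(
    site_id = "character", territory_id = "character", name = "character",
    latitude = "numeric", longitude = "numeric",
    species_monitored = "character", breeding_site_coords = "character",
    ovitrap_count = "integer", surveyed_area_ha = "numeric",
    females_collected = "integer", generation_tested = "character",
    last_survey_date = "character")
)

coerce_schema <- function(df, schema, what, file = "<data.frame>") {
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop_psir(sprintf("%s (%s): missing column(s): %s", what, file,
                      paste(missing_cols, collapse = ", ")),
              class = "psir_parse_error")
  }
  df <- df[names(schema)]
  for (col in names(schema)) {
    target <- schema[[col]]
    x <- df[[col]]
    if (target == "integer") {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & (is.na(xn) | xn != floor(xn)))
      if (length(bad)) {
        stop_psir(sprintf("%s (%s): column '%s' not integer at row %d (value '%s')",
                          what, file, col, bad[1], x[bad[1]]),
                  class = "psir_parse_error")
      }
      df[[col]] <- as.integer(xn)
    } else if (target == "numeric") {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(xn))
      if (length(bad)) {
        stop_psir(sprintf("%s (%s): column '%s' not numeric at row %d (value '%s')",
                          what, file, col, bad[1], x[bad[1]]),
                  class = "psir_parse_error")
      }
      df[[col]] <- xn
    } else {
      df[[col]] <- as.character(x)
    }
  }
  df
}

read_record_csv <- function(path, type) {
  schema <- .psir_schemas[[type]]
  if (!file.exists(path)) {
    stop_psir(sprintf("%s: file not found: %s", type, path),
              class = "psir_parse_error")
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                    check.names = FALSE, strip.white = TRUE),
    error = function(e) {
      stop_psir(sprintf("%s (%s): CSV parse failure: %s", type, path,
                        conditionMessage(e)), class = "psir_parse_error")
    })
  coerce_schema(df, schema, type, file = path)
}

write_record_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read and write surveillance record tables
#'
#' One reader/writer pair per record type. Readers enforce the column schema
#' and coerce types, raising a parse error that names the offending row and
#' column; they do not apply domain invariants (see [validate_records()]).
#'
#' @param path path to a CSV file (UTF-8, header row mandatory).
#' @param df a record table as returned by the matching reader.
#' @return Readers return a `data.frame` with typed columns; writers return
#'   the path, invisibly.
#' @seealso [validate_records()], [read_sites_geojson()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_adult_bioassays(data.frame(
#'   record_id = "a1", site_id = "s1", species = "Aedes albopictus",
#'   insecticide = "deltamethrin", dc_multiplier = 1L, n_exposed = 100L,
#'   n_dead = 99L, n_control_exposed = 100L, n_control_dead = 1L,
#'   readout_hours = 24L, assay_type = "tube", test_date = "2025-06-01"), f)
#' read_adult_bioassays(f)
#' @name record-io
NULL

#' @rdname record-io
#' @export
read_adult_bioassays <- function(path) read_record_csv(path, "adult_bioassays")
#' @rdname record-io
#' @export
read_larval_assays <- function(path) read_record_csv(path, "larval_assays")
#' @rdname record-io
#' @export
read_synergist_assays <- function(path) read_record_csv(path, "synergist_assays")
#' @rdname record-io
#' @export
read_genotypes <- function(path) read_record_csv(path, "genotypes")
#' @rdname record-io
#' @export
read_sites <- function(path) read_record_csv(path, "sites")
#' @rdname record-io
#' @export
write_adult_bioassays <- function(df, path) write_record_csv(df, path)
#' @rdname record-io
#' @export
write_larval_assays <- function(df, path) write_record_csv(df, path)
#' @rdname record-io
#' @export
write_synergist_assays <- function(df, path) write_record_csv(df, path)
#' @rdname record-io
#' @export
write_genotypes <- function(df, path) write_record_csv(df, path)
#' @rdname record-io
#' @export
write_sites <- function(df, path) write_record_csv(df, path)

# ---- compound field helpers -------------------------------------------------

#' Pack and unpack breeding-site coordinate lists
#'
#' Breeding-site coordinates are stored in the sites table as a single text
#' field: `"lat,lon;lat,lon;..."` (WGS84 decimal degrees). These helpers
#' convert between that encoding and a two-column matrix.
#'
#' @param coords matrix (or data.frame) with columns `lat`, `lon`.
#' @param x packed character scalar (may be `""` for no coordinates).
#' @return `pack_coords()` a character scalar; `unpack_coords()` a numeric
#'   matrix with columns `lat`, `lon` (zero rows when empty).
#' @export
pack_coords <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) return("")
  paste(sprintf("%.6f,%.6f", coords[, 1], coords[, 2]), collapse = ";")
}

#' @rdname pack_coords
#' @export
unpack_coords <- function(x) {
  out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lat", "lon")))
  if (is.na(x) || !nzchar(x)) return(out)
  pairs <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  m <- t(vapply(pairs, function(p) as.numeric(p[1:2]), numeric(2)))
  colnames(m) <- c("lat", "lon")
  m
}

# ---- GeoJSON sites ----------------------------------------------------------

#' Sentinel sites as GeoJSON
#'
#' Reads/writes a GeoJSON FeatureCollection of Point features whose
#' properties mirror the sites-table columns (`site_id`, `territory_id`,
#' `ovitrap_count`, ...). Point coordinates follow the GeoJSON convention
#' `[longitude, latitude]` in WGS84 decimal degrees.
#'
#' @param path path to a `.geojson` file.
#' @param sites a sites table (see [read_sites()]).
#' @return `read_sites_geojson()` returns a sites `data.frame`;
#'   `write_sites_geojson()` returns the path invisibly.
#' @export
read_sites_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_psir("GeoJSON sites file must be a FeatureCollection",
              class = "psir_parse_error")
  }
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      stop_psir("GeoJSON sites features must be Points",
                class = "psir_parse_error")
    }
    p <- f$properties
    data.frame(
      site_id = as.character(p$site_id %||% NA_character_),
      territory_id = as.character(p$territory_id %||% NA_character_),
      name = as.character(p$name %||% ""),
      latitude = as.numeric(f$geometry$coordinates[[2]]),
      longitude = as.numeric(f$geometry$coordinates[[1]]),
      species_monitored = as.character(p$species_monitored %||% ""),
      breeding_site_coords = as.character(p$breeding_site_coords %||% ""),
      ovitrap_count = as.integer(p$ovitrap_count %||% NA_integer_),
      surveyed_area_ha = as.numeric(p$surveyed_area_ha %||% NA_real_),
      females_collected = as.integer(p$females_collected %||% NA_integer_),
      generation_tested = as.character(p$generation_tested %||% NA_character_),
      last_survey_date = as.character(p$last_survey_date %||% NA_character_),
      stringsAsFactors = FALSE)
  })
  coerce_schema(do.call(rbind, rows), .psir_schemas$sites, "sites", path)
}

#' @rdname read_sites_geojson
#' @export
write_sites_geojson <- function(sites, path) {
  features <- lapply(seq_len(nrow(sites)), function(i) {
    r <- sites[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(r$longitude, r$latitude)),
      properties = list(
        site_id = r$site_id, territory_id = r$territory_id, name = r$name,
        species_monitored = r$species_monitored,
        breeding_site_coords = r$breeding_site_coords,
        ovitrap_count = r$ovitrap_count,
        surveyed_area_ha = r$surveyed_area_ha,
        females_collected = r$females_collected,
        generation_tested = r$generation_tested,
        last_survey_date = r$last_survey_date))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- DC registry ------------------------------------------------------------

#' Diagnostic-concentration registry
#'
#' The WHO diagnostic (discriminating) concentration for each species x
#' insecticide pair is user-supplied as a YAML file:
#'
#' ```yaml
#' "Aedes albopictus":
#'   deltamethrin:
#'     diagnostic_concentration: 0.03
#'     units: "%"
#'     assay_type: tube
#'     readout_hours: 24
#'     source: "local SOP"
#' ```
#'
#' `readout_hours` is optional and defaults to 24; slow-acting compounds
#' (e.g. chlorfenapyr, read at 72 h) override it per entry. The package
#' ships a placeholder template (`system.file("extdata",
#' "dc_registry_template.yaml", package = "psir")`); authoritative values
#' must come from the user's own WHO documentation.
#'
#' @param path path to the YAML registry.
#' @return A `data.frame` with columns `species`, `insecticide`,
#'   `diagnostic_concentration`, `units`, `assay_type`, `readout_hours`,
#'   `source`, of class `dc_registry`.
#' @export
read_dc_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- list()
  for (sp in names(raw)) {
    for (ins in names(raw[[sp]])) {
      e <- raw[[sp]][[ins]]
      dc <- as.numeric(e$diagnostic_concentration)
      if (!is.finite(dc) || dc <= 0) {
        stop_psir(sprintf("DC registry: %s / %s: diagnostic_concentration must be > 0",
                          sp, ins), class = "psir_parse_error")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, insecticide = ins, diagnostic_concentration = dc,
        units = as.character(e$units %||% ""),
        assay_type = as.character(e$assay_type %||% "tube"),
        readout_hours = as.integer(e$readout_hours %||% 24L),
        source = as.character(e$source %||% ""),
        stringsAsFactors = FALSE)
    }
  }
  reg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), insecticide = character(),
               diagnostic_concentration = numeric(), units = character(),
               assay_type = character(), readout_hours = integer(),
               source = character())
  class(reg) <- c("dc_registry", "data.frame")
  reg
}

#' @rdname read_dc_registry
#' @param registry a `dc_registry` data.frame.
#' @export
write_dc_registry <- function(registry, path) {
  out <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    out[[r$species]][[r$insecticide]] <- list(
      diagnostic_concentration = r$diagnostic_concentration,
      units = r$units, assay_type = r$assay_type,
      readout_hours = r$readout_hours, source = r$source)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- larval series object ---------------------------------------------------

#' A larval (or IGR) dose-response series
#'
#' Bundles the per-concentration response counts of one larval bioassay with
#' its untreated control arm. A series needs at least four distinct positive
#' concentrations; the endpoint is either larval `mortality` or
#' `emergence_inhibition` (insect growth regulators, where the response is a
#' larva failing to emerge as an adult).
#'
#' @param site_id site (or reference-strain) identifier.
#' @param species,insecticide test identity.
#' @param concentration numeric vector of exposure concentrations (> 0).
#' @param n_exposed,n_responded integer vectors parallel to `concentration`.
#' @param control_n_exposed,control_n_responded control-arm counts.
#' @param endpoint `"mortality"` or `"emergence_inhibition"`.
#' @param conc_units free-text units label (e.g. `"mg/L"`).
#' @return An object of class `larval_series`.
#' @export
larval_series <- function(site_id, species, insecticide,
                          concentration, n_exposed, n_responded,
                          control_n_exposed, control_n_responded,
                          endpoint = c("mortality", "emergence_inhibition"),
                          conc_units = "mg/L") {
  endpoint <- match.arg(endpoint)
  concentration <- as.numeric(concentration)
  n_exposed <- as.integer(n_exposed)
  n_responded <- as.integer(n_responded)
  if (any(concentration <= 0) || anyNA(concentration)) {
    stop_psir("larval_series: concentrations must be strictly positive")
  }
  if (length(unique(concentration)) < 4L) {
    stop_psir("larval_series: at least 4 distinct concentrations required")
  }
  if (length(n_exposed) != length(concentration) ||
      length(n_responded) != length(concentration)) {
    stop_psir("larval_series: count vectors must match concentration length")
  }
  if (any(n_responded > n_exposed) || any(n_responded < 0) || any(n_exposed <= 0)) {
    stop_psir("larval_series: need 0 <= n_responded <= n_exposed, n_exposed > 0")
  }
  if (control_n_responded > control_n_exposed || control_n_exposed <= 0) {
    stop_psir("larval_series: invalid control counts")
  }
  structure(list(
    site_id = site_id, species = species, insecticide = insecticide,
    endpoint = endpoint, conc_units = conc_units,
    points = data.frame(concentration = concentration,
                        n_exposed = n_exposed, n_responded = n_responded),
    control = list(n_exposed = as.integer(control_n_exposed),
                   n_responded = as.integer(control_n_responded))),
    class = "larval_series")
}

#' Split a long-format larval assay table into series objects
#'
#' The larval CSV is long format: one row per concentration, plus one row
#' with `concentration = 0` per series holding the control arm. `role` is
#' `"test"` for field populations and `"reference"` for the susceptible
#' reference strain.
#'
#' @param df a larval assay table (see [read_larval_assays()]).
#' @return Named list of `larval_series`, one per `series_id`.
#' @export
split_larval_series <- function(df) {
  out <- list()
  for (sid in unique(df$series_id)) {
    sub <- df[df$series_id == sid, , drop = FALSE]
    ctrl <- sub[sub$concentration == 0, , drop = FALSE]
    pts <- sub[sub$concentration > 0, , drop = FALSE]
    if (nrow(ctrl) != 1L) {
      stop_psir(sprintf("series %s: exactly one control row (concentration 0) required", sid))
    }
    out[[sid]] <- larval_series(
      site_id = pts$site_id[1], species = pts$species[1],
      insecticide = pts$insecticide[1],
      concentration = pts$concentration,
      n_exposed = pts$n_exposed, n_responded = pts$n_responded,
      control_n_exposed = ctrl$n_exposed,
      control_n_responded = ctrl$n_responded,
      endpoint = pts$endpoint[1], conc_units = pts$conc_units[1])
    attr(out[[sid]], "role") <- sub$role[1]
  }
  out
}

#' @export
print.larval_series <- function(x, ...) {
  cat(sprintf("<larval_series> %s / %s / %s (%s)\n", x$site_id, x$species,
              x$insecticide, x$endpoint))
  cat(sprintf("  %d concentrations [%s], control %d/%d responded\n",
              nrow(x$points), x$conc_units,
              x$control$n_responded, x$control$n_exposed))
  invisible(x)
}
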