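#' psir: territory-scale surveillance of insecticide resistance in mosquitoes
#'
#' From raw bioassay, genotype and sentinel-site records to population
#' resistance levels, territory Risk-of-Resistance scores and graded
#' surveillance / vector-control recommendations.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_psir <- function(..., class = "psir_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Deterministic substream seed: mixes a master seed with integer labels so
# that record i's draws do not shift when record j is added. Constants are
# arbitrary odd multipliers; result kept in [0, 2^31 - 2].
substream_seed <- function(seed, ...) {
  labs <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(labs)) {
    h <- (h * 48271 + as.double(labs[[k]]) * 16807 + k * 69621) %% 2147483647
  }
  as.integer(h)
}
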