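#' Read and write survey tables
#'
#' Site and horizon tables are UTF-8 comma-delimited text with a header row
#' and empty fields for missing values (never numeric sentinels). Column
#' names follow the data dictionary in the package README. Reading
#' validates every record against the type invariants; writing is lossless
#' at full double precision, so write-then-read round-trips are identities.
#'
#' @param path file path.
#' @return `read_sites`: a validated tibble of site records.
#' @seealso [validate_sites()], [validate_horizons()]
#' @export
read_sites <- function(path) {
  spec <- readr::cols(
    site_id = readr::col_character(),
    reporting_group = readr::col_character(),
    region = readr::col_character(),
    wetland_type = readr::col_character(),
    hgm_class = readr::col_character(),
    tidal_saline = readr::col_logical(),
    probability_site = readr::col_logical(),
    weight_ha = readr::col_double(),
    impenetrable_depth_cm = readr::col_double(),
    .default = readr::col_double()
  )
  df <- readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  validate_sites(df)
}

#' @rdname read_sites
#' @return `read_horizons`: a validated tibble of horizons sorted by site
#'   and horizon order, with `soc_pct` recomputed as total minus inorganic
#'   carbon (clipped at 0) wherever both are present.
#' @export
read_horizons <- function(path) {
  spec <- readr::cols(
    site_id = readr::col_character(),
    horizon_order = readr::col_integer(),
    organic_flag = readr::col_logical(),
    thin_flag = readr::col_logical(),
    bd_source = readr::col_character(),
    .default = readr::col_double()
  )
  df <- readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  validate_horizons(df)
}

#' @rdname read_sites
#' @param x a tibble to write.
#' @export
write_sites <- function(x, path) {
  readr::write_csv(validate_sites(x), path, na = "")
  invisible(path)
}

#' @rdname read_sites
#' @export
write_horizons <- function(x, path) {
  readr::write_csv(validate_horizons(x, recompute_soc = FALSE), path, na = "")
  invisible(path)
}

estimate_schema <- function() {
  c("subpopulation", "depth_lo_cm", "depth_hi_cm", "n_sites", "area_Mha",
    "mean_tC_ha", "se_mean", "total_PgC", "se_total")
}

#' Write and re-read population estimate tables
#'
#' One row per subpopulation x depth range, with the mean carbon density
#' (tC ha-1), total stock (PgC), their standard errors, the contributing
#' site count and represented area (million ha). Values are written at full
#' precision; an empty estimate set yields a header-only file.
#'
#' @param estimates tibble of population estimates.
#' @param path file path.
#' @export
write_estimates <- function(estimates, path) {
  estimates <- tibble::as_tibble(estimates)
  require_columns(estimates, estimate_schema(), "estimate")
  readr::write_csv(estimates[, estimate_schema()], path, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  spec <- readr::cols(
    subpopulation = readr::col_character(),
    n_sites = readr::col_integer(),
    .default = readr::col_double()
  )
  df <- readr::read_csv(path, col_types = spec, na = "", progress = FALSE)
  require_columns(df, estimate_schema(), "estimate")
  df
}
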