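#' Published 2011 NWCA soil-carbon summary tables
#'
#' Small reference tables transcribed from the published national
#' wetland soil-carbon summaries of the 2011 National Wetland Condition
#' Assessment: carbon stocks (PgC) by depth increment and represented
#' area (million ha) for the inference and target populations, broken
#' out by region, carbon type and disturbance category, plus screened
#' site counts, disturbance-class mean densities, and deep-layer bulk
#' density modelling counts. They serve as inputs to the package's
#' ratio/aggregation operations (depth shares, area shares, class
#' contrasts), not as values the estimators are tuned to.
#'
#' @return `nwca2011_stock_summary`: tibble with one row per population
#'   (`inference`/`target`) x subpopulation, increment stocks `d0_30` ..
#'   `d90_120`, `total_0_120` (PgC) and `area_Mha`.
#' @export
nwca2011_stock_summary <- function() {
  path <- system.file("extdata", "nwca2011_stock_summary.csv",
                      package = "wetcarbon", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    population = readr::col_character(),
    grouping = readr::col_character(),
    subpopulation = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}

#' @rdname nwca2011_stock_summary
#' @return `nwca2011_condition_summary`: named numeric vector of counts
#'   and mean densities (screened site counts by disturbance class,
#'   least/most mean tC ha-1, deep-layer bulk density counts).
#' @export
nwca2011_condition_summary <- function() {
  path <- system.file("extdata", "nwca2011_condition_summary.csv",
                      package = "wetcarbon", mustWork = TRUE)
  df <- readr::read_csv(path, col_types = "cd", progress = FALSE)
  setNames(df$value, df$key)
}
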