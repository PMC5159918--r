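#' Design-based subpopulation estimate of carbon density and stock
#'
#' Sites enter with survey weights w_i (hectares represented; the inverse
#' inclusion probability expressed as area). For a subpopulation and depth
#' range, with y_i the site's carbon density (tC ha-1) and the sum running
#' over the n contributing sites (those whose profile fully covers the
#' range):
#'
#' * represented area:  A-hat = sum(w_i)  (ha)
#' * total stock:       T-hat = sum(w_i * y_i)  (tC, reported as PgC)
#' * mean density:      T-hat / A-hat  (tC ha-1)
#'
#' with sums over the n contributing sites: those in the subpopulation
#' whose profile fully covers the depth range.
#'
#' Standard errors use the with-replacement (Hansen-Hurwitz style)
#' approximation computed over the full sample: var(T-hat) =
#' m/(m-1) * sum((z_i - mean(z))^2) with m the full sample size and
#' z_i = w_i * y_i for contributing sites, 0 otherwise — subpopulation
#' membership and depth availability are themselves random under the
#' design, so non-contributing sampled sites carry zeros rather than
#' being dropped, which would understate the variance of the total. The
#' mean uses the ratio-linearized version with residuals
#' w_i * (y_i - mean). The estimator ignores the spatial structure of
#' the original sample selection, which changes SEs but not point
#' estimates.
#'
#' @param data tibble with one row per *sampled* site: a density column,
#'   a weight column (ha), and any subpopulation labels. Pass the full
#'   sample rather than a pre-filtered subset so variances account for
#'   random membership; rows outside `domain` contribute only zeros.
#' @param y_col name of the density column (tC ha-1; `NA` = range not
#'   available at that site).
#' @param subpopulation label for the output row.
#' @param domain logical vector over rows of `data` marking
#'   subpopulation membership (default: all rows).
#' @param depth_lo_cm,depth_hi_cm depth range covered by `y_col`.
#' @param weight_col name of the weight column.
#' @return one-row tibble: `subpopulation`, `depth_lo_cm`, `depth_hi_cm`,
#'   `n_sites` (contributing count), `area_Mha`, `mean_tC_ha`,
#'   `se_mean`, `total_PgC`, `se_total`. An empty subpopulation yields
#'   `n_sites = 0` and `NA` estimates.
#' @export
estimate_subpopulation <- function(data, y_col, subpopulation = "all",
                                   domain = NULL,
                                   depth_lo_cm = NA_real_,
                                   depth_hi_cm = NA_real_,
                                   weight_col = "weight_ha") {
  y <- data[[y_col]]
  w <- data[[weight_col]]
  if (is.null(domain)) domain <- rep(TRUE, nrow(data))
  stopifnot(length(domain) == nrow(data))
  domain[is.na(domain)] <- FALSE
  contrib <- domain & !is.na(y) & !is.na(w)
  if (any(w[contrib] <= 0)) {
    stop("survey weights must be positive", call. = FALSE)
  }
  n <- sum(contrib)
  if (n == 0) {
    return(tibble::tibble(subpopulation = subpopulation,
                          depth_lo_cm = depth_lo_cm,
                          depth_hi_cm = depth_hi_cm,
                          n_sites = 0L, area_Mha = NA_real_,
                          mean_tC_ha = NA_real_, se_mean = NA_real_,
                          total_PgC = NA_real_, se_total = NA_real_))
  }
  area_ha <- sum(w[contrib])
  total_tC <- sum(w[contrib] * y[contrib])
  mean_d <- total_tC / area_ha

  in_sample <- !is.na(w)
  m <- sum(in_sample)
  if (m >= 2 && n >= 2) {
    z <- ifelse(contrib, w * y, 0)[in_sample]
    var_total <- m / (m - 1) * sum((z - mean(z))^2)       # (tC)^2
    u <- ifelse(contrib, w * (y - mean_d), 0)[in_sample]  # sums to 0
    var_mean <- m / (m - 1) * sum((u - mean(u))^2) / area_ha^2
    se_total_PgC <- sqrt(var_total) / 1e9
    se_mean <- sqrt(var_mean)
  } else {
    se_total_PgC <- NA_real_
    se_mean <- NA_real_
  }

  tibble::tibble(subpopulation = subpopulation,
                 depth_lo_cm = depth_lo_cm, depth_hi_cm = depth_hi_cm,
                 n_sites = n, area_Mha = area_ha / 1e6,
                 mean_tC_ha = mean_d, se_mean = se_mean,
                 total_PgC = total_tC / 1e9, se_total = se_total_PgC)
}

#' Estimate all subpopulations across depth ranges
#'
#' Runs [estimate_subpopulation()] for the whole sample ("National") and
#' for every level of each grouping column, for every `d<lo>_<hi>`
#' density column present.
#'
#' @param data per-site tibble: density columns from
#'   [site_depth_densities()] joined with weights and grouping labels.
#' @param groupings character vector of grouping column names (e.g.
#'   `c("region", "carbon_type", "disturbance_class", "soil_class")`).
#' @param weight_col name of the weight column.
#' @return tibble of estimates with a `grouping` column.
#' @export
estimate_all <- function(data,
                         groupings = c("region", "carbon_type",
                                       "disturbance_class", "soil_class"),
                         weight_col = "weight_ha") {
  y_cols <- grep("^d[0-9]+_[0-9]+$", names(data), value = TRUE)
  if (length(y_cols) == 0) stop("no depth-range density columns found",
                                call. = FALSE)
  parse_range <- function(col) as.numeric(strsplit(sub("^d", "", col), "_")[[1]])

  one_block <- function(domain, label, grouping) {
    dplyr::bind_rows(lapply(y_cols, function(col) {
      r <- parse_range(col)
      estimate_subpopulation(data, col, label, domain = domain,
                             depth_lo_cm = r[1], depth_hi_cm = r[2],
                             weight_col = weight_col)
    })) |> dplyr::mutate(grouping = grouping, .before = 1)
  }

  out <- list(one_block(NULL, "National", "national"))
  for (g in groupings) {
    if (!g %in% names(data)) next
    for (lev in sort(unique(stats::na.omit(data[[g]])))) {
      out[[length(out) + 1]] <-
        one_block(!is.na(data[[g]]) & data[[g]] == lev, lev, g)
    }
  }
  dplyr::bind_rows(out)
}

#' Scale an inference-population estimate to a target population
#'
#' Part of a survey frame typically cannot be sampled; extrapolating to
#' the full target area assumes the unsampled area follows the same
#' trends. Totals scale by the area ratio, mean densities are unchanged,
#' and standard errors are dropped (they cannot be computed for the
#' unsampled area).
#'
#' @param est estimate tibble (rows from [estimate_subpopulation()]).
#' @param inference_area_Mha area represented by the sample, million ha.
#' @param target_area_Mha full target-population area, million ha.
#' @return the estimate tibble with scaled totals, `area_Mha` set to the
#'   target area, and SEs set to `NA`.
#' @export
scale_to_target <- function(est, inference_area_Mha, target_area_Mha) {
  if (!is.numeric(inference_area_Mha) || !is.numeric(target_area_Mha) ||
      any(inference_area_Mha <= 0) || any(target_area_Mha <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  ratio <- target_area_Mha / inference_area_Mha
  dplyr::mutate(est,
                total_PgC = .data$total_PgC * ratio,
                area_Mha = .data$area_Mha * ratio,
                se_mean = NA_real_, se_total = NA_real_)
}

#' Shares and contrasts from a stock table
#'
#' Ratio summaries used in reporting: the percentage share of each depth
#' increment in a subpopulation's 0-max stock, percentage area or stock
#' shares between subpopulations, and differences of mean densities
#' between classes.
#'
#' @param x numeric vector of increment stocks (PgC) or a part value.
#' @return `depth_shares`: percentages summing to 100.
#' @export
depth_shares <- function(x) {
  if (sum(x) == 0) stop("zero total stock; shares undefined", call. = FALSE)
  100 * x / sum(x)
}

#' @rdname depth_shares
#' @param part,whole numeric scalars (same units).
#' @return `pct_share`: 100 * part / whole.
#' @export
pct_share <- function(part, whole) {
  if (whole == 0) stop("zero denominator; share undefined", call. = FALSE)
  100 * part / whole
}
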