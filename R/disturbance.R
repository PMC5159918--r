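#' Disturbance screening thresholds
#'
#' Sites are placed on a least / intermediate / most disturbed gradient by
#' screening ten stressor measures (buffer agriculture, residential/urban,
#' hydrologic, industrial and habitat-modification counts, a buffer
#' summary score, high- and moderate-impact hydrologic counts within the
#' assessment area, a soil heavy-metal exceedance index, and relative
#' alien plant cover) against per-reporting-group thresholds. A site is
#' *least* disturbed only when every measure is at or below its least
#' threshold; it is *most* disturbed when any single measure exceeds its
#' most threshold; all remaining sites are intermediate. Exceedance is
#' strict (>) for the most thresholds and non-strict (<=) for least
#' compliance.
#'
#' @param thresholds tibble with columns `reporting_group`, `measure`,
#'   `least_max`, `most_min`; one row per group x measure, with
#'   `least_max <= most_min`.
#' @return the validated thresholds tibble.
#' @export
disturbance_thresholds <- function(thresholds) {
  thresholds <- tibble::as_tibble(thresholds)
  require_columns(thresholds,
                  c("reporting_group", "measure", "least_max", "most_min"),
                  "thresholds")
  if (!all(thresholds$measure %in% disturbance_measures())) {
    stop("unknown disturbance measure in thresholds", call. = FALSE)
  }
  if (any(thresholds$least_max > thresholds$most_min + 1e-9)) {
    stop("least_max must not exceed most_min for any measure", call. = FALSE)
  }
  thresholds
}

#' Screen one site's disturbance indices
#'
#' @param indices named numeric vector of the ten measures.
#' @param least_max,most_min named numeric threshold vectors for the
#'   site's reporting group.
#' @return `"least"`, `"intermediate"`, `"most"`, or `NA` when any index
#'   is missing (site excluded from the gradient).
#' @export
screen_site <- function(indices, least_max, most_min) {
  meas <- disturbance_measures()
  v <- indices[meas]
  if (anyNA(v)) return(NA_character_)
  if (all(v <= least_max[meas] + 1e-12)) return("least")
  if (any(v > most_min[meas] + 1e-12)) return("most")
  "intermediate"
}

#' Screen every site against group thresholds
#'
#' @param sites validated site table with `dist_*` index columns.
#' @param thresholds a [disturbance_thresholds()] table.
#' @return the site table with a `disturbance_class` column appended.
#' @export
screen_sites <- function(sites, thresholds) {
  thresholds <- disturbance_thresholds(thresholds)
  idx_mat <- as.matrix(sites[, dist_cols()])
  colnames(idx_mat) <- disturbance_measures()
  cls <- character(nrow(sites))
  for (g in unique(sites$reporting_group)) {
    th <- thresholds[thresholds$reporting_group == g, ]
    if (nrow(th) == 0) {
      stop(sprintf("no thresholds for reporting group %s", g), call. = FALSE)
    }
    lm <- setNames(th$least_max, th$measure)
    mm <- setNames(th$most_min, th$measure)
    rows <- which(sites$reporting_group == g)
    cls[rows] <- vapply(rows, function(i) {
      screen_site(idx_mat[i, ], lm, mm)
    }, "")
  }
  n_miss <- sum(is.na(cls))
  if (n_miss > 0) {
    message(sprintf("disturbance screen: %d site(s) with missing indices excluded",
                    n_miss))
  }
  dplyr::mutate(sites, disturbance_class = cls)
}

# realized most-disturbed fraction in a group when every measure's most
# threshold sits at pooled quantile q
realized_most_fraction <- function(idx_mat, q) {
  th <- apply(idx_mat, 2, quantile, probs = q, na.rm = TRUE, names = FALSE)
  mean(apply(idx_mat, 1, function(v) any(v > th + 1e-12)), na.rm = TRUE)
}

#' Calibrate most-disturbed thresholds to a target fraction
#'
#' "Most disturbed" is a relative designation: thresholds are set, per
#' reporting group, so that roughly 20-30% of screened sites exceed at
#' least one of them. For each group the ten most thresholds are placed
#' at a common upper quantile of that group's index distributions; the
#' quantile is chosen (over a fine deterministic grid) as the highest one
#' whose realized exceedance fraction still reaches `target_fraction`, so
#' the realized fraction is the smallest achievable value at or above the
#' target. With at least 20 sites per group this lands within
#' `target_fraction + 1/20`. When even the lowest grid quantile cannot
#' reach the target (e.g. degenerate, all-identical indices), the nearest
#' achievable fraction is used with a warning.
#'
#' Least thresholds are placed at `least_quantile` of each measure
#' (capped at the most threshold); raise the quantile to relax screening
#' for sparsely sampled groups.
#'
#' Both probability and non-probability sites should enter calibration;
#' only probability sites enter population estimates.
#'
#' @param sites site table (probability and non-probability).
#' @param target_fraction target most-disturbed fraction, default 0.25.
#' @param least_quantile quantile defining least-compliance thresholds.
#' @param pool_sparse calibrate groups with fewer than 20 sites from the
#'   pooled index distribution of all sites (with a message) instead of
#'   erroring; the analogue of relaxing thresholds for sparsely sampled
#'   groups.
#' @return a [disturbance_thresholds()] tibble covering every group
#'   present.
#' @export
calibrate_thresholds <- function(sites, target_fraction = 0.25,
                                 least_quantile = 0.50,
                                 pool_sparse = FALSE) {
  stopifnot(target_fraction > 0, target_fraction < 1)
  out <- list()
  for (g in unique(sites$reporting_group)) {
    rows <- sites$reporting_group == g
    if (sum(rows) < 20) {
      if (!pool_sparse) {
        stop(sprintf("reporting group %s has %d sites; >= 20 required for calibration",
                     g, sum(rows)), call. = FALSE)
      }
      message(sprintf(
        "calibrate_thresholds: group %s has %d sites; using pooled indices",
        g, sum(rows)))
      rows <- rep(TRUE, nrow(sites))
    }
    idx_mat <- as.matrix(sites[rows, dist_cols()])
    colnames(idx_mat) <- disturbance_measures()

    grid <- seq(0.50, 0.999, by = 0.001)
    frac <- vapply(grid, function(q) realized_most_fraction(idx_mat, q),
                   numeric(1))
    ok <- which(frac >= target_fraction - 1e-12)
    if (length(ok) == 0) {
      q_star <- grid[which.max(frac)]
      warning(sprintf(
        "group %s: target most fraction %.2f unattainable; nearest achievable %.2f",
        g, target_fraction, max(frac)), call. = FALSE)
    } else {
      q_star <- grid[max(ok)]   # smallest achievable fraction >= target
    }
    most_min <- apply(idx_mat, 2, quantile, probs = q_star, na.rm = TRUE,
                      names = FALSE)
    least_max <- pmin(
      apply(idx_mat, 2, quantile, probs = least_quantile, na.rm = TRUE,
            names = FALSE),
      most_min)
    out[[g]] <- tibble::tibble(
      reporting_group = g, measure = disturbance_measures(),
      least_max = least_max, most_min = most_min)
  }
  disturbance_thresholds(dplyr::bind_rows(out))
}

#' Summarise a disturbance gradient
#'
#' @param classes character vector of per-site assignments (`NA` =
#'   excluded).
#' @return tibble with class, count and integer-rounded percentage of
#'   screened sites; counts always sum to the screened total.
#' @export
gradient_summary <- function(classes) {
  lv <- c("least", "intermediate", "most")
  classes <- classes[!is.na(classes)]
  n <- as.integer(table(factor(classes, levels = lv)))
  tibble::tibble(
    disturbance_class = lv,
    n_sites = n,
    pct = if (sum(n) > 0) as.integer(round(100 * n / sum(n))) else
      rep(0L, 3))
}
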