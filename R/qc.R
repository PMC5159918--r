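#' Impute missing horizon carbon from adjacent horizons
#'
#' Thin horizons (< 8 cm) are not lab-sampled, so their SOC must be filled
#' from neighbours before accounting. The rules, applied per profile from
#' the surface down:
#'
#' * top horizon missing: SOC is equated to the next lower horizon with
#'   data (a conservative choice when an organic surface overlies mineral
#'   soil);
#' * interior horizon missing: the arithmetic mean of the SOC of the
#'   nearest non-missing horizons immediately above and below; a run of
#'   consecutive missing horizons shares the same neighbour average;
#' * bottom horizon missing: copied from the nearest horizon above
#'   (mirror of the top rule; disable with `impute_bottom = FALSE`).
#'
#' Profiles with no SOC anywhere cannot be used: their sites are listed in
#' the report's `unusable_sites` and left untouched for downstream
#' exclusion. Non-missing SOC values are never altered, and the operation
#' is idempotent.
#'
#' @param horizons validated horizon table (any number of sites).
#' @param impute_bottom also fill a missing bottom horizon from above.
#' @return list with `horizons` (imputed) and `report`: a per-site tibble
#'   of imputation counts (`n_top_imputed`, `n_mid_imputed`,
#'   `n_bottom_imputed`) plus an `unusable_sites` attribute.
#' @export
impute_missing_carbon <- function(horizons, impute_bottom = TRUE) {
  horizons <- tibble::as_tibble(horizons)
  idx_by_site <- split(seq_len(nrow(horizons)), horizons$site_id)
  soc <- horizons$soc_pct
  rep_rows <- list()
  unusable <- character(0)

  for (site in names(idx_by_site)) {
    idx <- idx_by_site[[site]]
    s <- soc[idx]
    n_top <- n_mid <- n_bot <- 0L
    if (all(is.na(s))) {
      unusable <- c(unusable, site)
    } else if (anyNA(s)) {
      known <- which(!is.na(s))
      for (k in which(is.na(s))) {
        above <- known[known < k]
        below <- known[known > k]
        if (length(above) == 0) {            # surface: copy from below
          s[k] <- s[min(below)]
          n_top <- n_top + 1L
        } else if (length(below) == 0) {     # bottom: copy from above
          if (impute_bottom) {
            s[k] <- s[max(above)]
            n_bot <- n_bot + 1L
          }
        } else {                             # interior: neighbour average
          s[k] <- (s[max(above)] + s[min(below)]) / 2
          n_mid <- n_mid + 1L
        }
      }
      soc[idx] <- s
    }
    rep_rows[[site]] <- tibble::tibble(
      site_id = site, n_top_imputed = n_top, n_mid_imputed = n_mid,
      n_bottom_imputed = n_bot)
  }

  if (length(unusable) > 0) {
    message(sprintf("QC: %d site(s) with no SOC on any horizon excluded: %s",
                    length(unusable), paste(head(unusable, 5), collapse = ", ")))
  }
  report <- dplyr::bind_rows(rep_rows)
  attr(report, "unusable_sites") <- unusable
  list(horizons = horizons |> dplyr::mutate(soc_pct = soc), report = report)
}

#' Screen measured bulk density against modelled values
#'
#' Field bulk density sampling is error prone, so measured values are
#' screened against model predictions. In order, per horizon:
#'
#' * measured > `bd_max` (default 2.0 g cm-3, the upper limit of
#'   measurable bulk density — larger values are assumed erroneous):
#'   replaced by the modelled value;
#' * measured value absent: filled with the modelled value;
#' * |measured - modelled| / modelled > `rel_diff_max` (default 0.40):
#'   replaced by the modelled value;
#' * otherwise the measurement is kept.
#'
#' `bd_source` records the disposition (`"measured"` or `"modelled"`).
#' Re-screening screened output against the same modelled values changes
#' nothing.
#'
#' @param horizons validated horizon table.
#' @param modelled_bd numeric vector of model predictions aligned with the
#'   rows of `horizons` (must be present wherever a replacement is
#'   needed).
#' @param rel_diff_max relative-discrepancy threshold (denominator:
#'   modelled value).
#' @param bd_max physical upper limit for a measured bulk density.
#' @return list with `horizons` (screened, `bd_source` updated) and
#'   `report`: per-site counts `n_bd_over_limit`, `n_bd_replaced_40pct`,
#'   `n_bd_filled_missing`.
#' @export
screen_bulk_density <- function(horizons, modelled_bd,
                                rel_diff_max = 0.40, bd_max = 2.0) {
  horizons <- tibble::as_tibble(horizons)
  stopifnot(length(modelled_bd) == nrow(horizons))
  bd <- horizons$bd_g_cm3
  src <- horizons$bd_source

  over <- !is.na(bd) & bd > bd_max
  miss <- is.na(bd)
  disc <- !is.na(bd) & !over &
    abs(bd - modelled_bd) / modelled_bd > rel_diff_max
  disc[is.na(disc)] <- FALSE
  need <- over | miss | disc

  if (any(need & is.na(modelled_bd))) {
    bad <- which(need & is.na(modelled_bd))
    stop(sprintf(
      "modelled bulk density required but absent for %d horizon(s), e.g. site %s order %d",
      length(bad), horizons$site_id[bad[1]], horizons$horizon_order[bad[1]]),
      call. = FALSE)
  }

  bd[need] <- modelled_bd[need]
  src[need] <- "modelled"
  src[!need & !is.na(bd) & is.na(src)] <- "measured"

  report <- tibble::tibble(site_id = horizons$site_id, over = over,
                           miss = miss, disc = disc) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_bd_over_limit = sum(.data$over),
                     n_bd_replaced_40pct = sum(.data$disc),
                     n_bd_filled_missing = sum(.data$miss),
                     .groups = "drop")
  list(horizons = horizons |>
         dplyr::mutate(bd_g_cm3 = bd, bd_source = src),
       report = report)
}

#' Full profile QC: carbon imputation plus bulk density screening
#'
#' Convenience wrapper: imputes missing SOC, then screens bulk density
#' against predictions from a fitted model (see [fit_bd_model()]).
#' Unusable sites (no SOC at all) are dropped from the returned horizons.
#'
#' @param horizons validated horizon table.
#' @param sites validated site table (model covariates).
#' @param bd_fit fitted bulk density model, or `NULL` to skip screening.
#' @inheritParams screen_bulk_density
#' @return list with `horizons`, `carbon_report`, `bd_report`,
#'   `unusable_sites`.
#' @export
qc_profiles <- function(horizons, sites, bd_fit = NULL,
                        rel_diff_max = 0.40, bd_max = 2.0) {
  imp <- impute_missing_carbon(horizons)
  unusable <- attr(imp$report, "unusable_sites")
  h <- imp$horizons[!imp$horizons$site_id %in% unusable, ]
  bd_report <- NULL
  if (!is.null(bd_fit)) {
    pred <- predict_bd(bd_fit, h, sites)
    scr <- screen_bulk_density(h, pred, rel_diff_max, bd_max)
    h <- scr$horizons
    bd_report <- scr$report
  } else if (anyNA(h$bd_g_cm3)) {
    stop("bulk density model disabled but missing bulk density values remain",
         call. = FALSE)
  }
  list(horizons = h, carbon_report = imp$report, bd_report = bd_report,
       unusable_sites = unusable)
}
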