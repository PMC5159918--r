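#' NWCA-style survey vocabulary
#'
#' The ten reporting groups cross four ecoregions (Coastal Plains CPL,
#' Eastern Mountains & Upper Midwest EMU, Interior Plains IPL, West W) with
#' inland woody/herbaceous wetland classes (PRLW/PRLH); all tidal saline
#' sites are pooled nationally (ALL-) and split into estuarine woody (EW)
#' and herbaceous (EH).
#'
#' @return character vector of level names.
#' @export
reporting_groups <- function() {
  c("ALL-EW", "ALL-EH",
    "EMU-PRLW", "EMU-PRLH", "CPL-PRLW", "CPL-PRLH",
    "IPL-PRLW", "IPL-PRLH", "W-PRLW", "W-PRLH")
}

#' @rdname reporting_groups
#' @export
survey_regions <- function() {
  c("Tidal Saline", "Coastal Plains", "EMU", "Interior Plains", "West")
}

#' @rdname reporting_groups
#' @export
wetland_types <- function() {
  c("EH", "EW", "PRL-EM", "PRL-SS", "PRL-FO", "PRL-f", "PRL-UBAB")
}

#' @rdname reporting_groups
#' @export
disturbance_measures <- function() {
  c("agriculture", "residential_urban", "hydrologic_buffer", "industrial",
    "habitat_modification", "buffer_summary", "hydro_high_impact",
    "hydro_moderate_impact", "soil_heavy_metal", "alien_plant_cover")
}

#' Region implied by a reporting group
#'
#' `ALL-*` groups are Tidal Saline; inland groups map to their ecoregion
#' prefix.
#'
#' @param reporting_group character vector of reporting-group codes.
#' @return character vector of region labels.
#' @export
region_for_group <- function(reporting_group) {
  prefix <- sub("-.*$", "", reporting_group)
  map <- c(ALL = "Tidal Saline", CPL = "Coastal Plains", EMU = "EMU",
           IPL = "Interior Plains", W = "West")
  unname(map[prefix])
}

dist_cols <- function() paste0("dist_", disturbance_measures())

site_schema <- function() {
  c("site_id", "reporting_group", "region", "wetland_type", "hgm_class",
    "tidal_saline", "probability_site", "weight_ha", "impenetrable_depth_cm",
    dist_cols())
}

horizon_schema <- function() {
  c("site_id", "horizon_order", "top_depth_cm", "bottom_depth_cm",
    "organic_flag", "thin_flag", "total_c_pct", "inorg_c_pct", "soc_pct",
    "bd_g_cm3", "bd_source", "ec", "cec", "sand_pct", "silt_pct", "clay_pct")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a site table
#'
#' Checks the documented schema and record invariants: known reporting
#' groups; `tidal_saline` true exactly for `ALL-*` groups; `region`
#' consistent with the reporting group; strictly positive weights (in
#' hectares represented) for probability sites.
#'
#' @param sites a data frame of site records.
#' @return the validated tibble, invisibly unchanged apart from class.
#' @export
validate_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  require_columns(sites, site_schema(), "site")
  bad_group <- !sites$reporting_group %in% reporting_groups()
  if (any(bad_group)) {
    stop(sprintf("unknown reporting_group for site(s): %s",
                 paste(head(sites$site_id[bad_group], 5), collapse = ", ")),
         call. = FALSE)
  }
  expect_tidal <- startsWith(sites$reporting_group, "ALL-")
  if (!identical(as.logical(sites$tidal_saline), expect_tidal)) {
    stop("tidal_saline flag inconsistent with reporting_group (ALL-* groups are tidal saline)",
         call. = FALSE)
  }
  expect_region <- region_for_group(sites$reporting_group)
  if (!identical(as.character(sites$region), expect_region)) {
    stop("region inconsistent with reporting_group", call. = FALSE)
  }
  bad_w <- sites$probability_site &
    (is.na(sites$weight_ha) | sites$weight_ha <= 0)
  if (any(bad_w)) {
    stop(sprintf("non-positive or missing weight_ha for probability site(s): %s",
                 paste(head(sites$site_id[bad_w], 5), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(sites$site_id) > 0) {
    stop("duplicated site_id in site table", call. = FALSE)
  }
  sites
}

#' Validate a horizon table
#'
#' Checks the documented schema and profile invariants: positive thickness,
#' per-site contiguity (each horizon's top equals the previous bottom when
#' ordered by `horizon_order`), percentage ranges, particle-size closure
#' (sand + silt + clay <= 100), and positive bulk density where present.
#' SOC is recomputed as total minus inorganic carbon where both are present;
#' small negative differences (carbonate-rich soils) are clipped to zero
#' with a warning.
#'
#' @param horizons a data frame of horizon records.
#' @param recompute_soc recompute `soc_pct` from total and inorganic carbon
#'   where both are present (default `TRUE`).
#' @return the validated tibble, sorted by site and horizon order.
#' @export
validate_horizons <- function(horizons, recompute_soc = TRUE) {
  horizons <- tibble::as_tibble(horizons)
  require_columns(horizons, horizon_schema(), "horizon")
  horizons <- dplyr::arrange(horizons, .data$site_id, .data$horizon_order)

  bad_depth <- !(horizons$bottom_depth_cm > horizons$top_depth_cm)
  if (any(bad_depth, na.rm = TRUE)) {
    i <- which(bad_depth)[1]
    stop(sprintf("non-positive horizon thickness at site %s (%.1f-%.1f cm)",
                 horizons$site_id[i], horizons$top_depth_cm[i],
                 horizons$bottom_depth_cm[i]), call. = FALSE)
  }

  # contiguity: within each site, top of horizon k equals bottom of k-1
  by_site <- split(seq_len(nrow(horizons)), horizons$site_id)
  for (idx in by_site) {
    top <- horizons$top_depth_cm[idx]
    bot <- horizons$bottom_depth_cm[idx]
    if (abs(top[1]) > 1e-6) {
      stop(sprintf("profile for site %s does not start at the surface (top = %.2f cm)",
                   horizons$site_id[idx[1]], top[1]), call. = FALSE)
    }
    if (length(idx) > 1) {
      gap <- abs(top[-1] - bot[-length(bot)])
      if (any(gap > 1e-6)) {
        k <- which(gap > 1e-6)[1]
        stop(sprintf(
          "overlapping or discontiguous horizons for site %s: [%.1f, %.1f) then [%.1f, %.1f)",
          horizons$site_id[idx[1]], top[k], bot[k], top[k + 1], bot[k + 1]),
          call. = FALSE)
      }
    }
  }

  for (col in c("total_c_pct", "inorg_c_pct", "soc_pct",
                "sand_pct", "silt_pct", "clay_pct")) {
    v <- horizons[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      stop(sprintf("%s outside [0, 100]", col), call. = FALSE)
    }
  }
  psa <- horizons$sand_pct + horizons$silt_pct + horizons$clay_pct
  if (any(psa > 100 + 1e-6, na.rm = TRUE)) {
    stop("sand + silt + clay exceeds 100%", call. = FALSE)
  }
  if (any(horizons$bd_g_cm3 <= 0, na.rm = TRUE)) {
    stop("bulk density must be positive where present", call. = FALSE)
  }

  if (recompute_soc) {
    both <- !is.na(horizons$total_c_pct) & !is.na(horizons$inorg_c_pct)
    soc <- horizons$total_c_pct[both] - horizons$inorg_c_pct[both]
    if (any(soc < -1e-9)) {
      warning(sprintf(
        "%d horizon(s) with inorganic C exceeding total C; SOC clipped to 0",
        sum(soc < -1e-9)), call. = FALSE)
    }
    horizons$soc_pct[both] <- pmax(0, soc)
  }
  horizons
}
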