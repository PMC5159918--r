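# fixture builders: minimal valid tables constructed in code

make_horizons <- function(site_id, bounds, soc, bd,
                          organic = FALSE, total_c = NULL, inorg_c = 0) {
  k <- length(bounds) - 1
  organic <- rep_len(organic, k)
  soc <- rep_len(soc, k)
  bd <- rep_len(bd, k)
  inorg_c <- rep_len(inorg_c, k)
  if (is.null(total_c)) total_c <- soc + inorg_c
  tibble::tibble(
    site_id = site_id,
    horizon_order = seq_len(k),
    top_depth_cm = bounds[-(k + 1)],
    bottom_depth_cm = bounds[-1],
    organic_flag = organic,
    thin_flag = diff(bounds) < 8,
    total_c_pct = total_c,
    inorg_c_pct = inorg_c,
    soc_pct = soc,
    bd_g_cm3 = bd,
    bd_source = ifelse(is.na(bd), NA_character_, "measured"),
    ec = 1, cec = 15,
    sand_pct = ifelse(organic, NA_real_, 40),
    silt_pct = ifelse(organic, NA_real_, 40),
    clay_pct = ifelse(organic, NA_real_, 20))
}

make_sites <- function(site_id, reporting_group = "CPL-PRLW",
                       weight_ha = 1000, probability_site = TRUE,
                       dist = 0) {
  n <- length(site_id)
  reporting_group <- rep_len(reporting_group, n)
  tidal <- startsWith(reporting_group, "ALL-")
  df <- tibble::tibble(
    site_id = site_id,
    reporting_group = reporting_group,
    region = region_for_group(reporting_group),
    wetland_type = ifelse(tidal, "EH", "PRL-FO"),
    hgm_class = ifelse(tidal, "Tidal Fringe", "Riverine"),
    tidal_saline = tidal,
    probability_site = rep_len(probability_site, n),
    weight_ha = rep_len(weight_ha, n),
    impenetrable_depth_cm = NA_real_)
  idx <- matrix(dist, nrow = n, ncol = 10)
  colnames(idx) <- paste0("dist_", disturbance_measures())
  dplyr::bind_cols(df, tibble::as_tibble(idx))
}

# flat thresholds for direct screening tests
flat_thresholds <- function(groups, least = 1, most = 5) {
  dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(reporting_group = g, measure = disturbance_measures(),
                   least_max = least, most_min = most)
  }))
}
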