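#' Configuration for the synthetic survey generator
#'
#' The generator emulates an NWCA-like soil survey: a finite population of
#' wetland sites spread over ten reporting groups, each with a
#' horizon-described profile to 120 cm (or to a shallower impenetrable
#' layer), SOC declining exponentially with depth around organic and
#' mineral profile archetypes, bulk density tied to SOC through a
#' decaying-exponential pedotransfer relation, about a quarter of horizons
#' too thin (< 8 cm) to be lab-sampled, about 30% of bulk densities
#' missing, latent least/intermediate/most disturbance classes expressed
#' through ten stressor indices, and unequal inclusion probabilities by
#' wetland type.
#'
#' @param seed master integer seed; per-stage child seeds are derived
#'   deterministically from it.
#' @param n_population_sites finite population size.
#' @param n_sampled_sites default sample size for [sample_survey()].
#' @param frame_area_ha total area (ha) represented by the population;
#'   each population site represents `frame_area_ha / n_population_sites`.
#' @param group_mix named proportions over [reporting_groups()], sum 1.
#' @param organic_fraction_by_group named probability that a site in each
#'   group follows the organic-soil archetype.
#' @param archetypes per-archetype surface SOC mean (%) and exponential
#'   depth-decay rate (per cm).
#' @param soc_noise_sd lognormal (log-scale) noise on horizon SOC.
#' @param bd_relation bulk density relation rho_d = a * exp(-b * SOC) +
#'   N(0, noise_sd), truncated to (0.05, 2.0].
#' @param thin_horizon_rate fraction of horizons generated thin (< 8 cm,
#'   not sampled: chemistry and bulk density missing).
#' @param bd_missing_rate fraction of sampled horizons with missing bulk
#'   density.
#' @param bd_gross_error_rate fraction of measured bulk densities replaced
#'   by an erroneous value > 2.0 g cm-3 (exercises the QC screen).
#' @param disturbance_class_mix latent class proportions, sum 1.
#' @param disturbance_effect multiplicative SOC reduction at most
#'   disturbed sites: factor falls linearly from 1 at the surface to
#'   `most_factor` at `ramp_depth_cm`; intermediate sites get half the
#'   reduction. A convenience for exercising the gradient contrast, not a
#'   mechanistic claim.
#' @param disturbance_severity lognormal median index severity by latent
#'   class, log-sd, and gamma jitter shape across the ten measures.
#' @param impenetrable_prob probability of an impenetrable layer above
#'   120 cm (depth uniform on 30-110 cm), giving varying sample sizes by
#'   depth.
#' @param mineral_organic_cap_prob probability a mineral-archetype site
#'   carries a thin (< 25 cm) organic surface cap (never enough to pass
#'   the organic-soil rules).
#' @param inclusion_probability_by_type named relative inclusion
#'   probabilities over [wetland_types()].
#' @param depth_breaks reporting depth increment boundaries (cm).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1,
    n_population_sites = 2000,
    n_sampled_sites = 200,
    frame_area_ha = 25.2e6,
    group_mix = c("ALL-EW" = 0.02, "ALL-EH" = 0.07,
                  "EMU-PRLW" = 0.14, "EMU-PRLH" = 0.08,
                  "CPL-PRLW" = 0.17, "CPL-PRLH" = 0.12,
                  "IPL-PRLW" = 0.08, "IPL-PRLH" = 0.10,
                  "W-PRLW" = 0.10, "W-PRLH" = 0.12),
    organic_fraction_by_group = c("ALL-EW" = 0.15, "ALL-EH" = 0.20,
                                  "EMU-PRLW" = 0.35, "EMU-PRLH" = 0.30,
                                  "CPL-PRLW" = 0.15, "CPL-PRLH" = 0.12,
                                  "IPL-PRLW" = 0.08, "IPL-PRLH" = 0.08,
                                  "W-PRLW" = 0.10, "W-PRLH" = 0.10),
    archetypes = list(
      organic = list(soc_surface_mean_pct = 35, depth_decay_rate = 0.004),
      mineral = list(soc_surface_mean_pct = 8, depth_decay_rate = 0.025)),
    soc_noise_sd = 0.30,
    bd_relation = list(a = 1.6, b = 0.08, noise_sd = 0.1),
    thin_horizon_rate = 0.25,
    bd_missing_rate = 0.30,
    bd_gross_error_rate = 0.02,
    disturbance_class_mix = c(least = 0.25, intermediate = 0.45,
                              most = 0.30),
    disturbance_effect = list(most_factor = 0.6, ramp_depth_cm = 90),
    disturbance_severity = list(least = 0.3, intermediate = 1.2,
                                most = 3.5, sdlog = 0.3, shape = 4),
    impenetrable_prob = 0.15,
    mineral_organic_cap_prob = 0.20,
    inclusion_probability_by_type = c("EH" = 2.0, "EW" = 2.0,
                                      "PRL-EM" = 1.0, "PRL-SS" = 0.8,
                                      "PRL-FO" = 0.8, "PRL-f" = 1.5,
                                      "PRL-UBAB" = 1.2),
    depth_breaks = c(0, 30, 60, 90, 120)) {
  cfg <- list(seed = as.integer(seed),
              n_population_sites = as.integer(n_population_sites),
              n_sampled_sites = as.integer(n_sampled_sites),
              frame_area_ha = frame_area_ha,
              group_mix = group_mix,
              organic_fraction_by_group = organic_fraction_by_group,
              archetypes = archetypes,
              soc_noise_sd = soc_noise_sd,
              bd_relation = bd_relation,
              thin_horizon_rate = thin_horizon_rate,
              bd_missing_rate = bd_missing_rate,
              bd_gross_error_rate = bd_gross_error_rate,
              disturbance_class_mix = disturbance_class_mix,
              disturbance_effect = disturbance_effect,
              disturbance_severity = disturbance_severity,
              impenetrable_prob = impenetrable_prob,
              mineral_organic_cap_prob = mineral_organic_cap_prob,
              inclusion_probability_by_type = inclusion_probability_by_type,
              depth_breaks = depth_breaks)
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_sampled_sites > cfg$n_population_sites) {
    stop("n_sampled_sites exceeds n_population_sites", call. = FALSE)
  }
  if (abs(sum(cfg$group_mix) - 1) > 1e-9) {
    stop("group_mix proportions must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$group_mix), reporting_groups())) {
    stop("group_mix must be named by the ten reporting groups", call. = FALSE)
  }
  if (abs(sum(cfg$disturbance_class_mix) - 1) > 1e-9) {
    stop("disturbance_class_mix proportions must sum to 1", call. = FALSE)
  }
  rates <- c(cfg$thin_horizon_rate, cfg$bd_missing_rate,
             cfg$bd_gross_error_rate, cfg$impenetrable_prob,
             cfg$mineral_organic_cap_prob,
             cfg$organic_fraction_by_group)
  if (any(rates < 0 | rates > 1)) {
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$inclusion_probability_by_type <= 0)) {
    stop("inclusion probabilities must be positive", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# SOC disturbance reduction factor at depth d for a latent class
disturbance_soc_factor <- function(depth_cm, class, effect) {
  ramp <- pmin(depth_cm, effect$ramp_depth_cm) / effect$ramp_depth_cm
  reduction <- (1 - effect$most_factor) * ramp
  ifelse(class == "most", 1 - reduction,
         ifelse(class == "intermediate", 1 - reduction / 2, 1))
}

# horizon boundaries for one profile: thin horizons at the configured
# rate, forced breakpoints (organic cap / organic-mineral transition).
# When thin_rate is 0 every horizon must come out >= 8 cm, so truncation
# slivers are merged and a breakpoint too close to either end is skipped
# (the caller detects the skip by its absence from the result).
profile_boundaries <- function(depth, thin_rate, breakpoint = NULL) {
  min_thick <- if (thin_rate <= 0) 8 else 1
  bounds <- 0
  while (max(bounds) < depth) {
    thick <- if (runif(1) < thin_rate) round(runif(1, 2, 7.8), 1)
             else round(min(max(exp(rnorm(1, log(18), 0.45)), 8), 60), 1)
    bounds <- c(bounds, min(max(bounds) + thick, depth))
  }
  k <- length(bounds)
  if (k > 2 && bounds[k] - bounds[k - 1] < min_thick - 1e-6) {
    bounds <- bounds[-(k - 1)]
  }
  if (!is.null(breakpoint) && breakpoint >= min_thick - 1e-6 &&
      breakpoint <= depth - min_thick + 1e-6) {
    drop <- abs(bounds - breakpoint) < min_thick - 1e-6 & bounds != 0 &
      bounds != depth
    bounds <- sort(unique(c(bounds[!drop], breakpoint)))
  }
  unique(round(bounds, 1))
}

#' Generate a synthetic wetland survey population
#'
#' Produces a site table, a horizon table with realistic missingness, and
#' a `ground_truth` object computed from the complete (pre-missingness)
#' values. Output is deterministic for a fixed seed.
#'
#' The ground truth holds each site's true depth-range carbon densities
#' plus exact population means and totals (census aggregation with each
#' site weighted by its represented unit area) for the national
#' population and every region, carbon type, soil class and disturbance
#' class — the oracle against which design-based estimates from
#' [sample_survey()] draws are judged.
#'
#' @param config a [simulation_config()].
#' @return object of class `wetcarbon_sim`: list with `sites`,
#'   `horizons`, `truth` (list: `per_site`, `totals`, `unit_area_ha`,
#'   `horizons_true`), and `config`.
#' @export
generate_population <- function(config = simulation_config()) {
  cfg <- validate_simulation_config(config)
  n <- cfg$n_population_sites
  unit_area <- cfg$frame_area_ha / n

  set.seed(cfg$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1, 3)

  ## --- sites -----------------------------------------------------------
  set.seed(stage_seed[1])
  group <- sample(names(cfg$group_mix), n, replace = TRUE,
                  prob = cfg$group_mix)
  region <- region_for_group(group)
  tidal <- startsWith(group, "ALL-")
  wtype <- character(n)
  wtype[group == "ALL-EW"] <- "EW"
  wtype[group == "ALL-EH"] <- "EH"
  woody <- endsWith(group, "PRLW")
  herb <- endsWith(group, "PRLH")
  wtype[woody] <- sample(c("PRL-SS", "PRL-FO"), sum(woody), replace = TRUE,
                         prob = c(0.4, 0.6))
  wtype[herb] <- sample(c("PRL-EM", "PRL-f", "PRL-UBAB"), sum(herb),
                        replace = TRUE, prob = c(0.7, 0.1, 0.2))
  hgm <- ifelse(tidal, "Tidal Fringe",
                sample(c("Depression", "Riverine", "Slope", "Flat",
                         "Lacustrine Fringe"), n, replace = TRUE,
                       prob = c(0.35, 0.3, 0.1, 0.15, 0.1)))
  arche <- unname(ifelse(runif(n) < cfg$organic_fraction_by_group[group],
                         "organic", "mineral"))
  dclass <- sample(names(cfg$disturbance_class_mix), n, replace = TRUE,
                   prob = cfg$disturbance_class_mix)
  imp_depth <- ifelse(runif(n) < cfg$impenetrable_prob,
                      round(runif(n, 30, 110), 1), NA_real_)

  sev_cfg <- cfg$disturbance_severity
  sev_med <- c(least = sev_cfg$least, intermediate = sev_cfg$intermediate,
               most = sev_cfg$most)[dclass]
  severity <- rlnorm(n, log(sev_med), sev_cfg$sdlog)
  idx_mat <- severity *
    matrix(rgamma(n * 10, shape = sev_cfg$shape, rate = sev_cfg$shape),
           nrow = n)
  colnames(idx_mat) <- dist_cols()

  sites <- tibble::tibble(
    site_id = sprintf("S%05d", seq_len(n)),
    reporting_group = group, region = region, wetland_type = wtype,
    hgm_class = hgm, tidal_saline = tidal,
    probability_site = TRUE, weight_ha = unit_area,
    impenetrable_depth_cm = imp_depth)
  sites <- dplyr::bind_cols(sites, tibble::as_tibble(idx_mat))

  ## --- horizons --------------------------------------------------------
  set.seed(stage_seed[2])
  ec_site <- ifelse(tidal, rlnorm(n, log(20), 0.5), rlnorm(n, log(1), 0.8))
  org_pars <- cfg$archetypes$organic
  min_pars <- cfg$archetypes$mineral
  bd_rel <- cfg$bd_relation

  hz_list <- vector("list", n)
  for (i in seq_len(n)) {
    depth <- if (is.na(imp_depth[i])) 120 else min(120, imp_depth[i])
    if (arche[i] == "organic") {
      brk <- round(runif(1, 45, 120), 1)
      if (brk >= depth) brk <- NULL
    } else if (runif(1) < cfg$mineral_organic_cap_prob &&
               depth >= 40) {
      brk <- round(runif(1, 5, 25), 1)
    } else {
      brk <- NULL
    }
    bounds <- profile_boundaries(depth, cfg$thin_horizon_rate, brk)
    # a thin organic cap that could not be split off is dropped entirely;
    # it must never inflate a mineral site's organic thickness
    if (arche[i] == "mineral" && !is.null(brk) && !(brk %in% bounds)) {
      brk <- NULL
    }
    top <- bounds[-length(bounds)]
    bot <- bounds[-1]
    k <- length(top)
    mid <- (top + bot) / 2

    if (arche[i] == "organic") {
      org_flag <- if (is.null(brk)) rep(TRUE, k) else top < brk - 1e-9
    } else {
      org_flag <- if (is.null(brk)) rep(FALSE, k) else top < brk - 1e-9
    }

    s0 <- ifelse(org_flag, org_pars$soc_surface_mean_pct,
                 min_pars$soc_surface_mean_pct)
    kdec <- ifelse(org_flag, org_pars$depth_decay_rate,
                   min_pars$depth_decay_rate)
    soc <- s0 * exp(-kdec * mid) *
      exp(rnorm(k, 0, cfg$soc_noise_sd)) *
      disturbance_soc_factor(mid, dclass[i], cfg$disturbance_effect)
    soc <- pmin(pmax(soc, 0.05), 55)

    inorg <- ifelse(org_flag, 0, pmin(rexp(k, rate = 2.5), 3))
    bd_true <- bd_rel$a * exp(-bd_rel$b * soc) +
      rnorm(k, 0, bd_rel$noise_sd)
    bd_true <- pmin(pmax(bd_true, 0.05), 2.0)

    psa <- matrix(rgamma(3 * k, shape = c(2, 2, 1)), nrow = 3)
    psa <- 100 * sweep(psa, 2, colSums(psa), "/")
    sand <- ifelse(org_flag, NA_real_, round(psa[1, ], 1))
    silt <- ifelse(org_flag, NA_real_, round(psa[2, ], 1))
    clay <- ifelse(org_flag, NA_real_,
                   pmax(round(100 - sand - silt, 1), 0))

    ec <- ec_site[i] * exp(rnorm(k, 0, 0.2))
    cec <- pmax(10 + 1.2 * soc + 0.15 * ifelse(is.na(clay), 0, clay) +
                  rnorm(k, 0, 3), 1)

    hz_list[[i]] <- tibble::tibble(
      site_id = sites$site_id[i],
      horizon_order = seq_len(k),
      top_depth_cm = top, bottom_depth_cm = bot,
      organic_flag = org_flag,
      thin_flag = (bot - top) < 8 - 1e-6,
      total_c_pct = soc + inorg, inorg_c_pct = inorg, soc_pct = soc,
      bd_g_cm3 = bd_true, bd_source = "measured",
      ec = ec, cec = cec,
      sand_pct = sand, silt_pct = silt, clay_pct = clay)
  }
  horizons_true <- dplyr::bind_rows(hz_list)

  ## --- ground truth (complete data, census aggregation) ----------------
  brks <- cfg$depth_breaks
  ranges <- c(lapply(seq_len(length(brks) - 1),
                     function(j) c(brks[j], brks[j + 1])),
              list(c(min(brks), max(brks))))
  per_site <- site_depth_densities(horizons_true, ranges = ranges,
                                   max_depth_cm = max(brks))
  truth_labels <- tibble::tibble(
    site_id = sites$site_id,
    region = sites$region,
    carbon_type = carbon_type(sites$tidal_saline),
    soil_class = arche,
    disturbance_class = dclass,
    weight_ha = unit_area)
  per_site <- dplyr::left_join(truth_labels, per_site, by = "site_id")
  totals <- estimate_all(per_site) |>
    dplyr::select("grouping", "subpopulation", "depth_lo_cm",
                  "depth_hi_cm", "n_sites", "area_Mha",
                  true_mean_tC_ha = "mean_tC_ha",
                  true_total_PgC = "total_PgC")

  ## --- inject missingness ----------------------------------------------
  set.seed(stage_seed[3])
  horizons <- horizons_true
  thin <- horizons$thin_flag
  lab_cols <- c("total_c_pct", "inorg_c_pct", "soc_pct", "bd_g_cm3",
                "ec", "cec", "sand_pct", "silt_pct", "clay_pct")
  for (col in lab_cols) horizons[[col]][thin] <- NA_real_
  horizons$bd_source[thin] <- NA_character_

  m <- nrow(horizons)
  gross <- !thin & runif(m) < cfg$bd_gross_error_rate
  horizons$bd_g_cm3[gross] <- runif(sum(gross), 2.05, 2.6)
  bd_miss <- !thin & !gross & runif(m) < cfg$bd_missing_rate
  horizons$bd_g_cm3[bd_miss] <- NA_real_
  horizons$bd_source[bd_miss] <- NA_character_

  structure(
    list(sites = validate_sites(sites),
         horizons = validate_horizons(horizons, recompute_soc = FALSE),
         truth = list(per_site = per_site, totals = totals,
                      unit_area_ha = unit_area,
                      horizons_true = horizons_true),
         config = cfg),
    class = "wetcarbon_sim")
}

# fixed-size inclusion probabilities proportional to p, capped at 1
inclusion_probabilities <- function(p, n) {
  if (any(p <= 0)) stop("inclusion probabilities must be positive",
                        call. = FALSE)
  pik <- rep(0, length(p))
  active <- rep(TRUE, length(p))
  n_left <- n
  repeat {
    pik[active] <- n_left * p[active] / sum(p[active])
    over <- active & pik >= 1
    if (!any(pik[active] > 1 + 1e-12)) break
    pik[over] <- 1
    active <- active & !over
    n_left <- n - sum(pik >= 1)
  }
  pmin(pik, 1)
}

#' Draw an unequal-probability sample from a synthetic population
#'
#' Fixed-size systematic probability-proportional-to-size sampling on a
#' randomly permuted frame, with inclusion probabilities proportional to
#' the configured relative probability of the site's wetland type
#' (capped at 1). Each sampled site's weight is its represented area,
#' `unit_area_ha / pi_i`, so the weighted site count estimates the
#' population size and weighted totals are unbiased (Horvitz-Thompson)
#' for population totals. Optionally appends hand-picked
#' non-probability sites (no weight) for threshold calibration.
#'
#' @param sim a `wetcarbon_sim` population.
#' @param n sample size; defaults to the configured `n_sampled_sites`.
#' @param seed integer seed for the draw.
#' @param n_nonprobability number of extra non-probability sites.
#' @return site tibble of sampled rows with `weight_ha` and
#'   `probability_site` set.
#' @export
sample_survey <- function(sim, n = NULL, seed = 1, n_nonprobability = 0) {
  stopifnot(inherits(sim, "wetcarbon_sim"))
  cfg <- sim$config
  if (is.null(n)) n <- cfg$n_sampled_sites
  sites <- sim$sites
  N <- nrow(sites)
  if (n > N) stop("sample size exceeds population size", call. = FALSE)
  p <- cfg$inclusion_probability_by_type[sites$wetland_type]
  pik <- inclusion_probabilities(unname(p), n)

  set.seed(seed)
  perm <- sample.int(N)
  cum <- cumsum(pik[perm])
  points <- runif(1) + seq_len(n) - 1
  pos <- findInterval(points, cum, left.open = TRUE) + 1
  chosen <- perm[pos]

  out <- sites[sort(chosen), ]
  out$weight_ha <- sim$truth$unit_area_ha / pik[sort(chosen)]
  out$probability_site <- TRUE

  if (n_nonprobability > 0) {
    rest <- setdiff(seq_len(N), chosen)
    extra <- sites[sort(sample(rest, min(n_nonprobability, length(rest)))), ]
    extra$weight_ha <- NA_real_
    extra$probability_site <- FALSE
    out <- dplyr::bind_rows(out, extra)
  }
  out
}
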