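test_that("generation is deterministic for a fixed seed", {
  cfg <- simulation_config(seed = 9, n_population_sites = 120,
                           n_sampled_sites = 30)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$horizons, b$horizons)
  expect_identical(a$truth$totals, b$truth$totals)
  sa <- sample_survey(a, seed = 4)
  sb <- sample_survey(b, seed = 4)
  expect_identical(sa, sb)
})

test_that("configured rates drive thin horizons and missing bulk density", {
  cfg0 <- simulation_config(seed = 3, n_population_sites = 150,
                            n_sampled_sites = 30, thin_horizon_rate = 0,
                            bd_missing_rate = 0, bd_gross_error_rate = 0)
  s0 <- generate_population(cfg0)
  expect_false(any(s0$horizons$thin_flag))
  expect_false(anyNA(s0$horizons$bd_g_cm3))

  h <- shared_sim$horizons   # default 25% / 30% rates
  expect_gt(mean(h$thin_flag), 0.15)
  expect_lt(mean(h$thin_flag), 0.35)
  miss <- mean(is.na(h$bd_g_cm3[!h$thin_flag]))
  expect_gt(miss, 0.22)
  expect_lt(miss, 0.38)
  # generated tables satisfy the schema invariants by construction
  expect_silent(validate_sites(shared_sim$sites))
  expect_silent(validate_horizons(shared_sim$horizons,
                                  recompute_soc = FALSE))
})

test_that("ground truth equals a census recomputation from the horizons", {
  cfg <- simulation_config(seed = 21, n_population_sites = 100,
                           n_sampled_sites = 20, thin_horizon_rate = 0,
                           bd_missing_rate = 0, bd_gross_error_rate = 0)
  sim <- generate_population(cfg)
  # no missingness: the emitted horizon table is the complete data
  expect_equal(sim$horizons$bd_g_cm3, sim$truth$horizons_true$bd_g_cm3)
  per_site <- site_depth_densities(sim$horizons)
  labels <- sim$truth$per_site[, c("site_id", "region", "carbon_type",
                                   "soil_class", "disturbance_class",
                                   "weight_ha")]
  redo <- estimate_all(dplyr::left_join(labels, per_site, by = "site_id"))
  expect_equal(redo$total_PgC, sim$truth$totals$true_total_PgC,
               tolerance = 1e-12)
  expect_equal(redo$mean_tC_ha, sim$truth$totals$true_mean_tC_ha,
               tolerance = 1e-12)
})

test_that("profiles reach 120 cm unless an impenetrable layer intervenes", {
  bot <- tapply(shared_sim$horizons$bottom_depth_cm,
                shared_sim$horizons$site_id, max)
  imp <- setNames(shared_sim$sites$impenetrable_depth_cm,
                  shared_sim$sites$site_id)[names(bot)]
  expect_equal(as.numeric(bot[is.na(imp)]),
               rep(120, sum(is.na(imp))))
  expect_equal(as.numeric(bot[!is.na(imp)]),
               as.numeric(pmin(imp[!is.na(imp)], 120)))
})

test_that("census and equal-probability draws reduce to textbook designs", {
  cfg <- simulation_config(seed = 5, n_population_sites = 80,
                           n_sampled_sites = 80)
  sim <- generate_population(cfg)
  census <- sample_survey(sim, n = 80, seed = 1)
  expect_equal(nrow(census), 80)
  expect_equal(census$weight_ha, rep(sim$truth$unit_area_ha, 80))

  cfg_eq <- simulation_config(
    seed = 5, n_population_sites = 80, n_sampled_sites = 20,
    inclusion_probability_by_type = setNames(rep(1, 7), wetland_types()))
  sim_eq <- generate_population(cfg_eq)
  s <- sample_survey(sim_eq, n = 20, seed = 2)
  expect_equal(nrow(s), 20)
  expect_equal(unique(s$weight_ha), sim_eq$truth$unit_area_ha * 80 / 20)

  expect_error(sample_survey(sim, n = 100), "exceeds")
  expect_error(simulation_config(
    inclusion_probability_by_type = setNames(rep(0, 7), wetland_types())),
    "positive")
  expect_error(simulation_config(n_population_sites = 10,
                                 n_sampled_sites = 20), "exceeds")
  expect_error(simulation_config(thin_horizon_rate = 1.2), "rates")
})

test_that("weighted site counts estimate the population size without bias", {
  sim <- shared_sim  # 600 sites, unequal probabilities by wetland type
  n_hat <- vapply(1:200, function(r) {
    s <- sample_survey(sim, n = 60, seed = 5000 + r)
    sum(s$weight_ha) / sim$truth$unit_area_ha
  }, numeric(1))
  mc_se <- sd(n_hat) / sqrt(length(n_hat))
  expect_lt(abs(mean(n_hat) - 600), 3 * mc_se + 1e-9)
  # non-probability add-ons are flagged and unweighted
  s <- sample_survey(sim, n = 50, seed = 77, n_nonprobability = 10)
  expect_equal(sum(!s$probability_site), 10)
  expect_true(all(is.na(s$weight_ha[!s$probability_site])))
  expect_silent(validate_sites(s))
})
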