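test_that("equal weights reduce the estimator to sample means", {
  d <- tibble::tibble(weight_ha = rep(500, 6),
                      d0_120 = c(100, 150, 200, 250, 300, 350))
  est <- estimate_subpopulation(d, "d0_120", depth_lo_cm = 0,
                                depth_hi_cm = 120)
  expect_equal(est$mean_tC_ha, mean(d$d0_120))
  expect_equal(est$total_PgC, 6 * 500 * mean(d$d0_120) / 1e9)
  expect_equal(est$n_sites, 6L)
  expect_equal(est$area_Mha, 3000 / 1e6)
})

test_that("a single-site estimate follows the unit chain", {
  d <- tibble::tibble(weight_ha = 1e6, d0_120 = 400)
  est <- estimate_subpopulation(d, "d0_120")
  expect_equal(est$total_PgC, 0.4)
  expect_equal(est$mean_tC_ha, 400)
  expect_true(is.na(est$se_total))

  empty <- estimate_subpopulation(d[0, ], "d0_120", "void")
  expect_equal(empty$n_sites, 0L)
  expect_true(is.na(empty$total_PgC))
})

test_that("population estimate internal identity holds (total = mean x area)", {
  s <- sample_survey(shared_sim, seed = 12)
  d <- dplyr::left_join(s[, c("site_id", "weight_ha")],
                        shared_sim$truth$per_site, by = "site_id",
                        suffix = c("", ".t"))
  est <- estimate_all(d, groupings = c("region", "carbon_type"))
  filled <- est[est$n_sites > 0, ]
  expect_equal(filled$total_PgC,
               filled$mean_tC_ha * filled$area_Mha * 1e6 * 1e6 / 1e15,
               tolerance = 1e-9)
})

test_that("subpopulation totals add up over a partition", {
  s <- sample_survey(shared_sim, seed = 8)
  d <- dplyr::left_join(s[, c("site_id", "weight_ha")],
                        shared_sim$truth$per_site, by = "site_id",
                        suffix = c("", ".t"))
  est <- estimate_all(d, groupings = c("carbon_type", "region"))
  for (rng in list(c(0, 30), c(0, 120))) {
    nat <- est$total_PgC[est$grouping == "national" &
                           est$depth_lo_cm == rng[1] &
                           est$depth_hi_cm == rng[2]]
    ct <- est$total_PgC[est$grouping == "carbon_type" &
                          est$depth_lo_cm == rng[1] &
                          est$depth_hi_cm == rng[2]]
    rg <- est$total_PgC[est$grouping == "region" &
                          est$depth_lo_cm == rng[1] &
                          est$depth_hi_cm == rng[2]]
    expect_equal(sum(ct), nat, tolerance = 1e-12)  # blue + teal
    expect_equal(sum(rg), nat, tolerance = 1e-12)
  }
})

test_that("standard errors shrink like 1/sqrt(n)", {
  ns <- c(40, 80, 160, 320)
  ps <- shared_sim$truth$per_site[, c("site_id", "d0_120")]
  mean_se <- vapply(ns, function(n) {
    mean(vapply(1:30, function(r) {
      s <- sample_survey(shared_sim, n = n, seed = 300 * n + r)
      d <- dplyr::left_join(s[, c("site_id", "weight_ha")], ps,
                            by = "site_id")
      estimate_subpopulation(d, "d0_120")$se_total
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(mean_se) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("target-population scaling rescales totals only", {
  est <- tibble::tibble(subpopulation = "National", depth_lo_cm = 0,
                        depth_hi_cm = 120, n_sites = 100L, area_Mha = 25.2,
                        mean_tC_ha = 299, se_mean = 10,
                        total_PgC = 7.54, se_total = 0.59)
  same <- scale_to_target(est, 25.2, 25.2)
  expect_equal(same$total_PgC, 7.54)
  expect_equal(same$mean_tC_ha, 299)

  up <- scale_to_target(est, 25.2, 38.4)
  expect_equal(up$total_PgC, 7.54 * 38.4 / 25.2, tolerance = 1e-12)
  expect_equal(round(up$total_PgC, 2), 11.49)
  expect_equal(up$mean_tC_ha, est$mean_tC_ha)   # density invariant
  expect_equal(up$area_Mha, 38.4)
  expect_true(is.na(up$se_total) && is.na(up$se_mean))
  expect_error(scale_to_target(est, 0, 38.4), "positive")
  expect_error(scale_to_target(est, 25.2, -1), "positive")
})

test_that("share helpers compute depth and partition percentages", {
  expect_equal(depth_shares(c(2, 2, 2, 2)), rep(25, 4))
  expect_equal(pct_share(0.76, 7.54), 100 * 0.76 / 7.54)
  expect_error(depth_shares(c(0, 0)), "zero")
  expect_error(pct_share(1, 0), "zero")
})
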