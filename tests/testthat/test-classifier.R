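org_min <- function(id, bounds, organic) {
  make_horizons(id, bounds, soc = 10, bd = 1, organic = organic)
}

test_that("histosol rule truth table covers every branch and boundary", {
  # rule (a): organic throughout the top 40 cm
  expect_equal(classify_soil(org_min("a1", c(0, 45, 120), c(TRUE, FALSE))),
               "organic")
  expect_equal(classify_soil(org_min("a2", c(0, 40, 120), c(TRUE, FALSE))),
               "organic")  # organic to exactly 40
  expect_equal(classify_soil(org_min("a3", c(0, 39, 120), c(TRUE, FALSE))),
               "mineral")  # mineral horizon starts above 40, (b) fails too

  # all-mineral profile
  expect_equal(classify_soil(org_min("m", c(0, 60, 120), c(FALSE, FALSE))),
               "mineral")

  # rule (b): >= 40 organic cm within the top 80
  expect_equal(classify_soil(
    org_min("b1", c(0, 20, 50, 75), c(TRUE, FALSE, TRUE))), "organic") # 45 cm
  expect_equal(classify_soil(
    org_min("b2", c(0, 20, 60, 80, 120), c(TRUE, FALSE, TRUE, FALSE))),
    "organic")  # exactly 40 of the top 80
  expect_equal(classify_soil(
    org_min("b3", c(0, 19, 60, 80, 120), c(TRUE, FALSE, TRUE, FALSE))),
    "mineral")  # 39 cm falls short
  # organic below 80 cm does not count toward rule (b)
  expect_equal(classify_soil(
    org_min("b4", c(0, 30, 80, 120), c(TRUE, FALSE, TRUE))), "mineral")

  # rule (c): impenetrable layer above 40 cm
  expect_equal(classify_soil(
    org_min("c1", c(0, 26, 35), c(TRUE, FALSE)),
    impenetrable_depth_cm = 35), "organic")   # 26/35 >= 2/3, mineral 9 < 10
  expect_equal(classify_soil(
    org_min("c2", c(0, 25, 35), c(TRUE, FALSE)),
    impenetrable_depth_cm = 35), "mineral")   # mineral exactly 10: fails
  expect_equal(classify_soil(
    org_min("c3", c(0, 20, 35), c(TRUE, FALSE)),
    impenetrable_depth_cm = 35), "mineral")   # organic 20/35 < 2/3
  # no recorded impenetrable layer: shallow organic profile is not enough
  expect_equal(classify_soil(org_min("c4", c(0, 30), TRUE)), "mineral")
  # impenetrable at/below 40 does not trigger rule (c)
  expect_equal(classify_soil(org_min("c5", c(0, 30, 45), c(TRUE, FALSE)),
                             impenetrable_depth_cm = 45), "mineral")

  expect_error(classify_soil(org_min("e", c(0, 50), NA)), "organic_flag")
})

test_that("classification is invariant to horizon subdivision", {
  set.seed(7)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    bounds <- round(c(0, sort(runif(k - 1, 5, 115)), 120), 1)
    if (any(diff(bounds) < 2)) next
    flags <- runif(k) < 0.5
    p <- org_min("sub", bounds, flags)
    cls <- classify_soil(p)
    # split horizon j at its midpoint, duplicating its flag
    j <- sample(k, 1)
    mid <- (bounds[j] + bounds[j + 1]) / 2
    bounds2 <- sort(c(bounds, mid))
    flags2 <- append(flags, flags[j], after = j)
    p2 <- org_min("sub2", bounds2, flags2)
    expect_equal(classify_soil(p2), cls)
  }
})

test_that("generator archetypes are recovered by the classifier", {
  got <- classify_soil_sites(shared_sim$truth$horizons_true,
                             shared_sim$sites)
  truth <- shared_sim$truth$per_site
  m <- match(got$site_id, truth$site_id)
  expect_equal(unname(got$soil_class), truth$soil_class[m])
})

test_that("carbon type is a total two-way split on the tidal flag", {
  expect_equal(carbon_type(c(TRUE, FALSE)), c("blue", "teal"))
  s <- make_sites(c("t1", "t2"), reporting_group = c("ALL-EH", "CPL-PRLH"))
  expect_equal(carbon_type(s$tidal_saline), c("blue", "teal"))
  expect_error(carbon_type(c(TRUE, NA)))
  expect_true(all(carbon_type(shared_sim$sites$tidal_saline) %in%
                    c("blue", "teal")))
})
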