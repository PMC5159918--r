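test_that("threshold screening separates least, intermediate and most", {
  th <- flat_thresholds("CPL-PRLW", least = 1, most = 5)
  lm <- setNames(th$least_max, th$measure)
  mm <- setNames(th$most_min, th$measure)
  idx <- setNames(rep(0, 10), disturbance_measures())

  expect_equal(screen_site(idx, lm, mm), "least")
  idx2 <- idx; idx2[3] <- 6                      # any single exceedance
  expect_equal(screen_site(idx2, lm, mm), "most")
  idx3 <- idx; idx3[] <- 3                       # between the vectors
  expect_equal(screen_site(idx3, lm, mm), "intermediate")
  idx4 <- idx; idx4[7] <- NA
  expect_true(is.na(screen_site(idx4, lm, mm)))
  # least compliance is non-strict at the boundary, most is strict
  idx5 <- idx; idx5[] <- 1
  expect_equal(screen_site(idx5, lm, mm), "least")
  idx6 <- idx; idx6[1] <- 5
  expect_equal(screen_site(idx6, lm, mm), "intermediate")
})

test_that("screening is monotone in every index", {
  rank <- c(least = 1, intermediate = 2, most = 3)
  th <- flat_thresholds("CPL-PRLW", least = 1, most = 4)
  lm <- setNames(th$least_max, th$measure)
  mm <- setNames(th$most_min, th$measure)
  set.seed(31)
  for (rep in 1:60) {
    idx <- setNames(rexp(10, 1 / 2), disturbance_measures())
    before <- screen_site(idx, lm, mm)
    j <- sample(10, 1)
    idx[j] <- idx[j] + rexp(1, 1 / 3)
    after <- screen_site(idx, lm, mm)
    expect_gte(rank[after], rank[before])
  }
})

test_that("calibration hits the target most fraction and is monotone in it", {
  sites <- shared_sim$sites
  suppressMessages(
    th <- calibrate_thresholds(sites, target_fraction = 0.25,
                               pool_sparse = TRUE))
  expect_true(all(th$least_max <= th$most_min + 1e-9))
  cls <- screen_sites(sites, th)$disturbance_class
  frac <- mean(cls == "most", na.rm = TRUE)
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)

  targets <- c(0.15, 0.20, 0.25, 0.30, 0.40)
  fracs <- vapply(targets, function(t) {
    th_t <- suppressMessages(
      calibrate_thresholds(sites, t, pool_sparse = TRUE))
    cl <- screen_sites(sites, th_t)$disturbance_class
    mean(cl == "most", na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fracs) >= -1e-12))
})

test_that("degenerate identical indices yield fraction 0 with a warning", {
  sites <- make_sites(sprintf("D%02d", 1:25), dist = 1)
  expect_warning(th <- calibrate_thresholds(sites), "unattainable")
  cls <- screen_sites(sites, th)$disturbance_class
  expect_equal(mean(cls == "most"), 0)
})

test_that("sparse groups error unless pooled calibration is requested", {
  sites <- make_sites(sprintf("P%02d", 1:30),
                      reporting_group = c(rep("CPL-PRLW", 25),
                                          rep("W-PRLH", 5)),
                      dist = NA)
  sites[paste0("dist_", disturbance_measures())] <-
    matrix(rexp(300), nrow = 30)
  expect_error(calibrate_thresholds(sites), "W-PRLH.*20")
  expect_message(th <- calibrate_thresholds(sites, pool_sparse = TRUE),
                 "pooled")
  expect_equal(sort(unique(th$reporting_group)), c("CPL-PRLW", "W-PRLH"))
})

test_that("gradient summaries reproduce screened counts and percentages", {
  classes <- rep(c("least", "intermediate", "most"), c(277, 530, 331))
  gs <- gradient_summary(classes)
  expect_equal(gs$n_sites, c(277L, 530L, 331L))
  expect_equal(gs$pct, c(24L, 47L, 29L))
  expect_equal(sum(gs$n_sites), 1138L)

  # permutation invariance and empty input
  gs2 <- gradient_summary(sample(classes))
  expect_equal(gs2, gs)
  expect_equal(gradient_summary(character(0))$n_sites, c(0L, 0L, 0L))

  expect_error(disturbance_thresholds(
    flat_thresholds("CPL-PRLW", least = 6, most = 5)), "least_max")
})
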