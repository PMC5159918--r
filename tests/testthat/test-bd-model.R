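# sites/horizons where bulk density is a clean function of SOC
step_fixture <- function(n = 300, seed = 5) {
  set.seed(seed)
  ids <- sprintf("X%03d", seq_len(n))
  sites <- make_sites(ids)
  soc <- runif(n, 0, 30)
  bd <- ifelse(soc > 10, 0.5, 1.5)
  horizons <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_horizons(ids[i], c(0, 30), soc = soc[i], bd = bd[i])
  }))
  list(sites = sites, horizons = horizons)
}

test_that("a constant response is predicted exactly with zero R2", {
  fx <- step_fixture(100)
  fx$horizons$bd_g_cm3 <- 1.3
  expect_warning(
    fit <- fit_bd_model(fx$horizons, fx$sites,
                        bd_model_spec(n_trees = 50, shrinkage = 0.3,
                                      seed = 3)),
    "degenerate")
  expect_equal(fit$holdout_r2, 0)
  pred <- predict_bd(fit, fx$horizons, fx$sites)
  expect_equal(pred, rep(1.3, 100), tolerance = 1e-6)
})

test_that("a noise-free step function of one predictor is learned almost exactly", {
  fx <- step_fixture(300)
  fit <- fit_bd_model(fx$horizons, fx$sites,
                      bd_model_spec(n_trees = 300, shrinkage = 0.2,
                                    bag_fraction = 1, seed = 3))
  expect_gte(fit$holdout_r2, 0.99)
  expect_equal(names(which.max(fit$importance)), "soc_pct")
})

test_that("fits are deterministic under a fixed seed and importance sums to 100", {
  sim <- shared_sim
  spec <- bd_model_spec(n_trees = 150, shrinkage = 0.1, seed = 11)
  f1 <- fit_bd_model(sim$horizons, sim$sites, spec)
  f2 <- fit_bd_model(sim$horizons, sim$sites, spec)
  expect_identical(f1$holdout_r2, f2$holdout_r2)
  expect_equal(sum(f1$importance), 100, tolerance = 1e-6)
  expect_true(all(f1$importance >= 0))
  p1 <- predict_bd(f1, sim$horizons, sim$sites)
  p2 <- predict_bd(f2, sim$horizons, sim$sites)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1)) && all(p1 > 0))
})

test_that("training loss is monotone non-increasing over boosting iterations", {
  fx <- step_fixture(200, seed = 9)
  fit <- fit_bd_model(fx$horizons, fx$sites,
                      bd_model_spec(n_trees = 60, shrinkage = 0.3,
                                    bag_fraction = 1, train_fraction = 0.9,
                                    seed = 2))
  X <- wetcarbon:::bd_design_matrix(fx$horizons, fx$sites, fit$hgm_levels)
  d <- xgboost::xgb.DMatrix(X[, fit$feature_names], missing = NA)
  y <- fx$horizons$bd_g_cm3
  sse <- vapply(seq(5, 60, by = 5), function(k) {
    sum((y - predict(fit$booster, d, iterationrange = c(1, k)))^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("predictions are truncated to the stated physical interval", {
  fx <- step_fixture(120, seed = 13)
  fit <- fit_bd_model(fx$horizons, fx$sites,
                      bd_model_spec(n_trees = 100, shrinkage = 0.3,
                                    seed = 1))
  # tighten bounds so the truncation path is exercised on real predictions
  expect_message(
    pred <- predict_bd(fit, fx$horizons, fx$sites,
                       lower = 0.6, upper = 1.4),
    "truncated")
  expect_true(all(pred >= 0.6 & pred <= 1.4))
  expect_identical(predict_bd(fit, fx$horizons[0, ], fx$sites), numeric(0))
})

test_that("unseen categorical levels fall back to an 'other' encoding", {
  fx <- step_fixture(150, seed = 17)
  fit <- fit_bd_model(fx$horizons, fx$sites,
                      bd_model_spec(n_trees = 80, shrinkage = 0.2, seed = 4))
  new_sites <- fx$sites
  new_sites$hgm_class[1] <- "Playa"
  expect_warning(pred <- predict_bd(fit, fx$horizons, new_sites),
                 "unseen")
  expect_length(pred, nrow(fx$horizons))
  expect_error(fit_bd_model(fx$horizons[1:20, ], fx$sites,
                            bd_model_spec(n_trees = 10)), ">= 50")
})
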