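#' Bulk density model specification
#'
#' Stagewise gradient-boosted shallow regression trees under squared-error
#' loss predict bulk density (g cm-3) from ten horizon and site
#' covariates: SOC concentration, reporting group, electrical
#' conductivity, cation exchange capacity, horizon mid depth, percent
#' clay, percent silt, HGM class, percent sand, and the 1-based order of
#' the horizon within the profile. 70% of complete records train the
#' model; fit quality is the R-squared (1 - SSE/SST) on the withheld 30%.
#'
#' Hyperparameter defaults follow common boosted-regression-tree practice
#' for pedotransfer modelling: many small steps (`n_trees` = 3000,
#' `shrinkage` = 0.01), shallow trees (`max_tree_depth` = 5), and row
#' subsampling (`bag_fraction` = 0.5). All are configurable.
#'
#' @param n_trees number of boosting iterations.
#' @param shrinkage learning rate in (0, 1].
#' @param max_tree_depth maximum tree depth.
#' @param bag_fraction row subsampling fraction per tree in (0, 1].
#' @param train_fraction fraction of complete records used for training.
#' @param seed integer seed controlling the split and subsampling.
#' @return a `bd_model_spec` list.
#' @export
bd_model_spec <- function(n_trees = 3000, shrinkage = 0.01,
                          max_tree_depth = 5, bag_fraction = 0.5,
                          train_fraction = 0.70, seed = 1) {
  stopifnot(n_trees >= 1, shrinkage > 0, shrinkage <= 1,
            max_tree_depth >= 1, bag_fraction > 0, bag_fraction <= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(n_trees = as.integer(n_trees), shrinkage = shrinkage,
                 max_tree_depth = as.integer(max_tree_depth),
                 bag_fraction = bag_fraction,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "bd_model_spec")
}

bd_predictors <- function() {
  c("soc_pct", "reporting_group", "ec", "cec", "horizon_mid_depth_cm",
    "clay_pct", "silt_pct", "hgm_class", "sand_pct", "horizon_order")
}

# design matrix: numeric covariates as-is (NAs routed by the trees'
# learned default directions), categoricals one-hot against fixed levels
bd_design_matrix <- function(horizons, sites, hgm_levels) {
  m <- match(horizons$site_id, sites$site_id)
  if (anyNA(m)) {
    stop("horizon rows reference site_ids absent from the site table",
         call. = FALSE)
  }
  rg <- factor(sites$reporting_group[m], levels = reporting_groups())
  hgm_raw <- sites$hgm_class[m]
  unseen <- !is.na(hgm_raw) & !hgm_raw %in% hgm_levels
  if (any(unseen)) {
    warning(sprintf(
      "%d horizon(s) with HGM class unseen in training mapped to 'other'",
      sum(unseen)), call. = FALSE)
  }
  hgm <- factor(ifelse(unseen, NA, hgm_raw), levels = hgm_levels)

  onehot <- function(f, prefix) {
    cols <- sapply(levels(f), function(l) as.numeric(!is.na(f) & f == l))
    cols <- matrix(cols, nrow = length(f),
                   dimnames = list(NULL, paste0(prefix, ".", levels(f))))
    cols
  }
  num <- cbind(
    soc_pct = horizons$soc_pct,
    ec = horizons$ec,
    cec = horizons$cec,
    horizon_mid_depth_cm = (horizons$top_depth_cm + horizons$bottom_depth_cm) / 2,
    clay_pct = horizons$clay_pct,
    silt_pct = horizons$silt_pct,
    sand_pct = horizons$sand_pct,
    horizon_order = as.numeric(horizons$horizon_order))
  cbind(num, onehot(rg, "rg"), onehot(hgm, "hgm"))
}

feature_parent <- function(feature_names) {
  parent <- feature_names
  parent[startsWith(feature_names, "rg.")] <- "reporting_group"
  parent[startsWith(feature_names, "hgm.")] <- "hgm_class"
  parent
}

#' Fit the bulk density model
#'
#' Trains on horizons with a usable measured bulk density (0 < bd <=
#' `bd_max`) and non-missing SOC, using a seeded simple random
#' `train_fraction` / holdout split. Reports holdout R-squared and
#' relative variable importance: the share of total squared-error
#' reduction attributable to splits on each predictor, normalized to sum
#' to 100 (one-hot columns are pooled back to their parent predictor).
#'
#' @param horizons validated horizon table.
#' @param sites validated site table.
#' @param spec a [bd_model_spec()].
#' @param bd_max upper limit of a credible measured bulk density.
#' @return object of class `bd_model_fit`: the booster plus
#'   `holdout_r2`, `importance` (named percentages summing to 100),
#'   `n_train`, `n_holdout`.
#' @export
fit_bd_model <- function(horizons, sites, spec = bd_model_spec(),
                         bd_max = 2.0) {
  horizons <- tibble::as_tibble(horizons)
  usable <- !is.na(horizons$bd_g_cm3) & horizons$bd_g_cm3 > 0 &
    horizons$bd_g_cm3 <= bd_max & !is.na(horizons$soc_pct)
  h <- horizons[usable, ]
  if (nrow(h) < 50) {
    stop(sprintf("need >= 50 complete records to fit the bulk density model, have %d",
                 nrow(h)), call. = FALSE)
  }
  m <- match(h$site_id, sites$site_id)
  hgm_levels <- sort(unique(sites$hgm_class[m[!is.na(m)]]))
  X <- bd_design_matrix(h, sites, hgm_levels)
  y <- h$bd_g_cm3

  set.seed(spec$seed)
  n <- nrow(h)
  idx_train <- sort(sample.int(n, size = round(spec$train_fraction * n)))
  idx_test <- setdiff(seq_len(n), idx_train)

  dtrain <- xgboost::xgb.DMatrix(X[idx_train, , drop = FALSE],
                                 label = y[idx_train], missing = NA)
  params <- list(objective = "reg:squarederror",
                 eta = spec$shrinkage,
                 max_depth = spec$max_tree_depth,
                 subsample = spec$bag_fraction,
                 nthread = 1,
                 seed = spec$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = spec$n_trees, verbose = 0)

  pred <- predict(booster,
                  xgboost::xgb.DMatrix(X[idx_test, , drop = FALSE],
                                       missing = NA))
  sst <- sum((y[idx_test] - mean(y[idx_test]))^2)
  if (sst <= 0) {
    warning("degenerate (constant) bulk density response; holdout R2 reported as 0",
            call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - sum((y[idx_test] - pred)^2) / sst
  }

  imp_raw <- xgboost::xgb.importance(model = booster)
  gain <- setNames(rep(0, ncol(X)), colnames(X))
  if (!is.null(imp_raw) && nrow(imp_raw) > 0) {
    gain[imp_raw$Feature] <- imp_raw$Gain
  }
  parent <- feature_parent(names(gain))
  imp <- tapply(gain, parent, sum)
  importance <- setNames(rep(0, length(bd_predictors())), bd_predictors())
  importance[names(imp)] <- imp
  if (sum(importance) > 0) importance <- 100 * importance / sum(importance)

  structure(list(booster = booster, spec = spec,
                 feature_names = colnames(X), hgm_levels = hgm_levels,
                 holdout_r2 = r2,
                 importance = importance,
                 n_train = length(idx_train), n_holdout = length(idx_test)),
            class = "bd_model_fit")
}

#' Predict bulk density for horizons
#'
#' Predictions are truncated to the physically plausible interval
#' (0.05, 2.0\] g cm-3; truncation is reported via a message. HGM classes
#' unseen at training time are mapped to an "other" (all-zero indicator)
#' level with a warning; missing numeric covariates follow the trees'
#' learned default branch directions.
#'
#' @param fit a `bd_model_fit`.
#' @param horizons horizon rows to predict for (may be empty).
#' @param sites site table supplying group covariates.
#' @param lower,upper truncation bounds.
#' @return numeric vector of predictions, one per horizon row.
#' @export
predict_bd <- function(fit, horizons, sites, lower = 0.05, upper = 2.0) {
  stopifnot(inherits(fit, "bd_model_fit"))
  horizons <- tibble::as_tibble(horizons)
  if (nrow(horizons) == 0) return(numeric(0))
  X <- bd_design_matrix(horizons, sites, fit$hgm_levels)
  X <- X[, fit$feature_names, drop = FALSE]
  pred <- predict(fit$booster, xgboost::xgb.DMatrix(X, missing = NA))
  n_trunc <- sum(pred < lower | pred > upper)
  if (n_trunc > 0) {
    message(sprintf("predict_bd: %d prediction(s) truncated to (%.2f, %.2f]",
                    n_trunc, lower, upper))
  }
  pmin(pmax(pred, lower), upper)
}

#' @export
print.bd_model_fit <- function(x, ...) {
  cat(sprintf("Bulk density boosted-tree model: %d trees, holdout R2 = %.3f\n",
              x$spec$n_trees, x$holdout_r2))
  cat(sprintf("  train n = %d, holdout n = %d\n", x$n_train, x$n_holdout))
  imp <- sort(x$importance, decreasing = TRUE)
  cat("  relative importance (%):\n")
  for (p in names(imp)) cat(sprintf("    %-22s %6.2f\n", p, imp[p]))
  invisible(x)
}
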