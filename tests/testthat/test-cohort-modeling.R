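test_that("isolation forest flags gross outliers, spares duplicated inliers", {
  d <- make_tabular_cohort(120, effect = 0, seed = 201)
  f <- d$features
  # one subject far outside the cohort range on every feature
  f[1, -1] <- 10 * vapply(f[-1], function(col) diff(range(col)), numeric(1))
  flags <- detect_outliers(f, contamination = 0.05, seed = 1)
  expect_true(flags[1])
  expect_equal(sum(flags), ceiling(0.05 * nrow(f)))

  # a duplicated inlier is not flagged
  mid <- which.min(abs(f$f1 - median(f$f1[-1])))
  f2 <- rbind(f, f[mid, ])
  flags2 <- detect_outliers(f2, contamination = 0.05, seed = 1)
  expect_false(flags2[nrow(f2)])

  # determinism and contamination validation
  expect_identical(detect_outliers(f, 0.05, seed = 4),
                   detect_outliers(f, 0.05, seed = 4))
  expect_error(detect_outliers(f, 0.7), "contamination")
  expect_error(detect_outliers(f, 0), "contamination")
})

test_that("the 13 default specs cover the documented families and ranges", {
  specs <- default_model_specs(paste0("f", 1:20), seed = 3)
  expect_length(specs, 13)
  fams <- vapply(specs, `[[`, character(1), "family")
  expect_equal(sum(fams == "random_forest"), 4)
  expect_equal(sum(fams == "xgboost"), 5)
  expect_equal(sum(fams == "elastic_net"), 4)
  for (s in specs) {
    if (s$family %in% c("random_forest", "xgboost")) {
      expect_true(s$hyperparameters$max_depth >= 3 &&
                    s$hyperparameters$max_depth <= 7)
    }
    expect_gte(length(s$feature_subset), 2)
    expect_true(all(s$label_threshold[1] %in% c(25, 20)))
    expect_true(all(s$label_threshold[2] %in% c(12, 15)))
  }
})

test_that("ensemble training discriminates, is deterministic, nulls out", {
  d <- make_tabular_cohort(300, effect = 2, seed = 202)
  m <- train_ensemble(d$features, d$cohort, seed = 7)
  expect_s3_class(m, "ensemble_model")
  expect_length(m$constituents, 13)

  v <- make_tabular_cohort(200, effect = 2, seed = 203)
  sc <- ensemble_predict(m, v$features)
  expect_true(all(sc >= 0 & sc <= 1))
  sel <- v$cohort$lvedp >= 25 | v$cohort$lvedp <= 12
  auc <- roc_auc(sc[sel], as.integer(v$cohort$lvedp[sel] >= 25))$auc
  expect_gt(auc, 0.9)

  # same seed twice -> identical held-out predictions
  m2 <- train_ensemble(d$features, d$cohort, seed = 7)
  expect_identical(ensemble_predict(m2, v$features), sc)

  # null features -> chance-level held-out AUC
  d0 <- make_tabular_cohort(300, effect = 0, seed = 204)
  v0 <- make_tabular_cohort(200, effect = 0, seed = 205)
  m0 <- train_ensemble(d0$features, d0$cohort, seed = 7)
  sc0 <- ensemble_predict(m0, v0$features)
  sel0 <- v0$cohort$lvedp >= 25 | v0$cohort$lvedp <= 12
  auc0 <- roc_auc(sc0[sel0], as.integer(v0$cohort$lvedp[sel0] >= 25))$auc
  expect_lt(abs(auc0 - 0.5), 0.12)

  # missing feature column is a schema error
  expect_error(ensemble_predict(m, v$features[, 1:4]), "missing columns")

  # a cohort with an empty stratum cannot be trained on
  only_mid <- d
  keep <- d$cohort$stratum == "mid"
  expect_error(train_ensemble(d$features[keep, ], d$cohort[keep, ], seed = 1),
               "stratum")
})

test_that("ensemble averaging matches the hand-computed mean of normalized outputs", {
  d <- make_tabular_cohort(200, effect = 2, seed = 206)
  m <- train_ensemble(d$features, d$cohort, seed = 11)
  v <- make_tabular_cohort(25, effect = 2, seed = 207)
  sc <- ensemble_predict(m, v$features)
  manual <- rowMeans(vapply(seq_len(13), function(i) {
    x <- pulsespace:::feature_matrix(v$features, m$specs[[i]]$feature_subset)
    raw <- pulsespace:::predict_constituent(m$constituents[[i]], x)
    rng <- m$normalizers[[i]]
    pmin(pmax((raw - rng[1]) / (rng[2] - rng[1]), 0), 1)
  }, numeric(25)))
  expect_equal(unname(sc), manual, tolerance = 1e-12)
})

test_that("cross-validation behaves at the two extremes and reduces correctly", {
  d <- make_tabular_cohort(160, effect = 0, seed = 208)
  # perfect single feature
  f <- d$features
  f$f1 <- d$cohort$lvedp
  spec <- list(model_id = 1, family = "elastic_net",
               feature_subset = c("f1"), label_threshold = c(25, 12),
               bootstrap = FALSE,
               hyperparameters = list(alpha = 0.5, lambda = 1e-4))
  cv <- cross_validate(spec, f, d$cohort, folds = 5, iterations = 2, seed = 5)
  expect_length(cv, 10)
  expect_gt(mean(cv), 0.99)

  # pure-noise features hover at chance
  spec2 <- modifyList(spec, list(feature_subset = paste0("f", 1:10)))
  cv2 <- cross_validate(spec2, d$features, d$cohort,
                        folds = 5, iterations = 4, seed = 6)
  expect_gt(mean(cv2), 0.40)
  expect_lt(mean(cv2), 0.60)

  # iterations = 1 is a single stratified 5-fold run
  cv3 <- cross_validate(spec, f, d$cohort, folds = 5, iterations = 1, seed = 5)
  expect_length(cv3, 5)

  # a class smaller than the fold count errors
  tiny <- d$cohort$lvedp >= 25
  few <- c(which(tiny)[1:3], which(!tiny & d$cohort$lvedp <= 12))
  expect_error(
    cross_validate(spec, f[few, ], d$cohort[few, ], folds = 5, iterations = 1),
    "at least"
  )
})

test_that("ensembling does not fall below its constituents on held-out data", {
  # across simulated cohorts: ensemble AUC >= mean constituent AUC - 0.02
  for (r in 1:5) {
    d <- make_tabular_cohort(220, effect = 1.2, seed = 400 + r)
    v <- make_tabular_cohort(150, effect = 1.2, seed = 500 + r)
    m <- train_ensemble(d$features, d$cohort, seed = r)
    sel <- v$cohort$lvedp >= 25 | v$cohort$lvedp <= 12
    y <- as.integer(v$cohort$lvedp[sel] >= 25)
    ens_auc <- roc_auc(ensemble_predict(m, v$features)[sel], y)$auc
    cons_auc <- vapply(seq_len(13), function(i) {
      x <- pulsespace:::feature_matrix(v$features[sel, ],
                                       m$specs[[i]]$feature_subset)
      pulsespace:::auc_mw(
        pulsespace:::predict_constituent(m$constituents[[i]], x), y)
    }, numeric(1))
    expect_gte(ens_auc, mean(cons_auc) - 0.02)
  }
})

test_that("held-out ensemble AUC rises monotonically with the effect size", {
  effects <- c(0, 0.5, 1, 2, 4)
  aucs <- vapply(seq_along(effects), function(i) {
    d <- make_tabular_cohort(250, effect = effects[i], seed = 700)
    v <- make_tabular_cohort(180, effect = effects[i], seed = 701)
    m <- train_ensemble(d$features, d$cohort, seed = 13)
    sel <- v$cohort$lvedp >= 25 | v$cohort$lvedp <= 12
    roc_auc(ensemble_predict(m, v$features)[sel],
            as.integer(v$cohort$lvedp[sel] >= 25))$auc
  }, numeric(1))
  expect_gt(cor(aucs, effects, method = "spearman"), 0.9)
})
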