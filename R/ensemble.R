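# 13-constituent ensemble: random forests, gradient-boosted trees, elastic
# nets, each trained on its own bootstrap of subjects, feature subset and
# LVEDP label-threshold pair, combined as the mean of min-max normalized
# outputs.

#' Default constituent model specifications
#'
#' Builds the 13 constituent specifications: four random forests with maximum
#' tree depths spanning 3--7, five gradient-boosted tree configurations
#' (depths 3--7), and four elastic nets with mixing parameters 0.2--0.8.
#' Every model draws its own feature subset (a fraction of the available
#' columns, defaulting to 30--66\%), its own bootstrap of training subjects,
#' and its own LVEDP label-threshold pair from
#' `(>=25 vs <=12)`, `(>=25 vs <=15)`, `(>=20 vs <=12)` mmHg.
#'
#' @param feature_names character vector of available feature columns
#' @param seed integer seed for subset / threshold draws
#' @param subset_range absolute subset-size range; when infeasible for the
#'   available columns it falls back to `subset_fraction`
#' @param subset_fraction fractional subset-size range
#' @return list of 13 `model_spec` lists (`model_id`, `family`,
#'   `feature_subset`, `label_threshold` = c(elevated_def, nonelevated_def),
#'   `bootstrap`, `hyperparameters`)
#' @export
default_model_specs <- function(feature_names, seed = 1L,
                                subset_range = c(89L, 194L),
                                subset_fraction = c(0.30, 0.66)) {
  p <- length(feature_names)
  set.seed(child_seed(seed, 29L))
  threshold_pool <- list(c(25, 12), c(25, 15), c(20, 12))
  fam <- c(rep("random_forest", 4), rep("xgboost", 5), rep("elastic_net", 4))
  depth <- c(3, 4, 5, 7, 3, 4, 5, 6, 7, NA, NA, NA, NA)
  alpha <- c(rep(NA, 9), 0.2, 0.4, 0.6, 0.8)
  lapply(seq_len(13L), function(i) {
    if (p >= subset_range[2]) {
      k <- sample(seq(subset_range[1], subset_range[2]), 1L)
    } else {
      k <- max(2L, round(p * stats::runif(1, subset_fraction[1], subset_fraction[2])))
    }
    hp <- switch(fam[i],
      random_forest = list(num_trees = 200L, max_depth = depth[i]),
      xgboost = list(nrounds = 60L, max_depth = depth[i], eta = 0.1,
                     subsample = 0.8, colsample_bytree = 0.8),
      elastic_net = list(alpha = alpha[i], lambda = 0.01)
    )
    list(
      model_id = i,
      family = fam[i],
      feature_subset = sample(feature_names, k),
      label_threshold = threshold_pool[[sample.int(3L, 1L)]],
      bootstrap = TRUE,
      hyperparameters = hp
    )
  })
}

feature_matrix <- function(features, cols) {
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stopf("feature table missing columns: %s", paste(missing, collapse = ", "))
  }
  x <- as.matrix(features[cols])
  storage.mode(x) <- "double"
  x
}

fit_constituent <- function(spec, x, y, seed) {
  set.seed(child_seed(seed, 100L + spec$model_id))
  hp <- spec$hyperparameters
  if (spec$family == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      probability = TRUE,
      num.trees = hp$num_trees, max.depth = hp$max_depth,
      seed = child_seed(seed, 200L + spec$model_id), num.threads = 1
    )
    list(family = spec$family, fit = fit)
  } else if (spec$family == "xgboost") {
    fit <- xgboost::xgboost(
      x, factor(y, levels = c(0, 1)),
      objective = "binary:logistic", nrounds = hp$nrounds,
      max_depth = hp$max_depth, learning_rate = hp$eta,
      subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
      nthreads = 1, seed = child_seed(seed, 400L + spec$model_id),
      verbosity = 0
    )
    list(family = spec$family, fit = fit)
  } else if (spec$family == "elastic_net") {
    pad <- ncol(x) < 2L # glmnet requires >= 2 columns
    if (pad) x <- cbind(x, .pad = 0)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = hp$alpha)
    list(family = spec$family, fit = fit, lambda = hp$lambda, pad = pad)
  } else {
    stopf("unknown model family: %s", spec$family)
  }
}

predict_constituent <- function(model, x) {
  if (model$family == "random_forest") {
    p <- stats::predict(model$fit, data = x, num.threads = 1)$predictions
    as.numeric(p[, "1"])
  } else if (model$family == "xgboost") {
    as.numeric(stats::predict(model$fit, x))
  } else {
    if (isTRUE(model$pad)) x <- cbind(x, .pad = 0)
    as.numeric(stats::predict(model$fit, newx = x, s = model$lambda,
                              type = "response"))
  }
}

spec_labels <- function(lvedp, threshold) {
  ifelse(lvedp >= threshold[1], 1L, ifelse(lvedp <= threshold[2], 0L, NA_integer_))
}

#' Train the 13-model ensemble
#'
#' Joins the feature table to the cohort on `subject_id`, restricts training
#' to the non-elevated (\eqn{\le} 12 mmHg) and elevated (\eqn{\ge} 25 mmHg)
#' strata, and fits each constituent on its own bootstrap, feature subset and
#' label-threshold pair. Per-model min-max output normalizers are fitted on
#' the constituent's training outputs. Fully deterministic given the seed.
#'
#' @param features feature table (`subject_id` + numeric columns)
#' @param subjects cohort data.frame with `subject_id` and `lvedp`
#' @param specs list of model specs (default [default_model_specs()])
#' @param seed integer seed
#' @return object of class `ensemble_model`
#' @export
train_ensemble <- function(features, subjects, specs = NULL, seed = 1L) {
  df <- merge(features, subjects[c("subject_id", "lvedp")], by = "subject_id")
  feature_names <- setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], "lvedp")
  if (is.null(specs)) specs <- default_model_specs(feature_names, seed = seed)

  train <- df[df$lvedp <= 12 | df$lvedp >= 25, , drop = FALSE]
  if (!any(train$lvedp >= 25) || !any(train$lvedp <= 12)) {
    stopf("training requires both an elevated and a non-elevated stratum")
  }

  constituents <- vector("list", length(specs))
  normalizers <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    y_all <- spec_labels(train$lvedp, spec$label_threshold)
    sub <- train[!is.na(y_all), , drop = FALSE]
    y <- y_all[!is.na(y_all)]
    if (isTRUE(spec$bootstrap)) {
      set.seed(child_seed(seed, 300L + spec$model_id))
      repeat { # bootstrap must keep both classes
        idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
      }
      sub <- sub[idx, , drop = FALSE]
      y <- y[idx]
    }
    x <- feature_matrix(sub, spec$feature_subset)
    constituents[[i]] <- fit_constituent(spec, x, y, seed)
    out <- predict_constituent(constituents[[i]], x)
    rng <- range(out)
    if (diff(rng) <= 0) rng <- c(rng[1] - 0.5, rng[1] + 0.5)
    normalizers[[i]] <- rng
  }
  structure(list(
    specs = specs,
    constituents = constituents,
    normalizers = normalizers,
    feature_names = feature_names,
    seed = seed,
    frozen = FALSE
  ), class = "ensemble_model")
}

#' Ensemble risk score
#'
#' Mean of the 13 constituents' min-max normalized outputs, each clipped to
#' [0, 1]; higher scores indicate higher risk of elevated LVEDP.
#'
#' @param model an `ensemble_model`
#' @param features feature table with the training columns
#' @return numeric vector of scores in [0, 1], named by `subject_id` when
#'   present
#' @export
ensemble_predict <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"))
  scores <- vapply(seq_along(model$specs), function(i) {
    x <- feature_matrix(features, model$specs[[i]]$feature_subset)
    raw <- predict_constituent(model$constituents[[i]], x)
    rng <- model$normalizers[[i]]
    pmin(pmax((raw - rng[1]) / (rng[2] - rng[1]), 0), 1)
  }, numeric(nrow(features)))
  if (nrow(features) == 1L) scores <- matrix(scores, nrow = 1L)
  out <- rowMeans(scores)
  if (!is.null(features$subject_id)) names(out) <- features$subject_id
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  fams <- table(vapply(x$specs, `[[`, character(1), "family"))
  cat(sprintf("<ensemble_model: %d constituents (%s), %d features%s>\n",
              length(x$specs),
              paste(sprintf("%s x%d", names(fams), fams), collapse = ", "),
              length(x$feature_names),
              if (isTRUE(x$frozen)) ", FROZEN" else ""))
  invisible(x)
}

# Mann-Whitney AUC with ties counted one-half (midrank formulation); the
# fast internal AUC used by cross-validation and the BNP simulation.
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified cross-validation of one constituent spec
#'
#' Stratified k-fold cross-validation of a single model specification,
#' repeated with re-randomized fold assignments; returns the out-of-fold AUC
#' of every (iteration, fold) pair. Labels are the spec's own threshold pair.
#'
#' @param spec one model spec (see [default_model_specs()])
#' @param features feature table
#' @param subjects cohort data.frame
#' @param folds number of folds (default 5)
#' @param iterations number of repeats (default 100)
#' @param seed integer seed
#' @return numeric vector of `iterations * folds` AUCs
#' @export
cross_validate <- function(spec, features, subjects, folds = 5L,
                           iterations = 100L, seed = 1L) {
  df <- merge(features, subjects[c("subject_id", "lvedp")], by = "subject_id")
  y <- spec_labels(df$lvedp, spec$label_threshold)
  df <- df[!is.na(y), , drop = FALSE]
  y <- y[!is.na(y)]
  if (min(table(factor(y, levels = c(0, 1)))) < folds) {
    stopf("each class needs at least %d members for %d-fold CV", folds, folds)
  }
  x <- feature_matrix(df, spec$feature_subset)
  aucs <- numeric(0)
  for (it in seq_len(iterations)) {
    set.seed(child_seed(seed, 1000L + it))
    fold_id <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_constituent(spec, x[tr, , drop = FALSE], y[tr],
                             child_seed(seed, 2000L + it * folds + f))
      pred <- predict_constituent(fit, x[!tr, , drop = FALSE])
      aucs <- c(aucs, auc_mw(pred, y[!tr]))
    }
  }
  aucs
}
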