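# Boxplot-constrained BNP simulation, Bayesian post-test probability
# analysis, and the net reclassification index of the ML predictor over BNP.

#' Five-number (boxplot) summary constraint
#'
#' @param minimum,q25,median,q75,maximum concentration statistics
#'   (non-decreasing)
#' @return list of class `boxplot_summary`
#' @export
#' @examples
#' bnp_noncardiac_summary()
#' bnp_hfpef_summary()
boxplot_summary <- function(minimum, q25, median, q75, maximum) {
  q <- c(minimum, q25, median, q75, maximum)
  if (any(diff(q) < 0)) stopf("five-number summary must be non-decreasing")
  structure(list(minimum = minimum, q25 = q25, median = median,
                 q75 = q75, maximum = maximum), class = "boxplot_summary")
}

#' @describeIn boxplot_summary published five-number summary of BNP in the
#'   non-cardiac-etiology (non-elevated) cohort
#' @export
bnp_noncardiac_summary <- function() boxplot_summary(0, 75, 190, 475, 1075)

#' @describeIn boxplot_summary published five-number summary of BNP in the
#'   obese-HFpEF (elevated) cohort; note the coincident 25th percentile and
#'   median, a 25\% point mass at 250 under the piecewise-uniform scheme
#' @export
bnp_hfpef_summary <- function() boxplot_summary(0, 250, 250, 750, 5000)

summary_knots <- function(summary) {
  c(summary$minimum, summary$q25, summary$median, summary$q75, summary$maximum)
}

#' Sample from a boxplot-constrained distribution
#'
#' Piecewise-uniform scheme: each draw lands in one of the four
#' inter-quartile segments with probability 1/4 and is uniform within it
#' (equivalently, linear interpolation of the inverse CDF through the five
#' statistics). A zero-width segment yields a point mass. All samples lie in
#' `[minimum, maximum]` and the empirical quartiles converge to the
#' constraints.
#'
#' @param summary a [boxplot_summary()]
#' @param n number of draws (>= 1)
#' @param seed integer seed (`NULL` = use the current RNG stream)
#' @return numeric vector of length `n`
#' @export
#' @examples
#' quantile(sample_boxplot_constrained(bnp_noncardiac_summary(), 1e4, seed = 1))
sample_boxplot_constrained <- function(summary, n, seed = NULL) {
  stopifnot(inherits(summary, "boxplot_summary"))
  if (n < 1) stopf("n must be >= 1")
  if (!is.null(seed)) set.seed(child_seed(seed, 3L))
  q <- summary_knots(summary)
  u <- stats::runif(n)
  seg <- pmin(floor(u * 4) + 1L, 4L)
  frac <- u * 4 - (seg - 1L)
  q[seg] + frac * (q[seg + 1L] - q[seg])
}

# Closed-form P(X > thr) under the piecewise-uniform scheme.
boxplot_exceedance <- function(summary, thr) {
  q <- summary_knots(summary)
  p <- 0
  for (i in 1:4) {
    a <- q[i]; b <- q[i + 1]
    p <- p + 0.25 * if (b <= a) as.numeric(a > thr) else
      max(0, min(1, (b - thr) / (b - a)))
  }
  p
}

# Closed-form P(X_a > X_b) + 0.5 P(X_a = X_b) for two independent
# piecewise-uniform draws: the analytic AUC of the BNP simulation, summed
# over the 16 segment pairs.
boxplot_auc <- function(summary_a, summary_b) {
  qa <- summary_knots(summary_a)
  qb <- summary_knots(summary_b)
  total <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      a1 <- qa[i]; a2 <- qa[i + 1]
      b1 <- qb[j]; b2 <- qb[j + 1]
      wa <- a2 - a1
      wb <- b2 - b1
      if (wa == 0 && wb == 0) {
        p <- if (a1 > b1) 1 else if (a1 == b1) 0.5 else 0
      } else if (wa == 0) {
        p <- max(0, min(1, (a1 - b1) / wb))
      } else if (wb == 0) {
        p <- max(0, min(1, (a2 - b1) / wa))
      } else {
        # P(U > V), U ~ Unif(a1,a2), V ~ Unif(b1,b2): integrate the V-CDF
        f <- function(u) pmin(pmax((u - b1) / wb, 0), 1)
        p <- stats::integrate(f, a1, a2, rel.tol = 1e-10)$value / wa
      }
      total <- total + p / 16
    }
  }
  total
}

#' Simulate BNP diagnostic performance from boxplot constraints
#'
#' Per iteration, draws `n_non` non-elevated and `n_elev` elevated BNP values
#' from the respective piecewise-uniform boxplot-constrained distributions,
#' computes the Mann-Whitney AUC (ties one-half) and, at each threshold, the
#' sensitivity, specificity, PPV, NPV and likelihood ratios of the rule
#' `BNP > threshold`. Statistics are aggregated as the mean over iterations
#' with 2.5th/97.5th-percentile confidence intervals.
#'
#' @param non_elevated,elevated [boxplot_summary()] constraints for the two
#'   cohorts (defaults: the published non-cardiac and obese-HFpEF summaries)
#' @param n_non,n_elev per-iteration group sizes (defaults 258 and 79)
#' @param thresholds BNP decision thresholds in pg/mL (default 50 and 150)
#' @param iterations number of Monte-Carlo iterations (default 1000)
#' @param seed integer seed
#' @return object of class `bnp_simulation`: list with `aggregate` (data.frame
#'   statistic/threshold/mean/lo/hi), `per_iteration` (data.frame), and the
#'   call settings
#' @export
#' @examples
#' sim <- simulate_bnp_performance(iterations = 50, seed = 1)
#' subset(sim$aggregate, statistic == "auc")
simulate_bnp_performance <- function(non_elevated = bnp_noncardiac_summary(),
                                     elevated = bnp_hfpef_summary(),
                                     n_non = 258L, n_elev = 79L,
                                     thresholds = c(50, 150),
                                     iterations = 1000L, seed = 1L) {
  stopifnot(inherits(non_elevated, "boxplot_summary"),
            inherits(elevated, "boxplot_summary"))
  if (iterations < 1 || n_non < 1 || n_elev < 1) stopf("invalid simulation size")
  labels <- c(rep(0L, n_non), rep(1L, n_elev))
  rows <- vector("list", iterations)
  set.seed(child_seed(seed, 5L))
  for (it in seq_len(iterations)) {
    x_non <- sample_boxplot_constrained(non_elevated, n_non)
    x_elev <- sample_boxplot_constrained(elevated, n_elev)
    auc <- auc_mw(c(x_non, x_elev), labels)
    row <- list(iteration = it, auc = auc)
    for (thr in thresholds) {
      sens <- mean(x_elev > thr)
      spec <- mean(x_non <= thr)
      ppv <- sum(x_elev > thr) /
        max(1L, sum(x_elev > thr) + sum(x_non > thr))
      npv <- sum(x_non <= thr) /
        max(1L, sum(x_non <= thr) + sum(x_elev <= thr))
      lr_pos <- if (spec < 1) sens / (1 - spec) else Inf
      lr_neg <- if (spec > 0) (1 - sens) / spec else Inf
      nm <- function(s) sprintf("%s_%g", s, thr)
      row[[nm("sens")]] <- sens
      row[[nm("spec")]] <- spec
      row[[nm("ppv")]] <- ppv
      row[[nm("npv")]] <- npv
      row[[nm("lr_pos")]] <- lr_pos
      row[[nm("lr_neg")]] <- lr_neg
    }
    rows[[it]] <- as.data.frame(row)
  }
  per_iter <- do.call(rbind, rows)
  stat_cols <- setdiff(names(per_iter), "iteration")
  agg <- do.call(rbind, lapply(stat_cols, function(cn) {
    v <- per_iter[[cn]]
    fin <- v[is.finite(v)]
    qs <- stats::quantile(fin, c(0.025, 0.975), names = FALSE)
    data.frame(statistic = cn, mean = mean(fin), lo = qs[1], hi = qs[2])
  }))
  structure(list(
    aggregate = agg,
    per_iteration = per_iter,
    thresholds = thresholds,
    n_non = n_non, n_elev = n_elev,
    iterations = iterations, seed = seed
  ), class = "bnp_simulation")
}

#' Bayesian post-test probability of elevated LVEDP
#'
#' Converts a pre-test (prior) probability into the post-test probability
#' given a test result, using the likelihood ratios implied by constant
#' sensitivity and specificity: `LR+ = sens / (1 - spec)`,
#' `LR- = (1 - sens) / spec`; posterior odds = prior odds x LR.
#'
#' @param prior pre-test probability in [0, 1] (vectorized)
#' @param sens,spec test sensitivity and specificity in (0, 1); `spec = 1`
#'   with a positive result gives posterior 1 for any positive prior
#' @param result `"positive"` or `"negative"`
#' @return posterior probability, same length as `prior`
#' @export
#' @examples
#' post_test_probability(0.59, 0.82, 0.68, "positive") # 0.79
#' post_test_probability(0.77, 0.82, 0.68, "positive") # 0.90
post_test_probability <- function(prior, sens, spec,
                                  result = c("positive", "negative")) {
  result <- match.arg(result)
  if (any(prior < 0 | prior > 1)) stopf("prior must lie in [0, 1]")
  if (sens <= 0 || sens > 1 || spec <= 0 || spec > 1) {
    stopf("sens and spec must lie in (0, 1]")
  }
  lr <- if (result == "positive") {
    if (spec == 1) Inf else sens / (1 - spec)
  } else {
    (1 - sens) / spec
  }
  if (is.infinite(lr)) return(ifelse(prior > 0, 1, 0))
  odds <- prior / (1 - prior)
  post <- (odds * lr) / (1 + odds * lr)
  post[prior == 1] <- 1
  post[prior == 0] <- 0
  post
}

#' Posterior-probability curves over a prior grid
#'
#' Post-test probability for a positive and a negative result over a grid of
#' pre-test probabilities (always including the 0.30 / 0.50 / 0.70 anchors).
#'
#' @inheritParams post_test_probability
#' @param grid_resolution grid step (default 0.01)
#' @return data.frame with `prior`, `posterior_positive`,
#'   `posterior_negative`; attributes `sens`, `spec`
#' @export
posterior_curve <- function(sens, spec, grid_resolution = 0.01) {
  grid <- sort(unique(c(seq(0, 1, by = grid_resolution), 0.30, 0.50, 0.70)))
  out <- data.frame(
    prior = grid,
    posterior_positive = post_test_probability(grid, sens, spec, "positive"),
    posterior_negative = post_test_probability(grid, sens, spec, "negative")
  )
  attr(out, "sens") <- sens
  attr(out, "spec") <- spec
  out
}

#' Net reclassification index of the ML predictor over simulated BNP
#'
#' Two-category NRI from marginal sensitivity/specificity differences: per
#' simulation iteration, `(ml_sens - bnp_sens) + (ml_spec - bnp_spec)` at the
#' requested BNP threshold, aggregated as the mean with a 2.5th/97.5th
#' percentile interval.
#'
#' @param ml_sens,ml_spec operating characteristics of the ML predictor
#'   (defaults: the validated 82\% sensitivity and 68\% specificity)
#' @param bnp_result a [simulate_bnp_performance()] result
#' @param threshold BNP threshold (must be one the simulation evaluated)
#' @return list with `mean`, `ci95` = c(lo, hi), `per_iteration`
#' @export
#' @examples
#' sim <- simulate_bnp_performance(iterations = 50, seed = 1)
#' nri_vs_bnp(bnp_result = sim, threshold = 150)$mean
nri_vs_bnp <- function(ml_sens = 0.82, ml_spec = 0.68, bnp_result, threshold) {
  stopifnot(inherits(bnp_result, "bnp_simulation"))
  if (!threshold %in% bnp_result$thresholds) {
    stopf("threshold %g not present in the simulation", threshold)
  }
  sens <- bnp_result$per_iteration[[sprintf("sens_%g", threshold)]]
  spec <- bnp_result$per_iteration[[sprintf("spec_%g", threshold)]]
  nri <- (ml_sens - sens) + (ml_spec - spec)
  qs <- stats::quantile(nri, c(0.025, 0.975), names = FALSE)
  list(mean = mean(nri), ci95 = c(lo = qs[1], hi = qs[2]), per_iteration = nri)
}
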