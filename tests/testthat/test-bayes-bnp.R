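test_that("boxplot-constrained sampling honours its five-number constraints", {
  s <- bnp_noncardiac_summary()
  x <- sample_boxplot_constrained(s, 1e5, seed = 1)
  expect_true(all(x >= 0 & x <= 1075))
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  rng <- 1075
  expect_lt(abs(q[1] - 75) / rng, 0.02)
  expect_lt(abs(q[2] - 190) / rng, 0.02)
  expect_lt(abs(q[3] - 475) / rng, 0.02)

  # degenerate summary collapses to a point mass
  point <- boxplot_summary(7, 7, 7, 7, 7)
  expect_true(all(sample_boxplot_constrained(point, 1000, seed = 2) == 7))

  # the HFpEF zero-width quartile puts ~25% mass exactly at 250
  h <- sample_boxplot_constrained(bnp_hfpef_summary(), 1e5, seed = 3)
  expect_lt(abs(mean(h == 250) - 0.25), 0.01)

  # determinism and validation
  expect_identical(sample_boxplot_constrained(s, 100, seed = 9),
                   sample_boxplot_constrained(s, 100, seed = 9))
  expect_error(sample_boxplot_constrained(s, 0), ">= 1")
  expect_error(boxplot_summary(0, 10, 5, 20, 30), "non-decreasing")
})

test_that("sampler quartiles converge for arbitrary valid summaries", {
  set.seed(101)
  for (rep in 1:8) {
    q <- sort(runif(5, 0, 1000))
    s <- boxplot_summary(q[1], q[2], q[3], q[4], q[5])
    x <- sample_boxplot_constrained(s, 2e5, seed = 200 + rep)
    expect_gte(min(x), q[1])
    expect_lte(max(x), q[5])
    emp <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    expect_true(all(abs(emp - q[2:4]) < 0.01 * (q[5] - q[1])))
  }
})

test_that("simulated BNP performance matches the closed-form oracles", {
  sim <- simulate_bnp_performance(iterations = 300, seed = 17)
  agg <- sim$aggregate

  # Monte-Carlo AUC vs the analytic piecewise-uniform P(elev > non)
  oracle_auc <- pulsespace:::boxplot_auc(bnp_hfpef_summary(),
                                         bnp_noncardiac_summary())
  auc_iter <- sim$per_iteration$auc
  mc_se <- sd(auc_iter) / sqrt(length(auc_iter))
  expect_lt(abs(mean(auc_iter) - oracle_auc), 3 * mc_se + 1e-6)

  # threshold statistics vs closed-form exceedance probabilities
  for (thr in c(50, 150)) {
    sens_true <- pulsespace:::boxplot_exceedance(bnp_hfpef_summary(), thr)
    spec_true <- 1 - pulsespace:::boxplot_exceedance(bnp_noncardiac_summary(), thr)
    sens_iter <- sim$per_iteration[[sprintf("sens_%g", thr)]]
    spec_iter <- sim$per_iteration[[sprintf("spec_%g", thr)]]
    expect_lt(abs(mean(sens_iter) - sens_true),
              3 * sd(sens_iter) / sqrt(length(sens_iter)) + 1e-6)
    expect_lt(abs(mean(spec_iter) - spec_true),
              3 * sd(spec_iter) / sqrt(length(spec_iter)) + 1e-6)
  }

  # identical summaries for both groups -> exchangeable, AUC ~ 0.5
  null_sim <- simulate_bnp_performance(
    non_elevated = bnp_noncardiac_summary(),
    elevated = bnp_noncardiac_summary(),
    iterations = 150, seed = 19
  )
  expect_lt(abs(null_sim$aggregate$mean[null_sim$aggregate$statistic == "auc"] - 0.5),
            0.02)

  # aggregate intervals bracket their means
  expect_true(all(agg$lo <= agg$mean + 1e-12 & agg$mean <= agg$hi + 1e-12))
})

test_that("closed-form AUC agrees with Monte Carlo on random summary pairs", {
  set.seed(23)
  for (rep in 1:6) {
    qa <- sort(c(runif(4, 0, 500), runif(1, 500, 2000)))
    qb <- sort(runif(5, 0, 1500))
    sa <- boxplot_summary(qa[1], qa[2], qa[3], qa[4], qa[5])
    sb <- boxplot_summary(qb[1], qb[2], qb[3], qb[4], qb[5])
    xa <- sample_boxplot_constrained(sa, 4e4, seed = 300 + rep)
    xb <- sample_boxplot_constrained(sb, 4e4, seed = 400 + rep)
    mc <- pulsespace:::auc_mw(c(xb, xa), c(rep(0, 4e4), rep(1, 4e4)))
    expect_lt(abs(mc - pulsespace:::boxplot_auc(sa, sb)), 0.01)
  }
})

test_that("Bayesian post-test probabilities follow the likelihood-ratio algebra", {
  # the validated test applied at the published priors
  expect_equal(round(post_test_probability(0.59, 0.82, 0.68, "positive"), 2), 0.79)
  expect_equal(round(post_test_probability(0.77, 0.82, 0.68, "positive"), 2), 0.90)

  # uninformative test leaves the prior untouched
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(post_test_probability(p, 0.5, 0.5, "positive"), p)
  expect_equal(post_test_probability(p, 0.5, 0.5, "negative"), p)

  # chaining two independent tests = one test with the product of LRs
  pri <- 0.3
  one_then_two <- post_test_probability(
    post_test_probability(pri, 0.82, 0.68, "positive"), 0.9, 0.75, "positive")
  lr <- (0.82 / 0.32) * (0.9 / 0.25)
  odds <- pri / (1 - pri) * lr
  expect_equal(one_then_two, odds / (1 + odds), tolerance = 1e-12)

  # perfect specificity with a positive result is conclusive
  expect_equal(post_test_probability(0.4, 0.8, 1, "positive"), 1)
  expect_equal(post_test_probability(0, 0.8, 1, "positive"), 0)
  expect_error(post_test_probability(1.2, 0.8, 0.7), "prior")
})

test_that("posterior curves are monotone and hit their algebraic anchors", {
  cur <- posterior_curve(0.82, 0.68)
  expect_true(all(c(0.30, 0.50, 0.70) %in% cur$prior))
  inner <- cur$prior > 0 & cur$prior < 1
  expect_true(all(diff(cur$posterior_positive) >= 0))
  # positive curve above the prior, negative below (LR+ > 1 > LR-)
  expect_true(all(cur$posterior_positive[inner] > cur$prior[inner]))
  expect_true(all(cur$posterior_negative[inner] < cur$prior[inner]))
  # at prior 0.5 the positive posterior is LR+/(LR+ + 1)
  lr_pos <- 0.82 / 0.32
  expect_equal(cur$posterior_positive[cur$prior == 0.5],
               lr_pos / (lr_pos + 1), tolerance = 1e-12)
  expect_equal(cur$posterior_positive[cur$prior == 0], 0)
  expect_equal(cur$posterior_positive[cur$prior == 1], 1)
})

test_that("the NRI follows its marginal arithmetic and antisymmetry", {
  sim <- simulate_bnp_performance(iterations = 100, seed = 29)

  # ML identical to BNP -> NRI 0 per iteration
  s150 <- sim$per_iteration$sens_150
  p150 <- sim$per_iteration$spec_150
  zero <- mapply(function(a, b) (a - a) + (b - b), s150, p150)
  expect_true(all(zero == 0))

  # hand case: (0.9, 0.8) vs (0.7, 0.6) -> 0.4
  hand <- (0.9 - 0.7) + (0.8 - 0.6)
  expect_equal(hand, 0.4)

  nri <- nri_vs_bnp(0.82, 0.68, sim, threshold = 150)
  manual <- mean((0.82 - s150) + (0.68 - p150))
  expect_equal(nri$mean, manual, tolerance = 1e-12)

  # antisymmetry: swapping the comparator's role flips the sign
  flipped <- mean((mean(s150) - 0.82) + (mean(p150) - 0.68))
  expect_equal(flipped, -((0.82 - mean(s150)) + (0.68 - mean(p150))),
               tolerance = 1e-12)

  expect_error(nri_vs_bnp(0.82, 0.68, sim, threshold = 75), "not present")
})
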