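# Threshold sweeps, propensity matching and subgroup reports around the
# primary elevated-vs-normal LVEDP analysis.

#' Sweep the LVEDP definitions of elevation and non-elevation
#'
#' Recomputes the AUC of the scores for every pair of definitions: cell
#' `(i, j)` restricts to subjects with `lvedp >= elevated_defs[i]` (positive)
#' or `lvedp <= nonelevated_defs[j]` (negative); everyone in neither group is
#' excluded. Cells whose groups are empty (or degenerate) are `NA`.
#'
#' @param scores numeric scores, one per subject
#' @param lvedp LVEDP in mmHg, one per subject
#' @param elevated_defs vector of elevation cut-offs (default 25)
#' @param nonelevated_defs vector of non-elevation cut-offs (default 12:24)
#' @return matrix of AUCs, rows = elevated_defs, cols = nonelevated_defs
#' @export
threshold_sweep <- function(scores, lvedp, elevated_defs = 25,
                            nonelevated_defs = 12:24) {
  stopifnot(length(scores) == length(lvedp))
  out <- matrix(NA_real_, length(elevated_defs), length(nonelevated_defs),
                dimnames = list(paste0(">=", elevated_defs),
                                paste0("<=", nonelevated_defs)))
  for (i in seq_along(elevated_defs)) {
    for (j in seq_along(nonelevated_defs)) {
      if (nonelevated_defs[j] >= elevated_defs[i]) next
      pos <- lvedp >= elevated_defs[i]
      neg <- lvedp <= nonelevated_defs[j]
      sel <- pos | neg
      if (sum(pos) == 0L || sum(neg) == 0L) next
      out[i, j] <- roc_auc(scores[sel], as.integer(pos[sel]))$auc
    }
  }
  out
}

#' Propensity matching of elevated to non-elevated subjects
#'
#' Logistic propensity score on the requested covariates, then 1:1 greedy
#' nearest-neighbour matching without replacement; the order in which treated
#' subjects claim their match is randomized by the seed. With overlapping
#' covariate support the pair count equals the smaller group size.
#'
#' @param subjects cohort data.frame (needs `stratum` plus the covariates)
#' @param covariates covariate column names (default age and gender)
#' @param caliper optional maximum propensity-score distance for a valid pair
#' @param seed integer seed
#' @return data.frame of pairs (`treated_id`, `control_id`, `distance`) with
#'   the per-covariate post-match standardized mean differences as attribute
#'   `"smd"`
#' @export
propensity_match <- function(subjects, covariates = c("age", "gender"),
                             caliper = NULL, seed = 1L) {
  treated <- subjects$stratum == "elevated"
  control <- subjects$stratum == "non_elevated"
  if (!any(treated) || !any(control)) stopf("both groups must be non-empty")
  dat <- subjects[treated | control, , drop = FALSE]
  dat$.treat <- as.integer(dat$stratum == "elevated")
  # degenerate covariates (a single observed level) carry no information for
  # the propensity model and would break the GLM contrasts
  usable <- covariates[vapply(covariates, function(v) {
    length(unique(dat[[v]])) > 1L
  }, logical(1))]
  ps <- if (length(usable)) {
    fml <- stats::reformulate(usable, response = ".treat")
    stats::predict(stats::glm(fml, data = dat, family = stats::binomial()),
                   type = "response")
  } else {
    rep(0.5, nrow(dat))
  }
  t_idx <- which(dat$.treat == 1L)
  c_idx <- which(dat$.treat == 0L)
  set.seed(child_seed(seed, 41L))
  t_idx <- sample(t_idx)
  avail <- rep(TRUE, length(c_idx))
  pairs <- list()
  for (ti in t_idx) {
    if (!any(avail)) break
    d <- abs(ps[c_idx] - ps[ti])
    d[!avail] <- Inf
    k <- which.min(d)
    if (!is.null(caliper) && d[k] > caliper) next
    avail[k] <- FALSE
    pairs[[length(pairs) + 1L]] <- data.frame(
      treated_id = dat$subject_id[ti],
      control_id = dat$subject_id[c_idx[k]],
      distance = d[k]
    )
  }
  if (!length(pairs)) {
    warning("no pairs within caliper; returning empty matching")
    out <- data.frame(treated_id = character(0), control_id = character(0),
                      distance = numeric(0))
  } else {
    out <- do.call(rbind, pairs)
  }
  smd <- vapply(covariates, function(v) {
    x <- dat[[v]]
    if (is.factor(x) || is.character(x)) x <- as.integer(factor(x))
    xt <- x[match(out$treated_id, dat$subject_id)]
    xc <- x[match(out$control_id, dat$subject_id)]
    s <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (mean(xt) - mean(xc)) / s
  }, numeric(1))
  attr(out, "smd") <- smd
  out
}

#' Per-subgroup ROC performance
#'
#' Computes a [roc_auc()] per level of a grouping column and, for two-level
#' groupings, a DeLong test for the AUC difference (unpaired). Levels with a
#' single class are marked non-evaluable.
#'
#' @param scores numeric scores
#' @param labels binary labels
#' @param subjects cohort data.frame aligned with `scores`
#' @param grouping name of the grouping column in `subjects`
#' @return list with `per_level` (named list of `roc_result` or `NULL` when
#'   non-evaluable) and `p_between` (DeLong p-value for 2-level groupings,
#'   else `NA`)
#' @export
subgroup_report <- function(scores, labels, subjects, grouping) {
  if (!grouping %in% names(subjects)) stopf("no column '%s' in subjects", grouping)
  g <- factor(subjects[[grouping]])
  labels <- normalize_labels(labels)
  per_level <- lapply(levels(g), function(lv) {
    sel <- g == lv
    if (length(unique(labels[sel])) < 2L) return(NULL)
    roc_auc(scores[sel], labels[sel])
  })
  names(per_level) <- levels(g)
  p_between <- NA_real_
  ok <- !vapply(per_level, is.null, logical(1))
  if (nlevels(g) == 2L && all(ok)) {
    sel1 <- g == levels(g)[1]
    sel2 <- g == levels(g)[2]
    r1 <- pROC::roc(labels[sel1], as.numeric(scores[sel1]),
                    levels = c("0", "1"), direction = "<", quiet = TRUE)
    r2 <- pROC::roc(labels[sel2], as.numeric(scores[sel2]),
                    levels = c("0", "1"), direction = "<", quiet = TRUE)
    p_between <- pROC::roc.test(r1, r2, method = "delong", paired = FALSE)$p.value
  }
  list(per_level = per_level, p_between = p_between)
}
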