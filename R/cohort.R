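#' Default cohort configuration
#'
#' Describes the population the synthetic cohort emulates: the three LVEDP
#' strata (non-elevated \eqn{\le} 12 mmHg, mid 13--24 mmHg, elevated
#' \eqn{\ge} 25 mmHg) in the proportions of the validation population
#' (258/347/79), truncated-normal demographics with the published group means,
#' per-stratum LVEDP moments, gender mix, obstructive-CAD rates and a pool of
#' enrollment sites.
#'
#' @param stratum_proportions named numeric vector of length 3 (non_elevated,
#'   mid, elevated) summing to 1
#' @param n_sites number of site identifiers to draw from
#' @return a list of class `cohort_config`
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$stratum_proportions
cohort_config <- function(stratum_proportions = c(
                            non_elevated = 258, mid = 347, elevated = 79
                          ) / 684,
                          n_sites = 15L) {
  if (length(stratum_proportions) != 3L || any(stratum_proportions < 0) ||
      abs(sum(stratum_proportions) - 1) > 1e-8) {
    stopf("stratum_proportions must be 3 non-negative values summing to 1")
  }
  names(stratum_proportions) <- c("non_elevated", "mid", "elevated")
  structure(list(
    stratum_proportions = stratum_proportions,
    # per-stratum LVEDP moments (mmHg): mean, sd, lower, upper
    lvedp = list(
      non_elevated = c(mean = 9, sd = 3, lo = 0, hi = 12),
      mid          = c(mean = 18, sd = 3, lo = 13, hi = 24),
      elevated     = c(mean = 29, sd = 4, lo = 25, hi = 45)
    ),
    age = c(mean = 63, sd = 10, lo = 18, hi = 95),
    bmi = list( # elevated-LVEDP subjects skew heavier
      non_elevated = c(mean = 30, sd = 6, lo = 16, hi = 60),
      mid          = c(mean = 32, sd = 6, lo = 16, hi = 60),
      elevated     = c(mean = 37, sd = 8, lo = 16, hi = 60)
    ),
    ef = c(mean = 60, sd = 7, lo = 15, hi = 80),
    p_female = c(non_elevated = 0.39, mid = 0.42, elevated = 0.65),
    p_cad = c(non_elevated = 0.43, mid = 0.33, elevated = 0.24),
    n_sites = as.integer(n_sites)
  ), class = "cohort_config")
}

# Truncated-normal draw by inverse-CDF restriction (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Classify LVEDP into the three study strata
#'
#' @param lvedp numeric vector of LVEDP values in mmHg
#' @return factor with levels `non_elevated` (\eqn{\le} 12), `mid` (13--24),
#'   `elevated` (\eqn{\ge} 25)
#' @export
lvedp_stratum <- function(lvedp) {
  factor(
    ifelse(lvedp <= 12, "non_elevated", ifelse(lvedp < 25, "mid", "elevated")),
    levels = c("non_elevated", "mid", "elevated")
  )
}

#' Generate a synthetic subject cohort
#'
#' Draws `n` subjects with stratum membership multinomial in the configured
#' proportions, LVEDP from the stratum's truncated normal, and demographics
#' (age, gender, BMI, EF, obstructive-CAD status, enrollment site) from the
#' configured distributions. Reproducible for a fixed seed.
#'
#' @param n number of subjects (>= 1)
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return a data.frame with one row per subject: `subject_id`, `age`,
#'   `gender`, `bmi`, `ef`, `lvedp` (mmHg), `stratum`, `cad_obstructive`,
#'   `site_id`
#' @export
#' @examples
#' cohort <- generate_cohort(50, cohort_config(), seed = 1)
#' table(cohort$stratum)
generate_cohort <- function(n, config = cohort_config(), seed = 1L) {
  stopifnot(n >= 1)
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config")
  set.seed(child_seed(seed, 0L))
  strata <- sample(names(config$stratum_proportions), n,
                   replace = TRUE, prob = config$stratum_proportions)
  lvedp <- vapply(strata, function(s) {
    p <- config$lvedp[[s]]
    rtruncnorm(1, p["mean"], p["sd"], p["lo"], p["hi"])
  }, numeric(1))
  lvedp <- round(pmin(pmax(lvedp, 0), 45), 1)
  bmi <- vapply(strata, function(s) {
    p <- config$bmi[[s]]
    rtruncnorm(1, p["mean"], p["sd"], p["lo"], p["hi"])
  }, numeric(1))
  a <- config$age
  age <- rtruncnorm(n, a["mean"], a["sd"], a["lo"], a["hi"])
  e <- config$ef
  ef <- rtruncnorm(n, e["mean"], e["sd"], e["lo"], e["hi"])
  gender <- ifelse(stats::runif(n) < config$p_female[strata], "female", "male")
  cad <- stats::runif(n) < config$p_cad[strata]
  site <- sprintf("site%02d", sample.int(config$n_sites, n, replace = TRUE))
  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = round(age, 1),
    gender = factor(gender, levels = c("female", "male")),
    bmi = round(bmi, 1),
    ef = round(ef, 1),
    lvedp = lvedp,
    stratum = lvedp_stratum(lvedp),
    cad_obstructive = cad,
    site_id = site,
    stringsAsFactors = FALSE
  )
  out
}

#' Write / read a cohort table as CSV
#'
#' Plain CSV with the canonical column set; [read_cohort()] validates the
#' schema and re-derives the stratum factor so a hand-edited file that breaks
#' the LVEDP/stratum correspondence fails loudly.
#'
#' @param cohort a cohort data.frame from [generate_cohort()]
#' @param path file path
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort data.frame
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "gender", "bmi", "ef", "lvedp", "stratum",
            "cad_obstructive", "site_id")
  missing <- setdiff(need, names(x))
  if (length(missing)) stopf("cohort file missing columns: %s",
                             paste(missing, collapse = ", "))
  derived <- lvedp_stratum(x$lvedp)
  if (!identical(as.character(derived), as.character(x$stratum))) {
    stopf("cohort file corrupt: stratum column does not match lvedp cut-points")
  }
  x$stratum <- derived
  x$gender <- factor(x$gender, levels = c("female", "male"))
  x
}
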