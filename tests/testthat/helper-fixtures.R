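# Shared fixtures: small acquisitions and tabular feature cohorts built in
# code at test time.

# A short clean acquisition for a subject with the given LVEDP.
make_record <- function(lvedp = 9, duration = 12, seed = 101,
                        config = NULL) {
  subj <- data.frame(subject_id = sprintf("T%03d", seed %% 1000), lvedp = lvedp)
  cfg <- config %||% signal_config(duration = duration)
  generate_signals(subj, cfg, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tabular feature cohort with an LVEDP-linked mean shift on the first
# `n_affected` columns; bypasses signal synthesis for speed where only the
# modeling layer is under test.
make_tabular_cohort <- function(n, effect, seed, p = 10L, n_affected = 4L) {
  set.seed(seed)
  cohort <- generate_cohort(n, seed = seed)
  e <- pmin(pmax((cohort$lvedp - 12) / 13, 0), 1)
  features <- data.frame(subject_id = cohort$subject_id)
  for (j in seq_len(p)) {
    shift <- if (j <= n_affected) effect * e else 0
    features[[paste0("f", j)]] <- stats::rnorm(n) + shift
  }
  list(cohort = cohort, features = features)
}

# Exhaustive pair-counting AUC oracle (ties count one-half).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
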