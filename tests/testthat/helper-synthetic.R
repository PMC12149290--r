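# shared fixtures, built in code

# a trial list with the canonical event schedule
makeTrial <- function(rule, locs, t0 = 500, stim = "none",
                      config = taskConfig()) {
  step <- config@cueDuration + config@delayDuration
  list(trial_id = 1L, rule = rule, cue_locations = as.integer(locs),
       cue_onsets = t0 + (seq_along(locs) - 1) * step,
       fp_offset = t0 + length(locs) * step,
       stim = stim)
}

# trials data.frame from a list of cue-location vectors
makeTrialsDf <- function(rules, locsList, config = taskConfig()) {
  step <- config@cueDuration + config@delayDuration
  n <- length(locsList)
  out <- data.frame(trial_id = seq_len(n), rule = rules,
                    n_cues = lengths(locsList), stringsAsFactors = FALSE)
  t0 <- 500
  locs <- matrix(NA_integer_, n, 4)
  ons <- matrix(NA_real_, n, 4)
  fp <- numeric(n)
  for (i in seq_len(n)) {
    L <- length(locsList[[i]])
    locs[i, seq_len(L)] <- as.integer(locsList[[i]])
    ons[i, seq_len(L)] <- t0 + (seq_len(L) - 1) * step
    fp[i] <- ons[i, L] + step
    t0 <- fp[i] + 2000
  }
  for (j in 1:4) out[[paste0("cue_loc_", j)]] <- locs[, j]
  for (j in 1:4) out[[paste0("cue_onset_", j)]] <- ons[, j]
  out$fp_offset <- fp
  out$stim <- "none"
  out
}

# epoch-count pools shaped like assemblePseudopopulation output, built
# directly from per-rule feature matrices
makeTensor <- function(perNeuron) {
  if (is.null(names(perNeuron)))
    names(perNeuron) <- paste0("n", seq_along(perNeuron))
  structure(list(neurons = perNeuron, excluded = character(0),
                 epochs = c("D1_early", "D1_late", "D2_early", "D2_late")),
            class = "FeatureTensor")
}

# gaussian feature pools for decoding tests: per-rule mean vectors over the
# four epochs
gaussPools <- function(mu1b, mu2b, nTrials = 20, sdev = 1) {
  m1 <- matrix(stats::rnorm(nTrials * 4, rep(mu1b, each = nTrials), sdev),
               nTrials, 4, dimnames = list(NULL, c("D1_early", "D1_late",
                                                   "D2_early", "D2_late")))
  m2 <- matrix(stats::rnorm(nTrials * 4, rep(mu2b, each = nTrials), sdev),
               nTrials, 4, dimnames = dimnames(m1))
  list("1-back" = m1, "2-back" = m2)
}
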