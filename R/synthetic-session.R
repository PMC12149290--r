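ARCHETYPES <- c("memory", "extinction", "visual", "order", "rule", "mixed", "null")

#' Specification of one synthetic neuron
#'
#' Describes a neuron as one of the canonical delay-activity archetypes:
#' \describe{
#'   \item{memory}{sustained elevation while its preferred location is in the
#'     required memory set;}
#'   \item{extinction}{a transient burst when the memory of its preferred
#'     location becomes obsolete;}
#'   \item{visual}{a transient burst after each cue at its preferred location;}
#'   \item{order}{delay activity scaled by the serial position of the current
#'     cue (the order covariate, 0 to 1 over positions 1--4);}
#'   \item{rule}{tonic elevation in 2-back trials;}
#'   \item{mixed}{a weighted blend of the above;}
#'   \item{null}{constant baseline (no task modulation).}
#' }
#'
#' @param neuron_id character or integer identifier.
#' @param archetype one of \code{"memory"}, \code{"extinction"},
#'   \code{"visual"}, \code{"order"}, \code{"rule"}, \code{"mixed"},
#'   \code{"null"}.
#' @param preferred_location 0-based location index (directional archetypes).
#' @param baseline_rate baseline firing rate, spikes/s.
#' @param gain added rate (spikes/s) at full component drive.
#' @param transient_duration duration (ms) of visual/extinction transients,
#'   aligned to cue onset.
#' @param mixture_weights named numeric weights over
#'   \code{c("memory","extinction","visual","order","rule")} for the mixed
#'   archetype; must sum to 1.
#' @param spike_width_ms trough-to-peak spike width carried as metadata.
#' @return A validated list of class \code{"NeuronSpec"}.
#' @export
neuronSpec <- function(neuron_id, archetype,
                       preferred_location = 0L,
                       baseline_rate = 5,
                       gain = 8,
                       transient_duration = 400,
                       mixture_weights = NULL,
                       spike_width_ms = 0.4) {
  archetype <- match.arg(archetype, ARCHETYPES)
  if (baseline_rate < 0 || gain < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (archetype == "mixed") {
    if (is.null(mixture_weights) || is.null(names(mixture_weights)) ||
        !all(names(mixture_weights) %in% ARCHETYPES[1:5]))
      stop("mixed archetype needs named mixture_weights over the five components",
           call. = FALSE)
    if (abs(sum(mixture_weights) - 1) > 1e-8)
      stop("mixture_weights must sum to 1", call. = FALSE)
  }
  structure(list(neuron_id = as.character(neuron_id),
                 archetype = archetype,
                 preferred_location = as.integer(preferred_location),
                 baseline_rate = baseline_rate,
                 gain = gain,
                 transient_duration = transient_duration,
                 mixture_weights = mixture_weights,
                 spike_width_ms = spike_width_ms),
            class = "NeuronSpec")
}

#' @export
print.NeuronSpec <- function(x, ...) {
  cat("NeuronSpec", x$neuron_id, "-", x$archetype,
      if (x$archetype %in% c("memory", "extinction", "visual", "mixed"))
        paste0("(pref loc ", x$preferred_location, ")") else "",
      sprintf("baseline %g + gain %g spikes/s\n", x$baseline_rate, x$gain))
  invisible(x)
}

#' Behavioral parameters of the synthetic subject
#'
#' Per-rule probabilities of the behavioral outcome categories, reaction-time
#' moments, saccade endpoint noise, the trajectory-angle bias toward or away
#' from the non-target cue, and the causal parameters of the stimulation
#' manipulation. Defaults reproduce the published session-level behavior:
#' rule errors 1.7\%/3.3\%, 2/3-back memory errors 2.8\%/4.1\%, random
#' memory errors 0.2\%/0.4\%, fixation breaks 5.6\%/7.5\%, reaction times
#' 208±51 / 194±29 ms (1-back/2-back), and a trajectory-angle difference of
#' -3 degrees (2-back minus 1-back: the endpoint shifts away from the
#' non-target cue under the 2-back rule).
#'
#' All per-rule vectors are named \code{c("1-back", "2-back")}.
#'
#' @param p_rule_error probability of a rule error.
#' @param p_mem_23back probability of a 2/3-back memory error.
#' @param p_mem_random probability of a never-cued-location memory error.
#' @param p_fixation_break probability of breaking fixation before FP offset.
#' @param rt_mean,rt_sd reaction-time mean and SD (ms).
#' @param endpoint_radial_sd radial endpoint noise SD (deg).
#' @param theta_bias_mean mean trajectory angle (deg), positive toward the
#'   non-target cue.
#' @param theta_sd SD of the per-trial trajectory angle (deg).
#' @param stim_p_erase probability that eligible stimulation erases the
#'   targeted memory.
#' @param stim_rt_shortening latency reduction (ms) on stimulation trials.
#' @param stim_accuracy_worsening added endpoint scatter (deg) on stimulation
#'   trials.
#' @return A validated list of class \code{"BehaviorSpec"}.
#' @export
behaviorSpec <- function(p_rule_error = c("1-back" = 0.017, "2-back" = 0.033),
                         p_mem_23back = c("1-back" = 0.028, "2-back" = 0.041),
                         p_mem_random = c("1-back" = 0.002, "2-back" = 0.004),
                         p_fixation_break = c("1-back" = 0.056, "2-back" = 0.075),
                         rt_mean = c("1-back" = 208, "2-back" = 194),
                         rt_sd = c("1-back" = 51, "2-back" = 29),
                         endpoint_radial_sd = 0.8,
                         theta_bias_mean = c("1-back" = 1, "2-back" = -2),
                         theta_sd = c("1-back" = 6, "2-back" = 6),
                         stim_p_erase = 0.3,
                         stim_rt_shortening = 15,
                         stim_accuracy_worsening = 0.5) {
  spec <- list(p_rule_error = p_rule_error, p_mem_23back = p_mem_23back,
               p_mem_random = p_mem_random, p_fixation_break = p_fixation_break,
               rt_mean = rt_mean, rt_sd = rt_sd,
               endpoint_radial_sd = endpoint_radial_sd,
               theta_bias_mean = theta_bias_mean, theta_sd = theta_sd,
               stim_p_erase = stim_p_erase,
               stim_rt_shortening = stim_rt_shortening,
               stim_accuracy_worsening = stim_accuracy_worsening)
  for (nm in c("p_rule_error", "p_mem_23back", "p_mem_random",
               "p_fixation_break", "rt_mean", "rt_sd",
               "theta_bias_mean", "theta_sd")) {
    v <- spec[[nm]]
    if (length(v) != 2L || !all(RULES %in% names(v)))
      stop(nm, " must be a length-2 vector named '1-back'/'2-back'", call. = FALSE)
  }
  probs <- c(p_rule_error, p_mem_23back, p_mem_random, p_fixation_break,
             stim_p_erase)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  tot <- p_rule_error + p_mem_23back + p_mem_random
  if (any(tot >= 1))
    stop("per-rule error probabilities must sum to < 1", call. = FALSE)
  if (any(rt_sd <= 0)) stop("rt_sd must be positive", call. = FALSE)
  structure(spec, class = "BehaviorSpec")
}

#' Generate the trial schedule of a synthetic session
#'
#' Cue counts are drawn uniformly from the configured range, cue locations
#' uniformly with replacement over the four task locations, rules drawn
#' according to \code{ruleMix}, and stimulation assigned independently to the
#' requested fraction of trials, randomly interleaved. Trials are laid out
#' consecutively on a session-relative millisecond clock: cue onsets are
#' separated by cue duration + delay duration, and FP offset falls one full
#' cue + delay interval after the last cue onset.
#'
#' @param config a [TaskConfig-class].
#' @param nTrials number of trials (> 0).
#' @param ruleMix named numeric proportions over \code{c("1-back","2-back")}.
#' @param stimFraction fraction of trials receiving electrical stimulation.
#' @param stimTiming "early" (first half of the last delay period), "late"
#'   (last 400 ms before FP offset), or "both" (an even split).
#' @param horizontalOnly logical; restrict cues to the two horizontal
#'   locations (the stimulation-experiment configuration). Requires the
#'   cardinal angle set.
#' @param seed optional integer seed (the schedule is deterministic given it).
#' @return trials data.frame (see [SessionBundle-class] for the schema).
#' @export
generateTrials <- function(config, nTrials,
                           ruleMix = c("1-back" = 0.5, "2-back" = 0.5),
                           stimFraction = 0,
                           stimTiming = c("early", "late", "both"),
                           horizontalOnly = FALSE,
                           seed = NULL) {
  stimTiming <- match.arg(stimTiming)
  if (nTrials <= 0) stop("nTrials must be positive", call. = FALSE)
  if (!length(ruleMix) || !all(names(ruleMix) %in% RULES))
    stop("ruleMix must be named over '1-back'/'2-back'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ruleMix <- ruleMix / sum(ruleMix)
  n <- as.integer(nTrials)
  rule <- sample(names(ruleMix), n, replace = TRUE, prob = ruleMix)
  nc <- sample(seq(config@cueCountRange[1], config@cueCountRange[2]),
               n, replace = TRUE)
  locPool <- if (horizontalOnly) {
    hv <- which(abs(sin(config@locationAngles * pi / 180)) < 1e-9) - 1L
    if (length(hv) < 2L)
      stop("horizontalOnly requires two horizontal locations in the angle set",
           call. = FALSE)
    hv
  } else seq_len(config@nLocations) - 1L
  locs <- matrix(NA_integer_, n, 4)
  ons <- matrix(NA_real_, n, 4)
  step <- config@cueDuration + config@delayDuration
  t0 <- 500  # fixation lead-in before the first cue of the session
  fp <- numeric(n)
  for (i in seq_len(n)) {
    L <- nc[i]
    locs[i, seq_len(L)] <- sample(locPool, L, replace = TRUE)
    ons[i, seq_len(L)] <- t0 + (seq_len(L) - 1) * step
    fp[i] <- ons[i, L] + step
    # trial ends after target reappearance + hold; next trial after the ITI
    t0 <- fp[i] + config@targetReappearAfterFpOff + 1000 +
      config@intertrialInterval + 500
  }
  stim <- rep("none", n)
  if (stimFraction > 0) {
    on <- runif(n) < stimFraction
    stim[on] <- switch(stimTiming,
                       early = "early",
                       late = "late",
                       both = sample(c("early", "late"), sum(on), replace = TRUE))
  }
  out <- data.frame(trial_id = seq_len(n), rule = rule, n_cues = nc,
                    stringsAsFactors = FALSE)
  for (j in 1:4) out[[paste0("cue_loc_", j)]] <- locs[, j]
  for (j in 1:4) out[[paste0("cue_onset_", j)]] <- ons[, j]
  out$fp_offset <- fp
  out$stim <- stim
  out
}

# onset (ms) of electrical stimulation for a trial row, or NA
stimOnsetTime <- function(trials, config) {
  lastOn <- trials$fp_offset - config@delayDuration
  ifelse(trials$stim == "early", lastOn,
         ifelse(trials$stim == "late", trials$fp_offset - 400, NA_real_))
}

# ---------------------------------------------------------------------------
# choice behavior

# per-trial bookkeeping used by the choice simulator and the stimulation tests
trialGeometry <- function(trials, config, hemisphere = "left") {
  n <- nrow(trials)
  locs <- as.matrix(trials[paste0("cue_loc_", 1:4)])
  L <- trials$n_cues
  idx <- cbind(seq_len(n), L)
  lastLoc <- locs[idx]
  prevLoc <- locs[cbind(seq_len(n), L - 1L)]
  target <- ifelse(trials$rule == "1-back", lastLoc, prevLoc)
  other <- ifelse(trials$rule == "1-back", prevLoc, lastLoc)
  hemi <- hemifieldMap(config, hemisphere)
  list(locs = locs, L = L, lastLoc = lastLoc, prevLoc = prevLoc,
       target = target, other = other,
       lastContra = hemi[lastLoc + 1L] %in% "contra",
       prevContra = hemi[prevLoc + 1L] %in% "contra")
}

# most recent earlier-cue location (positions 1..L-2) outside {target, other};
# NA when none exists
mem23Candidate <- function(geo) {
  n <- nrow(geo$locs)
  cand <- rep(NA_integer_, n)
  # positions L-2 down to 1 (at most 4 cues per trial)
  for (back in 2:3) {
    pos <- geo$L - back
    ok <- is.na(cand) & pos >= 1L
    if (!any(ok)) next
    v <- geo$locs[cbind(seq_len(n), pmax(pos, 1L))]
    good <- ok & !is.na(v) & v != geo$target & v != geo$other
    cand[good] <- v[good]
  }
  cand
}

# a never-cued location for each trial (uniform among those), NA when all cued
randomCandidate <- function(geo, nLocations, u) {
  n <- nrow(geo$locs)
  cued <- matrix(FALSE, n, nLocations)
  for (j in 1:4) {
    v <- geo$locs[, j]
    ok <- !is.na(v)
    cued[cbind(which(ok), v[ok] + 1L)] <- TRUE
  }
  avail <- nLocations - rowSums(cued)
  cand <- rep(NA_integer_, n)
  has <- avail > 0
  pick <- ceiling(u * avail)
  for (i in which(has)) {
    open <- which(!cued[i, ]) - 1L
    cand[i] <- open[pick[i]]
  }
  cand
}

#' Simulate choice behavior for a table of trials
#'
#' Draws a behavioral outcome for every trial: a fixation break with the
#' per-rule probability, otherwise a choice category (correct / rule error /
#' 2-3-back memory error / random memory error) whose marginal frequencies
#' converge to the \code{BehaviorSpec} probabilities. Because some categories
#' are unachievable on some trials (a 2-cue trial has no 2/3-back location; a
#' trial cueing all four locations has no never-cued one), category
#' probabilities are renormalized by each category's achievable fraction
#' within the generated trial set, and the recorded category is always
#' re-derived from the chosen location via [classifyChoice()].
#'
#' Stimulation acts causally: early stimulation in the last delay period of a
#' 2-back trial whose last-1 cue is contralateral erases that memory with
#' probability \code{stim_p_erase}, redirecting the saccade to the most
#' recent cue (a rule error); late stimulation in a 1-back trial with a
#' contralateral last cue erases the retained memory and redirects to the
#' one-previous cue. Stimulation also shortens latency by
#' \code{stim_rt_shortening} and inflates endpoint scatter by
#' \code{stim_accuracy_worsening} on all stimulation trials.
#'
#' @param trials trials data.frame from [generateTrials()].
#' @param spec a [behaviorSpec()].
#' @param config a [TaskConfig-class].
#' @param hemisphere recorded hemisphere ("left"/"right"), used to decide
#'   which cues are contralateral.
#' @param seed optional integer seed.
#' @return data.frame with one row per trial: \code{trial_id},
#'   \code{category}, \code{chosen_loc}, \code{rt_ms}, \code{end_x},
#'   \code{end_y} and \code{erased} (logical stimulation-erasure flag).
#' @export
simulateChoices <- function(trials, spec, config = taskConfig(),
                            hemisphere = "left", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  rule <- trials$rule
  geo <- trialGeometry(trials, config, hemisphere)
  fb <- runif(n) < spec$p_fixation_break[rule]

  availRule <- geo$other != geo$target
  cand23 <- mem23Candidate(geo)
  avail23 <- !is.na(cand23)
  candRand <- randomCandidate(geo, config@nLocations, runif(n))
  availRand <- !is.na(candRand)

  chosen <- geo$target
  for (r in RULES) {
    sel <- rule == r & !fb
    if (!any(sel)) next
    fRule <- max(mean(availRule[sel]), 1e-12)
    f23 <- max(mean(avail23[sel]), 1e-12)
    fRand <- max(mean(availRand[sel]), 1e-12)
    pR <- ifelse(availRule[sel], spec$p_rule_error[r] / fRule, 0)
    p2 <- ifelse(avail23[sel], spec$p_mem_23back[r] / f23, 0)
    pX <- ifelse(availRand[sel], spec$p_mem_random[r] / fRand, 0)
    v <- runif(sum(sel))
    pick <- ifelse(v < pR, "rule",
                   ifelse(v < pR + p2, "mem23",
                          ifelse(v < pR + p2 + pX, "rand", "correct")))
    ch <- geo$target[sel]
    ch[pick == "rule"] <- geo$other[sel][pick == "rule"]
    ch[pick == "mem23"] <- cand23[sel][pick == "mem23"]
    ch[pick == "rand"] <- candRand[sel][pick == "rand"]
    chosen[sel] <- ch
  }

  # stimulation-induced memory erasure
  eligible <- !fb &
    ((trials$stim == "early" & rule == "2-back" & geo$prevContra) |
     (trials$stim == "late" & rule == "1-back" & geo$lastContra))
  erased <- eligible & runif(n) < spec$stim_p_erase
  redirect <- ifelse(trials$stim == "early", geo$lastLoc, geo$prevLoc)
  chosen[erased] <- redirect[erased]

  # re-derive the category from the chosen location (taxonomy authority)
  earlier <- matrix(NA_integer_, n, 2)
  earlier[, 1] <- ifelse(geo$L >= 3L, geo$locs[cbind(seq_len(n), pmax(geo$L - 2L, 1L))],
                         NA_integer_)
  earlier[, 2] <- ifelse(geo$L >= 4L, geo$locs[, 1], NA_integer_)
  category <- ifelse(chosen == geo$target, "correct",
              ifelse(chosen == geo$other, "rule_error",
              ifelse((!is.na(earlier[, 1]) & chosen == earlier[, 1]) |
                     (!is.na(earlier[, 2]) & chosen == earlier[, 2]),
                     "mem_error_23back", "mem_error_random")))
  category[fb] <- "fixation_break"
  chosen[fb] <- NA_integer_

  stimOn <- trials$stim != "none"
  rt <- rnorm(n, spec$rt_mean[rule], spec$rt_sd[rule]) -
    ifelse(stimOn, spec$stim_rt_shortening, 0)
  rt <- pmax(rt, 60)
  rt[fb] <- NA_real_

  ang <- config@locationAngles
  chosenAng <- ang[chosen + 1L]
  nontarget <- ifelse(chosen == geo$target, geo$other,
                      ifelse(chosen == geo$other, geo$target, NA_integer_))
  diffAng <- wrapDeg(ang[nontarget + 1L] - chosenAng)
  s <- ifelse(is.na(diffAng) | diffAng == 0,
              sample(c(-1, 1), n, replace = TRUE), sign(diffAng))
  biased <- !is.na(diffAng) & abs(abs(diffAng) - 90) < 1e-6
  theta <- rnorm(n, ifelse(biased, spec$theta_bias_mean[rule], 0),
                 spec$theta_sd[rule])
  endAng <- (chosenAng + s * theta) * pi / 180
  radius <- config@eccentricity +
    rnorm(n, 0, spec$endpoint_radial_sd +
                ifelse(stimOn, spec$stim_accuracy_worsening, 0))
  ex <- radius * cos(endAng)
  ey <- radius * sin(endAng)
  ex[fb] <- NA_real_; ey[fb] <- NA_real_

  data.frame(trial_id = trials$trial_id, category = category,
             chosen_loc = chosen, rt_ms = rt, end_x = ex, end_y = ey,
             erased = erased, stringsAsFactors = FALSE)
}

#' @rdname simulateChoices
#' @param trial a single trial (list from [trialFromRow()] or a one-row
#'   trials data.frame).
#' @export
simulateChoice <- function(trial, spec, config = taskConfig(),
                           hemisphere = "left", seed = NULL) {
  if (is.list(trial) && !is.data.frame(trial)) {
    row <- data.frame(trial_id = trial$trial_id, rule = trial$rule,
                      n_cues = length(trial$cue_locations),
                      stringsAsFactors = FALSE)
    for (j in 1:4) row[[paste0("cue_loc_", j)]] <-
        if (j <= length(trial$cue_locations)) trial$cue_locations[j] else NA_integer_
    for (j in 1:4) row[[paste0("cue_onset_", j)]] <-
        if (j <= length(trial$cue_onsets)) trial$cue_onsets[j] else NA_real_
    row$fp_offset <- trial$fp_offset
    row$stim <- trial$stim
    trial <- row
  }
  simulateChoices(trial, spec, config, hemisphere, seed)
}

wrapDeg <- function(x) ((x + 180) %% 360) - 180

# ---------------------------------------------------------------------------
# firing-rate model and spike sampling

#' Piecewise-constant firing-rate profile of a neuron on one trial
#'
#' Builds the inhomogeneous firing rate implied by the neuron's archetype:
#' memory neurons are elevated while their preferred location is in the
#' required memory set; extinction neurons fire a transient after the cue at
#' which that memory becomes obsolete; visual neurons a transient after each
#' preferred-location cue; order neurons scale with the serial position of
#' the current cue ((k-1)/3 over positions 1--4); rule neurons are tonically
#' elevated in 2-back trials. When the trial's memory was erased by
#' stimulation, the memory component for the erased location terminates at
#' stimulation onset.
#'
#' @param spec a [neuronSpec()].
#' @param trial a trial list (see [trialFromRow()]).
#' @param config a [TaskConfig-class].
#' @param erased logical, stimulation-erasure flag for this trial.
#' @return list with numeric \code{breaks} (length m+1, ms) and \code{rates}
#'   (length m, spikes/s >= 0): the rate is \code{rates[i]} on
#'   \code{[breaks[i], breaks[i+1])}.
#' @export
rateProfile <- function(spec, trial, config = taskConfig(), erased = FALSE) {
  on <- trial$cue_onsets
  locs <- trial$cue_locations
  L <- length(on)
  t0 <- on[1] - 600
  t1 <- trial$fp_offset + 600
  w <- switch(spec$archetype,
              mixed = spec$mixture_weights,
              null = c(),
              stats::setNames(1, spec$archetype))
  cw <- function(nm) if (!is.null(w) && nm %in% names(w)) w[[nm]] else 0

  starts <- numeric(0); ends <- numeric(0); amps <- numeric(0)
  add <- function(s, e, a) {
    if (e > s && a != 0) {
      starts <<- c(starts, s); ends <<- c(ends, e); amps <<- c(amps, a)
    }
  }

  segEnd <- c(on[-1], trial$fp_offset)
  stimT <- if (trial$stim == "early") trial$fp_offset - config@delayDuration
           else if (trial$stim == "late") trial$fp_offset - 400 else NA_real_
  erasedLoc <- if (isTRUE(erased)) {
    if (trial$stim == "early") locs[L - 1L] else locs[L]
  } else NA_integer_

  for (k in seq_len(L)) {
    if (cw("visual") > 0 && locs[k] == spec$preferred_location)
      add(on[k], on[k] + spec$transient_duration, spec$gain * cw("visual"))
    if (cw("extinction") > 0) {
      ex <- extinctionLocation(trial$rule, locs, k)
      if (!is.na(ex) && ex == spec$preferred_location)
        add(on[k], on[k] + spec$transient_duration, spec$gain * cw("extinction"))
    }
    if (cw("memory") > 0 &&
        spec$preferred_location %in% requiredMemorySet(trial$rule, locs, k)) {
      e <- segEnd[k]
      if (!is.na(erasedLoc) && spec$preferred_location == erasedLoc &&
          !is.na(stimT))
        e <- min(e, stimT)
      add(on[k], e, spec$gain * cw("memory"))
    }
    if (cw("order") > 0)
      add(on[k], segEnd[k], spec$gain * cw("order") * (k - 1) / 3)
  }
  if (cw("rule") > 0 && trial$rule == "2-back")
    add(t0, t1, spec$gain * cw("rule"))

  breaks <- sort(unique(c(t0, t1, pmax(pmin(c(starts, ends), t1), t0))))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rates <- rep(spec$baseline_rate, length(mids))
  for (a in seq_along(starts)) {
    inside <- mids >= starts[a] & mids < ends[a]
    rates[inside] <- rates[inside] + amps[a]
  }
  list(breaks = breaks, rates = rates)
}

#' Sample spikes from a piecewise-constant rate by thinning
#'
#' Inhomogeneous-Poisson sampling: candidate events are drawn from a
#' homogeneous process at the profile's maximum rate and accepted with
#' probability rate(t)/bound, so counts over any window are Poisson with mean
#' equal to the integral of the rate.
#'
#' @param profile a profile from [rateProfile()] (or any list with
#'   \code{breaks}/\code{rates}).
#' @param tRange optional length-2 window (ms) to restrict sampling to.
#' @param seed optional integer seed.
#' @return Strictly increasing numeric spike times (ms).
#' @export
sampleSpikes <- function(profile, tRange = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(profile$rates < 0)) stop("negative rate", call. = FALSE)
  br <- profile$breaks
  a <- if (is.null(tRange)) br[1] else max(tRange[1], br[1])
  b <- if (is.null(tRange)) br[length(br)] else min(tRange[2], br[length(br)])
  if (!is.finite(a) || !is.finite(b) || b <= a)
    stop("sampling range must be finite and non-empty", call. = FALSE)
  bound <- max(profile$rates)
  if (bound == 0) return(numeric(0))
  nCand <- rpois(1, bound * (b - a) / 1000)
  if (nCand == 0) return(numeric(0))
  tt <- sort(runif(nCand, a, b))
  seg <- findInterval(tt, br, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg > length(profile$rates)] <- length(profile$rates)
  keep <- runif(nCand) < profile$rates[seg] / bound
  unique(tt[keep])
}

# expected spike count of a profile over [w0, w1) (ms)
profileIntegral <- function(profile, w0, w1) {
  br <- profile$breaks
  lo <- pmax(br[-length(br)], w0)
  hi <- pmin(br[-1], w1)
  sum(pmax(hi - lo, 0) * profile$rates) / 1000
}

#' Draw early/late delay-epoch spike counts for one neuron
#'
#' A fast path equivalent in distribution to sampling full spike trains with
#' [sampleSpikes()] and counting: for every delay period of every trial the
#' expected count is the integral of the neuron's [rateProfile()] over the
#' 400-ms epoch and the count is a Poisson draw with that mean.
#'
#' @param spec a [neuronSpec()].
#' @param trials trials data.frame.
#' @param config a [TaskConfig-class].
#' @param erasedFlags logical vector over trials (stimulation erasure), or
#'   NULL for none.
#' @param seed optional integer seed.
#' @return data.frame: \code{trial_id}, \code{delay}, \code{epoch}
#'   ("early"/"late"), \code{count}, \code{d_tag}.
#' @export
simulateEpochCounts <- function(spec, trials, config = taskConfig(),
                                erasedFlags = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(erasedFlags)) erasedFlags <- rep(FALSE, nrow(trials))
  res <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trialFromRow(trials, i)
    prof <- rateProfile(spec, tr, config, erased = erasedFlags[i])
    ep <- delayEpochs(tr, config)
    mu <- numeric(2 * nrow(ep))
    for (k in seq_len(nrow(ep))) {
      mu[2 * k - 1] <- profileIntegral(prof, ep$early_start[k], ep$early_end[k])
      mu[2 * k] <- profileIntegral(prof, ep$late_start[k], ep$late_end[k])
    }
    res[[i]] <- data.frame(
      trial_id = tr$trial_id,
      delay = rep(ep$delay, each = 2),
      epoch = rep(c("early", "late"), nrow(ep)),
      count = rpois(length(mu), mu),
      d_tag = rep(ep$d_tag, each = 2),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Synthesize a 1-kHz eye-position trace for one trial
#'
#' Gaussian fixation jitter (SD 0.05 deg) around the fixation point until FP
#' offset + reaction time, then a stereotyped saccade with a raised-cosine
#' velocity profile (40 ms duration, peak velocity well above the 70 deg/s
#' detection threshold for 12-degree saccades) landing on the outcome's
#' endpoint, followed by fixation at the endpoint. Fixation-break outcomes
#' saccade to a random peripheral point 200 ms before FP offset; no-response
#' outcomes never leave fixation.
#'
#' @param trial a trial list (see [trialFromRow()]).
#' @param outcome one outcome row from [simulateChoices()] (needs
#'   \code{rt_ms}, \code{end_x}, \code{end_y}, \code{category}).
#' @param spec a [behaviorSpec()] (fixation jitter scale source).
#' @param config a [TaskConfig-class].
#' @param seed optional integer seed.
#' @return data.frame \code{t_ms}, \code{x_deg}, \code{y_deg} sampled every
#'   millisecond from 500 ms before the first cue to 600 ms after FP offset.
#' @export
synthesizeEyeTrace <- function(trial, outcome, spec = behaviorSpec(),
                               config = taskConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(floor(trial$cue_onsets[1] - 500), ceiling(trial$fp_offset + 600))
  n <- length(t)
  jit <- 0.05
  x <- rnorm(n, 0, jit)
  y <- rnorm(n, 0, jit)
  cat. <- outcome$category
  sacDur <- 40
  launch <- function(t_on, ex, ey) {
    tau <- (t - t_on) / sacDur
    s <- ifelse(tau <= 0, 0, ifelse(tau >= 1, 1, tau - sin(2 * pi * tau) / (2 * pi)))
    x <<- x + s * ex
    y <<- y + s * ey
  }
  if (cat. == "fixation_break") {
    ang <- runif(1, 0, 2 * pi)
    launch(trial$fp_offset - 200, config@eccentricity * cos(ang),
           config@eccentricity * sin(ang))
  } else if (cat. != "no_response" && !is.na(outcome$rt_ms)) {
    launch(trial$fp_offset + outcome$rt_ms, outcome$end_x, outcome$end_y)
  }
  data.frame(t_ms = t, x_deg = x, y_deg = y)
}

# ---------------------------------------------------------------------------
# whole-session orchestration

#' Simulate a complete synthetic session
#'
#' Generates the trial schedule, choice behavior (including stimulation
#' erasure), spike trains for every specified neuron (full inhomogeneous-
#' Poisson sampling via [sampleSpikes()]), optionally 1-kHz eye traces, and a
#' ground-truth sidecar holding the specifications, the master seed and the
#' per-trial erased-memory flags. Identical arguments (including
#' \code{seed}) regenerate the identical session.
#'
#' @param config a [TaskConfig-class].
#' @param nTrials number of trials.
#' @param neuronSpecs list of [neuronSpec()] objects.
#' @param behavior a [behaviorSpec()].
#' @param hemisphere recorded hemisphere, "left" or "right".
#' @param ruleMix,stimFraction,stimTiming,horizontalOnly passed to
#'   [generateTrials()].
#' @param eyeTraces logical; synthesize the (large) 1-kHz eye table.
#' @param sessionId identifier stored in the metadata.
#' @param seed master integer seed; every stochastic stage derives its own
#'   stream from it.
#' @return A [SessionBundle-class] with outcome columns merged into the
#'   trials table and ground truth attached.
#' @export
simulateSession <- function(config = taskConfig(), nTrials = 200,
                            neuronSpecs = list(),
                            behavior = behaviorSpec(),
                            hemisphere = "left",
                            ruleMix = c("1-back" = 0.5, "2-back" = 0.5),
                            stimFraction = 0,
                            stimTiming = "early",
                            horizontalOnly = FALSE,
                            eyeTraces = FALSE,
                            sessionId = "synthetic-01",
                            seed = 1L) {
  trials <- generateTrials(config, nTrials, ruleMix, stimFraction,
                           stimTiming, horizontalOnly, seed = seed)
  outcomes <- simulateChoices(trials, behavior, config, hemisphere,
                              seed = seed + 1L)
  spikes <- data.frame(neuron_id = character(0), t_ms = numeric(0))
  if (length(neuronSpecs)) {
    per <- vector("list", length(neuronSpecs))
    for (j in seq_along(neuronSpecs)) {
      sp <- neuronSpecs[[j]]
      set.seed(seed + 100L + j)
      ts <- lapply(seq_len(nrow(trials)), function(i) {
        tr <- trialFromRow(trials, i)
        prof <- rateProfile(sp, tr, config, erased = outcomes$erased[i])
        sampleSpikes(prof)
      })
      ts <- sort(unlist(ts))
      per[[j]] <- data.frame(neuron_id = sp$neuron_id, t_ms = ts,
                             stringsAsFactors = FALSE)
    }
    spikes <- do.call(rbind, per)
  }
  eye <- data.frame(t_ms = numeric(0), x_deg = numeric(0), y_deg = numeric(0),
                    trial_id = integer(0))
  if (eyeTraces) {
    per <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- trialFromRow(trials, i)
      e <- synthesizeEyeTrace(tr, outcomes[i, ], behavior, config,
                              seed = seed + 10000L + i)
      e$trial_id <- tr$trial_id
      per[[i]] <- e
    }
    eye <- do.call(rbind, per)
  }
  neurons <- if (length(neuronSpecs)) {
    data.frame(neuron_id = vapply(neuronSpecs, `[[`, "", "neuron_id"),
               spike_width_ms = vapply(neuronSpecs, `[[`, 0, "spike_width_ms"),
               stringsAsFactors = FALSE)
  } else data.frame(neuron_id = character(0), spike_width_ms = numeric(0))
  trials2 <- cbind(trials, outcomes[match(trials$trial_id, outcomes$trial_id),
                                    c("category", "chosen_loc", "rt_ms",
                                      "end_x", "end_y", "erased")])
  truth <- list(seed = seed,
                behavior = unclass(behavior),
                neurons = lapply(neuronSpecs, unclass),
                erased = outcomes$erased)
  new("SessionBundle",
      meta = list(session_id = sessionId, hemisphere = hemisphere,
                  config = config),
      trials = trials2, spikes = spikes, neurons = neurons, eye = eye,
      truth = truth)
}
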