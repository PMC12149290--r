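cfg <- taskConfig()

test_that("trial generation respects counts, marginals and stimulation fraction", {
  expect_identical(nrow(generateTrials(cfg, 1, seed = 1)), 1L)
  expect_error(generateTrials(cfg, 0), "positive")
  expect_error(generateTrials(cfg, 10, ruleMix = c(foo = 1)), "ruleMix")
  big <- generateTrials(cfg, 10000, seed = 2)
  locs <- unlist(big[paste0("cue_loc_", 1:4)])
  tab <- table(factor(locs[!is.na(locs)], 0:3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  stim <- generateTrials(cfg, 4000, stimFraction = 0.5, seed = 3)
  nOn <- sum(stim$stim != "none")
  expect_lt(abs(nOn - 2000), 4 * sqrt(4000 * 0.25))
  # schedule invariant
  expect_equal(stim$fp_offset,
               stim$cue_onset_1 + stim$n_cues * (cfg@cueDuration + cfg@delayDuration))
})

test_that("rate profiles implement the archetype semantics", {
  nullSp <- neuronSpec("n", "null", baseline_rate = 4)
  prof <- rateProfile(nullSp, makeTrial("1-back", c(0, 1)), cfg)
  expect_equal(unique(prof$rates), 4)

  mem <- neuronSpec("m", "memory", preferred_location = 0L,
                    baseline_rate = 5, gain = 8)
  # 1-back, cues [P, N]: elevated during delay 1 only
  tr <- makeTrial("1-back", c(0, 1))
  p1 <- rateProfile(mem, tr, cfg)
  rateAt <- function(p, t) p$rates[findInterval(t, p$breaks)]
  expect_equal(rateAt(p1, 800), 13)             # mid delay 1
  expect_equal(rateAt(p1, 1800), 5)             # mid delay 2
  # 2-back, cues [P, N, N]: elevated through delays 1-2, baseline in delay 3
  tr2 <- makeTrial("2-back", c(0, 1, 1))
  p2 <- rateProfile(mem, tr2, cfg)
  expect_equal(rateAt(p2, 800), 13)
  expect_equal(rateAt(p2, 1800), 13)
  expect_equal(rateAt(p2, 2800), 5)

  ext <- neuronSpec("e", "extinction", preferred_location = 0L,
                    baseline_rate = 5, gain = 8, transient_duration = 400)
  # 1-back [P, N]: transient after cue 2 (memory of P dropped)
  p3 <- rateProfile(ext, tr, cfg)
  expect_equal(rateAt(p3, tr$cue_onsets[2] + 200), 13)
  expect_equal(rateAt(p3, tr$cue_onsets[2] + 500), 5)
})

test_that("stimulation erasure truncates the memory rate at stim onset", {
  # the erased memory under early stimulation is the last-1 cue (location 1
  # here), which is still in the required memory set during the last delay
  mem <- neuronSpec("m", "memory", preferred_location = 1L,
                    baseline_rate = 5, gain = 8)
  tr <- makeTrial("2-back", c(0, 1, 2), stim = "early")
  rateAt <- function(p, t) p$rates[findInterval(t, p$breaks)]
  pOn <- rateProfile(mem, tr, cfg, erased = TRUE)
  stimT <- tr$fp_offset - cfg@delayDuration
  expect_equal(rateAt(pOn, stimT - 300), 13)  # before stim: P still remembered
  expect_equal(rateAt(pOn, stimT + 300), 5)   # after stim onset: erased
  pOff <- rateProfile(mem, tr, cfg, erased = FALSE)
  expect_equal(rateAt(pOff, stimT + 300), 13)
})

test_that("thinning sampler has Poisson moments and scales with rate", {
  expect_length(sampleSpikes(list(breaks = c(0, 1000), rates = 0), seed = 1), 0)
  expect_error(sampleSpikes(list(breaks = c(0, 1000), rates = -1)), "negative")
  prof <- list(breaks = c(0, 1000), rates = 20)
  set.seed(5)
  counts <- replicate(5000, length(sampleSpikes(prof)))
  expect_lt(abs(mean(counts) - 20), 0.3)
  expect_lt(abs(stats::var(counts) - 20), 1.5)
  prof2 <- list(breaks = c(0, 1000), rates = 40)
  set.seed(6)
  counts2 <- replicate(2000, length(sampleSpikes(prof2)))
  expect_lt(abs(mean(counts2) / mean(counts) - 2), 0.1)
  # timestamps strictly increasing
  ts <- sampleSpikes(prof, seed = 7)
  expect_true(all(diff(ts) > 0))
})

test_that("choice category frequencies converge to the behavior spec", {
  spec <- behaviorSpec()
  trials <- generateTrials(cfg, 5000, seed = 10)
  oc <- simulateChoices(trials, spec, cfg, seed = 11)
  expect_identical(nrow(oc), nrow(trials))   # conservation
  for (r in c("1-back", "2-back")) {
    sub <- oc[trials$rule == r, ]
    compl <- sub[sub$category != "fixation_break", ]
    pExp <- c(correct = unname(1 - spec$p_rule_error[r] - spec$p_mem_23back[r] -
                spec$p_mem_random[r]),
              rule_error = unname(spec$p_rule_error[r]),
              mem_error_23back = unname(spec$p_mem_23back[r]),
              mem_error_random = unname(spec$p_mem_random[r]))
    obs <- table(factor(compl$category, names(pExp)))
    # small expected counts in the random-error cell: Monte-Carlo p-value
    pv <- stats::chisq.test(obs, p = pExp, simulate.p.value = TRUE,
                            B = 2000)$p.value
    expect_gt(pv, 0.01)
    fbObs <- mean(sub$category == "fixation_break")
    expect_lt(abs(fbObs - spec$p_fixation_break[r]), 0.02)
  }
})

test_that("stimulation erases contralateral 2-back memories but spares 1-back", {
  hcfg <- taskConfig(locationAngles = c(0, 90, 180, 270))
  spec <- behaviorSpec(p_rule_error = c("1-back" = 0, "2-back" = 0),
                       p_mem_23back = c("1-back" = 0, "2-back" = 0),
                       p_mem_random = c("1-back" = 0, "2-back" = 0),
                       p_fixation_break = c("1-back" = 0, "2-back" = 0),
                       stim_p_erase = 1)
  trials <- generateTrials(hcfg, 800, stimFraction = 1, stimTiming = "early",
                           horizontalOnly = TRUE, seed = 12)
  oc <- simulateChoices(trials, spec, hcfg, hemisphere = "left", seed = 13)
  locs <- as.matrix(trials[paste0("cue_loc_", 1:4)])
  prev <- locs[cbind(seq_len(nrow(trials)), trials$n_cues - 1L)]
  last <- locs[cbind(seq_len(nrow(trials)), trials$n_cues)]
  # 2-back + contralateral (right hemifield, loc 0) last-1 cue -> rule error,
  # unless last and prev coincide (erasure is then behaviorally invisible)
  hit <- trials$rule == "2-back" & prev == 0 & last != prev
  expect_true(all(oc$category[hit] == "rule_error"))
  expect_true(all(oc$erased[trials$rule == "2-back" & prev == 0]))
  # early stimulation leaves 1-back trials untouched
  one <- trials$rule == "1-back"
  expect_true(all(oc$category[one] == "correct"))
  expect_false(any(oc$erased[one]))
})

test_that("noise-free eye traces land exactly on the chosen location", {
  spec <- behaviorSpec(endpoint_radial_sd = 1e-9,
                       theta_bias_mean = c("1-back" = 0, "2-back" = 0),
                       theta_sd = c("1-back" = 1e-9, "2-back" = 1e-9))
  tr <- makeTrial("1-back", c(0, 1))
  oc <- simulateChoice(tr, spec, cfg, seed = 21)
  expect_identical(oc$category, "correct")
  ang <- locationAngles(cfg)[2] * pi / 180   # chosen location 1
  expect_equal(oc$end_x, 12 * cos(ang), tolerance = 1e-6)
  expect_equal(oc$end_y, 12 * sin(ang), tolerance = 1e-6)
  eye <- synthesizeEyeTrace(tr, oc, spec, cfg, seed = 22)
  expect_equal(eye$t_ms, seq(min(eye$t_ms), max(eye$t_ms)))
  tail_ <- eye[eye$t_ms > tr$fp_offset + oc$rt_ms + 60, ]
  expect_lt(max(abs(tail_$x_deg - oc$end_x)), 0.3)
})

test_that("sessions regenerate bit-for-bit from the same seed", {
  specs <- defaultPopulation(1, cfg)
  s1 <- simulateSession(cfg, nTrials = 20, neuronSpecs = specs, seed = 33)
  s2 <- simulateSession(cfg, nTrials = 20, neuronSpecs = specs, seed = 33)
  expect_identical(trialTable(s1), trialTable(s2))
  expect_identical(spikeTable(s1), spikeTable(s2))
  s3 <- simulateSession(cfg, nTrials = 20, neuronSpecs = specs, seed = 34)
  expect_false(identical(spikeTable(s1), spikeTable(s3)))
  # spike trains strictly increasing per neuron
  for (id in unique(spikeTable(s1)$neuron_id)) {
    ts <- spikeTable(s1)$t_ms[spikeTable(s1)$neuron_id == id]
    expect_true(all(diff(ts) > 0))
  }
})

test_that("epoch-count fast path matches full spike sampling in distribution", {
  sp <- neuronSpec("m", "memory", preferred_location = 0L,
                   baseline_rate = 5, gain = 8)
  trials <- generateTrials(cfg, 60, seed = 40)
  ec <- simulateEpochCounts(sp, trials, cfg, seed = 41)
  # oracle: count spikes from fully sampled trains
  set.seed(42)
  full <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trialFromRow(trials, i)
    sampleSpikes(rateProfile(sp, tr, cfg))
  })
  oc <- epochCountMatrix(sort(unlist(full)), trials, cfg)
  expect_identical(nrow(ec), nrow(oc))
  # same mean over many epochs (both Poisson with identical means)
  expect_lt(abs(mean(ec$count) - mean(oc$count)),
            4 * sqrt(2 * mean(ec$count) / nrow(ec)))
})
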