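cfg <- taskConfig()

test_that("saccade detection applies velocity and displacement gates", {
  t <- 0:2000
  still <- data.frame(t_ms = t, x_deg = 0 * t, y_deg = 0 * t)
  expect_identical(nrow(detectSaccades(still)), 0L)
  expect_error(detectSaccades(data.frame(t_ms = c(0, 1, 3, 4, 6, 7, 9, 10),
                                         x_deg = 0, y_deg = 0)), "uniform")
  # stereotyped 12-degree saccade is detected once with the right amplitude
  tr <- makeTrial("1-back", c(0, 1))
  oc <- data.frame(category = "correct", rt_ms = 200,
                   end_x = 12 * cos(pi / 4), end_y = 12 * sin(pi / 4))
  eye <- synthesizeEyeTrace(tr, oc, behaviorSpec(), cfg, seed = 1)
  sac <- detectSaccades(eye)
  expect_identical(nrow(sac), 1L)
  expect_equal(sac$amplitude, 12, tolerance = 0.05)
  expect_gt(sac$peak_velocity, 70)
  # a fast but small (3 degree) excursion fails the displacement gate
  x <- 0 * t
  x[1001:1015] <- seq(0, 3, length.out = 15)
  x[1016:2001] <- 3
  small <- data.frame(t_ms = t, x_deg = x, y_deg = 0 * t)
  expect_identical(nrow(detectSaccades(small)), 0L)
})

test_that("trial scoring recovers outcome, RT and endpoint from eye data", {
  spec <- behaviorSpec(endpoint_radial_sd = 1e-9,
                       theta_bias_mean = c("1-back" = 0, "2-back" = 0),
                       theta_sd = c("1-back" = 1e-9, "2-back" = 1e-9),
                       p_fixation_break = c("1-back" = 0, "2-back" = 0))
  expect_error(scoreTrial(makeTrial("1-back", c(0, 1)), NULL), "eye")
  # round trip: synthesized trials are recovered within tight tolerances
  set.seed(2)
  nOk <- 0
  for (i in 1:60) {
    rule <- sample(c("1-back", "2-back"), 1)
    locs <- sample(0:3, sample(2:4, 1), replace = TRUE)
    tr <- makeTrial(rule, locs)
    oc <- simulateChoice(tr, spec, cfg)
    eye <- synthesizeEyeTrace(tr, oc, spec, cfg)
    sc <- scoreTrial(tr, eye, cfg)
    expect_identical(sc$category, oc$category)
    expect_identical(sc$chosen_loc, as.integer(oc$chosen_loc))
    expect_lt(abs(sc$rt_ms - oc$rt_ms), 5)
    expect_lt(sqrt((sc$end_x - oc$end_x)^2 + (sc$end_y - oc$end_y)^2), 0.2)
    nOk <- nOk + 1
  }
  expect_equal(nOk, 60)
  # a pre-offset saccade scores as fixation break
  tr <- makeTrial("1-back", c(0, 1))
  ocFb <- data.frame(category = "fixation_break", rt_ms = NA_real_,
                     end_x = NA_real_, end_y = NA_real_)
  eyeFb <- synthesizeEyeTrace(tr, ocFb, spec, cfg, seed = 3)
  expect_identical(scoreTrial(tr, eyeFb, cfg)$category, "fixation_break")
  # no saccade scores as no response
  ocNr <- data.frame(category = "no_response", rt_ms = NA_real_,
                     end_x = NA_real_, end_y = NA_real_)
  eyeNr <- synthesizeEyeTrace(tr, ocNr, spec, cfg, seed = 4)
  expect_identical(scoreTrial(tr, eyeNr, cfg)$category, "no_response")
})

test_that("theta is the signed angle toward the non-target cue", {
  # goal at 45 deg, non-target at 135 deg (counterclockwise of goal)
  expect_equal(thetaAngle(c(cos(pi / 4), sin(pi / 4)) * 12, 45, 135), 0)
  rot <- (45 + 5) * pi / 180
  expect_equal(thetaAngle(c(cos(rot), sin(rot)) * 12, 45, 135), 5)
  rot2 <- (45 - 5) * pi / 180
  expect_equal(thetaAngle(c(cos(rot2), sin(rot2)) * 12, 45, 135), -5)
  # invariant to radial distance
  expect_equal(thetaAngle(c(cos(rot), sin(rot)) * 3, 45, 135),
               thetaAngle(c(cos(rot), sin(rot)) * 40, 45, 135))
  expect_error(thetaAngle(c(0, 0), 45, 135), "zero")
})

test_that("session theta statistics recover the generator bias", {
  rec0 <- data.frame(trial_id = 1:20, rule = rep(c("1-back", "2-back"), 10),
                     theta = rep(1.5, 20), included = TRUE)
  st0 <- thetaSessionStats(rec0)
  expect_equal(st0$delta, 0)
  # only included trials count
  rec0$included[rec0$rule == "2-back"] <- FALSE
  expect_identical(thetaSessionStats(rec0)$n_2b, 0L)
  expect_true(is.na(thetaSessionStats(rec0)$mean_2b))
  # generator bias (+1 vs -2) appears in the per-session delta
  spec <- behaviorSpec()
  set.seed(5)
  deltas <- replicate(40, {
    trials <- generateTrials(cfg, 200)
    oc <- simulateChoices(trials, spec, cfg)
    trials <- cbind(trials, oc[, c("category", "chosen_loc", "end_x", "end_y")])
    thetaSessionStats(thetaRecords(trials, cfg))$delta
  })
  expect_lt(abs(mean(deltas) - (-3)), 3 * stats::sd(deltas) / sqrt(40))
})

test_that("KS statistic matches the brute-force ECDF gap", {
  expect_equal(thetaDistributionTest(1:10, 1:10)$D, 0)
  expect_equal(thetaDistributionTest(1:10, 101:110)$D, 1)
  set.seed(6)
  for (i in 1:20) {
    a <- stats::rnorm(152); b <- stats::rnorm(152, 0.3)
    D <- thetaDistributionTest(a, b)$D
    # oracle: max absolute ECDF difference over the pooled sample
    g <- sort(c(a, b))
    Dref <- max(abs(vapply(g, function(x) mean(a <= x) - mean(b <= x), 0)))
    expect_equal(D, Dref, tolerance = 1e-10)
  }
})

test_that("stimulation-effect tests isolate the affected condition", {
  hcfg <- taskConfig(locationAngles = c(0, 90, 180, 270))
  spec <- behaviorSpec(stim_p_erase = 0.3)
  set.seed(7)
  allTrials <- list()
  for (s in 1:8) {
    tr <- generateTrials(hcfg, 360, stimFraction = 0.5, stimTiming = "early",
                         horizontalOnly = TRUE)
    oc <- simulateChoices(tr, spec, hcfg, hemisphere = "left")
    tr <- cbind(tr, oc[, c("category", "chosen_loc", "rt_ms",
                           "end_x", "end_y", "erased")])
    tr$session_id <- paste0("s", s)
    allTrials[[s]] <- tr
  }
  res <- stimulationEffectTest(do.call(rbind, allTrials), hcfg, "left")
  expect_gt(res$fixation_break_rate, 0)
  cn <- res$conditions
  hit <- cn[cn$condition == "2-back_contra_last1", ]
  expect_gt(hit$err_delta, 0.1)
  expect_lt(hit$err_p, 0.01)
  # stimulation shortens RT in every condition
  expect_true(all(cn$rt_delta < 0))
  # identical arms yield zero deltas: rebuild with stimulation disabled effects
  spec0 <- behaviorSpec(stim_p_erase = 0, stim_rt_shortening = 0,
                        stim_accuracy_worsening = 0)
  tr0 <- generateTrials(hcfg, 2000, stimFraction = 0.5, stimTiming = "early",
                        horizontalOnly = TRUE, seed = 8)
  oc0 <- simulateChoices(tr0, spec0, hcfg, seed = 9)
  tr0 <- cbind(tr0, oc0[, c("category", "chosen_loc", "rt_ms",
                            "end_x", "end_y", "erased")])
  res0 <- stimulationEffectTest(tr0, hcfg, "left")
  expect_lt(max(abs(res0$conditions$err_delta)), 0.05)
})
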