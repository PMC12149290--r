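test_that("pseudo-population assembly selects P-N trials and enforces minima", {
  cfg <- taskConfig()
  set.seed(1)
  trials <- generateTrials(cfg, 400, seed = 1)
  trials$category <- "correct"
  sp <- neuronSpec("a", "memory", preferred_location = 0L, gain = 8)
  cc <- simulateEpochCounts(sp, trials, cfg, seed = 2)
  tensor <- assemblePseudopopulation(list(a = cc), trials, c(a = 0L))
  expect_s3_class(tensor, "FeatureTensor")
  expect_length(tensor$neurons, 1)
  pools <- tensor$neurons$a
  expect_identical(colnames(pools[["1-back"]]),
                   c("D1_early", "D1_late", "D2_early", "D2_late"))
  # qualifying trials: second-to-last cue at 0, last elsewhere, correct
  locs <- as.matrix(trials[paste0("cue_loc_", 1:4)])
  prev <- locs[cbind(seq_len(nrow(trials)), trials$n_cues - 1L)]
  last <- locs[cbind(seq_len(nrow(trials)), trials$n_cues)]
  nQual <- sum(prev == 0 & last != 0 & trials$rule == "1-back")
  expect_identical(nrow(pools[["1-back"]]), nQual)
  # a neuron below the per-rule minimum is excluded and logged
  few <- cc[cc$trial_id <= 20, ]
  t2 <- assemblePseudopopulation(list(a = cc, b = few), trials,
                                 c(a = 0L, b = 0L))
  expect_identical(t2$excluded, "b")
  expect_false("b" %in% names(t2$neurons))
})

test_that("decoder protocol is calibrated at chance and perfect when separable", {
  set.seed(2)
  # rule-identical pools: accuracy within the binomial CI of 0.5
  same <- makeTensor(lapply(1:6, function(i) gaussPools(rep(0, 4), rep(0, 4))))
  accNull <- trainValidate(same, 6, nValDraws = 100, nTrainDraws = 30, seed = 3)
  expect_gt(mean(accNull), 0.5 - 1.96 * sqrt(0.25 / 100))
  expect_lt(mean(accNull), 0.5 + 1.96 * sqrt(0.25 / 100))
  # perfectly separated features decode perfectly
  sep <- makeTensor(lapply(1:4, function(i)
    gaussPools(rep(-5, 4), rep(5, 4), sdev = 0.1)))
  accSep <- trainValidate(sep, 4, nValDraws = 50, nTrainDraws = 10, seed = 4)
  expect_equal(mean(accSep), 1)
  # shuffling labels flattens an informative population to chance
  set.seed(5)
  info <- makeTensor(lapply(1:6, function(i)
    gaussPools(rep(-1, 4), rep(1, 4))))
  accShuf <- trainValidate(info, 6, nValDraws = 100, nTrainDraws = 30,
                           shuffle = TRUE, seed = 6)
  expect_lt(abs(mean(accShuf) - 0.5), 0.1)
  # determinism under seed
  expect_identical(trainValidate(info, 6, nTrainDraws = 5, seed = 7),
                   trainValidate(info, 6, nTrainDraws = 5, seed = 7))
  expect_error(trainValidate(info, 99), "exceeds")
  expect_error(trainValidate(info, 2, epochs = integer(0)), "non-empty")
})

test_that("epoch subsets degrade gracefully and training size is 4x8x2", {
  set.seed(8)
  # information only in the D2 epochs
  d2only <- makeTensor(lapply(1:6, function(i)
    gaussPools(c(0, 0, -1.5, -1.5), c(0, 0, 1.5, 1.5))))
  accAll <- trainValidate(d2only, 6, nValDraws = 60, nTrainDraws = 20, seed = 9)
  accD2 <- epochSubsetVariant(d2only, 3:4, 6, nValDraws = 60,
                              nTrainDraws = 20, seed = 10)
  accD1 <- epochSubsetVariant(d2only, 1:2, 6, nValDraws = 60,
                              nTrainDraws = 20, seed = 11)
  expect_gt(mean(accD2), 0.8)
  expect_lt(abs(mean(accD1) - 0.5), 0.15)
  expect_gt(mean(accAll), mean(accD1))
  # the printed training-set size: 4 epochs x 8 trials x 2 rules per neuron
  expect_identical(attr(accAll, "training_points_per_neuron"), 64)
  expect_identical(attr(accD2, "training_points_per_neuron"), 32)
})

test_that("type exclusion pinpoints the information-bearing population", {
  set.seed(12)
  inf <- lapply(1:10, function(i) gaussPools(rep(-1.2, 4), rep(1.2, 4)))
  noise <- lapply(1:10, function(i) gaussPools(rep(0, 4), rep(0, 4)))
  pools <- c(inf, noise)
  names(pools) <- c(paste0("m", 1:10), paste0("z", 1:10))
  tensor <- makeTensor(pools)
  labels <- stats::setNames(rep(c("memory", "null"), each = 10), names(pools))
  deltas <- typeExclusionDeltas(tensor, labels, nFixed = 10, seed = 13,
                                nValDraws = 60, nTrainDraws = 20)
  dm <- deltas$delta[deltas$type == "memory"]
  dz <- deltas$delta[deltas$type == "null"]
  expect_gt(dm, 0.2)          # excluding the informative type hurts
  expect_lt(abs(dz), 0.1)     # excluding noise neurons is within noise
  expect_gt(dm, dz)
})

test_that("choice probability tracks the executed choice on error trials", {
  set.seed(14)
  # rule-error trials carry swapped-rule activity
  mk <- function() {
    cor <- gaussPools(rep(-1.5, 4), rep(1.5, 4), nTrials = 15)
    err <- list("1-back" = gaussPools(rep(1.5, 4), rep(0, 4), nTrials = 4)[["1-back"]],
                "2-back" = gaussPools(rep(-1.5, 4), rep(0, 4), nTrials = 4)[["1-back"]])
    list(correct = cor, error = err)
  }
  et <- lapply(1:8, function(i) mk())
  names(et) <- paste0("n", 1:8)
  cp <- errorTrialChoiceProbability(et, nValDraws = 40, nTrainDraws = 20,
                                    seed = 15)
  expect_true(all(cp$cp >= 0 & cp$cp <= 1))
  for (cond in c("1b-err", "2b-err")) {
    v <- cp$cp[cp$condition == cond & cp$epoch_set == "all4"]
    expect_gt(v, 0.8)  # decoder reads out the rule implied by the choice
  }
  expect_gt(cp$cp[cp$condition == "1b-cor" & cp$epoch_set == "all4"], 0.8)
  # chance decoder: featureless pools give CP near 0.5
  flat <- lapply(1:8, function(i) {
    cor <- gaussPools(rep(0, 4), rep(0, 4), nTrials = 15)
    list(correct = cor,
         error = list("1-back" = cor[["1-back"]][1:3, , drop = FALSE],
                      "2-back" = cor[["2-back"]][1:3, , drop = FALSE]))
  })
  names(flat) <- paste0("n", 1:8)
  cp0 <- errorTrialChoiceProbability(flat, nValDraws = 60, nTrainDraws = 20,
                                     seed = 16)
  expect_lt(abs(mean(cp0$cp) - 0.5), 0.12)
})
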