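cfg <- taskConfig()

test_that("design rows carry the worked dummy codings", {
  # 1-back [lower-left, upper-right]: cue 2 at index 0 (upper-right) while
  # the memory of index 2 (lower-left) is dropped
  trials <- makeTrialsDf("1-back", list(c(2L, 0L)))
  counts <- data.frame(trial_id = 1L, delay = c(1L, 1L, 2L, 2L),
                       epoch = c("early", "late", "early", "late"),
                       count = c(2L, 3L, 4L, 1L))
  des <- buildDesign(trials, counts, cfg, responseScale = "raw")
  early2 <- des$X[des$rows$delay == 2 & des$rows$epoch == "early", ]
  expect_equal(unname(early2[paste0("visual_", 0:3)]), c(1, 0, 0, 0))
  expect_equal(unname(early2[paste0("extinction_", 0:3)]), c(0, 0, 1, 0))
  # first delay has nothing to extinguish
  early1 <- des$X[des$rows$delay == 1 & des$rows$epoch == "early", ]
  expect_equal(sum(early1[paste0("extinction_", 0:3)]), 0)
  expect_equal(des$y, c(2, 3, 4, 1))
})

test_that("design invariants hold over random trial sets", {
  set.seed(1)
  trials <- generateTrials(cfg, 150, seed = 1)
  counts <- simulateEpochCounts(neuronSpec("n", "null"), trials, cfg, seed = 2)
  des <- buildDesign(trials, counts, cfg)
  expect_identical(ncol(des$X), 18L)
  expect_identical(nrow(des$X), 2L * sum(trials$n_cues))
  isEarly <- des$rows$epoch == "early"
  memB <- des$X[, paste0("memory_", 0:3)]
  visB <- des$X[, paste0("visual_", 0:3)]
  extB <- des$X[, paste0("extinction_", 0:3)]
  expect_true(all(memB[isEarly, ] == 0))
  expect_true(all(visB[!isEarly, ] == 0))
  expect_true(all(extB[!isEarly, ] == 0))
  expect_true(all(rowSums(visB) <= 1) && all(rowSums(extB) <= 1))
  expect_true(all(des$X[, c("order_early", "order_late")] >= 0 &
                  des$X[, c("order_early", "order_late")] <= 1))
  expect_true(all(des$X[, c("rule_early", "rule_late")] %in% 0:1))
  # exactly 2 rows per delay period
  expect_true(all(table(paste(des$rows$trial_id, des$rows$delay)) == 2))
  # response is scaled to percent of the maximum epoch count
  expect_equal(max(des$y), 100)
})

test_that("IRLS matches closed forms and the reference GLM implementation", {
  # intercept-only fit of a constant response
  n <- 50
  X <- matrix(0, n, 18, dimnames = list(NULL, colnames(buildDesign(
    makeTrialsDf("1-back", list(c(0L, 1L))),
    data.frame(trial_id = 1L, delay = c(1L, 1L, 2L, 2L),
               epoch = c("early", "late", "early", "late"), count = 1L),
    cfg)$X)))
  X[, "bias_late"] <- 1
  fit <- fitPoissonGLM(list(X = X, y = rep(7, n)))
  expect_equal(unname(fit$beta["bias_late"]), log(7), tolerance = 1e-8)
  expect_true(all(is.na(fit$beta[setdiff(names(fit$beta), "bias_late")])))
  # cross-check against stats::glm on random full-rank designs
  set.seed(3)
  for (i in 1:5) {
    Xr <- cbind(1, matrix(stats::rnorm(200 * 3), 200, 3))
    colnames(Xr) <- c("bias_late", "a", "b", "c")
    yr <- stats::rpois(200, exp(0.5 + Xr[, 2] * 0.3 - Xr[, 3] * 0.2))
    mine <- fitPoissonGLM(list(X = Xr, y = yr))
    ref <- stats::glm(yr ~ Xr[, 2] + Xr[, 3] + Xr[, 4], family = stats::poisson())
    expect_equal(unname(mine$beta[colnames(Xr)]), unname(stats::coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(mine$se[colnames(Xr)]),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-5)
    # deviance is non-increasing across IRLS iterations
    expect_true(all(diff(mine$deviance_trace) <= 1e-9))
  }
})

test_that("directional index follows the vector-sum geometry", {
  ang <- locationAngles(cfg)
  d1 <- directionalIndex(c(1, 0, 0, 0), ang)
  expect_equal(d1$DI, 1)
  expect_equal(d1$preferred_angle, ang[1])
  expect_equal(directionalIndex(c(2, 2, 2, 2), ang)$DI, 0, tolerance = 1e-12)
  expect_equal(directionalIndex(c(0, 0, 0, 0), ang)$DI, 0)
  # scale invariance under positive multiplication
  set.seed(4)
  for (i in 1:100) {
    b <- stats::rnorm(4)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(directionalIndex(b, ang)$DI,
                 directionalIndex(k * b, ang)$DI, tolerance = 1e-10)
  }
})

test_that("archetype neurons recover their generating components", {
  trials <- generateTrials(cfg, 300, seed = 5)
  # raw-count mode gives calibrated Wald tests: labels are specific
  for (arch in c("memory", "extinction", "visual")) {
    sp <- neuronSpec("x", arch, preferred_location = 2L,
                     baseline_rate = 5, gain = 8)
    ec <- simulateEpochCounts(sp, trials, cfg, seed = 6)
    fit <- fitPoissonGLM(buildDesign(trials, ec, cfg, responseScale = "raw"))
    cls <- classifyNeuron(fit, cfg)
    expect_true(cls[[paste0("dir_", arch)]])
    expect_identical(cls[[paste0("prefloc_", arch)]], 2L)
  }
  # a visual neuron's transient never reaches the late epochs
  spv <- neuronSpec("v", "visual", preferred_location = 1L, gain = 10)
  ecv <- simulateEpochCounts(spv, trials, cfg, seed = 7)
  fitv <- fitPoissonGLM(buildDesign(trials, ecv, cfg, responseScale = "raw"))
  clsv <- classifyNeuron(fitv, cfg)
  expect_true(clsv$dir_visual)
  expect_false(clsv$dir_memory)
  expect_identical(clsv$exclusive_type, "visual")
  # mixed memory+extinction archetype carries both labels
  spm <- neuronSpec("mx", "mixed", preferred_location = 0L, gain = 16,
                    mixture_weights = c(memory = 0.5, extinction = 0.5))
  ecm <- simulateEpochCounts(spm, trials, cfg, seed = 8)
  fitm <- fitPoissonGLM(buildDesign(trials, ecm, cfg, responseScale = "raw"))
  clsm <- classifyNeuron(fitm, cfg)
  expect_true(clsm$dir_memory && clsm$dir_extinction)
  expect_true(is.na(clsm$exclusive_type))
  # null neurons earn directional labels only at chance
  set.seed(9)
  falsePos <- replicate(30, {
    ec0 <- simulateEpochCounts(neuronSpec("0", "null"), trials, cfg)
    cls0 <- classifyNeuron(
      fitPoissonGLM(buildDesign(trials, ec0, cfg, responseScale = "raw")), cfg)
    cls0$dir_memory || cls0$dir_extinction || cls0$dir_visual
  })
  # chance for any-of-three directional labels: each needs one of four betas
  # at p < .05 (1 - .95^4 = .185) plus DI > 0.1, so < 1-(1-.185)^3 = 0.46
  expect_lt(mean(falsePos), 0.46)
})

test_that("flagged fits come back unclassified", {
  fit <- list(beta = stats::setNames(rep(NA_real_, 18), colnames(buildDesign(
    makeTrialsDf("1-back", list(c(0L, 1L))),
    data.frame(trial_id = 1L, delay = c(1L, 1L, 2L, 2L),
               epoch = c("early", "late", "early", "late"), count = 1L),
    cfg)$X)), flagged = TRUE)
  cls <- classifyNeuron(fit, cfg)
  expect_true(cls$unclassified)
  expect_true(is.na(cls$dir_memory))
})
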