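EPOCH_LABELS <- c("D1_early", "D1_late", "D2_early", "D2_late")

#' Assemble a pseudo-population feature tensor
#'
#' For each neuron, pools the spike counts of the four decoding epochs (early
#' and late 400-ms epochs of the last two delay periods, D1 and D2) over
#' qualifying trials, split by task rule. Qualifying trials are correct
#' trials in the P-N-FP-off configuration: the second-to-last cue at the
#' neuron's preferred location and the last cue elsewhere (the opposite
#' reading - last cue preferred - is available via \code{pnOrder}). Neurons
#' with fewer than \code{minTrialsPerRule} qualifying trials under either
#' rule are excluded and recorded in the exclusion log.
#'
#' Because neurons are recorded in different sessions, decoding draws trials
#' independently per neuron within rule (pseudo-trials).
#'
#' @param neuronCounts named list (by neuron id) of epoch-count data.frames
#'   ([epochCountMatrix()] / [simulateEpochCounts()] output).
#' @param trials trials data.frame with outcome \code{category} column.
#' @param preferredLoc named integer vector (by neuron id) of 0-based
#'   preferred locations.
#' @param minTrialsPerRule minimum qualifying trials per rule (9: 8 training
#'   plus at least one validation).
#' @param pnOrder "prev-preferred" (default) or "last-preferred".
#' @return list of class \code{"FeatureTensor"}: \code{neurons} (per neuron,
#'   a list of rule-named trial x 4-epoch count matrices), \code{excluded}
#'   (ids below the trial minimum), \code{epochs} (column labels).
#' @export
assemblePseudopopulation <- function(neuronCounts, trials, preferredLoc,
                                     minTrialsPerRule = 9,
                                     pnOrder = c("prev-preferred",
                                                 "last-preferred")) {
  pnOrder <- match.arg(pnOrder)
  geo <- trialGeometry(trials, taskConfig())
  correct <- !is.na(trials$category) & trials$category == "correct"
  out <- list(); excluded <- character(0)
  for (id in names(neuronCounts)) {
    pref <- preferredLoc[[id]]
    qual <- if (pnOrder == "prev-preferred")
      correct & geo$prevLoc == pref & geo$lastLoc != pref
    else
      correct & geo$lastLoc == pref & geo$prevLoc != pref
    cc <- neuronCounts[[id]]
    pools <- lapply(RULES, function(r) {
      ids <- trials$trial_id[qual & trials$rule == r]
      m <- matrix(NA_real_, length(ids), 4,
                  dimnames = list(NULL, EPOCH_LABELS))
      for (j in seq_along(ids)) {
        sub <- cc[cc$trial_id == ids[j] & !is.na(cc$d_tag), , drop = FALSE]
        if (nrow(sub)) {
          cn <- paste0(sub$d_tag, "_", sub$epoch)
          ok <- cn %in% colnames(m)
          m[j, cn[ok]] <- sub$count[ok]
        }
      }
      m[stats::complete.cases(m), , drop = FALSE]
    })
    names(pools) <- RULES
    if (any(vapply(pools, nrow, 0L) < minTrialsPerRule)) {
      excluded <- c(excluded, id)
    } else {
      out[[id]] <- pools
    }
  }
  structure(list(neurons = out, excluded = excluded, epochs = EPOCH_LABELS),
            class = "FeatureTensor")
}

#' @export
print.FeatureTensor <- function(x, ...) {
  cat("FeatureTensor:", length(x$neurons), "neurons (",
      length(x$excluded), "excluded );",
      length(x$epochs), "epochs\n")
  invisible(x)
}

# train one linear SVM and return a predictor over feature matrices;
# decision ties classify as 1-back (deterministic tie-break)
trainRuleSVM <- function(trainX, trainY, cost = 1) {
  mu <- colMeans(trainX)
  sg <- apply(trainX, 2, stats::sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(trainX, 2, mu), 2, sg, "/")
  fit <- e1071::svm(Xs, factor(trainY, levels = RULES),
                    kernel = "linear", cost = cost, scale = FALSE)
  function(newX) {
    Xn <- sweep(sweep(newX, 2, mu), 2, sg, "/")
    dv <- attr(stats::predict(fit, Xn, decision.values = TRUE),
               "decision.values")
    flip <- if (colnames(dv)[1] == "1-back/2-back") 1 else -1
    ifelse(flip * dv[, 1] >= 0, "1-back", "2-back")
  }
}

#' Resampled train/validate decoding of the task rule
#'
#' The resampling protocol: per classifier instance, \code{nNeurons} neurons
#' are drawn (without replacement) and for each neuron 8 trials per rule are
#' drawn as training data (4 epochs x 8 trials x 2 rules training points per
#' neuron); a validation pseudo-trial is then drawn \code{nValDraws} times
#' from the held-out trials and its rule decoded; the fraction decoded
#' correctly is one accuracy. The training draw is repeated
#' \code{nTrainDraws} times to produce the accuracy distribution. Features
#' are standardized per neuron-epoch using training-set statistics, the
#' classifier is a soft-margin linear SVM (cost 1), and decision-boundary
#' ties resolve to 1-back.
#'
#' @param tensor a [assemblePseudopopulation()] result.
#' @param nNeurons number of neurons per classifier instance.
#' @param nTrainPerRule training trials per rule (8).
#' @param nValDraws validation draws per instance (100).
#' @param nTrainDraws training re-draws (100).
#' @param epochs integer subset of 1:4 (D1 early, D1 late, D2 early,
#'   D2 late); must be non-empty.
#' @param shuffle logical; permute rule labels within each neuron's pooled
#'   trials first (the chance control).
#' @param seed integer seed; the full result is reproducible from it.
#' @return numeric vector of \code{nTrainDraws} accuracies in [0, 1], with
#'   attribute \code{training_points_per_neuron} measured from the assembled
#'   training matrix (2 rules x \code{nTrainPerRule} trials x the number of
#'   epochs; 4 x 8 x 2 = 64 under the default protocol).
#' @export
trainValidate <- function(tensor, nNeurons, nTrainPerRule = 8,
                          nValDraws = 100, nTrainDraws = 100,
                          epochs = 1:4, shuffle = FALSE, seed = NULL) {
  if (!length(epochs)) stop("epochs must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- names(tensor$neurons)
  if (nNeurons > length(ids))
    stop("nNeurons exceeds the available pool (", length(ids), ")",
         call. = FALSE)
  pools <- tensor$neurons
  if (shuffle) {
    pools <- lapply(pools, function(p) {
      all <- rbind(p[["1-back"]], p[["2-back"]])
      lab <- sample(rep(RULES, c(nrow(p[["1-back"]]), nrow(p[["2-back"]]))))
      list("1-back" = all[lab == "1-back", , drop = FALSE],
           "2-back" = all[lab == "2-back", , drop = FALSE])
    })
  }
  acc <- numeric(nTrainDraws)
  for (d in seq_len(nTrainDraws)) {
    sel <- if (nNeurons < length(ids)) sample(ids, nNeurons) else ids
    trainIdx <- lapply(sel, function(id)
      lapply(pools[[id]], function(m) sample(nrow(m), nTrainPerRule)))
    names(trainIdx) <- sel
    trainX <- do.call(cbind, lapply(sel, function(id) {
      p <- pools[[id]]; ti <- trainIdx[[id]]
      rbind(p[["1-back"]][ti[["1-back"]], epochs, drop = FALSE],
            p[["2-back"]][ti[["2-back"]], epochs, drop = FALSE])
    }))
    trainY <- rep(RULES, each = nTrainPerRule)
    pred <- trainRuleSVM(trainX, trainY)
    valRules <- rep(RULES, length.out = nValDraws)
    valX <- matrix(NA_real_, nValDraws, ncol(trainX))
    for (v in seq_len(nValDraws)) {
      r <- valRules[v]
      feat <- unlist(lapply(sel, function(id) {
        m <- pools[[id]][[r]]
        held <- setdiff(seq_len(nrow(m)), trainIdx[[id]][[r]])
        m[if (length(held) > 1) sample(held, 1) else held, epochs]
      }))
      valX[v, ] <- feat
    }
    acc[d] <- mean(pred(valX) == valRules)
    if (d == 1L)
      attr(acc, "training_points_per_neuron") <-
        nrow(trainX) * ncol(trainX) / length(sel)
  }
  acc
}

#' Decoding accuracy as a function of neuron count
#'
#' Repeats the [trainValidate()] protocol for each requested neuron count.
#'
#' @inheritParams trainValidate
#' @param nNeuronsVec neuron counts to sweep.
#' @param ... passed to [trainValidate()].
#' @return data.frame: \code{n_neurons}, \code{accuracy} (mean), \code{sem}.
#' @export
decodeSweep <- function(tensor, nNeuronsVec, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(nNeuronsVec, function(n) {
    a <- trainValidate(tensor, n, ...)
    data.frame(n_neurons = n, accuracy = mean(a),
               sem = stats::sd(a) / sqrt(length(a)))
  })
  do.call(rbind, rows)
}

#' Decoding with a restricted epoch set
#'
#' Same protocol as [trainValidate()] with features restricted to the
#' requested decoding epochs (e.g. D1-only = epochs 1:2, D2-only = 3:4).
#'
#' @inheritParams trainValidate
#' @param ... passed to [trainValidate()].
#' @return numeric accuracy vector.
#' @export
epochSubsetVariant <- function(tensor, epochs, nNeurons, seed = NULL, ...) {
  trainValidate(tensor, nNeurons, epochs = epochs, seed = seed, ...)
}

#' Accuracy change from excluding each neuron type
#'
#' Compares decoding accuracy using \code{nFixed} neurons sampled from the
#' whole population against \code{nFixed} neurons sampled from the
#' population minus one type, for each type in \code{typeLabels}; the change
#' is tested across training draws with a two-sample t test.
#'
#' @param tensor a [assemblePseudopopulation()] result.
#' @param typeLabels named character vector (by neuron id) of type labels.
#' @param nFixed number of neurons per classifier (67 in the full-scale
#'   protocol, the minimum remaining pool after type exclusion).
#' @param seed integer seed.
#' @param ... passed to [trainValidate()].
#' @return data.frame: \code{type}, \code{acc_full}, \code{acc_excluded},
#'   \code{delta} (full minus excluded), \code{t}, \code{p}.
#' @export
typeExclusionDeltas <- function(tensor, typeLabels, nFixed = 67,
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  accFull <- trainValidate(tensor, nFixed, ...)
  types <- sort(unique(typeLabels))
  rows <- lapply(types, function(tp) {
    keep <- names(tensor$neurons)[
      !(names(tensor$neurons) %in% names(typeLabels)[typeLabels == tp])]
    sub <- tensor
    sub$neurons <- tensor$neurons[keep]
    accEx <- trainValidate(sub, min(nFixed, length(keep)), ...)
    tt <- if (stats::sd(c(accFull, accEx)) == 0) list(statistic = 0, p.value = 1)
          else stats::t.test(accFull, accEx)
    data.frame(type = tp, acc_full = mean(accFull),
               acc_excluded = mean(accEx),
               delta = mean(accFull) - mean(accEx),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Choice probability of a correct-trial decoder on error trials
#'
#' A decoder is trained on randomly selected correct trials only (10 per
#' rule) and validated on correct and rule-error trials. For a correct
#' validation trial the choice probability (CP) is the fraction of draws
#' decoding the true rule; for a rule-error trial it is the fraction
#' decoding the rule consistent with the actually executed choice (the
#' opposite of the instructed rule, since a rule error is a saccade to the
#' other rule's target). The limited error pools are reused across
#' validation draws; variability comes from the \code{nTrainDraws} training
#' re-draws. CPs are computed for the all-4-epoch and first-3-epoch feature
#' sets.
#'
#' @param errorTensor named list (by neuron id), each element a list with
#'   \code{correct} and \code{error}, both rule-named lists of trial x
#'   4-epoch matrices. Neurons must have rule-error trials under both rules.
#' @param nTrainPerRule training (correct) trials per rule.
#' @param nValDraws validation draws per training draw.
#' @param nTrainDraws training re-draws.
#' @param seed integer seed.
#' @return data.frame: \code{condition} ("1b-cor", "2b-cor", "1b-err",
#'   "2b-err"), \code{epoch_set} ("all4"/"first3"), \code{cp}, \code{sem}.
#' @export
errorTrialChoiceProbability <- function(errorTensor, nTrainPerRule = 10,
                                        nValDraws = 100, nTrainDraws = 100,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(errorTensor)
  ok <- vapply(ids, function(id) {
    et <- errorTensor[[id]]
    all(vapply(et$correct, nrow, 0L) >= nTrainPerRule + 1) &&
      all(vapply(et$error, nrow, 0L) >= 1)
  }, logical(1))
  ids <- ids[ok]
  if (!length(ids)) stop("no neurons with error trials in both rules",
                         call. = FALSE)
  sets <- list(all4 = 1:4, first3 = 1:3)
  conds <- expand.grid(rule = RULES, kind = c("cor", "err"),
                       stringsAsFactors = FALSE)
  cp <- array(NA_real_, c(nTrainDraws, nrow(conds), length(sets)))
  for (d in seq_len(nTrainDraws)) {
    trainIdx <- lapply(ids, function(id)
      lapply(errorTensor[[id]]$correct, function(m)
        sample(nrow(m), nTrainPerRule)))
    names(trainIdx) <- ids
    for (s in seq_along(sets)) {
      ep <- sets[[s]]
      trainX <- do.call(cbind, lapply(ids, function(id) {
        p <- errorTensor[[id]]$correct; ti <- trainIdx[[id]]
        rbind(p[["1-back"]][ti[["1-back"]], ep, drop = FALSE],
              p[["2-back"]][ti[["2-back"]], ep, drop = FALSE])
      }))
      pred <- trainRuleSVM(trainX, rep(RULES, each = nTrainPerRule))
      for (ci in seq_len(nrow(conds))) {
        r <- conds$rule[ci]; kind <- conds$kind[ci]
        hits <- logical(nValDraws)
        valX <- matrix(NA_real_, nValDraws, length(ep) * length(ids))
        for (v in seq_len(nValDraws)) {
          valX[v, ] <- unlist(lapply(ids, function(id) {
            et <- errorTensor[[id]]
            if (kind == "cor") {
              m <- et$correct[[r]]
              held <- setdiff(seq_len(nrow(m)), trainIdx[[id]][[r]])
              m[if (length(held) > 1) sample(held, 1) else held, ep]
            } else {
              m <- et$error[[r]]
              m[if (nrow(m) > 1) sample(nrow(m), 1) else 1, ep]
            }
          }))
        }
        dec <- pred(valX)
        ref <- if (kind == "cor") r else setdiff(RULES, r)
        cp[d, ci, s] <- mean(dec == ref)
      }
    }
  }
  rows <- list()
  for (s in seq_along(sets)) for (ci in seq_len(nrow(conds))) {
    lab <- paste0(substr(conds$rule[ci], 1, 1), "b-", conds$kind[ci])
    rows[[length(rows) + 1L]] <- data.frame(
      condition = lab, epoch_set = names(sets)[s],
      cp = mean(cp[, ci, s]),
      sem = stats::sd(cp[, ci, s]) / sqrt(nTrainDraws),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
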