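DESIGN_COLS <- c(paste0("visual_", 0:3), paste0("extinction_", 0:3),
                 paste0("memory_", 0:3),
                 "order_early", "rule_early", "bias_early",
                 "order_late", "rule_late", "bias_late")

#' Build the early/late delay-period design matrix
#'
#' Every delay period of every analyzed trial contributes two rows. The
#' early row carries location-indicator dummies for the visual component
#' (the location of the cue that just appeared) and for the extinction
#' component (the location whose memory became obsolete at that cue, when
#' one exists), plus the early-model order, rule and bias terms. The late
#' row carries memory indicators for every location in the required memory
#' set (in 2-back trials both remembered locations are set; duplicates
#' collapse), plus the late-model order, rule and bias terms. The order
#' covariate is (k-1)/3 for cue position k, spanning 0 to 1 over positions
#' 1--4, and the rule covariate is 1 for 2-back trials. With 4 dummies per
#' directional component, an order, rule and bias term in each of the two
#' epoch models, the stacked design has 18 coefficient columns.
#'
#' The response is the matching spike count, by default scaled to 0--100%
#' of the neuron's maximum epoch count so that coefficient magnitudes are
#' comparable across neurons; \code{responseScale = "raw"} keeps integer
#' counts.
#'
#' @param trials trials data.frame. Trials whose \code{category} column (if
#'   present) is missing, a fixation break or a no-response are excluded.
#' @param counts epoch counts for one neuron ([epochCountMatrix()] /
#'   [simulateEpochCounts()] output).
#' @param config a [TaskConfig-class].
#' @param responseScale "scaled" (percent of the neuron's maximum) or "raw".
#' @return list: \code{X} (n x 18 matrix), \code{y} (response vector),
#'   \code{rows} (bookkeeping data.frame: trial_id, delay, epoch).
#' @export
buildDesign <- function(trials, counts, config = taskConfig(),
                        responseScale = c("scaled", "raw")) {
  responseScale <- match.arg(responseScale)
  if (!is.null(trials$category)) {
    keep <- !is.na(trials$category) &
      !trials$category %in% c("fixation_break", "no_response")
    trials <- trials[keep, , drop = FALSE]
  }
  lookup <- stats::setNames(counts$count,
                            paste(counts$trial_id, counts$delay, counts$epoch))
  rows <- list(); Xs <- list(); ys <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    tr <- trialFromRow(trials, i)
    L <- length(tr$cue_locations)
    for (k in seq_len(L)) {
      early <- stats::setNames(numeric(18), DESIGN_COLS)
      late <- early
      early[paste0("visual_", tr$cue_locations[k])] <- 1
      ex <- extinctionLocation(tr$rule, tr$cue_locations, k)
      if (!is.na(ex)) early[paste0("extinction_", ex)] <- 1
      early["order_early"] <- (k - 1) / 3
      early["rule_early"] <- as.numeric(tr$rule == "2-back")
      early["bias_early"] <- 1
      for (m in requiredMemorySet(tr$rule, tr$cue_locations, k))
        late[paste0("memory_", m)] <- 1
      late["order_late"] <- (k - 1) / 3
      late["rule_late"] <- as.numeric(tr$rule == "2-back")
      late["bias_late"] <- 1
      yE <- lookup[paste(tr$trial_id, k, "early")]
      yL <- lookup[paste(tr$trial_id, k, "late")]
      if (is.na(yE) || is.na(yL))
        stop("missing epoch count for trial ", tr$trial_id, " delay ", k,
             call. = FALSE)
      Xs[[length(Xs) + 1L]] <- rbind(early, late)
      ys <- c(ys, yE, yL)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tr$trial_id, delay = c(k, k), epoch = c("early", "late"))
    }
  }
  X <- do.call(rbind, Xs)
  rownames(X) <- NULL
  colnames(X) <- DESIGN_COLS
  y <- unname(ys)
  if (responseScale == "scaled") {
    mx <- max(y)
    y <- if (mx > 0) y / mx * 100 else y
  }
  list(X = X, y = y, rows = do.call(rbind, rows))
}

#' Fit the Poisson log-link encoding model by IRLS
#'
#' Iteratively reweighted least squares to the maximum-(quasi)likelihood
#' solution of a log-link Poisson regression, with Wald standard errors and
#' p-values at unit dispersion. Columns that are all zero (components never
#' instantiated in the trial set) or aliased are dropped before fitting and
#' reported as absent (NA), not as zero coefficients. Fits that fail to
#' converge within \code{maxIter} iterations, or that drift to extreme
#' coefficients (quasi-separation), are flagged.
#'
#' @param design output of [buildDesign()], or any list with \code{X} and
#'   \code{y}.
#' @param maxIter IRLS iteration cap.
#' @param tol relative deviance-change convergence tolerance.
#' @param dispersion "unit" (Wald tests at dispersion 1, the default, which
#'   mirrors a plain Poisson fit and is anticonservative when the response
#'   has been rescaled) or "pearson" (quasi-Poisson: standard errors scaled
#'   by the Pearson dispersion estimate).
#' @return object of class \code{"ComponentFit"}: \code{beta}, \code{se},
#'   \code{p} (named over the 18 design columns, NA where absent),
#'   \code{converged}, \code{flagged}, \code{deviance},
#'   \code{deviance_trace}, \code{dropped}.
#' @export
fitPoissonGLM <- function(design, maxIter = 100, tol = 1e-10,
                          dispersion = c("unit", "pearson")) {
  dispersion <- match.arg(dispersion)
  X <- design$X
  y <- design$y
  if (any(y < 0)) stop("negative response", call. = FALSE)
  full <- colnames(X)
  keep <- colSums(abs(X)) > 0
  Xk <- X[, keep, drop = FALSE]
  if (qr(Xk)$rank < ncol(Xk)) {
    # deterministic rank reduction: biases and scalar covariates have
    # priority, so when an indicator block is aliased with its epoch bias
    # (the visual block is always one-hot on early rows) the last dummy of
    # the block is dropped, not the bias. Over a symmetric location set the
    # four unit vectors sum to zero, so this reference coding leaves the
    # component's direction vector sum unchanged.
    prio <- c(grep("^bias_", colnames(Xk)),
              grep("^(order|rule)_", colnames(Xk)),
              grep("^(memory|extinction|visual)_", colnames(Xk)))
    kept <- integer(0)
    for (j in prio) {
      if (qr(Xk[, c(kept, j), drop = FALSE])$rank > length(kept))
        kept <- c(kept, j)
    }
    Xk <- Xk[, sort(kept), drop = FALSE]
  }
  p <- ncol(Xk)
  beta <- numeric(p)
  bias <- grep("^bias", colnames(Xk))
  mu0 <- max(mean(y), 1e-8)
  if (length(bias)) beta[bias] <- log(mu0) / length(bias)
  devOf <- function(mu) {
    term <- ifelse(y > 0, y * log(y / mu), 0)
    2 * sum(term - (y - mu))
  }
  eta <- drop(Xk %*% beta)
  mu <- exp(eta)
  devTrace <- devOf(mu)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    w <- mu
    z <- eta + (y - mu) / mu
    WX <- Xk * w
    H <- crossprod(Xk, WX)
    g <- crossprod(WX, z)
    betaNew <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
    if (is.null(betaNew)) break
    # step-halving keeps the deviance non-increasing
    stepOK <- FALSE
    for (h in 0:12) {
      cand <- beta + (betaNew - beta) / 2^h
      etaC <- drop(Xk %*% cand)
      muC <- exp(pmin(etaC, 50))
      devC <- devOf(muC)
      if (is.finite(devC) && devC <= devTrace[length(devTrace)] + 1e-12) {
        stepOK <- TRUE
        break
      }
    }
    if (!stepOK) break
    beta <- cand; eta <- etaC; mu <- muC
    devTrace <- c(devTrace, devC)
    dPrev <- devTrace[length(devTrace) - 1]
    if (abs(dPrev - devC) < tol * (abs(devC) + 0.1)) {
      converged <- TRUE
      break
    }
  }
  flagged <- !converged || any(abs(beta) > 30)
  W <- mu
  H <- crossprod(Xk, Xk * W)
  phi <- if (dispersion == "pearson")
    sum((y - mu)^2 / mu) / max(length(y) - p, 1) else 1
  se <- tryCatch(sqrt(phi * diag(solve(H))),
                 error = function(e) rep(NA_real_, p))
  pv <- 2 * stats::pnorm(-abs(beta / se))
  out <- list(
    beta = stats::setNames(rep(NA_real_, length(full)), full),
    se = stats::setNames(rep(NA_real_, length(full)), full),
    p = stats::setNames(rep(NA_real_, length(full)), full),
    converged = converged, flagged = flagged,
    deviance = devTrace[length(devTrace)],
    deviance_trace = devTrace,
    dropped = setdiff(full, colnames(Xk)))
  out$beta[colnames(Xk)] <- beta
  out$se[colnames(Xk)] <- se
  out$p[colnames(Xk)] <- pv
  class(out) <- "ComponentFit"
  out
}

#' @export
print.ComponentFit <- function(x, ...) {
  cat("ComponentFit:", sum(!is.na(x$beta)), "of", length(x$beta),
      "coefficients estimated; deviance", format(x$deviance, digits = 6),
      if (x$flagged) "(FLAGGED)" else "", "\n")
  invisible(x)
}

#' Directional index and preferred direction from four location betas
#'
#' The four beta values are treated as weights on unit vectors pointing at
#' the four cue locations; the directional index is the norm of the summed
#' vector normalized by the summed absolute betas (0 when all betas vanish),
#' and the preferred direction is the angle of the summed vector.
#'
#' @param betas4 numeric length-4 (NA treated as 0).
#' @param locationAngles the four location angles (deg).
#' @return list: \code{DI} in [0, 1], \code{preferred_angle} (deg in
#'   [0, 360), NA when the vector norm is 0).
#' @export
directionalIndex <- function(betas4, locationAngles) {
  b <- ifelse(is.na(betas4), 0, betas4)
  th <- locationAngles * pi / 180
  vx <- sum(b * cos(th))
  vy <- sum(b * sin(th))
  denom <- sum(abs(b))
  if (denom == 0) return(list(DI = 0, preferred_angle = NA_real_))
  nv <- sqrt(vx^2 + vy^2)
  ang <- if (nv < 1e-12) NA_real_ else (atan2(vy, vx) * 180 / pi) %% 360
  list(DI = nv / denom, preferred_angle = ang)
}

#' Classify a neuron from its component fit
#'
#' A neuron carries a component when any of that component's betas is
#' significant (Wald p < \code{alpha}); it carries a directional component
#' when in addition the component's directional index exceeds
#' \code{diThreshold}. The preferred location is the task location nearest
#' the preferred angle, and the contra flag marks preferred directions in the
#' hemifield opposite the recorded hemisphere. Flagged (non-converged) fits
#' are returned unclassified.
#'
#' @param fit a [fitPoissonGLM()] result.
#' @param config a [TaskConfig-class].
#' @param hemisphere recorded hemisphere ("left"/"right").
#' @param alpha component-significance level.
#' @param diThreshold directional-index threshold (0.1).
#' @return one-row data.frame: per component \code{has_*} and \code{dir_*}
#'   flags, \code{DI_*}, \code{angle_*}, \code{prefloc_*}, \code{contra_*}
#'   for the directional components, plus \code{exclusive_type} ("visual",
#'   "extinction", "memory" when exactly one directional component is
#'   present, NA otherwise) and \code{unclassified}.
#' @export
classifyNeuron <- function(fit, config = taskConfig(), hemisphere = "left",
                           alpha = 0.05, diThreshold = 0.1) {
  dirComps <- c("visual", "extinction", "memory")
  out <- data.frame(unclassified = fit$flagged)
  if (fit$flagged) {
    for (cp in dirComps) {
      out[[paste0("has_", cp)]] <- NA
      out[[paste0("dir_", cp)]] <- NA
      out[[paste0("DI_", cp)]] <- NA_real_
      out[[paste0("angle_", cp)]] <- NA_real_
      out[[paste0("prefloc_", cp)]] <- NA_integer_
      out[[paste0("contra_", cp)]] <- NA
    }
    out$has_order <- NA; out$has_rule <- NA
    out$exclusive_type <- NA_character_
    return(out)
  }
  hemi <- hemifieldMap(config, hemisphere)
  for (cp in dirComps) {
    cols <- paste0(cp, "_", 0:3)
    pv <- fit$p[cols]
    has <- any(pv < alpha, na.rm = TRUE)
    di <- directionalIndex(fit$beta[cols], config@locationAngles)
    dir <- has && di$DI > diThreshold
    prefloc <- if (!is.na(di$preferred_angle)) {
      d <- abs(wrapDeg(config@locationAngles - di$preferred_angle))
      which.min(d) - 1L
    } else NA_integer_
    contra <- if (!is.na(di$preferred_angle)) {
      cx <- cos(di$preferred_angle * pi / 180)
      side <- if (abs(cx) < 1e-9) NA_character_ else
        if (cx > 0) "right" else "left"
      !is.na(side) && side != hemisphere
    } else NA
    out[[paste0("has_", cp)]] <- has
    out[[paste0("dir_", cp)]] <- dir
    out[[paste0("DI_", cp)]] <- di$DI
    out[[paste0("angle_", cp)]] <- di$preferred_angle
    out[[paste0("prefloc_", cp)]] <- prefloc
    out[[paste0("contra_", cp)]] <- contra
  }
  out$has_order <- any(fit$p[c("order_early", "order_late")] < alpha,
                       na.rm = TRUE)
  out$has_rule <- any(fit$p[c("rule_early", "rule_late")] < alpha,
                      na.rm = TRUE)
  ndir <- sum(out$dir_visual, out$dir_extinction, out$dir_memory)
  out$exclusive_type <- if (ndir == 1)
    dirComps[c(out$dir_visual, out$dir_extinction, out$dir_memory)] else
      NA_character_
  out
}

#' Fit and classify every neuron of a session
#'
#' Runs the full encoding-model pipeline per neuron: task-relatedness screen,
#' design construction, Poisson IRLS fit, directional indices and type
#' classification. Screened-out neurons appear in the table with
#' \code{screened_out = TRUE} and no fit.
#'
#' @param session a [SessionBundle-class].
#' @param responseScale passed to [buildDesign()].
#' @param minTrials passed to [taskRelatedScreen()].
#' @param screen logical; apply the task-relatedness screen (TRUE).
#' @param dispersion passed to [fitPoissonGLM()].
#' @return list: \code{table} (one row per neuron: 18 betas, SEs, p-values,
#'   DIs, angles, type flags), \code{fits} (named list of
#'   \code{ComponentFit}s).
#' @export
analyzeNeurons <- function(session, responseScale = "scaled",
                           minTrials = 80, screen = TRUE,
                           dispersion = "unit") {
  trials <- trialTable(session)
  config <- sessionMeta(session)$config
  hemi <- sessionMeta(session)$hemisphere
  ids <- unique(spikeTable(session)$neuron_id)
  fits <- list()
  rows <- list()
  for (id in ids) {
    ts <- spikeTable(session)$t_ms[spikeTable(session)$neuron_id == id]
    scr <- if (screen)
      taskRelatedScreen(ts, trials, config, minTrials = minTrials)
    else list(pass = TRUE, excluded = FALSE)
    row <- data.frame(neuron_id = id,
                      screened_out = !scr$pass || scr$excluded,
                      stringsAsFactors = FALSE)
    if (!row$screened_out) {
      counts <- epochCountMatrix(ts, trials, config)
      des <- buildDesign(trials, counts, config, responseScale)
      fit <- fitPoissonGLM(des, dispersion = dispersion)
      fits[[id]] <- fit
      cls <- classifyNeuron(fit, config, hemi)
      bet <- as.data.frame(as.list(fit$beta))
      names(bet) <- paste0("beta_", names(fit$beta))
      pvs <- as.data.frame(as.list(fit$p))
      names(pvs) <- paste0("p_", names(fit$p))
      row <- cbind(row, bet, pvs, cls)
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  list(table = tab, fits = fits)
}
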