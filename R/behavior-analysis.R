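#' Detect saccades in a 1-kHz eye trace
#'
#' A saccade is an excursion during which the smoothed angular eye velocity
#' exceeds 70 deg/s and whose total displacement exceeds 6 degrees. Velocity
#' is computed by central differences and smoothed with a 5-ms boxcar; onset
#' and offset are the threshold crossings.
#'
#' @param eye data.frame with \code{t_ms}, \code{x_deg}, \code{y_deg} sampled
#'   uniformly at 1 kHz.
#' @param velocityThreshold deg/s (70 by default).
#' @param minDisplacement degrees (6 by default).
#' @return data.frame of saccade events: \code{onset}, \code{offset} (ms),
#'   \code{start_x}, \code{start_y}, \code{end_x}, \code{end_y},
#'   \code{amplitude} (deg) and \code{peak_velocity} (deg/s). Zero rows when
#'   no saccade qualifies.
#' @export
detectSaccades <- function(eye, velocityThreshold = 70, minDisplacement = 6) {
  t <- eye$t_ms
  if (length(t) < 7) return(emptySaccades())
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop("eye trace must be uniformly sampled", call. = FALSE)
  step <- dt[1]  # ms per sample
  n <- length(t)
  vx <- c(NA, (eye$x_deg[3:n] - eye$x_deg[1:(n - 2)]) / (2 * step), NA) * 1000
  vy <- c(NA, (eye$y_deg[3:n] - eye$y_deg[1:(n - 2)]) / (2 * step), NA) * 1000
  # smooth the velocity components (noise averages out there, unlike in the
  # speed magnitude), then take the angular speed
  k <- max(1L, round(5 / step))
  vx <- stats::filter(vx, rep(1 / k, k), sides = 2)
  vy <- stats::filter(vy, rep(1 / k, k), sides = 2)
  sp <- sqrt(vx^2 + vy^2)
  above <- !is.na(sp) & sp > velocityThreshold
  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  # refine onset/offset: extend to a lower secondary threshold (40% of the
  # main one) to capture the slow initial ramp and the landing phase
  lowThr <- 0.4 * velocityThreshold
  maxExt <- round(30 / step)
  out <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    for (e in seq_len(maxExt)) {
      if (i0 > 1 && !is.na(sp[i0 - 1]) && sp[i0 - 1] > lowThr) i0 <- i0 - 1L
      else break
    }
    for (e in seq_len(maxExt)) {
      if (i1 < n && !is.na(sp[i1 + 1]) && sp[i1 + 1] > lowThr) i1 <- i1 + 1L
      else break
    }
    disp <- sqrt((eye$x_deg[i1] - eye$x_deg[i0])^2 +
                 (eye$y_deg[i1] - eye$y_deg[i0])^2)
    if (disp > minDisplacement) {
      out[[length(out) + 1L]] <- data.frame(
        onset = t[i0], offset = t[i1],
        start_x = eye$x_deg[i0], start_y = eye$y_deg[i0],
        end_x = eye$x_deg[i1], end_y = eye$y_deg[i1],
        amplitude = disp, peak_velocity = max(sp[i0:i1], na.rm = TRUE))
    }
  }
  if (!length(out)) return(emptySaccades())
  do.call(rbind, out)
}

emptySaccades <- function() {
  data.frame(onset = numeric(0), offset = numeric(0),
             start_x = numeric(0), start_y = numeric(0),
             end_x = numeric(0), end_y = numeric(0),
             amplitude = numeric(0), peak_velocity = numeric(0))
}

#' Score one trial from its eye trace
#'
#' The first saccade after FP offset defines the reaction time and endpoint.
#' The chosen location is the task location nearest the endpoint (the
#' 4-degree target window governs reward only, not the error taxonomy), and
#' the outcome category follows [classifyChoice()]. A suprathreshold saccade
#' before FP offset yields a fixation break; no saccade within the
#' reaction-time limit yields no response.
#'
#' @param trial a trial list (see [trialFromRow()]).
#' @param eye eye trace for the trial (1-kHz data.frame).
#' @param config a [TaskConfig-class].
#' @return one-row data.frame: \code{trial_id}, \code{category},
#'   \code{chosen_loc}, \code{rt_ms}, \code{end_x}, \code{end_y},
#'   \code{in_window} (endpoint within the reward window).
#' @export
scoreTrial <- function(trial, eye, config = taskConfig()) {
  if (is.null(eye) || !nrow(eye)) stop("missing eye data", call. = FALSE)
  sac <- detectSaccades(eye)
  base <- data.frame(trial_id = trial$trial_id, category = NA_character_,
                     chosen_loc = NA_integer_, rt_ms = NA_real_,
                     end_x = NA_real_, end_y = NA_real_, in_window = FALSE,
                     stringsAsFactors = FALSE)
  if (nrow(sac) && any(sac$onset < trial$fp_offset)) {
    base$category <- "fixation_break"
    return(base)
  }
  ok <- which(sac$onset >= trial$fp_offset &
              sac$onset <= trial$fp_offset + config@maxReactionTime)
  if (!length(ok)) {
    base$category <- "no_response"
    return(base)
  }
  s <- sac[ok[1], ]
  ang <- config@locationAngles * pi / 180
  lx <- config@eccentricity * cos(ang)
  ly <- config@eccentricity * sin(ang)
  d <- sqrt((s$end_x - lx)^2 + (s$end_y - ly)^2)
  chosen <- which.min(d) - 1L
  base$category <- classifyChoice(trial$rule, trial$cue_locations, chosen)
  base$chosen_loc <- chosen
  base$rt_ms <- s$onset - trial$fp_offset
  base$end_x <- s$end_x
  base$end_y <- s$end_y
  base$in_window <- d[chosen + 1L] <= config@targetWindow
  base
}

#' Score every trial of a session
#'
#' Applies [scoreTrial()] across the trials of a [SessionBundle-class] using
#' its eye table.
#'
#' @param session a [SessionBundle-class] with eye data.
#' @return data.frame of per-trial outcomes (see [scoreTrial()]).
#' @export
scoreSession <- function(session) {
  trials <- trialTable(session)
  eye <- eyeTable(session)
  if (!nrow(eye)) stop("session has no eye data", call. = FALSE)
  config <- sessionMeta(session)$config
  out <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trialFromRow(trials, i)
    scoreTrial(tr, eye[eye$trial_id == tr$trial_id, , drop = FALSE], config)
  })
  do.call(rbind, out)
}

#' Signed trajectory angle of a saccade endpoint
#'
#' The unsigned angle between the fixation-to-endpoint and fixation-to-goal
#' vectors, signed positive when the endpoint is rotated toward the
#' non-target cue direction and negative when rotated away.
#'
#' @param endpoint numeric length-2 (x, y) in degrees.
#' @param goalAngle goal direction in degrees.
#' @param nontargetAngle direction of the non-target (other last-two) cue in
#'   degrees; must differ from the goal by 90 degrees for the inclusion rule
#'   used in the session statistics.
#' @return signed angle in degrees, in (-180, 180].
#' @export
thetaAngle <- function(endpoint, goalAngle, nontargetAngle) {
  if (sqrt(sum(endpoint^2)) < 1e-12)
    stop("endpoint vector has zero length", call. = FALSE)
  endAng <- atan2(endpoint[2], endpoint[1]) * 180 / pi
  dev <- wrapDeg(endAng - goalAngle)
  toward <- sign(wrapDeg(nontargetAngle - goalAngle))
  as.numeric(dev * toward)
}

#' Per-trial trajectory-angle records for a session
#'
#' Computes theta for every completed trial and flags trials for inclusion in
#' the session statistics: correct trials whose last two cue directions are
#' 90 degrees apart.
#'
#' @param trials trials data.frame carrying outcome columns (\code{category},
#'   \code{end_x}, \code{end_y}) as produced by [simulateSession()] or by
#'   merging [scoreSession()] output.
#' @param config a [TaskConfig-class].
#' @return data.frame: \code{trial_id}, \code{rule}, \code{theta},
#'   \code{included}.
#' @export
thetaRecords <- function(trials, config = taskConfig()) {
  geo <- trialGeometry(trials, config)
  ang <- config@locationAngles
  n <- nrow(trials)
  theta <- rep(NA_real_, n)
  sep <- abs(wrapDeg(ang[geo$lastLoc + 1L] - ang[geo$prevLoc + 1L]))
  included <- !is.na(trials$category) & trials$category == "correct" &
    abs(sep - 90) < 1e-6
  for (i in which(!is.na(trials$end_x))) {
    theta[i] <- thetaAngle(c(trials$end_x[i], trials$end_y[i]),
                           ang[geo$target[i] + 1L], ang[geo$other[i] + 1L])
  }
  data.frame(trial_id = trials$trial_id, rule = trials$rule,
             theta = theta, included = included & !is.na(theta),
             stringsAsFactors = FALSE)
}

#' Session-level trajectory-angle statistics
#'
#' Mean theta per rule over included trials and their difference (2-back
#' minus 1-back). Rules without included trials yield NA and are excluded
#' from group tests.
#'
#' @param records data.frame from [thetaRecords()].
#' @return list with \code{mean_1b}, \code{mean_2b}, \code{delta}
#'   (2-back minus 1-back), and per-rule included-trial counts.
#' @export
thetaSessionStats <- function(records) {
  inc <- records[records$included, , drop = FALSE]
  m1 <- if (any(inc$rule == "1-back")) mean(inc$theta[inc$rule == "1-back"]) else NA_real_
  m2 <- if (any(inc$rule == "2-back")) mean(inc$theta[inc$rule == "2-back"]) else NA_real_
  list(mean_1b = m1, mean_2b = m2, delta = m2 - m1,
       n_1b = sum(inc$rule == "1-back"), n_2b = sum(inc$rule == "2-back"))
}

#' Two-sample KS test on per-session mean trajectory angles
#'
#' @param theta1b,theta2b numeric vectors of per-session mean theta under the
#'   two rules.
#' @return list with \code{D} (the KS statistic) and \code{p}.
#' @export
thetaDistributionTest <- function(theta1b, theta2b) {
  kt <- suppressWarnings(stats::ks.test(theta1b, theta2b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Stimulation-effect statistics
#'
#' For each of the three analyzed stimulus configurations (1-back with the
#' last-1 cue contralateral; 2-back with the last-1 cue contralateral; 2-back
#' with the last-1 cue ipsilateral) the function computes, per session, the
#' choice-error proportion with and without stimulation and a per-session 2x2
#' test (Fisher's exact test by default); across sessions it runs a paired t
#' test on the error proportions, on reaction times and on endpoint accuracy
#' (distance from the goal location). Fixation breaks are excluded before
#' everything else, and their proportion is reported.
#'
#' @param trials trials data.frame with outcome columns (\code{category},
#'   \code{rt_ms}, \code{end_x}, \code{end_y}, \code{stim}) and a
#'   \code{session_id} column when pooling multiple sessions.
#' @param config a [TaskConfig-class].
#' @param hemisphere recorded hemisphere used to label contralateral cues.
#' @param perSessionTest "fisher" or "chisq".
#' @return list with a \code{conditions} data.frame (one row per condition:
#'   error rates, deltas, paired-t statistics and p for errors, RT and
#'   accuracy), \code{per_session} (the underlying per-session table with the
#'   per-session exact-test p), and \code{fixation_break_rate}.
#' @export
stimulationEffectTest <- function(trials, config = taskConfig(),
                                  hemisphere = "left",
                                  perSessionTest = c("fisher", "chisq")) {
  perSessionTest <- match.arg(perSessionTest)
  if (is.null(trials$session_id)) trials$session_id <- "s1"
  fbRate <- mean(trials$category == "fixation_break", na.rm = TRUE)
  keep <- !is.na(trials$category) & trials$category != "fixation_break" &
    trials$category != "no_response"
  trials <- trials[keep, , drop = FALSE]
  geo <- trialGeometry(trials, config, hemisphere)
  cond <- rep(NA_character_, nrow(trials))
  cond[trials$rule == "1-back" & geo$prevContra] <- "1-back_contra_last1"
  cond[trials$rule == "2-back" & geo$prevContra] <- "2-back_contra_last1"
  cond[trials$rule == "2-back" & !geo$prevContra] <- "2-back_ipsi_last1"
  trials$condition <- cond
  trials$error <- trials$category != "correct"
  ang <- config@locationAngles * pi / 180
  gx <- config@eccentricity * cos(ang[geo$target + 1L])
  gy <- config@eccentricity * sin(ang[geo$target + 1L])
  trials$acc_err <- sqrt((trials$end_x - gx)^2 + (trials$end_y - gy)^2)
  trials$stim_on <- trials$stim != "none"

  condNames <- c("1-back_contra_last1", "2-back_contra_last1",
                 "2-back_ipsi_last1")
  perSess <- list()
  for (cd in condNames) {
    sub <- trials[!is.na(trials$condition) & trials$condition == cd, ,
                  drop = FALSE]
    for (sid in unique(sub$session_id)) {
      ss <- sub[sub$session_id == sid, , drop = FALSE]
      nS <- sum(ss$stim_on); nC <- sum(!ss$stim_on)
      if (nS == 0 || nC == 0) {
        warning("condition ", cd, " session ", sid,
                ": empty stimulation or control cell, skipped")
        next
      }
      tab <- table(factor(ss$stim_on, c(FALSE, TRUE)),
                   factor(ss$error, c(FALSE, TRUE)))
      pv <- if (perSessionTest == "fisher") stats::fisher.test(tab)$p.value
            else suppressWarnings(stats::chisq.test(tab)$p.value)
      perSess[[length(perSess) + 1L]] <- data.frame(
        condition = cd, session_id = sid,
        err_ctrl = mean(ss$error[!ss$stim_on]),
        err_stim = mean(ss$error[ss$stim_on]),
        rt_ctrl = mean(ss$rt_ms[!ss$stim_on], na.rm = TRUE),
        rt_stim = mean(ss$rt_ms[ss$stim_on], na.rm = TRUE),
        acc_ctrl = mean(ss$acc_err[!ss$stim_on], na.rm = TRUE),
        acc_stim = mean(ss$acc_err[ss$stim_on], na.rm = TRUE),
        p_exact = pv, stringsAsFactors = FALSE)
    }
  }
  perSess <- if (length(perSess)) do.call(rbind, perSess) else
    data.frame(condition = character(0))
  rows <- list()
  for (cd in condNames) {
    ps <- perSess[perSess$condition == cd, , drop = FALSE]
    if (!nrow(ps)) next
    pt <- function(a, b) {
      if (nrow(ps) < 2 || all(!is.finite(a - b)) || stats::sd(a - b) == 0)
        return(c(NA_real_, NA_real_))
      tt <- stats::t.test(a, b, paired = TRUE)
      c(unname(tt$statistic), tt$p.value)
    }
    e <- pt(ps$err_stim, ps$err_ctrl)
    r <- pt(ps$rt_stim, ps$rt_ctrl)
    a <- pt(ps$acc_stim, ps$acc_ctrl)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cd, n_sessions = nrow(ps),
      err_ctrl = mean(ps$err_ctrl), err_stim = mean(ps$err_stim),
      err_delta = mean(ps$err_stim - ps$err_ctrl),
      err_t = e[1], err_p = e[2],
      rt_delta = mean(ps$rt_stim - ps$rt_ctrl, na.rm = TRUE),
      rt_t = r[1], rt_p = r[2],
      acc_delta = mean(ps$acc_stim - ps$acc_ctrl, na.rm = TRUE),
      acc_t = a[1], acc_p = a[2],
      stringsAsFactors = FALSE)
  }
  list(conditions = if (length(rows)) do.call(rbind, rows) else
         data.frame(condition = character(0)),
       per_session = perSess,
       fixation_break_rate = fbRate)
}

#' Per-session behavioral summary
#'
#' Error rates by category and rule, reaction-time statistics and the
#' trajectory-angle statistics, as a nested list ready for JSON export.
#'
#' @param trials trials data.frame with outcome columns.
#' @param config a [TaskConfig-class].
#' @return list of summaries.
#' @export
behaviorSummary <- function(trials, config = taskConfig()) {
  rec <- thetaRecords(trials, config)
  byRule <- lapply(RULES, function(r) {
    sub <- trials[trials$rule == r, , drop = FALSE]
    compl <- sub[!sub$category %in% c("fixation_break", "no_response"), ,
                 drop = FALSE]
    list(n_trials = nrow(sub),
         fixation_break_rate = mean(sub$category == "fixation_break"),
         rates = as.list(prop.table(table(factor(compl$category,
           c("correct", "rule_error", "mem_error_23back", "mem_error_random"))))),
         rt_mean = mean(compl$rt_ms[compl$category == "correct"], na.rm = TRUE),
         rt_sd = stats::sd(compl$rt_ms[compl$category == "correct"], na.rm = TRUE))
  })
  names(byRule) <- RULES
  list(by_rule = byRule, theta = thetaSessionStats(rec))
}
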