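#' Spike density function by Gaussian-kernel convolution
#'
#' Convolves the spike train with a Gaussian kernel (sigma = 20 ms by
#' default), each spike contributing unit integral, so the trace estimates
#' the instantaneous firing rate in spikes/s.
#'
#' @param timestamps spike times (ms).
#' @param tGrid evaluation grid (ms), typically 1-ms spacing.
#' @param sigma kernel SD (ms), > 0.
#' @return numeric rate trace (spikes/s) over \code{tGrid}.
#' @examples
#' peak <- spikeDensity(0, 0, sigma = 20)     # 1/(20 sqrt(2*pi)) * 1000
#' @export
spikeDensity <- function(timestamps, tGrid, sigma = 20) {
  if (!length(tGrid)) stop("empty evaluation grid", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (!length(timestamps)) return(numeric(length(tGrid)))
  out <- numeric(length(tGrid))
  # chunk over spikes to bound the outer-product size
  idx <- split(timestamps, ceiling(seq_along(timestamps) / 500))
  for (ch in idx)
    out <- out + rowSums(outer(tGrid, ch,
                               function(a, b) stats::dnorm(a, b, sigma)))
  out * 1000
}

#' Count spikes in half-open windows
#'
#' @param timestamps sorted spike times (ms).
#' @param w0,w1 window starts and ends (ms), vectorized.
#' @return integer counts, one per window.
#' @export
countInWindows <- function(timestamps, w0, w1) {
  ts <- sort(timestamps)
  findInterval(w1 - 1e-9, ts) - findInterval(w0 - 1e-9, ts)
}

#' Early/late delay-epoch spike counts for one neuron
#'
#' Tabulates spike counts in the first and second 400-ms epoch of every delay
#' period of every trial: the response data for the encoding model and the
#' decoding features.
#'
#' @param timestamps spike times (ms) of one neuron.
#' @param trials trials data.frame.
#' @param config a [TaskConfig-class].
#' @return data.frame: \code{trial_id}, \code{delay}, \code{epoch}
#'   ("early"/"late"), \code{count}, \code{d_tag} ("D1"/"D2"/NA).
#' @export
epochCountMatrix <- function(timestamps, trials, config = taskConfig()) {
  res <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trialFromRow(trials, i)
    ep <- delayEpochs(tr, config)
    res[[i]] <- data.frame(
      trial_id = tr$trial_id,
      delay = rep(ep$delay, each = 2),
      epoch = rep(c("early", "late"), nrow(ep)),
      count = as.integer(rbind(countInWindows(timestamps, ep$early_start, ep$early_end),
                               countInWindows(timestamps, ep$late_start, ep$late_end))),
      d_tag = rep(ep$d_tag, each = 2),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Z-score normalization of a spike train
#'
#' The neuron's normalization constants are the mean and SD of its spike
#' counts in consecutive 100-ms bins across the session's task time; any
#' aligned activity is then z-scored against them. Silent neurons (zero SD)
#' are flagged and must be excluded from population averages.
#'
#' @param timestamps spike times (ms).
#' @param taskSpan length-2 (start, end) of the task time (ms).
#' @param binWidth bin width (ms), 100 by default.
#' @return list: \code{mu}, \code{sigma} (count mean/SD per bin),
#'   \code{bins} data.frame (\code{t0}, \code{count}, \code{z}),
#'   \code{flagged} (TRUE when SD is zero).
#' @export
zscoreNormalize <- function(timestamps, taskSpan, binWidth = 100) {
  edges <- seq(taskSpan[1], taskSpan[2], by = binWidth)
  if (length(edges) < 2) stop("task span shorter than one bin", call. = FALSE)
  t0 <- edges[-length(edges)]
  counts <- countInWindows(timestamps, t0, t0 + binWidth)
  mu <- mean(counts)
  sigma <- stats::sd(counts)
  flagged <- !is.finite(sigma) || sigma == 0
  z <- if (flagged) rep(NA_real_, length(counts)) else (counts - mu) / sigma
  list(mu = mu, sigma = sigma,
       bins = data.frame(t0 = t0, count = counts, z = z),
       flagged = flagged)
}

#' Task-relatedness screen for one neuron
#'
#' A neuron passes when its per-trial firing rate in the delay, saccade or
#' reward period differs from the pre-trial baseline (the 400 ms before the
#' first cue) by an unpaired t test at p < 0.05. The saccade epoch is the
#' 400 ms after FP offset and the reward epoch the 400 ms after the nominal
#' reward time (target reappearance + 600 ms); the delay epoch is the last
#' delay period. Neurons recorded for fewer than \code{minTrials} trials are
#' excluded outright.
#'
#' @param timestamps spike times (ms).
#' @param trials trials data.frame.
#' @param config a [TaskConfig-class].
#' @param alpha significance level of the screen.
#' @param minTrials minimum trial count for inclusion (80 by default,
#'   approximating the five-block recording criterion).
#' @return list: \code{pass}, \code{excluded} (below the trial minimum),
#'   \code{stats} data.frame (epoch, t, p).
#' @export
taskRelatedScreen <- function(timestamps, trials, config = taskConfig(),
                              alpha = 0.05, minTrials = 80) {
  if (nrow(trials) < minTrials)
    return(list(pass = FALSE, excluded = TRUE,
                stats = data.frame(epoch = character(0))))
  first <- trials$cue_onset_1
  fp <- trials$fp_offset
  rates <- function(w0, w1)
    countInWindows(timestamps, w0, w1) / (w1 - w0) * 1000
  base <- rates(first - 400, first)
  win <- list(
    delay = cbind(fp - config@delayDuration, fp),
    saccade = cbind(fp, fp + 400),
    reward = cbind(fp + config@targetReappearAfterFpOff + 600,
                   fp + config@targetReappearAfterFpOff + 1000))
  st <- lapply(names(win), function(nm) {
    r <- rates(win[[nm]][, 1], win[[nm]][, 2])
    if (stats::sd(r) == 0 && stats::sd(base) == 0)
      return(data.frame(epoch = nm, t = 0, p = 1))
    tt <- stats::t.test(r, base)
    data.frame(epoch = nm, t = unname(tt$statistic), p = tt$p.value)
  })
  st <- do.call(rbind, st)
  list(pass = any(st$p < alpha), excluded = FALSE, stats = st)
}

#' Population-activity heatmap and average
#'
#' Given per-neuron normalized activity traces on a common 1-ms grid,
#' measures activity in sliding windows (150 ms long, advanced in 10-ms
#' steps), sorts neurons by the time of their peak, and returns the heatmap
#' together with the population mean and SEM trace.
#'
#' @param traces numeric matrix, neurons x time (1-ms grid), typically
#'   z-scored activity aligned to the preferred cue.
#' @param tGrid time stamps (ms) for the columns of \code{traces}.
#' @param window,step window length and step (ms).
#' @return list: \code{heatmap} (neurons x windows, rows in sorted order),
#'   \code{order} (row permutation applied), \code{centers} (window-center
#'   times), \code{mean}, \code{sem}.
#' @export
populationAverage <- function(traces, tGrid, window = 150, step = 10) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (!nrow(traces)) stop("empty neuron set", call. = FALSE)
  dt <- tGrid[2] - tGrid[1]
  wlen <- round(window / dt)
  starts <- seq(1, ncol(traces) - wlen + 1, by = round(step / dt))
  hm <- vapply(starts, function(s)
    rowMeans(traces[, s:(s + wlen - 1), drop = FALSE]), numeric(nrow(traces)))
  if (is.null(dim(hm))) hm <- matrix(hm, nrow = 1)
  centers <- tGrid[starts] + window / 2
  ord <- order(apply(hm, 1, which.max))
  n <- nrow(hm)
  list(heatmap = hm[ord, , drop = FALSE], order = ord, centers = centers,
       mean = colMeans(hm),
       sem = apply(hm, 2, stats::sd) / sqrt(n))
}

#' Sliding paired t test between two condition traces
#'
#' Paired t test in every 100-ms window advanced in 20-ms steps, uncorrected
#' for multiple comparisons. Rows of the two matrices are paired units
#' (neurons); columns are a common 1-ms time grid.
#'
#' @param condA,condB numeric matrices, units x time, same shape.
#' @param tGrid time stamps (ms) for the columns.
#' @param window,step window length and step (ms).
#' @return data.frame: \code{center} (ms), \code{t}, \code{p}; one row per
#'   window, \code{floor((span - window)/step) + 1} rows in total.
#' @export
slidingTTest <- function(condA, condB, tGrid, window = 100, step = 20) {
  stopifnot(all(dim(condA) == dim(condB)))
  dt <- tGrid[2] - tGrid[1]
  wlen <- round(window / dt)
  starts <- seq(1, ncol(condA) - wlen + 1, by = round(step / dt))
  out <- lapply(starts, function(s) {
    a <- rowMeans(condA[, s:(s + wlen - 1), drop = FALSE])
    b <- rowMeans(condB[, s:(s + wlen - 1), drop = FALSE])
    if (stats::sd(a - b) == 0)
      return(data.frame(center = tGrid[s] + window / 2, t = 0, p = 1))
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(center = tGrid[s] + window / 2,
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject ANOVA for a 2 (stimulus order) x 2 (task rule) design with
#' one observation per cell per neuron. Each effect is computed from the
#' per-neuron contrast scores, so every F statistic has (1, n-1) degrees of
#' freedom and equals the squared paired-t of its contrast.
#'
#' @param cellMeans numeric matrix, neurons x 4, columns in the order
#'   (order1,rule1), (order1,rule2), (order2,rule1), (order2,rule2). Rows
#'   with missing cells are dropped (df adjust accordingly).
#' @return data.frame: \code{effect} ("order", "rule", "interaction"),
#'   \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
rmAnova2x2 <- function(cellMeans) {
  stopifnot(ncol(cellMeans) == 4)
  ok <- stats::complete.cases(cellMeans)
  m <- cellMeans[ok, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop("need at least 2 complete neurons", call. = FALSE)
  contrasts <- list(
    order = (m[, 3] + m[, 4] - m[, 1] - m[, 2]) / 2,
    rule = (m[, 2] + m[, 4] - m[, 1] - m[, 3]) / 2,
    interaction = (m[, 4] - m[, 3]) - (m[, 2] - m[, 1]))
  out <- lapply(names(contrasts), function(nm) {
    d <- contrasts[[nm]]
    eps <- 1e-10 * (max(abs(m)) + 1)
    if (stats::sd(d) <= eps) {
      Fv <- if (abs(mean(d)) <= eps) 0 else Inf
      return(data.frame(effect = nm, F = Fv, df1 = 1, df2 = n - 1,
                        p = if (Fv == 0) 1 else 0))
    }
    tt <- unname(stats::t.test(d)$statistic)
    Fv <- tt^2
    data.frame(effect = nm, F = Fv, df1 = 1, df2 = n - 1,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
  })
  do.call(rbind, out)
}
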