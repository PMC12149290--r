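#' @import methods
NULL

#' Task configuration for the oculomotor n-back paradigm
#'
#' Geometry and timing constants of the task. Two to four peripheral cues
#' (small white squares at a fixed eccentricity) are flashed sequentially,
#' separated by fixed delay periods, while the subject fixates centrally.
#' Fixation-point (FP) offset is the go signal: under the 1-back rule the
#' saccade goal is the most recent cue location, under the 2-back rule the
#' one-previous cue location.
#'
#' Cue locations are 0-based indices into \code{locationAngles}; angles are
#' measured in degrees counterclockwise from the rightward horizontal. All
#' times are in milliseconds.
#'
#' @slot nLocations integer, number of possible cue locations (4).
#' @slot locationAngles numeric, polar angle of each location in degrees;
#'   must be pairwise distinct modulo 360.
#' @slot eccentricity numeric, cue eccentricity in degrees of visual angle.
#' @slot cueDuration numeric, cue flash duration (ms).
#' @slot delayDuration numeric, delay between cue offset and the next event (ms).
#' @slot cueCountRange integer length-2, inclusive range of cues per trial
#'   (within 2--4).
#' @slot targetReappearAfterFpOff numeric, ms after FP offset at which the
#'   target cue reappears.
#' @slot maxReactionTime numeric, latest accepted saccade latency (ms).
#' @slot targetWindow numeric, radius (deg) of the reward window around the goal.
#' @slot intertrialInterval numeric, intertrial interval (ms).
#'
#' @seealso [taskConfig()] for the user-facing constructor with the standard
#'   defaults, [writeTaskConfig()] / [readTaskConfig()] for serialization.
#' @export
setClass("TaskConfig",
  representation(
    nLocations = "integer",
    locationAngles = "numeric",
    eccentricity = "numeric",
    cueDuration = "numeric",
    delayDuration = "numeric",
    cueCountRange = "integer",
    targetReappearAfterFpOff = "numeric",
    maxReactionTime = "numeric",
    targetWindow = "numeric",
    intertrialInterval = "numeric"
  )
)

setValidity("TaskConfig", function(object) {
  msg <- character()
  ang <- object@locationAngles %% 360
  if (length(ang) != object@nLocations)
    msg <- c(msg, "locationAngles must have length nLocations")
  if (anyDuplicated(round(ang, 9)))
    msg <- c(msg, "locationAngles must be pairwise distinct modulo 360")
  durs <- c(object@eccentricity, object@cueDuration, object@delayDuration,
            object@targetReappearAfterFpOff, object@maxReactionTime,
            object@targetWindow, object@intertrialInterval)
  if (any(!is.finite(durs)) || any(durs <= 0))
    msg <- c(msg, "all durations and geometry constants must be positive and finite")
  r <- object@cueCountRange
  if (length(r) != 2L || r[1] > r[2] || r[1] < 2L || r[2] > 4L)
    msg <- c(msg, "cueCountRange must be an inclusive range within [2, 4]")
  if (length(msg)) msg else TRUE
})

#' Construct a task configuration
#'
#' Returns a [TaskConfig-class] object. The defaults are the standard task
#' constants: four oblique cue locations at 12 degrees eccentricity, 150-ms
#' cues separated by 800-ms delays, 2--4 cues per trial, a 400-ms reaction-time
#' limit and a 4-degree target window. Index 0 is the upper-right location and
#' index 2 the lower-left one under the default angle set.
#'
#' @param nLocations number of cue locations.
#' @param locationAngles polar angles (deg CCW from rightward horizontal); the
#'   oblique set \code{c(45, 135, 225, 315)} by default, the cardinal set
#'   \code{c(0, 90, 180, 270)} being the usual alternative.
#' @param eccentricity cue eccentricity (deg).
#' @param cueDuration cue duration (ms).
#' @param delayDuration delay duration (ms).
#' @param cueCountRange inclusive range of cues per trial.
#' @param targetReappearAfterFpOff ms after FP offset at which the target
#'   reappears.
#' @param maxReactionTime maximum accepted saccade latency (ms).
#' @param targetWindow reward-window radius (deg).
#' @param intertrialInterval intertrial interval (ms).
#' @return A validated \code{TaskConfig}.
#' @examples
#' cfg <- taskConfig()
#' locationAngles(cfg)
#' @export
taskConfig <- function(nLocations = 4L,
                       locationAngles = c(45, 135, 225, 315),
                       eccentricity = 12,
                       cueDuration = 150,
                       delayDuration = 800,
                       cueCountRange = c(2L, 4L),
                       targetReappearAfterFpOff = 400,
                       maxReactionTime = 400,
                       targetWindow = 4,
                       intertrialInterval = 800) {
  new("TaskConfig",
      nLocations = as.integer(nLocations),
      locationAngles = as.numeric(locationAngles),
      eccentricity = as.numeric(eccentricity),
      cueDuration = as.numeric(cueDuration),
      delayDuration = as.numeric(delayDuration),
      cueCountRange = as.integer(cueCountRange),
      targetReappearAfterFpOff = as.numeric(targetReappearAfterFpOff),
      maxReactionTime = as.numeric(maxReactionTime),
      targetWindow = as.numeric(targetWindow),
      intertrialInterval = as.numeric(intertrialInterval))
}

#' @describeIn taskConfig location angles accessor (degrees).
#' @param x a \code{TaskConfig}.
#' @export
locationAngles <- function(x) x@locationAngles

setMethod("show", "TaskConfig", function(object) {
  cat("TaskConfig:", object@nLocations, "locations at",
      paste(object@locationAngles, collapse = "/"), "deg,",
      object@eccentricity, "deg eccentricity\n")
  cat("  cue", object@cueDuration, "ms / delay", object@delayDuration,
      "ms;", paste(object@cueCountRange, collapse = "-"), "cues per trial\n")
})

#' A recorded or synthesized experimental session
#'
#' Container for one session of the oculomotor n-back task: metadata
#' (session id, recorded hemisphere, task configuration), the trials table,
#' spike timestamps for each neuron, per-neuron metadata, the 1-kHz eye
#' trace, and - for synthetic sessions - a ground-truth sidecar.
#'
#' The trials table uses one row per trial with columns \code{trial_id},
#' \code{rule} ("1-back"/"2-back"), \code{n_cues}, \code{cue_loc_1..4}
#' (0-based location indices, NA-padded), \code{cue_onset_1..4} (ms),
#' \code{fp_offset} (ms) and \code{stim} ("none"/"early"/"late"). Spike
#' timestamps and eye samples live on the same session-relative millisecond
#' clock.
#'
#' @slot meta list with at least \code{session_id}, \code{hemisphere}
#'   ("left"/"right") and \code{config} (a [TaskConfig-class]).
#' @slot trials data.frame, one row per trial (see Details).
#' @slot spikes data.frame with columns \code{neuron_id}, \code{t_ms}.
#' @slot neurons data.frame with at least \code{neuron_id},
#'   \code{spike_width_ms}.
#' @slot eye data.frame with columns \code{t_ms}, \code{x_deg}, \code{y_deg},
#'   and \code{trial_id}; may have zero rows when eye data were not kept.
#' @slot truth list, ground-truth sidecar for synthetic sessions (empty
#'   otherwise).
#' @seealso [simulateSession()], [readSession()], [writeSession()].
#' @export
setClass("SessionBundle",
  representation(
    meta = "list",
    trials = "data.frame",
    spikes = "data.frame",
    neurons = "data.frame",
    eye = "data.frame",
    truth = "list"
  )
)

setValidity("SessionBundle", function(object) {
  msg <- character()
  m <- object@meta
  if (is.null(m$hemisphere) || !m$hemisphere %in% c("left", "right"))
    msg <- c(msg, "meta$hemisphere must be 'left' or 'right'")
  if (!is(m$config, "TaskConfig"))
    msg <- c(msg, "meta$config must be a TaskConfig")
  tr <- object@trials
  need <- c("trial_id", "rule", "n_cues", "fp_offset", "stim")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("trials table lacks columns:",
                        paste(setdiff(need, names(tr)), collapse = ", ")))
  else {
    if (anyDuplicated(tr$trial_id))
      msg <- c(msg, "trial_id values must be unique")
    if (!all(tr$rule %in% c("1-back", "2-back")))
      msg <- c(msg, "rule must be '1-back' or '2-back'")
  }
  if (nrow(object@spikes) && nrow(tr)) {
    span <- sessionSpan(tr, if (is(m$config, "TaskConfig")) m$config else taskConfig())
    bad <- object@spikes$t_ms < span[1] | object@spikes$t_ms > span[2]
    if (any(bad)) {
      who <- unique(object@spikes$neuron_id[bad])
      msg <- c(msg, paste0("spike timestamps outside session span for neuron(s): ",
                           paste(utils::head(who, 3), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SessionBundle", function(object) {
  cat("SessionBundle '", object@meta$session_id, "' (",
      object@meta$hemisphere, " hemisphere)\n", sep = "")
  cat("  ", nrow(object@trials), " trials; ",
      length(unique(object@spikes$neuron_id)), " neurons, ",
      nrow(object@spikes), " spikes; ",
      nrow(object@eye), " eye samples",
      if (length(object@truth)) "; ground truth attached" else "", "\n", sep = "")
})

#' Accessors for SessionBundle components
#'
#' @param x a [SessionBundle-class].
#' @return \code{trialTable} the trials data.frame; \code{spikeTable} the
#'   spike timestamp table; \code{eyeTable} the eye-sample table;
#'   \code{neuronTable} per-neuron metadata; \code{sessionMeta} the metadata
#'   list; \code{groundTruth} the synthetic ground-truth sidecar (empty list
#'   for recorded sessions).
#' @name sessionAccessors
NULL

#' @rdname sessionAccessors
#' @export
trialTable <- function(x) x@trials

#' @rdname sessionAccessors
#' @export
spikeTable <- function(x) x@spikes

#' @rdname sessionAccessors
#' @export
eyeTable <- function(x) x@eye

#' @rdname sessionAccessors
#' @export
neuronTable <- function(x) x@neurons

#' @rdname sessionAccessors
#' @export
sessionMeta <- function(x) x@meta

#' @rdname sessionAccessors
#' @export
groundTruth <- function(x) x@truth

# session time span [start, end] in ms, with padding for pre-trial baseline
# and post-saccade reward activity
sessionSpan <- function(trials, config) {
  if (!nrow(trials)) return(c(0, 0))
  first <- min(trials$cue_onset_1, na.rm = TRUE)
  last <- max(trials$fp_offset, na.rm = TRUE)
  c(first - 1000, last + 2000)
}
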