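#' @importFrom stats rnorm runif rpois rexp sd quantile
#' @importFrom utils head
NULL

RULES <- c("1-back", "2-back")

checkRule <- function(rule) {
  if (!is.character(rule) || length(rule) != 1L || !rule %in% RULES)
    stop("rule must be '1-back' or '2-back'", call. = FALSE)
  rule
}

#' Saccade goal for a cue sequence under a task rule
#'
#' Under the 1-back rule the goal is the most recent cue location; under the
#' 2-back rule it is the one-previous cue location.
#'
#' @param rule "1-back" or "2-back".
#' @param cueLocations integer vector of 0-based location indices in
#'   presentation order (length >= 2).
#' @return The 0-based goal location index.
#' @examples
#' targetLocation("1-back", c(0L, 2L))  # most recent cue -> 2
#' targetLocation("2-back", c(0L, 2L))  # one-previous cue -> 0
#' @export
targetLocation <- function(rule, cueLocations) {
  checkRule(rule)
  L <- length(cueLocations)
  if (L < 2L) stop("invalid trial: cue sequence must contain at least 2 cues",
                   call. = FALSE)
  if (rule == "1-back") cueLocations[L] else cueLocations[L - 1L]
}

#' Locations that must be held in memory after cue k
#'
#' After the k-th cue, a 1-back subject needs only the most recent cue
#' location, while a 2-back subject needs the two most recent ones (which
#' collapse to one when they coincide).
#'
#' @inheritParams targetLocation
#' @param k cue position, 1-based, within the sequence.
#' @return Integer vector of required location indices (a set: duplicates
#'   collapsed, sorted).
#' @examples
#' requiredMemorySet("2-back", c(0L, 1L, 2L), 3)  # {1, 2}
#' requiredMemorySet("1-back", c(0L, 1L), 2)      # {1}
#' @export
requiredMemorySet <- function(rule, cueLocations, k) {
  checkRule(rule)
  if (k < 1L || k > length(cueLocations))
    stop("cue position k out of range", call. = FALSE)
  if (rule == "1-back" || k == 1L) {
    out <- cueLocations[k]
  } else {
    out <- cueLocations[c(k - 1L, k)]
  }
  sort(unique(as.integer(out)))
}

#' Location whose memory becomes obsolete at cue k
#'
#' The extinction location at cue position k is the location that was in the
#' required memory set after cue k-1 but is no longer required after cue k -
#' the moment its memory can be discarded. Same-location repeats produce no
#' extinction event (the location remains required), and the first cue never
#' does.
#'
#' @inheritParams requiredMemorySet
#' @return A single 0-based location index, or \code{NA_integer_} when no
#'   location dropped out of the memory set.
#' @examples
#' extinctionLocation("1-back", c(2L, 0L), 2)       # 2 dropped
#' extinctionLocation("2-back", c(2L, 0L, 1L), 3)   # 2 dropped
#' extinctionLocation("1-back", c(3L, 3L), 2)       # NA: still required
#' @export
extinctionLocation <- function(rule, cueLocations, k) {
  checkRule(rule)
  if (k < 1L || k > length(cueLocations))
    stop("cue position k out of range", call. = FALSE)
  if (k == 1L) return(NA_integer_)
  prev <- requiredMemorySet(rule, cueLocations, k - 1L)
  cur <- requiredMemorySet(rule, cueLocations, k)
  dropped <- setdiff(prev, cur)
  if (length(dropped)) as.integer(dropped[1]) else NA_integer_
}

#' Classify a completed choice
#'
#' Behavioral error taxonomy over the four task locations: a saccade to the
#' goal is \code{correct}; to the other of the last two cue locations a
#' \code{rule_error} (the wrong rule was applied); to an earlier cue location
#' within the trial a \code{mem_error_23back} (2/3-back memory error); and to
#' a location never cued in the trial a \code{mem_error_random}.
#'
#' @inheritParams targetLocation
#' @param chosenLocation 0-based index of the chosen location.
#' @return One of \code{"correct"}, \code{"rule_error"},
#'   \code{"mem_error_23back"}, \code{"mem_error_random"}.
#' @examples
#' classifyChoice("2-back", c(0L, 1L, 2L), 2L)  # chose the last cue: rule error
#' classifyChoice("1-back", c(0L, 1L, 2L), 2L)  # correct
#' @export
classifyChoice <- function(rule, cueLocations, chosenLocation) {
  checkRule(rule)
  L <- length(cueLocations)
  if (L < 2L) stop("invalid trial: cue sequence must contain at least 2 cues",
                   call. = FALSE)
  if (length(chosenLocation) != 1L || is.na(chosenLocation))
    stop("chosenLocation must be a single location index", call. = FALSE)
  tgt <- targetLocation(rule, cueLocations)
  other <- if (rule == "1-back") cueLocations[L - 1L] else cueLocations[L]
  if (chosenLocation == tgt) return("correct")
  if (chosenLocation == other) return("rule_error")
  if (chosenLocation %in% cueLocations[seq_len(max(L - 2L, 0L))])
    return("mem_error_23back")
  "mem_error_random"
}

#' Delay-period epochs of a trial
#'
#' Each cue is followed by one delay period, split into an early and a late
#' 400-ms epoch used for spike counting. The last two delay periods before FP
#' offset are tagged D1 and D2 (the decoding epochs).
#'
#' @param trial a trial as returned by [trialFromRow()], or any list with
#'   \code{cue_onsets} and \code{fp_offset}.
#' @param config a [TaskConfig-class].
#' @return data.frame with one row per delay period: \code{delay} (1-based
#'   index), \code{delay_start}, \code{early_start}, \code{early_end},
#'   \code{late_start}, \code{late_end} (ms), and \code{d_tag} ("D1", "D2" or
#'   NA).
#' @export
delayEpochs <- function(trial, config = taskConfig()) {
  on <- trial$cue_onsets
  L <- length(on)
  if (L < 1L) stop("trial has no cues", call. = FALSE)
  half <- config@delayDuration / 2
  start <- on + config@cueDuration
  tag <- rep(NA_character_, L)
  if (L >= 2L) tag[L - 1L] <- "D1"
  tag[L] <- "D2"
  data.frame(
    delay = seq_len(L),
    delay_start = start,
    early_start = start,
    early_end = start + half,
    late_start = start + half,
    late_end = start + config@delayDuration,
    d_tag = tag,
    stringsAsFactors = FALSE
  )
}

#' Extract one trial from a trials table
#'
#' @param trials trials data.frame (see [SessionBundle-class]).
#' @param i row index.
#' @return list with \code{trial_id}, \code{rule}, \code{cue_locations},
#'   \code{cue_onsets}, \code{fp_offset}, \code{stim}.
#' @export
trialFromRow <- function(trials, i) {
  row <- trials[i, , drop = FALSE]
  n <- row$n_cues
  locs <- as.integer(row[paste0("cue_loc_", seq_len(n))])
  ons <- as.numeric(row[paste0("cue_onset_", seq_len(n))])
  list(trial_id = row$trial_id,
       rule = row$rule,
       cue_locations = locs,
       cue_onsets = ons,
       fp_offset = row$fp_offset,
       stim = row$stim)
}

#' Hemifield of each task location
#'
#' Locations in the visual hemifield opposite the recorded hemisphere are
#' contralateral. Locations on the vertical meridian (cos(angle) == 0) are
#' assigned \code{NA}.
#'
#' @param config a [TaskConfig-class].
#' @param hemisphere "left" or "right" (the recorded hemisphere).
#' @return character vector over locations: "ipsi", "contra" or NA.
#' @export
hemifieldMap <- function(config, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  cx <- cos(config@locationAngles * pi / 180)
  side <- ifelse(abs(cx) < 1e-9, NA_character_,
                 ifelse(cx > 0, "right", "left"))
  ifelse(is.na(side), NA_character_,
         ifelse(side == hemisphere, "ipsi", "contra"))
}

#' Serialize / load a task configuration
#'
#' The configuration is stored as a flat JSON object using the slot names of
#' [TaskConfig-class]; \code{readTaskConfig} validates on load.
#'
#' @param config a [TaskConfig-class].
#' @param path file path.
#' @return \code{readTaskConfig} returns a \code{TaskConfig};
#'   \code{writeTaskConfig} returns \code{path} invisibly.
#' @export
writeTaskConfig <- function(config, path) {
  x <- list(
    nLocations = config@nLocations,
    locationAngles = config@locationAngles,
    eccentricity = config@eccentricity,
    cueDuration = config@cueDuration,
    delayDuration = config@delayDuration,
    cueCountRange = config@cueCountRange,
    targetReappearAfterFpOff = config@targetReappearAfterFpOff,
    maxReactionTime = config@maxReactionTime,
    targetWindow = config@targetWindow,
    intertrialInterval = config@intertrialInterval
  )
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeTaskConfig
#' @export
readTaskConfig <- function(path) {
  x <- jsonlite::fromJSON(path)
  taskConfig(nLocations = x$nLocations,
             locationAngles = x$locationAngles,
             eccentricity = x$eccentricity,
             cueDuration = x$cueDuration,
             delayDuration = x$delayDuration,
             cueCountRange = x$cueCountRange,
             targetReappearAfterFpOff = x$targetReappearAfterFpOff,
             maxReactionTime = x$maxReactionTime,
             targetWindow = x$targetWindow,
             intertrialInterval = x$intertrialInterval)
}
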