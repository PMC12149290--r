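TRIAL_COLS <- c("trial_id", "rule", "n_cues",
                paste0("cue_loc_", 1:4), paste0("cue_onset_", 1:4),
                "fp_offset", "stim",
                "category", "chosen_loc", "rt_ms", "end_x", "end_y", "erased")

#' Write a session to a directory
#'
#' Serializes a [SessionBundle-class] as plain-text files with fixed schemas
#' and canonical column order: \code{meta.json}, \code{trials.csv},
#' \code{spikes.csv} (\code{neuron_id}, \code{t_ms}), \code{neurons.csv}
#' (\code{neuron_id}, \code{spike_width_ms}), \code{eye.csv} (\code{t_ms},
#' \code{x_deg}, \code{y_deg}, \code{trial_id}; omitted when empty), and
#' \code{truth.json} for synthetic sessions only. Identical bundles produce
#' identical bytes.
#'
#' @param bundle a [SessionBundle-class].
#' @param path target directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeSession <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory ", path,
                              call. = FALSE)
  meta <- sessionMeta(bundle)
  cfgFile <- file.path(path, "meta.json")
  m <- list(session_id = meta$session_id, hemisphere = meta$hemisphere)
  writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA), cfgFile)
  writeTaskConfig(meta$config, file.path(path, "task_config.json"))
  wcsv <- function(df, cols, file) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    utils::write.csv(df[, cols, drop = FALSE],
                     file.path(path, file), row.names = FALSE, quote = FALSE)
  }
  wcsv(trialTable(bundle), intersect(TRIAL_COLS, union(names(trialTable(bundle)),
                                                       TRIAL_COLS[1:13])),
       "trials.csv")
  wcsv(spikeTable(bundle), c("neuron_id", "t_ms"), "spikes.csv")
  wcsv(neuronTable(bundle), c("neuron_id", "spike_width_ms"), "neurons.csv")
  if (nrow(eyeTable(bundle)))
    wcsv(eyeTable(bundle), c("t_ms", "x_deg", "y_deg", "trial_id"), "eye.csv")
  tr <- groundTruth(bundle)
  if (length(tr))
    writeLines(jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(path, "truth.json"))
  invisible(path)
}

#' Read a session directory
#'
#' Loads and validates a session written by [writeSession()]. A missing
#' \code{eye.csv} disables behavior-from-eye-data stages with a warning
#' while spike-based stages proceed; schema violations raise descriptive
#' errors naming the offending file.
#'
#' @param path session directory.
#' @return a validated [SessionBundle-class].
#' @export
readSession <- function(path) {
  need <- c("meta.json", "trials.csv", "spikes.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session directory ", path, " lacks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- jsonlite::fromJSON(file.path(path, "meta.json"))
  config <- if (file.exists(file.path(path, "task_config.json")))
    readTaskConfig(file.path(path, "task_config.json")) else taskConfig()
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  for (cl in c("trial_id", "n_cues", "fp_offset"))
    if (!cl %in% names(trials))
      stop("trials.csv: missing required column '", cl, "'", call. = FALSE)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(neuron_id = "character"))
  neurons <- if (file.exists(file.path(path, "neurons.csv")))
    utils::read.csv(file.path(path, "neurons.csv"), stringsAsFactors = FALSE,
                    colClasses = c(neuron_id = "character"))
  else data.frame(neuron_id = unique(spikes$neuron_id),
                  spike_width_ms = NA_real_, stringsAsFactors = FALSE)
  eye <- if (file.exists(file.path(path, "eye.csv"))) {
    utils::read.csv(file.path(path, "eye.csv"), stringsAsFactors = FALSE)
  } else {
    warning("eye.csv missing in ", path,
            ": eye-movement stages disabled, spike stages unaffected")
    data.frame(t_ms = numeric(0), x_deg = numeric(0), y_deg = numeric(0),
               trial_id = integer(0))
  }
  truth <- if (file.exists(file.path(path, "truth.json")))
    jsonlite::fromJSON(file.path(path, "truth.json"),
                       simplifyDataFrame = FALSE) else list()
  new("SessionBundle",
      meta = list(session_id = m$session_id, hemisphere = m$hemisphere,
                  config = config),
      trials = trials, spikes = spikes, neurons = neurons, eye = eye,
      truth = truth)
}

# small stable hash (polynomial rolling hash over the serialized object)
# for config logging
configHash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default synthetic population for the pipeline
#'
#' A balanced population with \code{perType} neurons of each directional
#' archetype (memory, extinction, visual) at each preferred location, plus
#' \code{perType} order, rule and null neurons.
#'
#' @param perType neurons per archetype.
#' @param config a [TaskConfig-class].
#' @param baseline,gain rate parameters (spikes/s).
#' @return list of [neuronSpec()]s.
#' @export
defaultPopulation <- function(perType = 8, config = taskConfig(),
                              baseline = 5, gain = 8) {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  i <- 0
  for (arch in c("memory", "extinction", "visual")) {
    for (j in seq_len(perType)) {
      i <- i + 1
      add(neuronSpec(sprintf("n%03d_%s", i, arch), arch,
                     preferred_location = (j - 1L) %% config@nLocations,
                     baseline_rate = baseline, gain = gain))
    }
  }
  for (arch in c("order", "rule", "null")) {
    for (j in seq_len(perType)) {
      i <- i + 1
      add(neuronSpec(sprintf("n%03d_%s", i, arch), arch,
                     baseline_rate = baseline, gain = gain))
    }
  }
  specs
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order: \code{simulate} (write a
#' synthetic session), \code{behavior} (outcome and trajectory statistics),
#' \code{glm} (per-neuron encoding-model fits and type classification),
#' \code{decode} (pseudo-population rule decoding; requires the glm stage),
#' and \code{stim} (a separate horizontal-cue stimulation session and the
#' stimulation-effect tests). Every artifact records the configuration hash
#' and seed; per-stage counts go to \code{pipeline.log}.
#'
#' @param config list with \code{out} (output directory), \code{seed},
#'   \code{stages} (character subset of the above, in any order; executed in
#'   canonical order), and optional \code{n_trials}, \code{per_type},
#'   \code{session} (path of an existing session to analyze instead of
#'   simulating). Unknown keys are rejected.
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config) {
  known <- c("out", "seed", "stages", "n_trials", "per_type", "session")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- config$out %||% stop("config$out required")
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "behavior", "glm", "decode")
  order. <- c("simulate", "behavior", "glm", "decode", "stim")
  stages <- order.[order. %in% stages]
  if ("decode" %in% stages && !"glm" %in% stages && is.null(config$session))
    stop("stage ordering: 'decode' requires 'glm' classification output",
         call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # hash the analysis-relevant configuration, not the output location
  hashed <- setdiff(sort(names(config)), "out")
  hash <- configHash(config[hashed])
  logf <- file.path(out, "pipeline.log")
  logLine <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("config_hash=", hash, " seed=", seed, "\n", sep = "", file = logf)

  cfg <- taskConfig()
  session <- NULL
  if ("simulate" %in% stages) {
    session <- simulateSession(cfg, nTrials = config$n_trials %||% 240,
                               neuronSpecs = defaultPopulation(
                                 config$per_type %||% 8, cfg),
                               seed = seed)
    writeSession(session, file.path(out, "session"))
    logLine("simulate: ", nrow(trialTable(session)), " trials, ",
            nrow(neuronTable(session)), " neurons")
  } else if (!is.null(config$session)) {
    session <- readSession(config$session)
    logLine("loaded session from ", config$session)
  }
  glmTab <- NULL
  for (st in stages) {
    if (st == "behavior") {
      if (is.null(session)) stop("behavior stage needs a session")
      sm <- behaviorSummary(trialTable(session), sessionMeta(session)$config)
      writeLines(jsonlite::toJSON(c(list(config_hash = hash, seed = seed), sm),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 file.path(out, "behavior_summary.json"))
      rec <- thetaRecords(trialTable(session), sessionMeta(session)$config)
      utils::write.csv(rec, file.path(out, "theta_records.csv"),
                       row.names = FALSE)
      logLine("behavior: ", sum(rec$included), " theta-included trials")
    } else if (st == "glm") {
      res <- analyzeNeurons(session)
      glmTab <- res$table
      utils::write.csv(glmTab, file.path(out, "neuron_fits.csv"),
                       row.names = FALSE)
      logLine("glm: ", sum(!glmTab$screened_out), " fitted / ",
              nrow(glmTab), " neurons (",
              sum(glmTab$screened_out), " screened out)")
    } else if (st == "decode") {
      if (is.null(glmTab)) stop("stage ordering: decode before glm",
                                call. = FALSE)
      fitRows <- glmTab[!glmTab$screened_out & !glmTab$unclassified, ,
                        drop = FALSE]
      pref <- ifelse(!is.na(fitRows$prefloc_memory) & fitRows$dir_memory,
                     fitRows$prefloc_memory, fitRows$prefloc_visual)
      ok <- !is.na(pref)
      counts <- lapply(fitRows$neuron_id[ok], function(id) {
        ts <- spikeTable(session)$t_ms[spikeTable(session)$neuron_id == id]
        epochCountMatrix(ts, trialTable(session), sessionMeta(session)$config)
      })
      names(counts) <- fitRows$neuron_id[ok]
      tensor <- assemblePseudopopulation(
        counts, trialTable(session),
        stats::setNames(pref[ok], fitRows$neuron_id[ok]))
      if (length(tensor$neurons) >= 2) {
        sweep. <- decodeSweep(tensor,
                              unique(pmin(c(2, 5, 10), length(tensor$neurons))),
                              nTrainPerRule = 5, nValDraws = 50,
                              nTrainDraws = 20, seed = seed)
        utils::write.csv(sweep., file.path(out, "decode_sweep.csv"),
                         row.names = FALSE)
        logLine("decode: ", length(tensor$neurons), " neurons in tensor, ",
                length(tensor$excluded), " excluded")
      } else {
        logLine("decode: insufficient qualifying neurons, stage skipped")
      }
    } else if (st == "stim") {
      stimTrials <- generateTrials(taskConfig(locationAngles = c(0, 90, 180, 270)),
                                   config$n_trials %||% 240,
                                   stimFraction = 0.5, horizontalOnly = TRUE,
                                   seed = seed + 7L)
      oc <- simulateChoices(stimTrials, behaviorSpec(),
                            taskConfig(locationAngles = c(0, 90, 180, 270)),
                            seed = seed + 8L)
      stimTrials <- cbind(stimTrials,
                          oc[c("category", "chosen_loc", "rt_ms",
                               "end_x", "end_y", "erased")])
      res <- stimulationEffectTest(stimTrials,
                                   taskConfig(locationAngles = c(0, 90, 180, 270)))
      utils::write.csv(res$conditions, file.path(out, "stim_effects.csv"),
                       row.names = FALSE)
      logLine("stim: ", nrow(res$per_session), " condition-session cells")
    }
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
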