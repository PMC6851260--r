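# Reproducible simulate -> analyze -> report runs driven by a YAML (or list)
# config. Each run writes a manifest (config + seed + package version) that
# reproduces the outputs bit-exactly for the deterministic stages.

PIPELINE_VERBS <- c("make-stimulus", "simulate", "detect-events",
                    "analyze-transient", "analyze-assr", "analyze-baseline",
                    "analyze-afc", "score-freezing", "report")

validateRunConfig <- function(config) {
  if (!is.list(config)) stop("config error: config must be a list")
  if (is.null(config$stages) || !length(config$stages))
    stop("config error: 'stages' must be a nonempty list")
  seed <- config$seed
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("config error: a single numeric 'seed' is required")
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$verb) || !st$verb %in% PIPELINE_VERBS)
      stop("config error: stage ", i, " has unknown verb '",
           if (is.null(st$verb)) "<missing>" else st$verb,
           "' (known: ", paste(PIPELINE_VERBS, collapse = ", "), ")")
    if (!is.null(st$bands)) {
      known <- bandDefinitions()$name
      bad <- setdiff(unlist(st$bands), known)
      if (length(bad))
        stop("config error: stage ", i, " has unknown band name(s): ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

# build a protocol from a stage's params
stageProtocol <- function(st) {
  kind <- if (is.null(st$protocol)) "afc" else st$protocol
  switch(kind,
         afc = do.call(afcProtocol, st$protocol_args %||% list()),
         assr = buildAssrSequence(do.call(stimulusSpec,
                                          st$stimulus_args %||% list()))$protocol,
         transient = transientProtocol(do.call(stimulusSpec,
                                               st$stimulus_args %||% list())),
         stop("config error: unknown protocol kind '", kind, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulate/analyze/report pipeline
#'
#' Executes the configured stages in order. The config is a YAML file path
#' or an equivalent list with fields \code{seed}, optional \code{name}, and
#' \code{stages}: a list of stages, each with a \code{verb} (one of
#' make-stimulus, simulate, detect-events, analyze-transient, analyze-assr,
#' analyze-baseline, analyze-afc, score-freezing, report) plus verb-specific
#' parameters. A \code{manifest.json} (config, seed, package version, output
#' files) is written to \code{output_dir}, and analysis stages write CSV
#' reports there.
#'
#' @param config YAML path or config list.
#' @param output_dir output directory (created if missing); defaults to
#'   \code{config$output_dir} or a temp directory.
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
runPipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validateRunConfig(config)
  output_dir <- output_dir %||% config$output_dir %||%
    file.path(tempdir(), paste0("icassr-run-", config$seed))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  state <- list(session = NULL, results = list(), files = character())
  addCsv <- function(df, name) {
    p <- file.path(output_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    state$files <<- c(state$files, p)
    p
  }

  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    switch(st$verb,
      "make-stimulus" = {
        spec <- do.call(stimulusSpec, st$stimulus_args %||% list())
        kind <- st$kind %||% "transient"
        stim <- switch(kind,
                       transient = buildTransientTrain(spec),
                       assr = buildAssrSequence(spec)$stimulus,
                       cs = buildAmTone(spec$carrier_hz, 53.7, spec$am_depth,
                                        spec$segment_dur_s,
                                        spec$audio_rate_hz),
                       stop("config error: unknown stimulus kind '", kind, "'"))
        p <- file.path(output_dir, paste0("stimulus-", kind, ".wav"))
        writeStereoWav(stim, p)
        state$files <- c(state$files, p)
      },
      "simulate" = {
        protocol <- stageProtocol(st)
        args <- st$synthetic_args %||% list()
        args$seed <- args$seed %||% config$seed
        ev <- protocolEvents(protocol)
        args$duration_s <- args$duration_s %||% (max(ev$time_s) + 1)
        cfg <- do.call(syntheticConfig, args)
        sim <- generateSession(protocol, cfg, meta = st$meta %||% list())
        state$session <- sim$session
        base <- file.path(output_dir, st$name %||% "session")
        writeSession(sim$session, base)
        state$files <- c(state$files, paste0(base, c(".wav", ".json")))
      },
      "detect-events" = {
        src <- if (!is.null(st$wav)) readStereoWav(st$wav)
               else if (!is.null(state$session))
                 new("StereoStimulus",
                     audio = numeric(length(referenceTrack(state$session))),
                     reference = referenceTrack(state$session) /
                       max(abs(referenceTrack(state$session)), 1e-12),
                     rate = sampleRate(state$session))
               else stop("detect-events: no input (give 'wav' or simulate first)")
        det <- detectReferenceEvents(referenceTrack(src), sampleRate(src))
        state$results$events <- protocolEvents(det)
        addCsv(protocolEvents(det), sprintf("stage%02d-events", si))
      },
      "analyze-transient" = {
        res <- analyzeTransient(state$session)
        state$results$transient <- res
        addCsv(res, sprintf("stage%02d-transient", si))
      },
      "analyze-assr" = {
        cfg <- do.call(analysisConfig,
                       c(list(preset = "sound-processing"),
                         st$analysis_args %||% list()))
        res <- analyzeAssr(state$session, cfg)
        state$results$assr <- res
        addCsv(res, sprintf("stage%02d-assr", si))
      },
      "analyze-baseline" = {
        cfg <- do.call(analysisConfig,
                       c(list(preset = "sound-processing"),
                         st$analysis_args %||% list()))
        seg <- st$segment %||% {
          ev <- protocolEvents(state$session)
          sil <- ev$time_s[ev$kind == "silence_start"][1]
          nxt <- min(ev$time_s[ev$time_s > sil])
          c(sil, nxt)
        }
        res <- baselineProfile(state$session, unlist(seg), cfg)
        state$results$baseline <- res
        addCsv(res, sprintf("stage%02d-baseline", si))
      },
      "analyze-afc" = {
        cfg <- do.call(analysisConfig,
                       c(list(preset = "afc"), st$analysis_args %||% list()))
        res <- csNormalizedPower(state$session, cfg)
        state$results$afc <- res$per_cs
        state$results$afc_session_value <- res$session_value
        addCsv(res$per_cs, sprintf("stage%02d-afc", si))
      },
      "score-freezing" = {
        tr <- readMovementTrace(st$csv)
        res <- data.frame(
          freezing_cs_pct = scoreFreezingCs(tr$immobile, tr$rate_hz,
                                            st$cs_window_s %||% 30,
                                            st$epoch_s %||% 5,
                                            st$min_immobile_s %||% 3),
          freezing_period_pct = scoreFreezingPeriod(tr$immobile, tr$rate_hz,
                                                    st$min_bout_s %||% 3))
        state$results$freezing <- res
        addCsv(res, sprintf("stage%02d-freezing", si))
      },
      "report" = {
        keep <- intersect(names(state$results),
                          c("assr", "transient", "baseline", "afc", "freezing"))
        if (!length(keep)) stop("report: no analysis results to report")
        rep <- sessionReport(state$results[keep],
                             session_id = config$name %||% "session1",
                             meta = st$meta %||% list())
        state$results$report <- rep
        addCsv(rep, sprintf("stage%02d-report", si))
      })
  }

  manifest <- list(name = config$name %||% "run", seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("icassr")),
                   config = config, files = basename(state$files))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = state$results,
                 output_dir = output_dir))
}
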