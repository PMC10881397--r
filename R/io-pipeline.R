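## End-to-end pipeline runner: synthesis and analysis stages driven by a
## single config, with a manifest, a log, and deterministic outputs.

.pipelineStages <- c("synth", "behavior", "imaging", "model")

#' Run analysis stages over a trial directory
#'
#' Stages: \code{"synth"} generates a synthetic trial into the output
#' directory; \code{"behavior"} computes sliding goal/consistency, path
#' segments and the classified jump table; \code{"imaging"} z-scores ROI
#' series, fits the bump per frame and infers the neural goal;
#' \code{"model"} runs a closed-loop simulation. Outputs are CSV/JSON
#' under \code{out}; \code{manifest.json} records the package version,
#' config hash and seeds, and \code{pipeline.log} per-stage timing and
#' exclusion counts. Given the same config, outputs are byte-identical.
#'
#' @param config A list (or path to a JSON file) with elements
#'   \code{stages} (subset of synth/behavior/imaging/model), \code{seed},
#'   and optional stage settings: \code{trial_dir} (input trial for the
#'   analysis stages; defaults to the synth output), \code{synth} (args
#'   for [synthTrialSpec()]), \code{model} (args for [modelParams()]).
#' @param out Output directory.
#' @param dryRun Validate the config and inputs, write nothing.
#' @return Invisibly, a list of per-stage result paths.
#' @export
runPipeline <- function(config, out, dryRun = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config$stages is required")
  bad <- setdiff(stages, .pipelineStages)
  if (length(bad)) {
    stop("unknown stage(s) ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(.pipelineStages, collapse = ", "))
  }
  seed <- as.integer(config$seed %||% 1L)
  trialDir <- config$trial_dir %||% file.path(out, "trial")
  if (!"synth" %in% stages && !is.null(config$trial_dir) &&
      !file.exists(file.path(trialDir, "trial.json"))) {
    stop("trial_dir does not contain a trial.json")
  }
  if (dryRun) {
    message("dry run: config valid; stages = ",
            paste(stages, collapse = ", "))
    return(invisible(list()))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(out, "pipeline.log")
  cat("", file = logFile)
  logLine <- function(...) {
    cat(sprintf(...), "\n", file = logFile, append = TRUE)
  }
  results <- list()
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    ok <- TRUE
    res <- tryCatch(
      switch(stage,
        synth = {
          spec <- do.call(synthTrialSpec,
                          c(config$synth %||% list(), list(seed = seed)))
          beh <- synthBehavior(spec)
          img <- synthCalcium(beh$kinematics@heading, spec$sampleRate,
                              thetaG = spec$goalSchedule$theta_g[1L],
                              seed = seed + 1L)
          writeTrial(trialDir, beh, imaging = list(PB = img$roi),
                     groundTruth = list(calcium = img$groundTruth))
          trialDir
        },
        behavior = {
          tr <- readTrial(trialDir)
          k <- tr$kinematics
          gw <- slidingGoalConsistency(
            k@heading, k@cumulativeSpeed, k@sampleRate,
            jumpTimes = tr$descriptor$jump_times_s)
          segs <- segmentPath(gw$rho, k@heading, k@cumulativeSpeed,
                              k@sampleRate)
          jumps <- classifyJump(
            k@heading, gw$rho, k@cumulativeSpeed, k@sampleRate,
            data.frame(time = tr$descriptor$jump_times_s,
                       magnitude = tr$descriptor$jump_magnitudes_deg))
          write.csv(cbind(time_s = k@time, gw),
                    file.path(out, "goal_consistency.csv"),
                    row.names = FALSE)
          write.csv(segs, file.path(out, "segments.csv"),
                    row.names = FALSE)
          write.csv(jumps, file.path(out, "jumps.csv"), row.names = FALSE)
          logLine("behavior: %d segments (%d valid), %d/%d jumps excluded",
                  nrow(segs), sum(segs$valid), sum(jumps$excluded),
                  nrow(jumps))
          file.path(out, c("goal_consistency.csv", "segments.csv",
                           "jumps.csv"))
        },
        imaging = {
          tr <- readTrial(trialDir)
          if (!length(tr$imaging)) stop("trial has no ROI channels")
          paths <- character(0)
          for (nm in names(tr$imaging)) {
            x <- zscoreDff(tr$imaging[[nm]])
            fits <- fitBumpSeries(roiValues(x, "zscored"))
            f <- file.path(out, sprintf("bump_%s.csv", nm))
            write.csv(cbind(time_s = frameTimes(x), fits), f,
                      row.names = FALSE)
            paths <- c(paths, f)
            logLine("imaging[%s]: %d/%d frames with valid fits", nm,
                    sum(fits$valid), nrow(fits))
          }
          paths
        },
        model = {
          p <- do.call(modelParams,
                       c(config$model %||% list(), list(seed = seed)))
          sim <- simulateClosedLoop(p, thetaInit = 0)
          writeSimulation(sim, out)
        }),
      error = function(e) {
        ok <<- FALSE
        logLine("stage %s FAILED: %s", stage, conditionMessage(e))
        writeLines(sprintf("stage %s failed: %s", stage,
                           conditionMessage(e)),
                   file.path(out, "FAILED"))
        stop("pipeline stage '", stage, "' failed: ",
             conditionMessage(e), call. = FALSE)
      })
    logLine("stage %s: %.2f s", stage, proc.time()[["elapsed"]] - t0)
    results[[stage]] <- res
  }
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfgJson), tmp)
  jsonlite::write_json(list(
    package_version = as.character(packageVersion("flysteer")),
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    stages = stages
  ), file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  unlink(tmp)
  invisible(results)
}
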