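## Trial directory format: CSV time series + JSON metadata.
##
## A trial directory holds kinematics.csv (columns with unit-suffixed
## names), optional roi_<REGION>.csv matrices (time_s, roi_01..roi_NN),
## optional vm.csv (time_s, vm_mV), trial.json (the descriptor: jump
## schedule, arena parameters, channel inventory, seed registry) and
## ground_truth.json when the trial is synthetic.

TRIAL_SCHEMA_VERSION <- 1L

#' Write a trial directory
#'
#' @param dir Output directory (created if needed).
#' @param behavior Output of [synthBehavior()] (or a compatible list
#'   with \code{kinematics}, \code{trial}, optional \code{cue_deg},
#'   \code{yaw_deg}, \code{groundTruth}).
#' @param imaging Optional named list of \linkS4class{RoiTimeSeries}
#'   (names are used in file names).
#' @param vm Optional \linkS4class{VmTrace}.
#' @param groundTruth Optional extra ground truth merged into
#'   \code{ground_truth.json}.
#' @return Invisibly, the directory path.
#' @export
writeTrial <- function(dir, behavior, imaging = NULL, vm = NULL,
                       groundTruth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kin <- as.data.frame(behavior$kinematics)
  if (!is.null(behavior$cue_deg)) kin$cue_deg <- behavior$cue_deg
  if (!is.null(behavior$yaw_deg)) kin$yaw_deg <- behavior$yaw_deg
  write.csv(kin, file.path(dir, "kinematics.csv"), row.names = FALSE)

  channels <- list(kinematics = list(
    file = "kinematics.csv", sample_rate_hz = behavior$kinematics@sampleRate,
    n_samples = nrow(kin)))
  for (nm in names(imaging)) {
    x <- imaging[[nm]]
    f <- sprintf("roi_%s.csv", nm)
    m <- t(roiValues(x, "raw"))
    colnames(m) <- sprintf("roi_%02d", seq_len(ncol(m)))
    write.csv(data.frame(time_s = frameTimes(x), m, check.names = FALSE),
              file.path(dir, f), row.names = FALSE)
    channels[[paste0("roi_", nm)]] <- list(
      file = f, region = imagingRegion(x), sample_rate_hz = frameRate(x),
      n_samples = ncol(x), n_roi = nrow(x))
  }
  if (!is.null(vm)) {
    write.csv(data.frame(time_s = vm@time, vm_mV = vm@vm),
              file.path(dir, "vm.csv"), row.names = FALSE)
    channels$vm <- list(file = "vm.csv", sample_rate_hz = vm@samplingRate,
                        n_samples = length(vm@vm),
                        cell_type = vm@cellType,
                        junction_corrected = TRUE)
  }
  desc <- behavior$trial
  desc$schema_version <- TRIAL_SCHEMA_VERSION
  desc$channels <- channels
  jsonlite::write_json(desc, file.path(dir, "trial.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gt <- c(behavior$groundTruth, groundTruth)
  if (length(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(dir)
}

.trialStop <- function(field, why) {
  stop("trial format error at '", field, "': ", why, call. = FALSE)
}

#' Read and validate a trial directory
#'
#' Loads the descriptor and every declared channel, checking that files
#' exist, required columns are present and lengths match the
#' declaration; violations raise errors naming the offending field.
#'
#' @param dir Trial directory (as written by [writeTrial()]).
#' @return A list: \code{descriptor}, \code{kinematics}
#'   (\linkS4class{KinematicsTrace}), \code{imaging} (named list of
#'   \linkS4class{RoiTimeSeries}), \code{vm} (\linkS4class{VmTrace} or
#'   NULL), \code{groundTruth} (list or NULL).
#' @export
readTrial <- function(dir) {
  jf <- file.path(dir, "trial.json")
  if (!file.exists(jf)) .trialStop("trial.json", "file missing")
  desc <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (is.null(desc$channels$kinematics)) {
    .trialStop("channels.kinematics", "missing from descriptor")
  }
  kf <- file.path(dir, desc$channels$kinematics$file)
  if (!file.exists(kf)) .trialStop("channels.kinematics.file", "file missing")
  kin <- read.csv(kf)
  need <- c("time_s", "forward_mm_s", "sideways_mm_s",
            "rotational_deg_s", "cumulative_speed_rad_s", "heading_deg")
  miss <- setdiff(need, names(kin))
  if (length(miss)) {
    .trialStop(paste0("kinematics.", miss[1L]), "column missing")
  }
  if (nrow(kin) != desc$channels$kinematics$n_samples) {
    .trialStop("channels.kinematics.n_samples",
               sprintf("descriptor declares %d samples but file has %d",
                       desc$channels$kinematics$n_samples, nrow(kin)))
  }
  kinTrace <- new("KinematicsTrace", time = kin$time_s,
                  forward = kin$forward_mm_s, sideways = kin$sideways_mm_s,
                  rotational = kin$rotational_deg_s,
                  cumulativeSpeed = kin$cumulative_speed_rad_s,
                  heading = kin$heading_deg,
                  mobile = kin$cumulative_speed_rad_s > MOBILE_SPEED_RAD_S,
                  sampleRate = desc$channels$kinematics$sample_rate_hz)
  imaging <- list()
  vm <- NULL
  for (nm in names(desc$channels)) {
    ch <- desc$channels[[nm]]
    if (startsWith(nm, "roi_")) {
      f <- file.path(dir, ch$file)
      if (!file.exists(f)) .trialStop(paste0(nm, ".file"), "file missing")
      d <- read.csv(f, check.names = FALSE)
      roiCols <- sprintf("roi_%02d", seq_len(ch$n_roi))
      miss <- setdiff(c("time_s", roiCols), names(d))
      if (length(miss)) {
        .trialStop(paste0(nm, ".", miss[1L]), "column missing")
      }
      if (nrow(d) != ch$n_samples) {
        .trialStop(paste0(nm, ".n_samples"),
                   sprintf("declared %d, found %d", ch$n_samples, nrow(d)))
      }
      imaging[[sub("^roi_", "", nm)]] <-
        roiTimeSeries(t(as.matrix(d[roiCols])), region = ch$region,
                      frameRate = ch$sample_rate_hz, time = d$time_s)
    } else if (nm == "vm") {
      vm <- readVmCsv(file.path(dir, ch$file),
                      cellType = ch$cell_type %||% "PFL2",
                      corrected = isTRUE(ch$junction_corrected))
      if (length(vm@vm) != ch$n_samples) {
        .trialStop("vm.n_samples",
                   sprintf("declared %d, found %d", ch$n_samples,
                           length(vm@vm)))
      }
    }
  }
  gtf <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtf)) {
    jsonlite::read_json(gtf, simplifyVector = TRUE)
  } else NULL
  list(descriptor = desc, kinematics = kinTrace, imaging = imaging,
       vm = vm, groundTruth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
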