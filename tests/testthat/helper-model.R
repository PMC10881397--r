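## Shared, memoized model fixtures: activation calibration is the
## expensive step, so tests reuse one calibration per configuration.

.fixtureEnv <- new.env(parent = emptyenv())

fsParams <- function(...) {
  args <- utils::modifyList(list(duration = 10, noiseSd = 0), list(...))
  do.call(modelParams, args)
}

fsCal <- function(params = fsParams(), pathway = "full") {
  key <- paste(params@nUnits, params@activation, params@goalAmplitude,
               pathway, paste(params@calibrationS, collapse = ","),
               sep = "|")
  if (is.null(.fixtureEnv[[key]])) {
    .fixtureEnv[[key]] <- calibrateModel(params, pathway)
  }
  .fixtureEnv[[key]]
}

## noise-free open-loop drive at a given directional error
fsDrive <- function(e, params = fsParams(), cal = fsCal(params),
                    pathway = "full") {
  act <- pflRates(e, 0, params, cal)
  dna <- descendingOutputs(act, params, cal, pathway)
  steeringDrive(dna, cal)
}
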