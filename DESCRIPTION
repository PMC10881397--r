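Package: flysteer
Title: Goal-Directed Steering in the Fly Central Complex: Network Model and
    Analysis Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a firing-rate network model of the Drosophila
    head-direction-to-steering pathway (PFL2 and PFL3 columnar outputs,
    descending neurons DNa03 and DNa02), including closed-loop steering
    simulations with frozen low-pass-filtered noise and sweeps over the
    input scale factor. Provides the accompanying analysis pipelines for
    tethered-fly experiments: circular statistics (goal direction and
    consistency of head direction), spherical-treadmill kinematics
    preprocessing, path segmentation by walking straightness, cue-jump
    classification, sinusoidal activity-bump fitting for columnar calcium
    imaging, neural inference of the goal direction from bump amplitude,
    membrane-potential processing with spike and IPSP detection, and
    head-direction tuning analyses. A synthetic-data module generates
    behavior, imaging and electrophysiology fixtures with recorded ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    car,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'circular.R'
    'bump.R'
    'model-activation.R'
    'model-network.R'
    'model-simulate.R'
    'behavior-kinematics.R'
    'behavior-goal.R'
    'behavior-jumps.R'
    'behavior-binning.R'
    'imaging.R'
    'ephys-vm.R'
    'ephys-ipsp.R'
    'ephys-tuning.R'
    'ephys-jumps.R'
    'synth-behavior.R'
    'synth-imaging.R'
    'synth-ephys.R'
    'io-trial.R'
    'io-pipeline.R'
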