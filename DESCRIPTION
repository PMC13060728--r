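Package: swgaze
Title: Social Wayfinding Gaze and Trajectory Analysis in Virtual Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing locomotion and eye-movement behaviour in
    social-wayfinding tasks run in room-scale virtual reality. The package
    encodes a virtual train-station scene and factorial session designs,
    simulates walker rows, participant trajectories, binocular gaze streams
    and pupil signals with ground-truth labels, reconstructs 3D gaze points
    from eye rays by vergence and collider ray-casting, classifies eye
    movements with a velocity-threshold filter and a four-state hidden
    Markov model (fixation, saccade, post-saccadic oscillation, smooth
    pursuit), segments trials into task phases, and computes the metric
    suite: attention-type gaze allocation, gaze transition entropy, the
    ambient-focal K coefficient, inter-walker gap crossing position, path
    and speed profiles, gaze-movement alignment, and a wavelet-based
    pupillary activity index.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
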