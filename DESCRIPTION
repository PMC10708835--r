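Package: gaittorque
Title: Lower-Limb Joint Torque Prediction from Surface EMG and Joint Angles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sagittal-plane hip, knee and ankle torques during walking
    from windowed surface electromyography (sEMG) features and joint angles.
    Implements seven classical sEMG window features (MAV, RMS, zero crossings,
    slope sign changes, waveform length, mean and median frequency), zero-lag
    Butterworth preprocessing, a from-scratch stacked LSTM sequence regressor
    trained by backpropagation through time, and exponential-kernel Gaussian
    process regression with a constant basis fitted by maximising the log
    marginal likelihood. A synthetic gait generator produces dynamically
    consistent torques for a planar three-link swing-limb model together with
    activation-modulated sEMG, so the full pipeline is reproducible without
    motion-capture data. Evaluation follows a leave-one-gait-cycle-out protocol
    with NRMSE, Pearson correlation and the coefficient of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rlang,
    signal,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    kernlab,
    jsonlite
Config/testthat/edition: 3
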