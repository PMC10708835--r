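# Synthetic gait generator: kinematic exactness, envelope construction, sEMG
# statistics, and the on-disk dataset contract.

test_that("zero harmonic amplitudes give a constant angle with zero derivatives", {
  cfg <- tiny_gait_config(angle_amp_deg = list(hip = c(0, 0), knee = c(0, 0),
                                               ankle = c(0, 0)))
  kin <- generate_kinematics(cfg, subject_seed = 1)
  expect_equal(max(abs(sweep(kin$q, 2, kin$q[1, ]))), 0)
  expect_equal(max(abs(kin$qd)), 0)
  expect_equal(max(abs(kin$qdd)), 0)
})

test_that("kinematics are exactly periodic on the sampled grid", {
  cfg <- tiny_gait_config()
  kin <- generate_kinematics(cfg, subject_seed = 2)
  spc <- kin$samples_per_cycle
  n <- nrow(kin$q)
  expect_equal(kin$q[1:(n - spc), ], kin$q[(spc + 1):n, ], tolerance = 1e-12)
  expect_equal(kin$qd[1:(n - spc), ], kin$qd[(spc + 1):n, ], tolerance = 1e-12)
})

test_that("analytic acceleration matches a central difference of the angles", {
  cfg <- tiny_gait_config()
  kin <- generate_kinematics(cfg, subject_seed = 4)
  dt <- 1 / cfg$mocap_rate
  idx <- 2:(nrow(kin$q) - 1)
  fd <- (kin$q[idx + 1, ] - 2 * kin$q[idx, ] + kin$q[idx - 1, ]) / dt^2
  # central difference is exact to O(dt^2); bound the relative error
  expect_lt(max(abs(fd - kin$qdd[idx, ])), 0.02 * max(abs(kin$qdd)))
})

test_that("generated angles stay inside the configured physiological bounds", {
  cfg <- gait_config(n_subjects = 1)
  for (s in 1:10) {
    kin <- generate_kinematics(cfg, subject_seed = s)
    for (j in joint_names <- c("hip", "knee", "ankle")) {
      bound <- max(cfg$angle_amp_deg[[j]]) * pi / 180 + 1e-12
      mean_j <- cfg$angle_mean_deg[[j]] * pi / 180
      expect_lte(max(abs(kin$q[, j] - mean_j)), bound)
    }
  }
})

test_that("activation envelopes mix rectified torque and phase bursts in [0, 1]", {
  n <- 200
  phase <- (0:(n - 1)) / n
  tau <- cbind(hip = sin(2 * pi * phase) * 30,
               knee = cos(2 * pi * phase) * 20,
               ankle = sin(4 * pi * phase) * 10)
  env <- activation_envelopes(tau, phase, c("GMX", "RF", "BF", "TA", "GC"))
  expect_true(all(env >= 0 & env <= 1))
  # zero torque and zero burst weight -> identically zero
  env0 <- activation_envelopes(tau * 0, phase, "RF", burst_weight = 0)
  expect_equal(max(abs(env0)), 0)
  # the torque-driven component is linear in torque before normalization
  e1 <- attr(activation_envelopes(tau, phase, "TA"), "torque_component")
  e2 <- attr(activation_envelopes(2 * tau, phase, "TA"), "torque_component")
  expect_equal(e2, 2 * e1)
  # with the torque term off, envelope maxima sit at the configured bursts
  envb <- activation_envelopes(tau, phase, c("GMX", "TA"), torque_weight = 0)
  expect_equal(phase[which.max(envb[, "GMX"])], 0.60, tolerance = 0.02)
  expect_equal(phase[which.max(envb[, "TA"])], 0.05, tolerance = 0.02)
  expect_error(activation_envelopes(tau, phase, "VASTUS"), "unknown muscle")
})

test_that("sEMG synthesis is seed-deterministic with the configured noise floor", {
  cfg <- tiny_gait_config()
  n <- 300   # 3 s on the 100 Hz grid
  env <- matrix(0, n, 2, dimnames = list(NULL, c("GMX", "TA")))
  e1 <- synthesize_emg(env, cfg, seed = 99)
  e2 <- synthesize_emg(env, cfg, seed = 99)
  expect_identical(e1, e2)
  e3 <- synthesize_emg(env, cfg, seed = 100)
  expect_false(identical(e1, e3))
  # zero envelope: channel sd equals the baseline level amplitude / snr
  expect_equal(sd(e1[, 1]), 0.5 / cfg$snr, tolerance = 0.1)
})

test_that("windowed RMS of a synthesized channel tracks its envelope", {
  cfg <- tiny_gait_config()
  n <- 400
  phase <- (0:(n - 1)) / 100
  env <- matrix(0.5 + 0.45 * sin(2 * pi * phase / 2), n, 1,
                dimnames = list(NULL, "GC"))
  emg <- synthesize_emg(env, cfg, seed = 12)
  feats <- extract_features(emg[, 1], fs = cfg$emg_rate)
  env_at <- env[round(feats$time * 100), 1]
  expect_gt(cor(feats$rms, env_at), 0.8)
})

test_that("the dataset writer round-trips through its CSV dialect and manifest", {
  cfg <- gait_config(cycles_per_subject = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  trials <- make_gait_dataset(cfg, dir = d1)
  expect_length(trials, 4)
  for (tr in trials) {
    expect_length(tr$boundaries, 6)   # 5 cycle starts + endpoint
    validate_gait_trial(tr)
  }
  mocap <- read.csv(file.path(d1, "sub1_mocap.csv"))
  emg <- read.csv(file.path(d1, "sub1_emg.csv"))
  expect_equal(nrow(emg), 20 * nrow(mocap))
  expect_named(emg, c("time_s", "GMX", "RF", "BF", "TA", "GC"))
  expect_named(mocap, c("time_s", "hip_rad", "knee_rad", "ankle_rad",
                        "hip_Nm", "knee_Nm", "ankle_Nm"))
  # regenerating from the same config reproduces identical files
  make_gait_dataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
  # reading back reproduces the in-memory trial
  back <- read_gait_trial(d1, 1)
  expect_equal(back$angles, trials[[1]]$angles, tolerance = 1e-12)
  expect_equal(back$torques, trials[[1]]$torques, tolerance = 1e-12)
  expect_equal(back$boundaries, trials[[1]]$boundaries)
})

test_that("torques in a simulated trial satisfy the chain's equation of motion", {
  cfg <- tiny_gait_config()
  trial <- simulate_gait_trial(cfg, 1)
  kin <- generate_kinematics(cfg, cfg$seed + 1)
  tau <- inverse_dynamics(kin, trial$chain)
  expect_equal(unname(trial$torques), unname(tau))
})
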