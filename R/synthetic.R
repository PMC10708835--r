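#' Configuration of the synthetic gait dataset
#'
#' Describes the study conditions emulated by the generator: treadmill-speed
#' walking recorded as multichannel sEMG at 2000 Hz plus sagittal hip, knee
#' and ankle angles and torques at 100 Hz, segmented into complete gait
#' cycles (toe-off to toe-off).
#'
#' @param n_subjects Number of synthetic subjects.
#' @param cycles_per_subject Complete gait cycles per subject (>= 2).
#' @param cycle_period Gait-cycle duration in seconds; must be a whole number
#'   of mocap samples.
#' @param emg_rate sEMG sampling rate (Hz); integer multiple of `mocap_rate`.
#' @param mocap_rate Kinematics/kinetics sampling rate (Hz).
#' @param muscles Muscle channel names.
#' @param n_harmonics Harmonics in each joint-angle Fourier series.
#' @param angle_mean_deg Named mean angle per joint (degrees).
#' @param angle_amp_deg Named list of c(min, max) peak-excursion ranges per
#'   joint (degrees); the harmonic amplitudes are drawn so the total excursion
#'   about the mean never exceeds the drawn bound.
#' @param snr sEMG amplitude signal-to-noise ratio (> 0).
#' @param subject_jitter Relative jitter applied to the link-chain segment
#'   parameters per subject (e.g. 0.1 = +/-10 %).
#' @param seed Master seed; per-subject seeds are derived as `seed + subject`.
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(n_subjects = 4L,
                        cycles_per_subject = 5L,
                        cycle_period = 1.1,
                        emg_rate = 2000,
                        mocap_rate = 100,
                        muscles = c("GMX", "RF", "BF", "TA", "GC"),
                        n_harmonics = 4L,
                        angle_mean_deg = c(hip = 0, knee = 30, ankle = 0),
                        angle_amp_deg = list(hip = c(15, 25),
                                             knee = c(20, 30),
                                             ankle = c(8, 15)),
                        snr = 40,
                        subject_jitter = 0.10,
                        seed = 42L) {
  if (cycles_per_subject < 2L) stop("need at least 2 cycles", call. = FALSE)
  if (cycle_period <= 0) stop("cycle period must be positive", call. = FALSE)
  if (emg_rate %% mocap_rate != 0) {
    stop("emg_rate must be an integer multiple of mocap_rate", call. = FALSE)
  }
  spc <- cycle_period * mocap_rate
  if (abs(spc - round(spc)) > 1e-9) {
    stop("cycle_period must be a whole number of mocap samples", call. = FALSE)
  }
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  if (n_harmonics < 1L) stop("need at least one harmonic", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         cycles_per_subject = as.integer(cycles_per_subject),
         cycle_period = cycle_period, emg_rate = emg_rate,
         mocap_rate = mocap_rate, muscles = muscles,
         n_harmonics = as.integer(n_harmonics),
         angle_mean_deg = angle_mean_deg, angle_amp_deg = angle_amp_deg,
         snr = snr, subject_jitter = subject_jitter, seed = as.integer(seed)),
    class = "gait_config"
  )
}

#' @export
print.gait_config <- function(x, ...) {
  cat("Synthetic gait configuration\n")
  cat(sprintf("  %d subjects x %d cycles, period %.3f s\n",
              x$n_subjects, x$cycles_per_subject, x$cycle_period))
  cat(sprintf("  sEMG %g Hz (%s), mocap %g Hz, SNR %g, seed %d\n",
              x$emg_rate, paste(x$muscles, collapse = ", "),
              x$mocap_rate, x$snr, x$seed))
  invisible(x)
}

joint_names <- function() c("hip", "knee", "ankle")

#' Periodic joint-angle trajectories with analytic derivatives
#'
#' Each joint angle is a truncated harmonic series
#' `q(t) = mean + sum_k A_k sin(2 pi k t / T + phi_k)` with per-subject random
#' amplitudes and phases drawn inside the configured physiological excursion
#' bounds; angular velocity and acceleration are the exact analytic
#' derivatives. The trajectory is exactly periodic with the cycle period, and
#' `sum |A_k|` never exceeds the drawn excursion bound, so the angle range
#' stays inside the configured limits.
#'
#' @param config A [gait_config()].
#' @param subject_seed Seed for this subject's random draw.
#' @return A list with `time` (s), matrices `q`, `qd`, `qdd`
#'   (rows = 100 Hz samples over all cycles, half-open grid; columns = hip,
#'   knee, ankle; radians), `period` and `samples_per_cycle`.
#' @export
generate_kinematics <- function(config, subject_seed) {
  stopifnot(inherits(config, "gait_config"))
  T_cyc <- config$cycle_period
  K <- config$n_harmonics
  spc <- as.integer(round(T_cyc * config$mocap_rate))
  n <- spc * config$cycles_per_subject
  tt <- (0:(n - 1)) / config$mocap_rate
  nj <- length(joint_names())
  q <- qd <- qdd <- matrix(0, n, nj, dimnames = list(NULL, joint_names()))
  coefs <- with_seed(subject_seed, {
    lapply(joint_names(), function(j) {
      rng <- config$angle_amp_deg[[j]]
      bound <- stats::runif(1, rng[1], rng[2]) * pi / 180
      w <- (1 / (1:K)^2) * stats::runif(K, 0.5, 1)
      list(mean = config$angle_mean_deg[[j]] * pi / 180,
           amp = bound * w / sum(w),
           phase = stats::runif(K, 0, 2 * pi))
    })
  })
  for (jj in seq_len(nj)) {
    cf <- coefs[[jj]]
    q[, jj] <- cf$mean
    for (k in seq_len(K)) {
      om <- 2 * pi * k / T_cyc
      arg <- om * tt + cf$phase[k]
      q[, jj]   <- q[, jj]   + cf$amp[k] * sin(arg)
      qd[, jj]  <- qd[, jj]  + cf$amp[k] * om * cos(arg)
      qdd[, jj] <- qdd[, jj] - cf$amp[k] * om^2 * sin(arg)
    }
  }
  list(time = tt, q = q, qd = qd, qdd = qdd, period = T_cyc,
       samples_per_cycle = spc, coefficients = coefs)
}

# Muscle model table: which joint each channel acts on, its torque sign
# (flexion-positive convention; extensors fire for negative torque) and the
# centre/width of its gait-phase activation burst (phase 0 = left toe-off).
muscle_table <- function() {
  data.frame(
    muscle = c("GMX", "RF", "BF", "TA", "GC"),
    joint  = c("hip", "hip", "knee", "ankle", "ankle"),
    sign   = c(-1, 1, 1, 1, -1),
    burst_center = c(0.60, 0.10, 0.45, 0.05, 0.80),
    burst_width  = c(0.10, 0.08, 0.10, 0.08, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Muscle activation envelopes from joint torque and gait phase
#'
#' Builds a normalized per-muscle activation in [0, 1] as a mixture of (a) the
#' rectified torque of the muscle's joint with a muscle-specific sign (flexor
#' vs extensor under the flexion-positive convention) and (b) a Gaussian burst
#' at a muscle-specific gait phase. This coupling is what makes the synthetic
#' sEMG informative about torque.
#'
#' @param torques Matrix of joint torques on the 100 Hz grid (columns hip,
#'   knee, ankle).
#' @param phase Gait phase in [0, 1) per row of `torques`.
#' @param muscles Muscle names; must appear in the built-in muscle table.
#' @param torque_weight,burst_weight Nonnegative mixture weights of the two
#'   components.
#' @return Matrix (rows = time, columns = muscles) with values in [0, 1].
#'   Attribute `torque_component` holds the rectified signed torque per muscle
#'   (N m, linear in the input torque, before weighting and normalization);
#'   attribute `burst_component` the unit-height phase bursts.
#' @export
activation_envelopes <- function(torques, phase, muscles,
                                 torque_weight = 0.6, burst_weight = 0.4) {
  tab <- muscle_table()
  unknown <- setdiff(muscles, tab$muscle)
  if (length(unknown) > 0) {
    stop("unknown muscle name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  torques <- as.matrix(torques)
  stopifnot(nrow(torques) == length(phase))
  env <- tq <- bu <- matrix(0, nrow(torques), length(muscles),
                            dimnames = list(NULL, muscles))
  for (m in seq_along(muscles)) {
    row <- tab[tab$muscle == muscles[m], ]
    tau <- torques[, row$joint]
    tq[, m] <- pmax(row$sign * tau, 0)
    d <- abs(phase - row$burst_center)
    d <- pmin(d, 1 - d)                       # wrap-around phase distance
    bu[, m] <- exp(-d^2 / (2 * row$burst_width^2))
    tqn <- if (max(tq[, m]) > 0) tq[, m] / max(tq[, m]) else tq[, m]
    raw <- torque_weight * tqn + burst_weight * bu[, m]
    env[, m] <- if (max(raw) > 0) raw / max(raw) else raw
  }
  attr(env, "torque_component") <- tq
  attr(env, "burst_component") <- bu
  env
}

#' Synthesize sEMG channels from activation envelopes
#'
#' Each channel is an activation-modulated band-limited noise process: the
#' 100 Hz envelope is upsampled to the sEMG rate and multiplied by a zero-mean
#' Gaussian carrier band-limited to 20-450 Hz (unit variance), then additive
#' baseline noise with standard deviation `amplitude / snr` is added. The
#' carrier is a variance-preserving mixture of a low (20-80 Hz) and a high
#' (250-450 Hz) sub-band whose balance shifts towards the high band with
#' activation, a stylized version of the upward spectral shift of real sEMG
#' under motor unit recruitment; this is what makes the spectral window
#' features (ZC, MNF, MDF) informative about activation, not just the
#' amplitude features. Output is deterministic given the seed.
#'
#' @param envelopes Matrix of per-muscle activations in [0, 1] on the 100 Hz
#'   grid (columns named by muscle).
#' @param config A [gait_config()] (rates and SNR).
#' @param seed Integer seed.
#' @param amplitude Full-activation sEMG scale (mV).
#' @param spectral_shift Fraction of carrier variance moved from the low to
#'   the high sub-band as activation goes 0 to 1 (0 disables the shift).
#' @return Matrix (rows = sEMG samples at `emg_rate`, columns = muscles), with
#'   `nrow = nrow(envelopes) * emg_rate / mocap_rate`.
#' @export
synthesize_emg <- function(envelopes, config, seed, amplitude = 0.5,
                           spectral_shift = 0.9) {
  stopifnot(inherits(config, "gait_config"))
  if (config$snr <= 0) stop("snr must be positive", call. = FALSE)
  stopifnot(spectral_shift >= 0, spectral_shift <= 0.95)
  envelopes <- as.matrix(envelopes)
  ratio <- config$emg_rate / config$mocap_rate
  n_emg <- nrow(envelopes) * ratio
  t_mocap <- (seq_len(nrow(envelopes)) - 1) / config$mocap_rate
  t_emg <- (seq_len(n_emg) - 1) / config$emg_rate
  nyq <- config$emg_rate / 2
  bf_lo <- signal::butter(4, c(20, 80) / nyq, type = "pass")
  bf_hi <- signal::butter(4, c(250, 450) / nyq, type = "pass")
  with_seed(seed, {
    out <- matrix(0, n_emg, ncol(envelopes),
                  dimnames = list(NULL, colnames(envelopes)))
    for (m in seq_len(ncol(envelopes))) {
      env_up <- stats::approx(t_mocap, envelopes[, m], xout = t_emg,
                              rule = 2)$y
      lo <- signal::filtfilt(bf_lo, stats::rnorm(n_emg))
      hi <- signal::filtfilt(bf_hi, stats::rnorm(n_emg))
      lo <- lo / stats::sd(lo)
      hi <- hi / stats::sd(hi)
      a <- 0.05 + spectral_shift * env_up   # high-band variance share
      carrier <- sqrt(1 - a) * lo + sqrt(a) * hi
      out[, m] <- amplitude * env_up * carrier +
        stats::rnorm(n_emg, sd = amplitude / config$snr)
    }
    out
  })
}

#' One synthetic gait trial
#'
#' Generates a complete trial for one subject: periodic kinematics, torques by
#' inverse dynamics of the (per-subject jittered) planar leg chain, activation
#' envelopes and sEMG. The torque ground truth is that of a swing-limb chain
#' without ground reaction forces; it is dynamically consistent, which is all
#' the downstream learners require.
#'
#' @param config A [gait_config()].
#' @param subject Subject index (1-based).
#' @param chain Base [link_chain_params()]; defaults to [default_leg_params()].
#' @return An object of class `gait_trial`: list with `subject`, `emg_time`,
#'   `emg` (n x muscles, 2000 Hz), `time` (100 Hz), `angles` (T x 3, rad),
#'   `torques` (T x 3, N m), `boundaries` (0-based cycle start indices on the
#'   100 Hz grid, including the end index) and `config`.
#' @export
simulate_gait_trial <- function(config, subject, chain = default_leg_params()) {
  stopifnot(inherits(config, "gait_config"))
  subject_seed <- config$seed + subject
  chain_s <- with_seed(subject_seed * 7L + 1L, jitter_chain(chain, config$subject_jitter))
  kin <- generate_kinematics(config, subject_seed)
  tau <- inverse_dynamics(kin, chain_s)
  colnames(tau) <- joint_names()
  spc <- kin$samples_per_cycle
  phase <- ((seq_len(nrow(tau)) - 1) %% spc) / spc
  env <- activation_envelopes(tau, phase, config$muscles)
  emg <- synthesize_emg(env, config, seed = subject_seed * 11L + 3L)
  trial <- structure(
    list(subject = subject,
         emg_time = (seq_len(nrow(emg)) - 1) / config$emg_rate,
         emg = emg,
         time = kin$time, angles = kin$q, torques = tau,
         boundaries = seq(0L, nrow(tau), by = spc),
         config = config, chain = chain_s),
    class = "gait_trial"
  )
  validate_gait_trial(trial)
  trial
}

jitter_chain <- function(chain, jitter) {
  f <- function(x) x * stats::runif(length(x), 1 - jitter, 1 + jitter)
  link_chain_params(
    masses = f(chain$masses),
    lengths = chain$lengths * (s <- stats::runif(chain$n_links, 1 - jitter, 1 + jitter)),
    com = chain$com * s,                 # keep com <= length under jitter
    inertia = f(chain$inertia),
    gravity = chain$gravity
  )
}

#' Validate a gait trial's structural invariants
#'
#' Checks the rate contract (sEMG rows = angle rows x rate ratio), strictly
#' increasing cycle boundaries, and the configured number of complete cycles.
#'
#' @param trial A `gait_trial`.
#' @return The trial, invisibly; errors if an invariant fails.
#' @export
validate_gait_trial <- function(trial) {
  cfg <- trial$config
  ratio <- cfg$emg_rate / cfg$mocap_rate
  if (nrow(trial$emg) != nrow(trial$angles) * ratio) {
    stop("sEMG length must be angle length x rate ratio", call. = FALSE)
  }
  if (nrow(trial$torques) != nrow(trial$angles)) {
    stop("torques and angles must share the 100 Hz grid", call. = FALSE)
  }
  b <- trial$boundaries
  if (any(diff(b) <= 0)) stop("cycle boundaries must be strictly increasing",
                              call. = FALSE)
  if (length(b) != cfg$cycles_per_subject + 1L) {
    stop("expected ", cfg$cycles_per_subject, " complete cycles", call. = FALSE)
  }
  if (b[length(b)] != nrow(trial$angles)) {
    stop("last boundary must be the trial end", call. = FALSE)
  }
  invisible(trial)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("Gait trial, subject %d: %d cycles, %d mocap samples, %d sEMG samples\n",
              x$subject, length(x$boundaries) - 1L, nrow(x$angles), nrow(x$emg)))
  invisible(x)
}

#' Generate the full synthetic dataset (and optionally write CSV files)
#'
#' One trial per subject. With `dir` set, writes per-trial CSV files
#' (`sub<k>_emg.csv`, `sub<k>_mocap.csv`, `sub<k>_cycles.csv`) plus a
#' `manifest.yaml` recording the configuration and seeds, from which the
#' dataset can be regenerated identically.
#'
#' @param config A [gait_config()].
#' @param dir Output directory, or `NULL` for in-memory only.
#' @param chain Base link chain; see [simulate_gait_trial()].
#' @return List of `gait_trial` objects, invisibly if written to disk.
#' @export
make_gait_dataset <- function(config = gait_config(), dir = NULL,
                              chain = default_leg_params()) {
  trials <- lapply(seq_len(config$n_subjects), function(k) {
    simulate_gait_trial(config, k, chain)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (tr in trials) write_gait_trial(tr, dir)
    manifest <- list(
      config = unclass(config),
      subject_seeds = config$seed + seq_len(config$n_subjects),
      chain = unclass(chain)
    )
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    return(invisible(trials))
  }
  trials
}

write_gait_trial <- function(trial, dir) {
  k <- trial$subject
  emg <- data.frame(time_s = trial$emg_time, trial$emg, check.names = FALSE)
  utils::write.csv(emg, file.path(dir, sprintf("sub%d_emg.csv", k)),
                   row.names = FALSE)
  mocap <- data.frame(time_s = trial$time,
                      hip_rad = trial$angles[, "hip"],
                      knee_rad = trial$angles[, "knee"],
                      ankle_rad = trial$angles[, "ankle"],
                      hip_Nm = trial$torques[, "hip"],
                      knee_Nm = trial$torques[, "knee"],
                      ankle_Nm = trial$torques[, "ankle"])
  utils::write.csv(mocap, file.path(dir, sprintf("sub%d_mocap.csv", k)),
                   row.names = FALSE)
  utils::write.csv(data.frame(start_index = trial$boundaries),
                   file.path(dir, sprintf("sub%d_cycles.csv", k)),
                   row.names = FALSE)
  invisible(trial)
}

#' Read a gait trial written by [make_gait_dataset()]
#'
#' Also accepts any external recording exported in the same CSV dialect, so
#' real sEMG/angle/torque exports can enter the pipeline in place of the
#' generator.
#'
#' @param dir Directory containing the CSV files.
#' @param subject Subject index `k` in the file names.
#' @param config A [gait_config()] describing the rates; defaults to the
#'   manifest's config when present.
#' @return A `gait_trial`.
#' @export
read_gait_trial <- function(dir, subject, config = NULL) {
  if (is.null(config)) {
    mf <- file.path(dir, "manifest.yaml")
    if (!file.exists(mf)) stop("no config given and no manifest found",
                               call. = FALSE)
    config <- do.call(gait_config, yaml::read_yaml(mf)$config)
  }
  emg_df <- utils::read.csv(file.path(dir, sprintf("sub%d_emg.csv", subject)),
                            check.names = FALSE)
  mocap <- utils::read.csv(file.path(dir, sprintf("sub%d_mocap.csv", subject)))
  cyc <- utils::read.csv(file.path(dir, sprintf("sub%d_cycles.csv", subject)))
  angles <- as.matrix(mocap[, c("hip_rad", "knee_rad", "ankle_rad")])
  torques <- as.matrix(mocap[, c("hip_Nm", "knee_Nm", "ankle_Nm")])
  colnames(angles) <- colnames(torques) <- joint_names()
  trial <- structure(
    list(subject = subject,
         emg_time = emg_df$time_s,
         emg = as.matrix(emg_df[, setdiff(names(emg_df), "time_s")]),
         time = mocap$time_s, angles = angles, torques = torques,
         boundaries = as.integer(cyc$start_index),
         config = config),
    class = "gait_trial"
  )
  validate_gait_trial(trial)
  trial
}
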