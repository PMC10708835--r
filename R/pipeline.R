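#' Configuration of a full pipeline run
#'
#' Bundles the generator, preprocessing and model settings for
#' [run_pipeline()]. Defaults reproduce the packaged study conditions: four
#' subjects, five gait cycles, a 4-train/1-test cycle split, one LSTM and one
#' GPR per subject and joint.
#'
#' @param gait A [gait_config()].
#' @param window A [window_spec()].
#' @param filter_low,filter_high,filter_order Band-pass settings for the raw
#'   sEMG.
#' @param time_step LSTM sequence length (rows of the 100 Hz grid).
#' @param horizon Prediction horizon in rows (1 = 10 ms ahead).
#' @param hidden LSTM layer sizes.
#' @param epochs,lr,lr_drop_factor,lr_drop_period,clip LSTM training regime;
#'   see [lstm_train()].
#' @param lstm_restarts Candidate LSTM initializations per model; see
#'   [lstm_train()].
#' @param gpr_restarts Optimizer starts per GPR fit.
#' @param test_cycle Held-out cycle number, or `NULL` for the last cycle.
#' @param seed Master seed for model initialization and optimizer restarts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(gait = gait_config(), window = window_spec(),
                       filter_low = 20, filter_high = 450, filter_order = 4,
                       time_step = 5L, horizon = 1L,
                       hidden = c(32L, 16L, 8L), epochs = 500L, lr = 0.005,
                       lr_drop_factor = 0.2, lr_drop_period = 125L, clip = 1,
                       lstm_restarts = 3L, gpr_restarts = 5L,
                       test_cycle = NULL, seed = 7L) {
  stopifnot(inherits(gait, "gait_config"), inherits(window, "window_spec"),
            time_step >= 1L, horizon >= 1L, epochs >= 1L, lr > 0)
  structure(
    list(gait = gait, window = window, filter_low = filter_low,
         filter_high = filter_high, filter_order = filter_order,
         time_step = as.integer(time_step), horizon = as.integer(horizon),
         hidden = as.integer(hidden), epochs = as.integer(epochs), lr = lr,
         lr_drop_factor = lr_drop_factor,
         lr_drop_period = as.integer(lr_drop_period), clip = clip,
         lstm_restarts = as.integer(lstm_restarts),
         gpr_restarts = as.integer(gpr_restarts), test_cycle = test_cycle,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline run configuration\n")
  print(x$gait)
  cat(sprintf("  LSTM [%s], %d epochs, lr %g (x%g every %d), clip %g\n",
              paste(x$hidden, collapse = ", "), x$epochs, x$lr,
              x$lr_drop_factor, x$lr_drop_period, x$clip))
  cat(sprintf("  GPR: exponential kernel, %d restarts; horizon %d row(s); seed %d\n",
              x$gpr_restarts, x$horizon, x$seed))
  invisible(x)
}

# Feature matrix + aligned torque + cycle labels for one trial.
prepare_trial <- function(trial, config) {
  feats <- trial_features(trial, config$filter_low, config$filter_high,
                          config$filter_order, config$window)
  fm <- assemble_inputs(feats, trial$angles, trial$time,
                        muscles = trial$config$muscles)
  ridx <- match(round(fm$time * 1e6), round(trial$time * 1e6))
  stopifnot(!anyNA(ridx))
  torque <- trial$torques[ridx, , drop = FALSE]
  cyc_all <- row_cycles(nrow(trial$angles), trial$boundaries)
  list(fm = fm, torque = torque, cycles = cyc_all[ridx])
}

#' Run the full prediction pipeline
#'
#' Generates (or accepts) the gait trials, extracts and assembles the
#' 38-dimensional inputs, peak-normalizes on training rows only, then for
#' every subject and joint trains one LSTM on 5-step sequences and one
#' exponential-kernel GPR on one-step inputs, evaluates both on the held-out
#' gait cycle, and reports NRMSE, Pearson R and R-squared. With 4 subjects
#' and 3 joints this yields 12 LSTM and 12 GPR models.
#'
#' @param config A [run_config()].
#' @param trials Optional list of `gait_trial` objects (defaults to
#'   [make_gait_dataset()] under `config$gait`).
#' @param out_dir Optional directory; when set, metrics, traces, loss curves
#'   and the configuration are written as CSV/YAML.
#' @param verbose Print per-stage progress?
#' @return An object of class `run_report`: `metrics` (with per-joint average
#'   rows), `traces` (held-out-cycle true/predicted torque, with the GPR 95 %
#'   observation band), `loss` (LSTM loss histories), and `config`.
#' @export
run_pipeline <- function(config = run_config(), trials = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(trials)) trials <- make_gait_dataset(config$gait)
  say <- function(...) if (verbose) message(sprintf(...))
  metrics <- list(); traces <- list(); losses <- list()
  for (trial in trials) {
    sub <- trial$subject
    say("subject %d: preprocessing", sub)
    prep <- prepare_trial(trial, config)
    cyc <- prep$cycles
    test_cycle <- config$test_cycle %||% max(cyc)
    train_rows <- which(cyc != test_cycle)
    norm_x <- normalize_columns(prep$fm$values, reference = train_rows)
    norm_tau <- normalize_columns(prep$torque, reference = train_rows)
    for (j in joint_names()) {
      jj <- match(j, joint_names())
      target <- norm_tau$values[, j]
      model_seed <- config$seed + 100L * sub + jj
      # LSTM on 5-step sequences
      seq_set <- make_sequences(norm_x$values, target, config$time_step,
                                config$horizon)
      seq_split <- split_cycles(seq_set, cyc, test_cycle)
      say("subject %d, %s: LSTM (%d train samples)", sub, j,
          length(seq_split$train))
      fit <- lstm_train(subset_supervised(seq_set, seq_split$train),
                        hidden = config$hidden, epochs = config$epochs,
                        lr = config$lr, lr_drop_factor = config$lr_drop_factor,
                        lr_drop_period = config$lr_drop_period,
                        clip = config$clip, seed = model_seed,
                        restarts = config$lstm_restarts)
      seq_test <- subset_supervised(seq_set, seq_split$test)
      pred_lstm <- lstm_predict(fit$net, seq_test)
      # GPR on one-step inputs
      pw_set <- make_pointwise(norm_x$values, target, config$horizon)
      pw_split <- split_cycles(pw_set, cyc, test_cycle)
      say("subject %d, %s: GPR (%d train samples)", sub, j,
          length(pw_split$train))
      pw_train <- subset_supervised(pw_set, pw_split$train)
      gpr <- gpr_fit(pw_train$x, pw_train$y, restarts = config$gpr_restarts,
                     seed = model_seed)
      pw_test <- subset_supervised(pw_set, pw_split$test)
      pred_gpr <- gpr_predict(gpr, pw_test$x)
      metrics[[length(metrics) + 1L]] <- data.frame(
        subject = rep(as.character(sub), 2), joint = rep(j, 2),
        model = c("lstm", "gpr"),
        nrmse = c(nrmse(seq_test$y, pred_lstm),
                  nrmse(pw_test$y, pred_gpr$mean)),
        r = c(pearson_r(seq_test$y, pred_lstm),
              pearson_r(pw_test$y, pred_gpr$mean)),
        r2 = c(r_squared(seq_test$y, pred_lstm),
               r_squared(pw_test$y, pred_gpr$mean)))
      tau_const <- norm_tau$constants[j]
      traces[[length(traces) + 1L]] <- rbind(
        data.frame(subject = sub, joint = j, model = "lstm",
                   time = prep$fm$time[seq_test$target_row],
                   true = seq_test$y * tau_const,
                   pred = pred_lstm * tau_const,
                   lower = NA_real_, upper = NA_real_),
        data.frame(subject = sub, joint = j, model = "gpr",
                   time = prep$fm$time[pw_test$target_row],
                   true = pw_test$y * tau_const,
                   pred = pred_gpr$mean * tau_const,
                   lower = pred_gpr$lower * tau_const,
                   upper = pred_gpr$upper * tau_const))
      losses[[paste(sub, j, sep = "_")]] <- fit$loss
    }
  }
  report <- structure(
    list(metrics = metrics_table(do.call(rbind, metrics)),
         traces = do.call(rbind, traces),
         loss = losses, config = config),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  avg <- x$metrics[x$metrics$subject == "average", ]
  print(avg, row.names = FALSE, digits = 4)
  invisible(x)
}

write_run_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$traces, file.path(out_dir, "traces.csv"),
                   row.names = FALSE)
  loss_df <- do.call(rbind, lapply(names(report$loss), function(nm) {
    data.frame(model = nm, epoch = seq_along(report$loss[[nm]]),
               loss = report$loss[[nm]])
  }))
  utils::write.csv(loss_df, file.path(out_dir, "lstm_loss.csv"),
                   row.names = FALSE)
  cfg <- report$config
  yaml::write_yaml(list(gait = unclass(cfg$gait),
                        window = unclass(cfg$window),
                        run = unclass(cfg)[setdiff(names(unclass(cfg)),
                                                   c("gait", "window"))]),
                   file.path(out_dir, "config.yaml"))
  invisible(report)
}

#' Plot held-out-cycle predictions
#'
#' One panel per joint and model: measured torque, predicted torque, and for
#' the GPR the shaded 95 % observation interval around the predictive mean.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param subject Subject to plot (default first).
#' @param dir Optional directory to save one PNG per joint x model.
#' @return Named list of ggplot objects, invisibly when saved.
#' @export
plot_predictions <- function(report, subject = NULL, dir = NULL) {
  tr <- report$traces
  subject <- subject %||% tr$subject[1]
  tr <- tr[tr$subject == subject, ]
  if (nrow(tr) == 0) stop("no traces for subject ", subject, call. = FALSE)
  plots <- list()
  for (j in unique(tr$joint)) for (mod in unique(tr$model)) {
    d <- tr[tr$joint == j & tr$model == mod, ]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time))
    if (mod == "gpr") {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
        fill = "steelblue", alpha = 0.25)
    }
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$true), linewidth = 0.6) +
      ggplot2::geom_line(ggplot2::aes(y = .data$pred), colour = "steelblue",
                         linewidth = 0.6, linetype = "dashed") +
      ggplot2::labs(title = sprintf("Subject %s, %s torque (%s)",
                                    subject, j, toupper(mod)),
                    x = "time (s)", y = "torque (N m)") +
      ggplot2::theme_minimal()
    nm <- paste(mod, j, sep = "_")
    plots[[nm]] <- p
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), p,
                      width = 7, height = 4, dpi = 150)
    }
  }
  if (is.null(dir)) plots else invisible(plots)
}
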