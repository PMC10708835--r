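# Shared fixtures. Everything is generated in code; the default-scale pipeline
# run used by the acceptance tests is computed once per session and cached.

tiny_gait_config <- function(...) {
  args <- list(n_subjects = 1L, cycles_per_subject = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gait_config, args)
}

small_run_config <- function(...) {
  run_config(gait = gait_config(n_subjects = 2L, cycles_per_subject = 3L),
             epochs = 20L, gpr_restarts = 2L, ...)
}

# One-link pendulum chain for analytic dynamics checks.
pendulum_params <- function(m = 2, L = 0.5, r = 0.3, I = 0.04, g = 9.81) {
  link_chain_params(masses = m, lengths = L, com = r, inertia = I, gravity = g)
}

random_window <- function(n, rng) {
  stats::rnorm(n, mean = rng[1], sd = rng[2])
}

.fixture_cache <- new.env(parent = emptyenv())

# Full default-conditions pipeline run (4 subjects x 5 cycles, packaged
# seeds), shared across acceptance tests.
default_pipeline_report <- function() {
  if (is.null(.fixture_cache$report)) {
    .fixture_cache$report <- run_pipeline(run_config())
  }
  .fixture_cache$report
}

# Reduced-scale run shared by the orchestration tests.
small_pipeline_report <- function() {
  if (is.null(.fixture_cache$small_report)) {
    .fixture_cache$small_report <- run_pipeline(small_run_config())
  }
  .fixture_cache$small_report
}
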