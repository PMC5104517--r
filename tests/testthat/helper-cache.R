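# Session-level cache so that expensive simulated experiments are computed
# once and shared between test files (testthat runs all files in one
# process). Keys are fully explicit: condition, duration, seed, scale.

.sc_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sc_test_cache))
    assign(key, force(expr), envir = .sc_test_cache)
  get(key, envir = .sc_test_cache)
}

# Ground-truth-only run at the default movie scale (0.43 mm^2, 24 h).
gt_run <- function(cond, seed) {
  cached(paste0("gt_", cond, "_", seed),
         simulate_timelapse(cond, duration_h = 24, seed = seed))
}

# Full rendered pipeline at the default movie scale; used by the acceptance
# baselines (three seeds).
pipeline_run <- function(seed) {
  cached(paste0("pipe_", seed),
         analyze_timelapse("control", duration_h = 24, seed = seed))
}

acceptance_seeds <- c(101L, 102L, 103L)
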