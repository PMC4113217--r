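# Shared fixtures, built in code and memoised per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# A light session: few channels so decoder unit tests stay fast; the
# 31-channel dimensionality checks build their own epochs.
small_template <- function(amplitude = 0.35, channels = 8) {
  erp_template(channels = amuse_channels()[seq_len(channels)],
               difference_amplitude = amplitude)
}

small_session <- function(seed = 1, n_trials = 8, amplitude = 0.35,
                          channels = 8, n_blocks = 1) {
  generate_session(small_template(amplitude, channels), noise_model(),
                   n_blocks = n_blocks, trials_per_block = n_trials,
                   seed = seed)
}

small_features <- function(seed = 1, n_trials = 8, amplitude = 0.35,
                           channels = 8) {
  key <- sprintf("feat-%d-%d-%g-%d", seed, n_trials, amplitude, channels)
  fixture(key, function() {
    preprocess_session(small_session(seed, n_trials, amplitude, channels),
                       blocks = 1)
  })
}

# Run one unsupervised online block over precomputed features; returns
# predictions, truth and the final pool.
run_online_block <- function(fm, pool_seed = 1, config = bci_config()) {
  trial <- attr(fm, "trial"); stim <- attr(fm, "stimulus")
  truth <- attr(fm, "attended")
  pool <- init_pool(ncol(fm), config$n_pairs, seed = pool_seed,
                    config = config)
  n <- max(trial)
  pred <- integer(n)
  for (ti in seq_len(n)) {
    idx <- which(trial == ti)
    r <- online_step(pool, fm[idx, , drop = FALSE], stim[idx])
    pool <- r$pool
    pred[ti] <- r$prediction
  }
  list(pred = pred, truth = truth, pool = pool)
}

# Independent ridge-regression oracle: plain normal equations, rows = epochs.
ridge_oracle <- function(X, y, k) {
  d <- ncol(X)
  solve(t(X) %*% X + diag(k, d), t(X) %*% y)[, 1]
}
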