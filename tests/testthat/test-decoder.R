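test_that("pool initialization draws sign-flipped pairs with stated precisions", {
  pool <- init_pool(20, n_pairs = 5, seed = 3)
  expect_length(pool$states, 10)
  for (p in 1:5) {
    a <- pool$states[[2 * p - 1]]; b <- pool$states[[2 * p]]
    expect_equal(a$w + b$w, rep(0, 20))
    expect_equal(a$lambda, 1)
    expect_equal(a$beta, 100)
  }
  # deterministic given seed
  pool2 <- init_pool(20, n_pairs = 5, seed = 3)
  expect_identical(pool, pool2)
  expect_error(init_pool(1), "dim")
})

test_that("posterior inference matches a direct density-product oracle", {
  # zero weights: all projections equal -> uniform posterior
  st <- decoder_state(rep(0, 4))
  Ftr <- matrix(rnorm(24), 6, 4)
  post <- infer_attended(st, Ftr, stimulus = rep(1:3, 2), K = 3)
  expect_equal(as.numeric(post), rep(1 / 3, 3))

  # K = 2 toy with hand-set parameters: brute-force product of Gaussian
  # densities over both hypotheses
  set.seed(11)
  w <- c(0.7, -0.3, 0.2)
  lambda <- 2.3
  X <- matrix(rnorm(12), 4, 3)          # 4 epochs (J = 2 per stimulus)
  stim <- c(1L, 2L, 1L, 2L)
  st2 <- decoder_state(w, lambda = lambda, mu_target = 1, mu_nontarget = -1)
  post2 <- infer_attended(st2, X, stim, K = 2)
  proj <- as.numeric(X %*% w)
  dens <- function(c_hyp) {
    mu <- ifelse(stim == c_hyp, 1, -1)
    prod(dnorm(proj, mean = mu, sd = 1 / sqrt(lambda)))
  }
  oracle <- c(dens(1), dens(2)) / (dens(1) + dens(2))
  expect_equal(as.numeric(post2), oracle, tolerance = 1e-10)
  # the marginal matches the log of the prior-weighted density sum
  expect_equal(attr(post2, "logml"), log(0.5 * (dens(1) + dens(2))),
               tolerance = 1e-10)

  # normalization holds for random states and trials
  for (s in 1:5) {
    set.seed(s)
    stx <- decoder_state(rnorm(5), lambda = runif(1, 0.5, 3))
    px <- infer_attended(stx, matrix(rnorm(60), 12, 5),
                         rep(1:6, 2), K = 6)
    expect_equal(sum(px), 1)
  }
  expect_error(infer_attended(st, matrix(0, 0, 4), integer(0)), "no feature")
})

test_that("the E-step applies inference to every stored trial independently", {
  fm <- small_features(seed = 2, n_trials = 4)
  st <- decoder_state(rnorm(ncol(fm), sd = 0.05))
  P <- e_step(st, fm, K = 6)
  expect_equal(dim(P), c(4, 6))
  expect_equal(rowSums(P), rep(1, 4))
  # single trial equals infer_attended
  idx <- which(attr(fm, "trial") == 2)
  p1 <- infer_attended(st, fm[idx, , drop = FALSE],
                       attr(fm, "stimulus")[idx], K = 6)
  expect_equal(P[2, ], as.numeric(p1), tolerance = 1e-12)
  # reordering trials permutes rows only
  ord <- c(3L, 1L, 4L, 2L)
  perm <- order(match(attr(fm, "trial"), ord))
  fmp <- feature_matrix(as.matrix(fm)[perm, ],
                        stimulus = attr(fm, "stimulus")[perm],
                        trial = attr(fm, "trial")[perm])
  Pp <- e_step(st, fmp, K = 6)
  expect_equal(Pp, P[ord, ], tolerance = 1e-12, ignore_attr = TRUE)
  # near-infinite precision on a separable toy gives one-hot posteriors
  Xs <- rbind(c(1, 0), c(-1, 0), c(1, 0), c(-1, 0))
  fms <- feature_matrix(Xs, stimulus = c(1L, 2L, 1L, 2L),
                        trial = rep(1L, 4))
  sts <- decoder_state(c(1, 0), lambda = 1e6)
  Ps <- e_step(sts, fms, K = 2)
  expect_equal(as.numeric(Ps), c(1, 0), tolerance = 1e-10)
})

test_that("the weight update is the posterior-weighted ridge solution", {
  set.seed(21)
  # 2 trials, K = 2, J = 2, D = 3 (bias folded into the columns)
  X <- matrix(rnorm(8 * 3), 8, 3)
  stim <- rep(c(1L, 2L, 1L, 2L), 2)
  trial <- rep(1:2, each = 4)
  fm <- feature_matrix(X, stimulus = stim, trial = trial)
  lambda <- 1.7; beta <- 5

  # one-hot posteriors = ridge regression on the implied hard labels
  P1 <- rbind(c(1, 0), c(0, 1))
  w <- m_step_weights(fm, P1, lambda, beta)
  # trial 1 attends stimulus 1, trial 2 attends stimulus 2
  y <- ifelse((trial == 1 & stim == 1) | (trial == 2 & stim == 2), 1, -1)
  expect_equal(w, ridge_oracle(X, y, beta / lambda), tolerance = 1e-8)

  # soft posteriors = posterior-weighted enumeration of all labelings
  P2 <- rbind(c(0.3, 0.7), c(0.9, 0.1))
  w2 <- m_step_weights(fm, P2, lambda, beta)
  oracle <- rep(0, 3)
  for (c1 in 1:2) for (c2 in 1:2) {
    yy <- ifelse(stim == c(c1, c2)[trial], 1, -1)
    oracle <- oracle + P2[1, c1] * P2[2, c2] *
      ridge_oracle(X, yy, beta / lambda)
  }
  expect_equal(w2, oracle, tolerance = 1e-8)

  # strong prior shrinks the weights monotonically toward zero
  norms <- vapply(c(10, 100, 1000, 10000), function(b)
    sqrt(sum(m_step_weights(fm, P2, lambda, b)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("the lambda update inverts the expected MSE with a floor", {
  # 4-epoch hand example: projections and posteriors stated, MSE by hand
  X <- diag(4)                      # projections pick out w entries
  w <- c(0.5, -0.2, 1.4, 0.9)       # projections equal these values
  stim <- c(1L, 2L, 1L, 2L)
  trial <- c(1L, 1L, 2L, 2L)
  fm <- feature_matrix(X, stimulus = stim, trial = trial)
  P <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  # p(target) per epoch: trial 1: P[1,1], P[1,2]; trial 2: P[2,1], P[2,2]
  p <- c(0.8, 0.2, 0.4, 0.6)
  mse_hand <- mean(p * (w - 1)^2 + (1 - p) * (w + 1)^2)
  expect_equal(m_step_lambda(fm, P, w), 1 / mse_hand, tolerance = 1e-12)
  expect_gt(m_step_lambda(fm, P, w), 0)
  # exact fit under one-hot posteriors hits the floor guard
  Xs <- rbind(c(1, 0), c(-1, 0))
  fms <- feature_matrix(Xs, stimulus = c(1L, 2L), trial = c(1L, 1L))
  Ph <- matrix(c(1, 0), 1)
  expect_equal(m_step_lambda(fms, Ph, c(1, 0)), 1e10)
})

test_that("the beta update inverts the mean squared weight and is capped", {
  expect_equal(m_step_beta(c(1, -1, 1, -1)), 1)
  expect_equal(m_step_beta(c(2, 0)), 0.5)
  expect_equal(m_step_beta(rep(1e-6, 10)), 200)
  expect_warning(b0 <- m_step_beta(rep(0, 5)), "zero")
  expect_equal(b0, 200)
})

test_that("em_iterations chains the exported E/M operations exactly", {
  fm <- small_features(seed = 6, n_trials = 3)
  cfg <- bci_config()
  st0 <- init_pool(ncol(fm), n_pairs = 1, seed = 5)$states[[1]]
  fused <- em_iterations(st0, fm, n_iter = 3, config = cfg)
  # manual chain via the granular operations
  st <- st0
  for (it in 1:3) {
    P <- e_step(st, fm, cfg$K)
    st$w <- m_step_weights(fm, P, st$lambda, st$beta)
    st$lambda <- m_step_lambda(fm, P, st$w, floor = cfg$lambda_floor)
    st$beta <- m_step_beta(st$w, cfg$beta_cap)
  }
  expect_equal(fused$w, st$w, tolerance = 1e-10)
  expect_equal(fused$lambda, st$lambda, tolerance = 1e-8)
  expect_equal(fused$beta, st$beta, tolerance = 1e-10)
  # n_iter = 0 leaves the parameters unchanged (likelihood gets evaluated)
  same <- em_iterations(st0, fm, n_iter = 0, config = cfg)
  expect_equal(same$w, st0$w)
  expect_equal(same$lambda, st0$lambda)
  expect_false(is.na(same$log_likelihood))
})

test_that("every EM update increases the penalized likelihood objective", {
  # each update (posterior-weighted ridge for w, inverse expected MSE for
  # lambda, capped inverse mean-square for beta) ascends the objective
  # log p(X | w, lambda) + log N(w | 0, beta^-1 I); a few blocks here, the
  # broader seeded sweep lives in the acceptance suite
  for (s in 1:3) {
    fm <- small_features(seed = s, n_trials = 8)
    st0 <- init_pool(ncol(fm), n_pairs = 1, seed = s)$states[[1]]
    st <- em_iterations(st0, fm, n_iter = 5, trace = TRUE)
    obj <- attr(st, "objective_trace")
    expect_length(obj, 5)
    expect_true(all(diff(obj) >= -1e-6))
    # and the data log-likelihood of the fit beats the random start
    ll0 <- em_iterations(st0, fm, n_iter = 0)$log_likelihood
    expect_gte(st$log_likelihood, ll0)
  }
})

test_that("selection picks the maximal likelihood with documented tie-breaks", {
  pool <- init_pool(6, n_pairs = 2, seed = 1)
  lls <- c(-5, -9, -2, -7)
  for (i in 1:4) pool$states[[i]]$log_likelihood <- lls[i]
  best <- select_best(pool)
  expect_identical(attr(best, "index"), 3L)
  # exact tie: lowest index wins
  for (i in 1:4) pool$states[[i]]$log_likelihood <- -3
  expect_identical(attr(select_best(pool), "index"), 1L)
})

test_that("pair re-initialization keeps the winner and negates the loser", {
  fm <- small_features(seed = 4, n_trials = 3)
  r <- run_online_block(fm, pool_seed = 2)
  pool <- r$pool
  expect_length(pool$states, 10)
  for (p in 1:5) {
    a <- pool$states[[2 * p - 1]]; b <- pool$states[[2 * p]]
    expect_equal(a$w + b$w, rep(0, ncol(fm)), tolerance = 1e-12)
    expect_equal(a$lambda, b$lambda)
    expect_equal(a$beta, b$beta)
  }
  # the kept member is untouched by reinit
  pool2 <- pool
  pool2$states[[1]]$log_likelihood <- 10   # force member 1 to win its pair
  re <- reinit_pairs(pool2)
  expect_equal(re$states[[1]]$w, pool2$states[[1]]$w)
  expect_equal(re$states[[2]]$w, -pool2$states[[1]]$w)
  expect_length(re$states, 10)
})

test_that("online steps append trials and posthoc revisits them", {
  fm <- small_features(seed = 9, n_trials = 4)
  trial <- attr(fm, "trial"); stim <- attr(fm, "stimulus")
  pool <- init_pool(ncol(fm), seed = 1)
  expect_identical(pool$n_trials, 0L)
  idx <- which(trial == 1)
  r1 <- online_step(pool, fm[idx, , drop = FALSE], stim[idx])
  expect_identical(r1$pool$n_trials, 1L)
  # posthoc right after the first step agrees with the online prediction
  expect_identical(posthoc_reanalysis(r1$pool), r1$prediction)
  idx2 <- which(trial == 2)
  r2 <- online_step(r1$pool, fm[idx2, , drop = FALSE], stim[idx2])
  expect_identical(r2$pool$n_trials, 2L)
  expect_length(posthoc_reanalysis(r2$pool), 2)
  expect_error(posthoc_reanalysis(pool), "no stored")
})

test_that("the pipeline is symmetric under weight negation with swapped means", {
  fm <- small_features(seed = 13, n_trials = 6)
  trial <- attr(fm, "trial"); stim <- attr(fm, "stimulus")
  run_pipe <- function(cfg, flip) {
    pool <- init_pool(ncol(fm), seed = 77, config = cfg)
    if (flip) pool$states <- lapply(pool$states, function(s) {
      s$w <- -s$w; s
    })
    pred <- integer(6)
    for (ti in 1:6) {
      idx <- which(trial == ti)
      r <- online_step(pool, fm[idx, , drop = FALSE], stim[idx])
      pool <- r$pool
      pred[ti] <- r$prediction
    }
    pred
  }
  a <- run_pipe(bci_config(), flip = FALSE)
  b <- run_pipe(bci_config(mu_target = -1, mu_nontarget = 1), flip = TRUE)
  expect_identical(a, b)
})

test_that("the documented log-density constant toggle changes only the constant", {
  w <- c(0.4, -0.1)
  st <- decoder_state(w, lambda = 2)
  X <- matrix(rnorm(8), 4, 2)
  stim <- c(1L, 2L, 1L, 2L)
  correct <- infer_attended(st, X, stim, K = 2, bug_compat = FALSE)
  buggy <- infer_attended(st, X, stim, K = 2, bug_compat = TRUE)
  # per-trial posteriors are unaffected (the constant cancels)...
  expect_equal(as.numeric(correct), as.numeric(buggy), tolerance = 1e-12)
  # ...but the marginal likelihood differs by exactly n/4 * log(2 pi / lambda)
  expect_equal(attr(buggy, "logml") - attr(correct, "logml"),
               4 * 0.25 * log(2 * pi / 2), tolerance = 1e-10)
})

test_that("a non-uniform hypothesis prior reweights the posterior", {
  st <- decoder_state(rnorm(4, sd = 0.1))
  X <- matrix(rnorm(24), 6, 4)
  stim <- rep(1:3, 2)
  flat <- infer_attended(st, X, stim, K = 3)
  sharp <- infer_attended(st, X, stim, K = 3, prior = c(1, 0, 0))
  expect_equal(as.numeric(sharp), c(1, 0, 0))
  # a uniform prior reproduces the default
  unif <- infer_attended(st, X, stim, K = 3, prior = rep(1 / 3, 3))
  expect_equal(as.numeric(unif), as.numeric(flat), tolerance = 1e-12)
  expect_equal(attr(unif, "logml"), attr(flat, "logml"), tolerance = 1e-12)
  expect_error(infer_attended(st, X, stim, K = 3, prior = c(1, 1, 1)),
               "probability")
})
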