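# ---------------------------------------------------------------------------
# Unsupervised EM decoder.
#
# Probabilistic model: per epoch x (a D+1-dim feature vector), the 1-D
# projection w'x is Gaussian with precision lambda and a class-dependent mean
# mu_target / mu_nontarget determined by whether the presented stimulus equals
# the latent attended stimulus c of the trial; w carries a zero-mean isotropic
# Gaussian prior with precision beta; c is uniform over the K stimuli.
# ---------------------------------------------------------------------------

#' Construct a decoder state
#'
#' @param w weight vector (length D+1, bias included).
#' @param lambda precision of the 1-D projection (> 0).
#' @param beta precision of the isotropic weight prior (> 0, <= beta_cap).
#' @param mu_target,mu_nontarget class means of the projection (must differ).
#' @param log_likelihood running observed-data log-likelihood under the
#'   current parameters (NA until evaluated).
#' @return a \code{decoder_state}.
#' @export
decoder_state <- function(w, lambda = 1, beta = 100, mu_target = 1,
                          mu_nontarget = -1, log_likelihood = NA_real_) {
  if (lambda <= 0 || beta <= 0)
    stop("lambda and beta must be positive", call. = FALSE)
  if (mu_target == mu_nontarget)
    stop("class projection means must differ", call. = FALSE)
  structure(list(w = as.numeric(w), lambda = lambda, beta = beta,
                 mu_target = mu_target, mu_nontarget = mu_nontarget,
                 log_likelihood = log_likelihood),
            class = "decoder_state")
}

#' Initialize a pool of sign-flipped classifier pairs
#'
#' Per pair, a weight vector w0 is drawn from a zero-mean isotropic Gaussian
#' and the two members start at +w0 and -w0; because unsupervised training may
#' converge to the label-swapped solution, one member of each pair can be
#' expected to learn the task and the other its opposite. All members start
#' with lambda = 1 and beta = 100.
#'
#' @param dim feature dimension D+1 (bias included), >= 2.
#' @param n_pairs number of pairs (default 5).
#' @param seed integer seed; deterministic given it.
#' @param config a \code{bci_config} (initial lambda/beta, class means,
#'   \code{w_init_sd}; NULL \code{w_init_sd} means \code{1/sqrt(dim)}).
#' @return a \code{classifier_pool} holding \code{2 * n_pairs} decoder states
#'   (pair i occupies slots 2i-1, 2i) and, as the session proceeds, the
#'   stored unlabeled trials.
#' @export
init_pool <- function(dim, n_pairs = 5, seed = 1, config = bci_config()) {
  if (dim < 2) stop("dim must be >= 2", call. = FALSE)
  sdw <- config$w_init_sd %||% (1 / sqrt(dim))
  states <- with_seed(sub_seed(seed, "pool-init"), {
    out <- vector("list", 2 * n_pairs)
    for (p in seq_len(n_pairs)) {
      w0 <- stats::rnorm(dim, sd = sdw)
      out[[2 * p - 1]] <- decoder_state(w0, config$lambda_init,
                                        config$beta_init,
                                        config$mu_target, config$mu_nontarget)
      out[[2 * p]] <- decoder_state(-w0, config$lambda_init, config$beta_init,
                                    config$mu_target, config$mu_nontarget)
    }
    out
  })
  structure(list(states = states, n_pairs = as.integer(n_pairs),
                 dim = as.integer(dim), config = config, seed = seed,
                 data = NULL, n_trials = 0L),
            class = "classifier_pool")
}

#' @export
print.classifier_pool <- function(x, ...) {
  cat(sprintf("<classifier_pool> %d pairs (dim %d), %d stored trial(s)\n",
              x$n_pairs, x$dim, x$n_trials))
  if (x$n_trials > 0) {
    ll <- vapply(x$states, function(s) s$log_likelihood, numeric(1))
    cat("  data log-likelihoods:", paste(sprintf("%.1f", ll), collapse = " "),
        "\n")
  }
  invisible(x)
}

# -- internal stored-data representation ------------------------------------
# F: n x D matrix of (normalized, bias-augmented) features, rows = epochs
# stimulus: presented stimulus id per epoch; trial: trial id per epoch (1-based
# consecutive); trial_of: unique trial ids in order.

pool_data <- function(F, stimulus, trial) {
  ut <- unique(trial)
  tmap <- match(trial, ut)
  list(F = F, stimulus = as.integer(stimulus), trial = as.integer(tmap),
       n_trials = length(ut),
       n_per_trial = as.integer(tabulate(tmap, length(ut))),
       n_rows = nrow(F))
}

# Appends with capacity doubling so the feature store is not reallocated on
# every trial; data$F may hold spare rows beyond data$n_rows.
append_trial <- function(data, F_trial, stimulus) {
  m <- nrow(F_trial)
  if (is.null(data)) {
    cap <- max(4L * m, 512L)
    F <- matrix(0, cap, ncol(F_trial))
    F[seq_len(m), ] <- F_trial
    return(list(F = F, stimulus = as.integer(stimulus),
                trial = rep(1L, m), n_trials = 1L,
                n_per_trial = m, n_rows = m))
  }
  if (data$n_rows + m > nrow(data$F)) {
    F <- matrix(0, 2L * (data$n_rows + m), ncol(data$F))
    F[seq_len(data$n_rows), ] <- data$F[seq_len(data$n_rows), ]
    data$F <- F
  }
  rows <- data$n_rows + seq_len(m)
  data$F[rows, ] <- F_trial
  t_new <- data$n_trials + 1L
  data$stimulus <- c(data$stimulus, as.integer(stimulus))
  data$trial <- c(data$trial, rep(t_new, m))
  data$n_trials <- t_new
  data$n_per_trial <- c(data$n_per_trial, m)
  data$n_rows <- data$n_rows + m
  data
}

# Active feature rows of a pool-data store.
data_F <- function(data) {
  if (!is.null(data$n_rows) && data$n_rows < nrow(data$F))
    data$F[seq_len(data$n_rows), , drop = FALSE]
  else data$F
}

# Per-trial log-likelihood matrix under all K hypotheses, from projections.
# Returns n_trials x K matrix of sum_j log N(p_j | mu_{s(c, d_j)}, 1/lambda),
# including the Gaussian normalization constant (or the erroneous constant of
# the original online implementation when bug_compat).
hypothesis_logliks <- function(proj, stimulus, trial, n_trials, K, lambda,
                               mu_t, mu_nt, bug_compat = FALSE) {
  const <- if (bug_compat) -0.25 * log(2 * pi / lambda)
           else            -0.5  * log(2 * pi / lambda)
  r_nt <- (proj - mu_nt)^2
  r_t  <- (proj - mu_t)^2
  A <- rowsum(r_nt, trial, reorder = TRUE)[, 1]            # all-nontarget SSE
  grp <- (trial - 1L) * K + stimulus
  B <- matrix(0, n_trials, K)
  sw <- rowsum(r_nt - r_t, grp)                            # gain of switching
  g <- as.integer(rownames(sw))
  B[cbind((g - 1L) %/% K + 1L, (g - 1L) %% K + 1L)] <- sw[, 1]
  n_per <- tabulate(trial, n_trials)
  # loglik(t, c) = n_t * const - 0.5 * lambda * (A_t - B[t, c])
  n_per * const - 0.5 * lambda * (A - B)
}

posterior_from_logliks <- function(L) {
  m <- apply(L, 1, max)
  P <- exp(L - m)
  P / rowSums(P)
}

# Observed-data log-likelihood: sum over trials of log mean_c exp(loglik_c)
# (uniform prior over the K hypotheses, log-sum-exp in log space).
marginal_loglik <- function(L) {
  m <- apply(L, 1, max)
  sum(m + log(rowMeans(exp(L - m))))
}

#' Posterior over the attended stimulus of one trial
#'
#' Applies Bayes's rule under the model: for each hypothesis c, the trial's
#' log-likelihood sums the Gaussian log-densities of every epoch's projection
#' around the class mean implied by c; the posterior normalizes the
#' exponentials under a uniform prior over the K stimuli (computed in
#' log-space with max subtraction).
#'
#' @param state a \code{decoder_state}.
#' @param F_trial epochs x (D+1) feature matrix of one trial.
#' @param stimulus presented stimulus id per epoch.
#' @param K number of stimuli.
#' @param bug_compat reproduce the documented log-density constant error.
#' @param prior optional prior over the K hypotheses (non-negative, summing
#'   to 1); default uniform. The hook through which language-model
#'   information over upcoming symbols could enter; no language model ships.
#' @return numeric vector of K posterior probabilities (sums to 1), with the
#'   trial's marginal log-likelihood in \code{attr(, "logml")}.
#' @export
infer_attended <- function(state, F_trial, stimulus, K = 6,
                           bug_compat = FALSE, prior = NULL) {
  if (is.null(dim(F_trial)) || nrow(F_trial) == 0)
    stop("trial has no feature vectors", call. = FALSE)
  if (nrow(F_trial) != length(stimulus))
    stop("one stimulus id per epoch required", call. = FALSE)
  proj <- as.numeric(F_trial %*% state$w)
  L <- hypothesis_logliks(proj, as.integer(stimulus),
                          rep(1L, length(proj)), 1L, K,
                          state$lambda, state$mu_target, state$mu_nontarget,
                          bug_compat)
  if (!is.null(prior)) {
    if (length(prior) != K || any(prior < 0) || abs(sum(prior) - 1) > 1e-8)
      stop("prior must be a length-K probability vector", call. = FALSE)
    Lp <- L + rep(log(prior), each = nrow(L))
    post <- posterior_from_logliks(Lp)[1, ]
    attr(post, "logml") <- logsumexp(Lp[1, ])
    return(post)
  }
  post <- posterior_from_logliks(L)[1, ]
  attr(post, "logml") <- marginal_loglik(L)
  post
}

#' Expectation step over all stored trials
#'
#' @param state a \code{decoder_state}.
#' @param data stored-trial data (as held in a \code{classifier_pool}), or a
#'   \code{feature_matrix} whose \code{trial}/\code{stimulus} attributes
#'   define the trials.
#' @param K number of stimuli.
#' @param bug_compat see \code{\link{infer_attended}}.
#' @return n_trials x K matrix of posteriors (rows sum to 1); the summed
#'   marginal log-likelihood of all trials in \code{attr(, "logml")}.
#' @export
e_step <- function(state, data, K = 6, bug_compat = FALSE) {
  data <- as_pool_data(data)
  proj <- as.numeric(data$F %*% state$w)
  L <- hypothesis_logliks(proj, data$stimulus, data$trial, data$n_trials, K,
                          state$lambda, state$mu_target, state$mu_nontarget,
                          bug_compat)
  P <- posterior_from_logliks(L)
  attr(P, "logml") <- marginal_loglik(L)
  P
}

as_pool_data <- function(data) {
  if (inherits(data, "feature_matrix"))
    return(pool_data(unclass_matrix(data), attr(data, "stimulus"),
                     attr(data, "trial")))
  if (!is.null(data$n_rows) && data$n_rows < nrow(data$F))
    data$F <- data$F[seq_len(data$n_rows), , drop = FALSE]
  data
}

unclass_matrix <- function(fm) {
  x <- unclass(fm)
  attributes(x) <- list(dim = dim(x))
  x
}

#' M-step: weight vector update
#'
#' The posterior-weighted ridge solution \eqn{w = (F'F + (\beta/\lambda) I)^{-1}
#' F' \bar y}, where \eqn{\bar y} assigns each epoch the posterior expectation
#' of its class mean under the trial's posterior over attended stimuli. With
#' one-hot posteriors this is exactly ridge regression on the implied hard
#' labels; in general it equals the posterior-probability-weighted sum of all
#' labelings' ridge classifiers.
#'
#' @param data stored trials (see \code{\link{e_step}}).
#' @param posteriors n_trials x K posterior matrix.
#' @param lambda,beta current precisions (the ridge constant is beta/lambda).
#' @param mu_target,mu_nontarget class projection means.
#' @param eig optional eigendecomposition of \code{crossprod(F)} (list with
#'   \code{values}, \code{vectors}) to reuse across updates.
#' @return the updated weight vector.
#' @export
m_step_weights <- function(data, posteriors, lambda, beta,
                           mu_target = 1, mu_nontarget = -1, eig = NULL) {
  data <- as_pool_data(data)
  p_att <- posteriors[cbind(data$trial, data$stimulus)]
  ybar <- mu_nontarget + p_att * (mu_target - mu_nontarget)
  b <- crossprod(data$F, ybar)
  ridge <- beta / lambda
  if (is.null(eig)) {
    A <- crossprod(data$F)
    diag(A) <- diag(A) + ridge
    as.numeric(solve(A, b))
  } else {
    as.numeric(eig$vectors %*% (crossprod(eig$vectors, b) /
                                  (pmax(eig$values, 0) + ridge)))
  }
}

#' M-step: projection precision update
#'
#' lambda is the inverse of the expected mean squared error between the
#' projections and their class means under the trial posteriors, floored to
#' avoid infinite precision on degenerate (exactly separable) fits.
#'
#' @inheritParams m_step_weights
#' @param w current weight vector.
#' @param floor lower bound on the expected MSE.
#' @return the updated lambda (> 0).
#' @export
m_step_lambda <- function(data, posteriors, w, mu_target = 1,
                          mu_nontarget = -1, floor = 1e-10) {
  data <- as_pool_data(data)
  proj <- as.numeric(data$F %*% w)
  p_att <- posteriors[cbind(data$trial, data$stimulus)]
  mse <- mean(p_att * (proj - mu_target)^2 +
                (1 - p_att) * (proj - mu_nontarget)^2)
  1 / max(mse, floor)
}

#' M-step: weight-prior precision update
#'
#' beta is the inverse of the average squared classifier weight, capped
#' (default 200) to keep the classifier from collapsing onto the all-zero
#' weight vector.
#'
#' @param w weight vector.
#' @param beta_cap upper bound on beta.
#' @return the updated beta in (0, beta_cap].
#' @export
m_step_beta <- function(w, beta_cap = 200) {
  msq <- mean(w^2)
  if (msq == 0) {
    warning("all-zero weight vector: beta set to its cap")
    return(beta_cap)
  }
  min(1 / msq, beta_cap)
}

#' Run EM iterations of one classifier on the stored trials
#'
#' Each iteration: infer the posterior over every stored trial's attended
#' stimulus under the current parameters (E), then update w (posterior-
#' weighted ridge), lambda (inverse expected MSE) and beta (inverse average
#' squared weight, capped) in turn (M). Afterwards the state's
#' \code{log_likelihood} holds the observed-data log-likelihood of all stored
#' trials under the final parameters.
#'
#' @param state a \code{decoder_state}.
#' @param data stored trials (pool data or \code{feature_matrix}).
#' @param n_iter number of EM iterations (default 5).
#' @param config a \code{bci_config}.
#' @param eig optional cached eigendecomposition of \code{crossprod(F)}.
#' @param trace if TRUE, attach the log-likelihood after each iteration as
#'   \code{attr(, "loglik_trace")}.
#' @return the updated \code{decoder_state}.
#' @export
em_iterations <- function(state, data, n_iter = 5, config = bci_config(),
                          eig = NULL, trace = FALSE) {
  data <- as_pool_data(data)
  if (data$n_trials < 1) stop("at least one stored trial required",
                              call. = FALSE)
  K <- config$K; mu_t <- state$mu_target; mu_nt <- state$mu_nontarget
  F <- data$F
  tr <- numeric(0); obj <- numeric(0)
  proj <- as.numeric(F %*% state$w)
  if (n_iter > 0) {
    for (it in seq_len(n_iter)) {
      # E: posterior over each trial's attended stimulus at current (w, lambda)
      L <- hypothesis_logliks(proj, data$stimulus, data$trial, data$n_trials,
                              K, state$lambda, mu_t, mu_nt, config$bug_compat)
      P <- posterior_from_logliks(L)
      # M: posterior-weighted ridge for w, then lambda, then capped beta
      p_att <- P[cbind(data$trial, data$stimulus)]
      ybar <- mu_nt + p_att * (mu_t - mu_nt)
      b <- crossprod(F, ybar)
      ridge <- state$beta / state$lambda
      state$w <- if (is.null(eig)) {
        A <- crossprod(F)
        diag(A) <- diag(A) + ridge
        as.numeric(solve(A, b))
      } else {
        as.numeric(eig$vectors %*% (crossprod(eig$vectors, b) /
                                      (pmax(eig$values, 0) + ridge)))
      }
      proj <- as.numeric(F %*% state$w)
      mse <- mean(p_att * (proj - mu_t)^2 + (1 - p_att) * (proj - mu_nt)^2)
      state$lambda <- 1 / max(mse, config$lambda_floor)
      state$beta <- m_step_beta(state$w, config$beta_cap)
      if (trace) {
        Lc <- hypothesis_logliks(proj, data$stimulus, data$trial,
                                 data$n_trials, K, state$lambda, mu_t, mu_nt,
                                 config$bug_compat)
        tr <- c(tr, marginal_loglik(Lc))
        obj <- c(obj, tr[length(tr)] + weight_prior_logdens(state))
      }
    }
  }
  state$log_likelihood <- if (trace && length(tr)) tr[length(tr)] else {
    Lf <- hypothesis_logliks(proj, data$stimulus, data$trial, data$n_trials,
                             K, state$lambda, mu_t, mu_nt, config$bug_compat)
    marginal_loglik(Lf)
  }
  if (trace) {
    attr(state, "loglik_trace") <- tr
    attr(state, "objective_trace") <- obj
  }
  state
}

# Log-density of the isotropic zero-mean weight prior at the state's weights.
# The EM objective log p(X | w, lambda) + log N(w | 0, beta^-1 I) is the
# quantity every update (w, lambda, beta incl. cap/floor clipping) increases;
# the bare data log-likelihood is used for classifier selection but is not
# itself guaranteed monotone because w is regularized and beta re-estimated.
weight_prior_logdens <- function(state) {
  d <- length(state$w)
  0.5 * d * log(state$beta / (2 * pi)) -
    0.5 * state$beta * sum(state$w^2)
}

# Observed-data log-likelihood of the stored trials under a state.
state_loglik <- function(state, data, config = bci_config()) {
  data <- as_pool_data(data)
  proj <- as.numeric(data$F %*% state$w)
  L <- hypothesis_logliks(proj, data$stimulus, data$trial, data$n_trials,
                          config$K, state$lambda, state$mu_target,
                          state$mu_nontarget, config$bug_compat)
  marginal_loglik(L)
}

# Expected squared error selection score (lower is better); alternative to
# the log-likelihood criterion.
state_expected_mse <- function(state, data, config = bci_config()) {
  data <- as_pool_data(data)
  P <- e_step(state, data, config$K, config$bug_compat)
  proj <- as.numeric(data$F %*% state$w)
  p_att <- P[cbind(data$trial, data$stimulus)]
  mean(p_att * (proj - state$mu_target)^2 +
         (1 - p_att) * (proj - state$mu_nontarget)^2)
}

#' Select the best classifier of a pool
#'
#' By default the state with the maximal observed-data log-likelihood over
#' the stored trials; with \code{config$selection = "mse"}, the state with
#' minimal expected squared error between projections and class means. Ties
#' break to the lowest pair index, first member.
#'
#' @param pool a \code{classifier_pool} with current likelihoods.
#' @return the selected \code{decoder_state}; its pool index in
#'   \code{attr(, "index")}.
#' @export
select_best <- function(pool) {
  stopifnot(inherits(pool, "classifier_pool"))
  if (!length(pool$states)) stop("empty pool", call. = FALSE)
  if (pool$config$selection == "mse") {
    dat <- as_pool_data(pool$data)
    score <- vapply(pool$states, state_expected_mse, numeric(1),
                    data = dat, config = pool$config)
    i <- which.min(score)
  } else {
    ll <- vapply(pool$states, function(s) s$log_likelihood, numeric(1))
    i <- which.max(ll)              # first maximum = lowest pair index
  }
  s <- pool$states[[i]]
  attr(s, "index") <- i
  s
}

#' Re-initialize the weaker member of each classifier pair
#'
#' Per pair, the member with the higher data log-likelihood is kept; the
#' other is re-initialized with the negated weights of the kept member
#' (lambda and beta copied from it), so each pair remains a sign reflection
#' of one model.
#'
#' @param pool a \code{classifier_pool} with current likelihoods.
#' @return the updated pool.
#' @export
reinit_pairs <- function(pool) {
  stopifnot(inherits(pool, "classifier_pool"))
  dat <- if (!is.null(pool$data)) as_pool_data(pool$data)
  for (p in seq_len(pool$n_pairs)) {
    i <- 2L * p - 1L; j <- 2L * p
    a <- pool$states[[i]]; b <- pool$states[[j]]
    keep <- if (b$log_likelihood > a$log_likelihood) j else i
    lose <- if (keep == i) j else i
    k <- pool$states[[keep]]
    neg <- decoder_state(-k$w, k$lambda, k$beta, k$mu_target, k$mu_nontarget)
    if (!is.null(dat))
      neg$log_likelihood <- state_loglik(neg, dat, pool$config)
    pool$states[[lose]] <- neg
  }
  pool
}

#' One online decoding step
#'
#' Appends the new (unlabeled) trial to the stored data, runs
#' \code{config$em_iter} EM iterations of every classifier on all stored
#' trials, predicts the attended stimulus with the best classifier (argmax of
#' its posterior; ties to the lowest stimulus id), then re-initializes the
#' weaker member of each pair. The online prediction is final: it is never
#' revised (that is what \code{\link{posthoc_reanalysis}} is for).
#'
#' @param pool a \code{classifier_pool}.
#' @param F_trial epochs x (D+1) normalized feature matrix of the new trial.
#' @param stimulus presented stimulus id per epoch of the new trial.
#' @return list with \code{prediction} (stimulus id) and \code{pool} (updated).
#' @export
online_step <- function(pool, F_trial, stimulus) {
  stopifnot(inherits(pool, "classifier_pool"))
  if (inherits(F_trial, "feature_matrix")) {
    if (is.null(stimulus)) stimulus <- attr(F_trial, "stimulus")
    F_trial <- unclass_matrix(F_trial)
  }
  cfg <- pool$config
  pool$data <- append_trial(pool$data, F_trial, stimulus)
  pool$n_trials <- pool$data$n_trials
  # Gram matrix grows incrementally; eigendecomposed once per step and reused
  # by every classifier's ridge solves.
  Gt <- crossprod(F_trial)
  pool$XtX <- if (is.null(pool$XtX)) Gt else pool$XtX + Gt
  eig <- eigen(pool$XtX, symmetric = TRUE)
  dat <- as_pool_data(pool$data)       # trim spare capacity once per step
  pool$states <- lapply(pool$states, em_iterations, data = dat,
                        n_iter = cfg$em_iter, config = cfg, eig = eig)
  best <- select_best(pool)
  nt <- pool$data$n_trials
  idx <- which(pool$data$trial == nt)
  post <- infer_attended(best, pool$data$F[idx, , drop = FALSE],
                         pool$data$stimulus[idx], cfg$K, cfg$bug_compat)
  prediction <- which.max(post)        # first max = lowest stimulus id
  pool <- reinit_pairs(pool)
  list(prediction = as.integer(prediction), pool = pool,
       posterior = as.numeric(post))
}

#' Posthoc re-analysis of all stored trials
#'
#' Re-classifies every stored trial with the currently best classifier. As
#' the pool keeps learning from unlabeled data, this typically revises early
#' online mistakes; it can be called after every trial (a live updating
#' display) or once at block end.
#'
#' @param pool a \code{classifier_pool} with at least one stored trial.
#' @return integer vector of predicted attended stimuli, one per stored trial.
#' @export
posthoc_reanalysis <- function(pool) {
  stopifnot(inherits(pool, "classifier_pool"))
  if (pool$n_trials < 1) stop("no stored trials", call. = FALSE)
  cfg <- pool$config
  best <- select_best(pool)
  P <- e_step(best, pool$data, cfg$K, cfg$bug_compat)
  as.integer(apply(P, 1, which.max))
}

#' @export
print.decoder_state <- function(x, ...) {
  cat(sprintf("<decoder_state> dim %d, lambda %.4g, beta %.4g, loglik %s\n",
              length(x$w), x$lambda, x$beta,
              if (is.na(x$log_likelihood)) "NA"
              else sprintf("%.2f", x$log_likelihood)))
  invisible(x)
}
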