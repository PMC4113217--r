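#' Trial-wise selection accuracy
#'
#' @param truth ground-truth attended stimuli.
#' @param pred predicted stimuli (same length).
#' @param trials optional index vector restricting the scope (e.g. a block or
#'   sub-block).
#' @return fraction of correct trials in scope.
#' @export
selection_accuracy <- function(truth, pred, trials = NULL) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  if (!is.null(trials)) {
    truth <- truth[trials]; pred <- pred[trials]
  }
  if (!length(truth)) stop("empty scope", call. = FALSE)
  mean(truth == pred)
}

#' Symbol-level accuracy of a spelled string
#'
#' Consecutive trial pairs map to symbols through the two-step grid; a symbol
#' is spelled correctly iff both its trials are correct.
#'
#' @inheritParams selection_accuracy
#' @return fraction of correctly spelled symbols.
#' @export
symbol_accuracy <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  n <- length(truth)
  if (n == 0 || n %% 2 != 0)
    stop("symbol accuracy needs an even, positive number of trials",
         call. = FALSE)
  ok <- truth == pred
  first <- ok[seq(1, n, by = 2)]
  second <- ok[seq(2, n, by = 2)]
  mean(first & second)
}

#' Spell the symbols of a trial sequence
#'
#' Maps consecutive (group, within-group) selection pairs to symbols. When
#' both selections of a pair are wrong the both-failed sentinel
#' \code{"°"} is emitted, mirroring the speller's feedback display.
#'
#' @param truth,pred attended and predicted stimuli over an even number of
#'   trials.
#' @param grid a \code{symbol_grid}.
#' @return character vector of spelled symbols (length \code{n/2}).
#' @export
spell_symbols <- function(truth, pred, grid = symbol_grid()) {
  n <- length(pred)
  if (n %% 2 != 0) stop("need an even number of trials", call. = FALSE)
  out <- character(n / 2)
  for (s in seq_len(n / 2)) {
    i <- 2 * s - 1; j <- 2 * s
    both_wrong <- pred[i] != truth[i] && pred[j] != truth[j]
    out[s] <- if (both_wrong) "°"
              else decode_symbol(pred[i], pred[j], grid)
  }
  out
}

#' Time to control: first trial of the first run of 3 correct selections
#'
#' A user is considered in control of the speller once three consecutive
#' trials are decoded without mistake (the chance probability of such a run
#' is \eqn{(1/6)^3}); the time-to-control is the 1-based index of the first
#' trial of the first such run, or NA if none occurs.
#'
#' @param correct logical vector of per-trial correctness (or supply
#'   \code{truth}/\code{pred}).
#' @param truth,pred alternative input as stimulus vectors.
#' @param run_length required run of correct trials (default 3).
#' @return integer trial index, or NA.
#' @export
time_to_control <- function(correct = NULL, truth = NULL, pred = NULL,
                            run_length = 3) {
  if (is.null(correct)) correct <- truth == pred
  r <- rle(correct)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  if (!length(hit)) return(NA_integer_)
  as.integer(ends[hit[1]] - r$lengths[hit[1]] + 1L)
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' @param scores numeric scores.
#' @param is_target logical class labels.
#' @return the AUC of scores for target vs non-target.
#' @export
auc_rank <- function(scores, is_target) {
  n_t <- sum(is_target); n_nt <- sum(!is_target)
  if (n_t == 0 || n_nt == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                               # midranks for ties
  (sum(r[is_target]) - n_t * (n_t + 1) / 2) / (n_t * n_nt)
}

#' Signed scaled AUC map over channels and time intervals
#'
#' Class-discriminability map: per channel and interval, the AUC of the mean
#' potential for target vs non-target epochs, mapped linearly so that
#' AUC = 0.5 becomes 0 and the extremes 0 and 1 become -1 and +1
#' (ssAUC = 2 AUC - 1). Following the offline visualization path, epochs are
#' first band-pass filtered acausally (forward-backward, 0.5--20 Hz) and
#' re-baselined before scoring; set \code{bandpass = FALSE} to skip.
#'
#' @param es an \code{epoch_set}.
#' @param is_target logical label per epoch.
#' @param intervals n x 2 matrix of scoring intervals in ms.
#' @param bandpass apply the acausal 0.5--20 Hz band-pass first.
#' @param baseline baseline interval (seconds) for re-baselining.
#' @return channels x intervals matrix of ssAUC values in [-1, 1].
#' @export
ssauc_map <- function(es, is_target, intervals = default_intervals(),
                      bandpass = TRUE, baseline = c(-0.2, 0)) {
  stopifnot(inherits(es, "epoch_set"))
  if (length(is_target) != dim(es$epochs)[3])
    stop("one label per epoch required", call. = FALSE)
  if (!any(is_target) || all(is_target))
    stop("both classes must be present", call. = FALSE)
  if (bandpass) {
    es$epochs <- acausal_bandpass(es$epochs, es$sampling_rate)
    es <- baseline_correct(es, baseline)
  }
  fm <- extract_features(es, intervals)
  nI <- nrow(intervals); nC <- dim(es$epochs)[1]
  out <- matrix(0, nC, nI,
                dimnames = list(es$channels,
                                paste0(intervals[, 1], "-", intervals[, 2])))
  for (ch in seq_len(nC))
    for (i in seq_len(nI))
      out[ch, i] <- 2 * auc_rank(fm[, (ch - 1) * nI + i], is_target) - 1
  out
}

# Acausal forward-backward Butterworth band-pass (visualization path only;
# the online chain stays strictly causal).
acausal_bandpass <- function(epochs, sampling_rate, band = c(0.5, 20),
                             order = 2) {
  flt <- signal::butter(order, band / (sampling_rate / 2), type = "pass")
  d <- dim(epochs)
  for (e in seq_len(d[3]))
    for (ch in seq_len(d[1]))
      epochs[ch, , e] <- signal::filtfilt(flt, epochs[ch, , e])
  epochs
}

#' Run the block-alternation protocol on a synthetic session
#'
#' The online study's protocol: the supervised model is trained once on a
#' labeled calibration block (with variance-based outlier rejection) and then
#' applied fixed; the unsupervised pool is re-initialized randomly before
#' each unsupervised block, predicts each trial online, and its posthoc
#' trajectory (re-analysis of all past trials of the block) is recorded after
#' every trial.
#'
#' @param session a \code{bci_session} with at least 2 blocks.
#' @param methods character vector, one of "supervised"/"unsupervised" per
#'   non-calibration block; default alternates starting with supervised.
#' @param calibration_block index of the labeled calibration block.
#' @param seed master seed for the pool initializations.
#' @param config a \code{bci_config}.
#' @return a \code{run_record}: per evaluated block, ground truth, method,
#'   online predictions, posthoc trajectory and final posthoc predictions.
#' @export
run_block_protocol <- function(session, methods = NULL,
                               calibration_block = 1, seed = 1,
                               config = bci_config()) {
  stopifnot(inherits(session, "bci_session"))
  eval_blocks <- setdiff(seq_len(session$n_blocks), calibration_block)
  if (!length(eval_blocks))
    stop("session needs at least one non-calibration block", call. = FALSE)
  if (is.null(methods))
    methods <- rep(c("supervised", "unsupervised"),
                   length.out = length(eval_blocks))
  if (length(methods) != length(eval_blocks))
    stop("one method per evaluation block required", call. = FALSE)
  if (!all(methods %in% c("supervised", "unsupervised")))
    stop("methods must be 'supervised' or 'unsupervised'", call. = FALSE)

  model <- calibrate_supervised(session, calibration_block, config)

  blocks <- vector("list", length(eval_blocks))
  for (bi in seq_along(eval_blocks)) {
    b <- eval_blocks[bi]
    truth <- vapply(session$blocks[[b]], function(tr) tr$attended, 1L)
    if (methods[bi] == "supervised") {
      fm <- preprocess_session(session, blocks = b, normalize = FALSE,
                               config = config)
      trial <- attr(fm, "trial"); stim <- attr(fm, "stimulus")
      online <- vapply(seq_along(truth), function(ti) {
        idx <- which(trial == ti)
        predict_trial(model, fm[idx, , drop = FALSE], stim[idx], config$K)
      }, 1L)
      blocks[[bi]] <- list(block = b, method = "supervised", truth = truth,
                           online = online, posthoc = NULL,
                           posthoc_trajectory = NULL)
    } else {
      fm <- preprocess_session(session, blocks = b, normalize = TRUE,
                               config = config)
      trial <- attr(fm, "trial"); stim <- attr(fm, "stimulus")
      pool <- init_pool(ncol(fm), config$n_pairs,
                        seed = sub_seed(seed, paste0("pool-block-", b)),
                        config = config)
      online <- integer(length(truth))
      trajectory <- vector("list", length(truth))
      for (ti in seq_along(truth)) {
        idx <- which(trial == ti)
        step <- online_step(pool, fm[idx, , drop = FALSE], stim[idx])
        pool <- step$pool
        online[ti] <- step$prediction
        trajectory[[ti]] <- posthoc_reanalysis(pool)
      }
      blocks[[bi]] <- list(block = b, method = "unsupervised", truth = truth,
                           online = online,
                           posthoc = trajectory[[length(truth)]],
                           posthoc_trajectory = trajectory)
    }
  }
  structure(list(blocks = blocks, calibration_block = calibration_block,
                 model = model, seed = seed, config = config),
            class = "run_record")
}

#' Train the supervised baseline on a session's calibration block
#'
#' @param session a \code{bci_session}.
#' @param block calibration block index.
#' @param config a \code{bci_config}.
#' @return an \code{lda_model}.
#' @export
calibrate_supervised <- function(session, block = 1, config = bci_config()) {
  es <- session_epochs(session, block)
  es <- baseline_correct(es, config$baseline)
  rej <- reject_outlier_epochs(es, config$outlier_factor, config$outlier_prob)
  es <- rej$kept
  fm <- extract_features(es, config$intervals)
  attended_of_trial <- attr(es, "attended") %||% es$attended
  labels <- es$stimulus == attended_of_trial[es$trial]
  train_lda(fm, labels)
}

#' Simulated online experiment of extended duration
#'
#' Concatenates all blocks of a session in chronological order into one long
#' run: the unsupervised pool is initialized once, never reset, learns across
#' all trials, and the posthoc re-analysis re-classifies everything at the
#' end; a fixed supervised model (if supplied) decodes the same trials. Per
#' 10-trial sub-block (18 for six 30-trial blocks), accuracies are reported
#' for paired comparison across simulated subjects.
#'
#' @param session a \code{bci_session}.
#' @param model optional \code{lda_model} for the supervised arm.
#' @param seed master seed for the single pool initialization.
#' @param config a \code{bci_config}.
#' @param subblock_size trials per sub-block (default 10 = 5 symbols).
#' @return an \code{extended_record}: truth, per-method predictions, and a
#'   sub-block x method accuracy matrix.
#' @export
run_extended_simulation <- function(session, model = NULL, seed = 1,
                                    config = bci_config(),
                                    subblock_size = 10) {
  stopifnot(inherits(session, "bci_session"))
  fm_u <- preprocess_session(session, normalize = TRUE, config = config)
  trial <- attr(fm_u, "trial"); stim <- attr(fm_u, "stimulus")
  truth <- attr(fm_u, "attended")
  n_trials <- length(truth)
  pool <- init_pool(ncol(fm_u), config$n_pairs,
                    seed = sub_seed(seed, "pool-extended"), config = config)
  online <- integer(n_trials)
  for (ti in seq_len(n_trials)) {
    idx <- which(trial == ti)
    step <- online_step(pool, fm_u[idx, , drop = FALSE], stim[idx])
    pool <- step$pool
    online[ti] <- step$prediction
  }
  posthoc <- posthoc_reanalysis(pool)

  supervised <- NULL
  if (!is.null(model)) {
    fm_s <- preprocess_session(session, normalize = FALSE, config = config)
    trial_s <- attr(fm_s, "trial"); stim_s <- attr(fm_s, "stimulus")
    supervised <- vapply(seq_len(n_trials), function(ti) {
      idx <- which(trial_s == ti)
      predict_trial(model, fm_s[idx, , drop = FALSE], stim_s[idx], config$K)
    }, 1L)
  }

  n_sub <- as.integer(n_trials %/% subblock_size)
  sub_of <- rep(seq_len(n_sub), each = subblock_size)[seq_len(n_trials)]
  acc <- function(pred) {
    vapply(seq_len(n_sub),
           function(s) mean((pred == truth)[sub_of == s & !is.na(sub_of)]),
           numeric(1))
  }
  subblocks <- cbind(unsupervised = acc(online), posthoc = acc(posthoc))
  if (!is.null(supervised))
    subblocks <- cbind(supervised = acc(supervised), subblocks)

  structure(list(truth = truth, online = online, posthoc = posthoc,
                 supervised = supervised, n_subblocks = n_sub,
                 subblock_size = subblock_size, subblock_accuracy = subblocks,
                 pool = pool, seed = seed),
            class = "extended_record")
}

#' Paired t-tests per sub-block across simulated subjects
#'
#' Two-sided paired t-tests (alpha = 0.05, no multiple-testing correction)
#' comparing two methods' sub-block accuracies across matched subjects.
#'
#' @param acc_a,acc_b subjects x sub-blocks accuracy matrices, matched rows.
#' @param alpha significance level.
#' @return data.frame with one row per sub-block: t statistic, df, p value,
#'   significance flag.
#' @export
subblock_ttests <- function(acc_a, acc_b, alpha = 0.05) {
  stopifnot(all(dim(acc_a) == dim(acc_b)))
  out <- lapply(seq_len(ncol(acc_a)), function(j) {
    d <- acc_a[, j] - acc_b[, j]
    if (stats::sd(d) == 0)
      return(data.frame(subblock = j, t = NA_real_,
                        df = length(d) - 1, p = NA_real_,
                        significant = FALSE))
    tt <- stats::t.test(acc_a[, j], acc_b[, j], paired = TRUE)
    data.frame(subblock = j, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, out)
}

#' Accuracy summary of a block-protocol run
#'
#' @param record a \code{run_record}.
#' @return data.frame with one row per evaluated block: method, online
#'   accuracy, posthoc accuracy (NA for supervised blocks), symbol accuracy
#'   and time-to-control.
#' @export
summarize_run <- function(record) {
  stopifnot(inherits(record, "run_record"))
  rows <- lapply(record$blocks, function(b) {
    data.frame(
      block = b$block, method = b$method,
      online_accuracy = selection_accuracy(b$truth, b$online),
      posthoc_accuracy = if (is.null(b$posthoc)) NA_real_
                         else selection_accuracy(b$truth, b$posthoc),
      symbol_accuracy = if (length(b$truth) %% 2 == 0)
                          symbol_accuracy(b$truth, b$online) else NA_real_,
      time_to_control = time_to_control(b$truth == b$online)
    )
  })
  do.call(rbind, rows)
}

#' Tidy per-trial table of a run record
#'
#' @param record a \code{run_record}.
#' @return data.frame, one row per trial: block, method, trial, truth, online
#'   prediction, final posthoc prediction (NA when not applicable).
#' @export
run_record_table <- function(record) {
  stopifnot(inherits(record, "run_record"))
  rows <- lapply(record$blocks, function(b) {
    data.frame(block = b$block, method = b$method,
               trial = seq_along(b$truth), truth = b$truth,
               online = b$online,
               posthoc = if (is.null(b$posthoc)) NA_integer_ else b$posthoc)
  })
  do.call(rbind, rows)
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record>\n")
  print(summarize_run(x))
  invisible(x)
}

#' @export
print.extended_record <- function(x, ...) {
  cat(sprintf("<extended_record> %d trials, %d sub-blocks of %d\n",
              length(x$truth), x$n_subblocks, x$subblock_size))
  cat(sprintf("  online unsupervised accuracy %.3f, posthoc %.3f%s\n",
              mean(x$online == x$truth), mean(x$posthoc == x$truth),
              if (is.null(x$supervised)) ""
              else sprintf(", supervised %.3f", mean(x$supervised == x$truth))))
  invisible(x)
}

#' Simulate a cohort of subjects as independently seeded sessions
#'
#' "Subjects" are independent generator seeds with a subject-specific
#' class-difference amplitude drawn uniformly from \code{amplitude_range},
#' reproducing between-subject performance variability without claiming
#' biophysical realism. Useful as matched input to
#' \code{\link{subblock_ttests}}.
#'
#' @param n_subjects number of simulated subjects.
#' @param amplitude_range range the per-subject difference amplitude is drawn
#'   from.
#' @param seed master seed; subject i uses the named substream
#'   \code{"subject-i"}.
#' @param template base \code{erp_template} (its amplitude is overridden).
#' @param noise a \code{noise_model}.
#' @param ... passed to \code{\link{generate_session}}.
#' @return list of \code{bci_session}, one per subject, each carrying its
#'   amplitude in \code{$template$difference_amplitude}.
#' @export
simulate_subject_sessions <- function(n_subjects, amplitude_range = c(0.2, 0.5),
                                      seed = 1, template = erp_template(),
                                      noise = noise_model(), ...) {
  stopifnot(n_subjects >= 1, length(amplitude_range) == 2)
  lapply(seq_len(n_subjects), function(i) {
    s_i <- sub_seed(seed, paste0("subject-", i))
    amp <- with_seed(sub_seed(s_i, "amplitude"),
                     stats::runif(1, amplitude_range[1], amplitude_range[2]))
    tpl <- template
    tpl$difference_amplitude <- amp
    generate_session(tpl, noise, seed = s_i, ...)
  })
}
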