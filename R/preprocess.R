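#' Construct an epoch set
#'
#' The container for per-presentation EEG segments: a channels x samples x
#' epochs array plus the epoch window, sampling rate, presented-stimulus ids
#' and trial membership.
#'
#' @param epochs numeric array, channels x samples x n_epochs.
#' @param window epoch window in seconds (start, end).
#' @param sampling_rate Hz.
#' @param stimulus integer vector of presented stimulus ids, one per epoch.
#' @param trial integer vector of trial membership, one per epoch.
#' @param channels optional channel names.
#' @param attended optional ground-truth attended stimulus per trial.
#' @param baseline_corrected logical flag.
#' @return an \code{epoch_set}.
#' @export
epoch_set <- function(epochs, window, sampling_rate, stimulus = NULL,
                      trial = NULL, channels = NULL, attended = NULL,
                      baseline_corrected = FALSE) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3)
  n <- dim(epochs)[3]
  if (is.null(stimulus)) stimulus <- rep(NA_integer_, n)
  if (is.null(trial)) trial <- rep(1L, n)
  if (length(stimulus) != n || length(trial) != n)
    stop("stimulus and trial must have one entry per epoch", call. = FALSE)
  nS_expect <- round((window[2] - window[1]) * sampling_rate)
  if (dim(epochs)[2] != nS_expect)
    stop(sprintf("epoch length %d inconsistent with window/rate (expected %d samples)",
                 dim(epochs)[2], nS_expect), call. = FALSE)
  structure(list(epochs = epochs, window = window,
                 sampling_rate = sampling_rate,
                 stimulus = as.integer(stimulus), trial = as.integer(trial),
                 channels = channels %||% paste0("ch", seq_len(dim(epochs)[1])),
                 attended = attended,
                 baseline_corrected = baseline_corrected),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs, %d channels x %d samples, window [%g, %g] s @ %g Hz%s\n",
              dim(x$epochs)[3], dim(x$epochs)[1], dim(x$epochs)[2],
              x$window[1], x$window[2], x$sampling_rate,
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

# Sample times (seconds) of an epoch window at a given rate; samples cover
# [window[1], window[2]) so an 0.9 s window at 100 Hz has 90 samples.
# Rounded so half-open interval selections are not corrupted by seq()'s
# accumulated floating error at the interval edges.
epoch_times <- function(window, sampling_rate) {
  round(seq(window[1], window[2] - 1 / sampling_rate, by = 1 / sampling_rate),
        9)
}

#' Causal Chebyshev type 2 low-pass filter
#'
#' Forward-only (strictly causal, as used online) order-5 Chebyshev type 2
#' low-pass with 20 dB stop-band attenuation and stop edge at \code{cutoff}.
#'
#' @param x numeric matrix, channels x samples (a vector is treated as one
#'   channel), continuous signal.
#' @param sampling_rate Hz.
#' @param cutoff stop-band edge in Hz; must be below Nyquist.
#' @param order filter order.
#' @param attenuation stop-band attenuation in dB.
#' @return the filtered signal, same shape as the input.
#' @export
causal_lowpass <- function(x, sampling_rate, cutoff = 40, order = 5,
                           attenuation = 20) {
  if (cutoff >= sampling_rate / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  # signal::cheby2 names its stop-band attenuation argument Rp
  flt <- signal::cheby2(order, Rp = attenuation,
                        W = cutoff / (sampling_rate / 2), type = "low")
  out <- t(apply(x, 1, function(ch) signal::filter(flt, ch)))
  if (vec) out <- drop(out)
  out
}

#' Cut a continuous signal into baseline-corrected epochs
#'
#' Extracts one epoch per stimulus onset over \code{window} and subtracts,
#' per channel and epoch, the mean over the pre-stimulus baseline interval.
#' Onsets too close to the signal edges are skipped with a warning.
#'
#' @param x numeric matrix, channels x samples.
#' @param sampling_rate Hz.
#' @param onsets stimulus onset times in seconds (relative to sample 1 at
#'   time 0).
#' @param window epoch window in seconds relative to onset.
#' @param baseline baseline interval in seconds relative to onset.
#' @param stimulus,trial optional per-onset metadata carried into the result.
#' @return an \code{epoch_set} of the kept epochs; skipped onset indices are
#'   in \code{attr(, "skipped")}.
#' @export
epoch_and_baseline <- function(x, sampling_rate, onsets,
                               window = c(-0.2, 0.7), baseline = c(-0.2, 0),
                               stimulus = NULL, trial = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nS_sig <- ncol(x)
  times <- epoch_times(window, sampling_rate)
  nS <- length(times)
  off <- round(times * sampling_rate)      # sample offsets relative to onset
  onset_idx <- round(onsets * sampling_rate) + 1L
  ok <- onset_idx + off[1] >= 1 & onset_idx + off[nS] <= nS_sig
  if (any(!ok))
    warning(sum(!ok), " onset(s) too close to the signal edge were skipped")
  keep <- which(ok)
  eps <- array(0, dim = c(nrow(x), nS, length(keep)))
  for (i in seq_along(keep))
    eps[, , i] <- x[, onset_idx[keep[i]] + off, drop = FALSE]
  es <- epoch_set(eps, window, sampling_rate,
                  stimulus = if (!is.null(stimulus)) stimulus[keep],
                  trial = if (!is.null(trial)) trial[keep])
  es <- baseline_correct(es, baseline)
  attr(es, "skipped") <- which(!ok)
  es
}

#' Subtract the pre-stimulus baseline from each epoch
#'
#' @param es an \code{epoch_set}.
#' @param baseline interval in seconds; per channel and epoch, the mean over
#'   the samples in \code{[baseline[1], baseline[2])} is subtracted.
#' @return the baseline-corrected \code{epoch_set}.
#' @export
baseline_correct <- function(es, baseline = c(-0.2, 0)) {
  stopifnot(inherits(es, "epoch_set"))
  times <- epoch_times(es$window, es$sampling_rate)
  sel <- which(times >= baseline[1] & times < baseline[2])
  if (!length(sel))
    stop("baseline interval contains no samples", call. = FALSE)
  d <- dim(es$epochs)
  # per channel and epoch: mean over baseline samples
  bl <- apply(es$epochs[, sel, , drop = FALSE], c(1, 3), mean)
  es$epochs <- es$epochs - array(rep(bl, each = 1),
                                 dim = c(d[1], 1, d[3]))[, rep(1, d[2]), ,
                                                         drop = FALSE]
  es$baseline_corrected <- TRUE
  es
}

#' Variance-based outlier epoch rejection (calibration data only)
#'
#' An epoch is rejected when its variance exceeds \code{factor} (default 2.5)
#' times the threshold, the threshold being the \code{prob} (default 0.9)
#' quantile of all epoch variances. "Variance within an epoch" pools all
#' channel-sample values of the epoch by default; \code{method =
#' "per_channel_max"} instead uses the maximum per-channel variance. This rule
#' is meant for labeled calibration data; during online use all epochs are
#' kept (the caller decides where to apply it).
#'
#' @param es an \code{epoch_set} with at least 2 epochs (at least 10 for the
#'   percentile to be meaningful; fewer raises a warning).
#' @param factor multiplier on the variance threshold.
#' @param prob percentile defining the threshold (linear interpolation
#'   between order statistics, \code{quantile} type 7).
#' @param method pooled epoch variance (default) or max per-channel variance.
#' @return list with \code{kept} (an \code{epoch_set}) and \code{rejected}
#'   (integer indices into the input epochs).
#' @export
reject_outlier_epochs <- function(es, factor = 2.5, prob = 0.9,
                                  method = c("pooled", "per_channel_max")) {
  stopifnot(inherits(es, "epoch_set"))
  method <- match.arg(method)
  n <- dim(es$epochs)[3]
  if (n < 2) stop("need at least 2 epochs", call. = FALSE)
  if (n < 10) warning("fewer than 10 epochs: percentile threshold unreliable")
  v <- vapply(seq_len(n), function(i) {
    e <- es$epochs[, , i]
    if (method == "pooled") stats::var(as.numeric(e))
    else max(apply(e, 1, stats::var))
  }, numeric(1))
  thr <- stats::quantile(v, prob, type = 7, names = FALSE)
  rejected <- which(v > factor * thr)
  kept <- es
  if (length(rejected)) {
    keep <- setdiff(seq_len(n), rejected)
    kept$epochs <- es$epochs[, , keep, drop = FALSE]
    kept$stimulus <- es$stimulus[keep]
    kept$trial <- es$trial[keep]
  }
  list(kept = kept, rejected = rejected, threshold = thr, variances = v)
}

#' Variance-based outlier channel detection (offline utility)
#'
#' Flags channels whose variance across all epochs exceeds \code{factor}
#' times the \code{prob} quantile of channel variances. Not part of the
#' online path.
#'
#' @inheritParams reject_outlier_epochs
#' @return integer vector of flagged channel indices.
#' @export
flag_outlier_channels <- function(es, factor = 2.5, prob = 0.9) {
  stopifnot(inherits(es, "epoch_set"))
  v <- apply(es$epochs, 1, stats::var)
  thr <- stats::quantile(v, prob, type = 7, names = FALSE)
  which(v > factor * thr)
}

#' Interval-mean feature extraction
#'
#' Per epoch and channel, the mean potential within each interval; features
#' are concatenated channel-major (all intervals of channel 1, then channel
#' 2, ...). With 31 channels and the default 12 intervals this yields
#' 372-dimensional vectors. A sample at time t belongs to interval
#' \code{[a, b)} when \code{a <= t < b}.
#'
#' @param es a baseline-corrected \code{epoch_set}.
#' @param intervals n x 2 matrix of interval starts/ends in ms.
#' @return a \code{feature_matrix}: epochs x features numeric matrix with
#'   attributes \code{stimulus}, \code{trial}, \code{normalized},
#'   \code{has_bias}.
#' @export
extract_features <- function(es, intervals = default_intervals()) {
  stopifnot(inherits(es, "epoch_set"))
  t_ms <- round(epoch_times(es$window, es$sampling_rate) * 1000, 6)
  if (any(intervals[, 1] < t_ms[1]) ||
      any(intervals[, 2] > es$window[2] * 1000 + 1e-9))
    stop("feature intervals must lie within the epoch window", call. = FALSE)
  nI <- nrow(intervals)
  sel <- lapply(seq_len(nI), function(i)
    which(t_ms >= intervals[i, 1] & t_ms < intervals[i, 2]))
  if (any(vapply(sel, length, 1L) == 0))
    stop("an interval contains no samples at this sampling rate",
         call. = FALSE)
  d <- dim(es$epochs)
  nC <- d[1]; nE <- d[3]
  F <- matrix(0, nE, nC * nI)
  for (i in seq_len(nI)) {
    m <- apply(es$epochs[, sel[[i]], , drop = FALSE], c(1, 3), mean)  # nC x nE
    F[, (seq_len(nC) - 1) * nI + i] <- t(m)
  }
  feature_matrix(F, stimulus = es$stimulus, trial = es$trial)
}

#' Construct a feature matrix
#'
#' @param x epochs x features numeric matrix.
#' @param stimulus,trial per-epoch metadata.
#' @param normalized,has_bias flags.
#' @return a \code{feature_matrix}.
#' @export
feature_matrix <- function(x, stimulus = NULL, trial = NULL,
                           normalized = FALSE, has_bias = FALSE) {
  stopifnot(is.matrix(x))
  structure(x,
            stimulus = as.integer(stimulus %||% rep(NA_integer_, nrow(x))),
            trial = as.integer(trial %||% rep(1L, nrow(x))),
            normalized = normalized, has_bias = has_bias,
            class = c("feature_matrix", "matrix", "array"))
}

#' Per-trial feature normalization plus bias term
#'
#' For the unsupervised decoder: feature-wise, over the epochs of each trial,
#' subtract the mean and divide by the standard deviation, then append a
#' constant bias feature equal to 1 (so the classifier's offset is a weight).
#' A feature that is constant within a trial is set to 0 there (divide-by-zero
#' guard) with a warning.
#'
#' @param fm a \code{feature_matrix} (not yet normalized, no bias).
#' @return a \code{feature_matrix} with one extra (bias) column,
#'   \code{normalized = TRUE}.
#' @export
normalize_and_bias <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (isTRUE(attr(fm, "has_bias")))
    stop("features already carry a bias column", call. = FALSE)
  trial <- attr(fm, "trial")
  x <- unclass(fm); attributes(x) <- list(dim = dim(fm))
  warned <- FALSE
  for (tr in unique(trial)) {
    idx <- which(trial == tr)
    if (length(idx) < 2)
      stop("each trial needs at least 2 epochs to normalize", call. = FALSE)
    sub <- x[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, stats::sd)
    zero <- sdv == 0
    sdv[zero] <- 1
    sub <- sweep(sub, 2, mu, "-")
    sub <- sweep(sub, 2, sdv, "/")
    if (any(zero)) {
      sub[, zero] <- 0
      warned <- TRUE
    }
    x[idx, ] <- sub
  }
  if (warned)
    warning("constant feature(s) within a trial were set to 0")
  feature_matrix(cbind(x, 1), stimulus = attr(fm, "stimulus"), trial = trial,
                 normalized = TRUE, has_bias = TRUE)
}

#' Preprocess a synthetic session into per-trial features
#'
#' The online chain for generated sessions: baseline correction, interval-mean
#' features and (for the unsupervised path) per-trial normalization plus bias.
#' The generator emits 100 Hz epochs directly, so the causal low-pass of the
#' acquisition chain is not re-applied here; \code{\link{causal_lowpass}}
#' serves continuous or imported data.
#'
#' @param session a \code{bci_session}.
#' @param blocks block indices (default all).
#' @param normalize apply per-trial normalization + bias (unsupervised path);
#'   if FALSE, raw interval means (supervised path).
#' @param config a \code{bci_config}.
#' @return a \code{feature_matrix}; ground-truth attended stimuli per trial in
#'   \code{attr(, "attended")}.
#' @export
preprocess_session <- function(session, blocks = seq_len(session$n_blocks),
                               normalize = TRUE, config = bci_config()) {
  es <- session_epochs(session, blocks)
  es <- baseline_correct(es, config$baseline)
  fm <- extract_features(es, config$intervals)
  attended <- es$attended
  if (normalize) fm <- normalize_and_bias(fm)
  attr(fm, "attended") <- attended
  fm
}
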