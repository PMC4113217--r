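#' The 31-electrode montage (extended 10-20 names)
#'
#' Channel names used by the default synthetic template. Generation itself
#' ignores electrode geometry; names make spatial maps interpretable.
#'
#' @return character vector of 31 channel names.
#' @export
amuse_channels <- function() {
  c("Fp2", "F9", "F5", "F1", "F2", "F6", "F10", "FT7", "FC3", "FCz", "FC4",
    "FT8", "C5", "C1", "Cz", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P9", "P5", "P1", "P2", "P6", "P10", "POz", "O1", "O2")
}

# Smooth fronto-central / centro-parietal spatial weights for the two
# class-difference components. Generation ignores true electrode geometry;
# the names only make spatial maps interpretable.
spatial_profile <- function(channels, which = c("frontocentral",
                                                "centroparietal")) {
  which <- match.arg(which)
  w <- switch(which,
    frontocentral = c(
      Fp2 = 0.3, F9 = 0.2, F5 = 0.5, F1 = 0.8, F2 = 0.8, F6 = 0.5, F10 = 0.2,
      FT7 = 0.4, FC3 = 0.9, FCz = 1.0, FC4 = 0.9, FT8 = 0.4,
      C5 = 0.5, C1 = 0.9, Cz = 1.0, C2 = 0.9, C6 = 0.5,
      TP7 = 0.2, CP3 = 0.5, CPz = 0.6, CP4 = 0.5, TP8 = 0.2,
      P9 = 0.1, P5 = 0.2, P1 = 0.3, P2 = 0.3, P6 = 0.2, P10 = 0.1,
      POz = 0.2, O1 = 0.1, O2 = 0.1),
    centroparietal = c(
      Fp2 = 0.1, F9 = 0.1, F5 = 0.2, F1 = 0.3, F2 = 0.3, F6 = 0.2, F10 = 0.1,
      FT7 = 0.2, FC3 = 0.5, FCz = 0.6, FC4 = 0.5, FT8 = 0.2,
      C5 = 0.4, C1 = 0.8, Cz = 0.9, C2 = 0.8, C6 = 0.4,
      TP7 = 0.3, CP3 = 0.9, CPz = 1.0, CP4 = 0.9, TP8 = 0.3,
      P9 = 0.2, P5 = 0.5, P1 = 0.8, P2 = 0.8, P6 = 0.5, P10 = 0.2,
      POz = 0.6, O1 = 0.3, O2 = 0.3))
  out <- w[channels]
  out[is.na(out)] <- 0.3   # unknown channel names get a mid-level weight
  unname(out)
}

half_sine <- function(t_ms, from, to) {
  ifelse(t_ms >= from & t_ms <= to, sin(pi * (t_ms - from) / (to - from)), 0)
}

#' ERP template for synthetic target and non-target epochs
#'
#' The class difference carries the two attention-modulated components of
#' fast auditory oddball paradigms: a fronto-central negativity between 100
#' and 200 ms post stimulus (half-sine, peak at 150 ms, amplitude -1 before
#' scaling) and a slower centro-parietal positivity from 250 ms onwards
#' (half-sine over 250--600 ms, amplitude +1). Both classes additionally share
#' a small exogenous auditory response, so target and non-target epochs differ
#' only by \code{difference_amplitude * (target - nontarget)}.
#'
#' @param channels character vector of channel names (default the 31-channel
#'   montage).
#' @param sampling_rate Hz.
#' @param window epoch window in seconds, \code{c(-0.2, 0.7)}; samples are
#'   taken at \code{seq(window[1], window[2] - 1/rate, by = 1/rate)}.
#' @param difference_amplitude scale (arbitrary microvolt-like units) of the
#'   target-minus-nontarget difference; 0 makes the classes identical.
#' @return an \code{erp_template} with per-channel time courses
#'   \code{target} and \code{nontarget} (channels x samples).
#' @export
erp_template <- function(channels = amuse_channels(), sampling_rate = 100,
                         window = c(-0.2, 0.7), difference_amplitude = 0.35) {
  if (difference_amplitude < 0)
    stop("difference_amplitude must be >= 0", call. = FALSE)
  t_ms <- seq(window[1], window[2] - 1 / sampling_rate,
              by = 1 / sampling_rate) * 1000
  nC <- length(channels)
  common_sp <- spatial_profile(channels, "frontocentral")
  # exogenous response shared by both classes: N1-like dip then P2-like bump
  common_tc <- -0.4 * half_sine(t_ms, 60, 140) + 0.3 * half_sine(t_ms, 150, 260)
  nontarget <- outer(common_sp, common_tc)
  neg <- outer(spatial_profile(channels, "frontocentral"),
               -half_sine(t_ms, 100, 200))
  pos <- outer(spatial_profile(channels, "centroparietal"),
               half_sine(t_ms, 250, 600))
  diff_wave <- neg + pos
  structure(list(channels = channels, sampling_rate = sampling_rate,
                 window = window, times_ms = t_ms,
                 nontarget = nontarget, target = nontarget + diff_wave,
                 difference_amplitude = difference_amplitude,
                 n_samples = length(t_ms), n_channels = nC),
            class = "erp_template")
}

#' Structured noise model for synthetic epochs
#'
#' @param sd per-channel noise standard deviation (scalar or one per channel).
#' @param temporal \code{"ar1"} (EEG-like autocorrelation) or \code{"white"}.
#' @param ar_coef AR(1) coefficient when \code{temporal = "ar1"}.
#' @param spatial_cov optional channel covariance (symmetric positive
#'   semi-definite correlation structure mixed into the noise); NULL = none.
#' @param drift amplitude of an additive slow DC offset ramping linearly over
#'   the trials of a block (a simple non-stationarity control); 0 = none.
#' @param outlier_rate fraction of epochs turned into high-variance artifact
#'   epochs (noise sd scaled by \code{sqrt(outlier_scale)}).
#' @param outlier_scale variance multiplier of artifact epochs (default 20).
#' @return a \code{noise_model}.
#' @export
noise_model <- function(sd = 1, temporal = c("ar1", "white"), ar_coef = 0.8,
                        spatial_cov = NULL, drift = 0,
                        outlier_rate = 0, outlier_scale = 20) {
  temporal <- match.arg(temporal)
  if (any(sd < 0)) stop("noise sd must be >= 0", call. = FALSE)
  if (temporal == "ar1" && (ar_coef <= -1 || ar_coef >= 1))
    stop("ar_coef must lie in (-1, 1)", call. = FALSE)
  if (!is.null(spatial_cov)) {
    if (!isSymmetric(unname(spatial_cov)))
      stop("spatial_cov must be symmetric", call. = FALSE)
    ev <- eigen(spatial_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("spatial_cov must be positive semi-definite", call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]", call. = FALSE)
  structure(list(sd = sd, temporal = temporal, ar_coef = ar_coef,
                 spatial_cov = spatial_cov, drift = drift,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale),
            class = "noise_model")
}

# Draw noise for n_epochs epochs of one trial: channels x samples x epochs.
draw_noise <- function(noise, n_channels, n_samples, n_epochs) {
  n_col <- n_channels * n_epochs
  if (noise$temporal == "white") {
    e <- matrix(rnorm(n_samples * n_col), n_samples, n_col)
  } else {
    a <- noise$ar_coef
    innov <- matrix(rnorm(n_samples * n_col, sd = sqrt(1 - a^2)),
                    n_samples, n_col)
    innov[1, ] <- rnorm(n_col)          # stationary start: marginal sd 1
    e <- stats::filter(innov, a, method = "recursive")
    e <- matrix(as.numeric(e), n_samples, n_col)
  }
  x <- array(e, dim = c(n_samples, n_channels, n_epochs))
  x <- aperm(x, c(2, 1, 3))             # channels x samples x epochs
  x <- x * noise$sd                     # recycles over channels if vector
  if (!is.null(noise$spatial_cov)) {
    L <- t(chol(noise$spatial_cov + diag(1e-10, n_channels)))
    dim(x) <- c(n_channels, n_samples * n_epochs)
    x <- L %*% x
    dim(x) <- c(n_channels, n_samples, n_epochs)
  }
  x
}

#' Generate a synthetic multichannel ERP speller session
#'
#' Produces raw (not yet baseline-corrected) epochs for every stimulus
#' presentation of \code{n_blocks} blocks of \code{trials_per_block} trials
#' with the six-class trial structure: per trial an attended stimulus is drawn
#' uniformly, a pseudo-randomized sequence is generated, and each epoch is the
#' template's target or non-target waveform (difference scaled by the
#' template's \code{difference_amplitude}) plus a structured noise draw.
#'
#' @param template an \code{erp_template}.
#' @param noise a \code{noise_model}.
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param seed integer master seed; the session is deterministic given it.
#' @param config a \code{bci_config} supplying K, J and the SOA.
#' @return a \code{bci_session}: list with \code{blocks} (list of blocks,
#'   each a list of trials carrying \code{sequence}, \code{attended},
#'   \code{epochs} channels x samples x (K*J)), channel metadata and
#'   generator provenance (seed, parameters).
#' @export
generate_session <- function(template = erp_template(),
                             noise = noise_model(),
                             n_blocks = 6, trials_per_block = 30,
                             seed = 1, config = bci_config()) {
  stopifnot(inherits(template, "erp_template"), inherits(noise, "noise_model"))
  if (n_blocks < 1 || trials_per_block < 1)
    stop("n_blocks and trials_per_block must be >= 1", call. = FALSE)
  K <- config$K; J <- config$J
  nC <- template$n_channels; nS <- template$n_samples
  amp <- template$difference_amplitude
  diff_wave <- template$target - template$nontarget
  blocks <- vector("list", n_blocks)
  trial_counter <- 0L
  for (b in seq_len(n_blocks)) {
    blk_seed <- sub_seed(seed, paste0("generator-block-", b))
    blocks[[b]] <- with_seed(blk_seed, {
      lapply(seq_len(trials_per_block), function(ti) {
        trial_counter <<- trial_counter + 1L
        attended <- sample.int(K, 1)
        seqc <- generate_sequence(K, J, seed = NULL, soa = config$soa,
                                  stimulus_duration = config$stimulus_duration,
                                  trial_index = trial_counter)
        nE <- K * J
        eps <- draw_noise(noise, nC, nS, nE)
        if (noise$outlier_rate > 0) {
          art <- which(stats::runif(nE) < noise$outlier_rate)
          if (length(art))
            eps[, , art] <- eps[, , art] * sqrt(noise$outlier_scale)
        }
        is_target <- seqc$presentations == attended
        base_t <- template$nontarget + amp * diff_wave
        for (e in seq_len(nE))
          eps[, , e] <- eps[, , e] +
            (if (is_target[e]) base_t else template$nontarget)
        if (noise$drift != 0)
          eps <- eps + noise$drift * (ti - 1) / max(1, trials_per_block - 1)
        list(sequence = seqc, attended = attended, epochs = eps)
      })
    })
  }
  structure(list(blocks = blocks, channels = template$channels,
                 sampling_rate = template$sampling_rate,
                 window = template$window,
                 template = template, noise = noise,
                 seed = seed, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 config = config),
            class = "bci_session")
}

#' Generate sessions along a sweep of class-difference amplitudes
#'
#' Same seed and parameters for every session; only the template's
#' \code{difference_amplitude} changes, so separability comparisons across
#' amplitudes are paired at the noise level.
#'
#' @param template an \code{erp_template} (its amplitude is overridden).
#' @param noise a \code{noise_model}.
#' @param amplitudes numeric vector of non-negative amplitudes.
#' @param seed master seed shared by all sessions.
#' @param ... passed to \code{generate_session}.
#' @return a list of \code{bci_session}, one per amplitude.
#' @export
snr_sweep <- function(template = erp_template(), noise = noise_model(),
                      amplitudes = c(0, 0.5, 1), seed = 1, ...) {
  if (any(amplitudes < 0))
    stop("amplitudes must be >= 0", call. = FALSE)
  lapply(amplitudes, function(a) {
    tpl <- template
    tpl$difference_amplitude <- a
    generate_session(tpl, noise, seed = seed, ...)
  })
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf("<bci_session> %d block(s) x %d trials, %d channels @ %g Hz, seed %s\n",
              x$n_blocks, x$trials_per_block, length(x$channels),
              x$sampling_rate, format(x$seed)))
  cat(sprintf("  difference_amplitude %g, noise %s(sd %s)\n",
              x$template$difference_amplitude, x$noise$temporal,
              format(x$noise$sd[1])))
  invisible(x)
}

# Flatten one block (or trial subset) of a session into an epoch_set.
#' Collect the raw epochs of selected trials into an epoch set
#'
#' @param session a \code{bci_session}.
#' @param blocks block indices to include (default all).
#' @return an \code{epoch_set} (see \code{\link{epoch_and_baseline}}) carrying
#'   stimulus ids, trial membership and the ground-truth labels as attributes.
#' @export
session_epochs <- function(session, blocks = seq_len(session$n_blocks)) {
  stopifnot(inherits(session, "bci_session"))
  trials <- unlist(lapply(session$blocks[blocks], identity), recursive = FALSE)
  nE_per <- dim(trials[[1]]$epochs)[3]
  nC <- dim(trials[[1]]$epochs)[1]; nS <- dim(trials[[1]]$epochs)[2]
  n_total <- nE_per * length(trials)
  eps <- array(0, dim = c(nC, nS, n_total))
  stimulus <- integer(n_total); trial_id <- integer(n_total)
  attended <- integer(length(trials))
  for (i in seq_along(trials)) {
    idx <- ((i - 1) * nE_per + 1):(i * nE_per)
    eps[, , idx] <- trials[[i]]$epochs
    stimulus[idx] <- trials[[i]]$sequence$presentations
    trial_id[idx] <- i
    attended[i] <- trials[[i]]$attended
  }
  epoch_set(eps, window = session$window,
            sampling_rate = session$sampling_rate,
            stimulus = stimulus, trial = trial_id,
            channels = session$channels, attended = attended)
}
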