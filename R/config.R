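#' Default feature-extraction intervals
#'
#' Twelve post-stimulus intervals (ms): five short ones over 100--250 ms for
#' the early transient components and seven longer ones over 250--700 ms for
#' the slower positivity. Per channel, the mean potential in each interval is
#' one feature.
#'
#' @return a 12 x 2 matrix of interval starts and ends in milliseconds.
#' @export
default_intervals <- function() {
  m <- matrix(c(
    100, 130,
    130, 160,
    160, 190,
    190, 220,
    220, 250,
    250, 300,
    300, 350,
    350, 400,
    400, 450,
    450, 500,
    500, 600,
    600, 700
  ), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

#' Run configuration with paradigm and decoder defaults
#'
#' Bundles every tunable of the pipeline with its default: the AMUSE trial
#' structure (\code{K = 6} stimuli, \code{J = 15} iterations, SOA 0.175 s,
#' 40 ms tones, 30 trials per block), the decoder hyperparameters (5
#' classifier pairs, 5 EM iterations per trial, lambda initialized to 1, beta
#' initialized to 100 and capped at 200), the epoch window and baseline
#' interval, the feature intervals, and the outlier-rejection constants
#' (variance above 2.5 x the 90th-percentile threshold).
#'
#' @param ... named overrides of the defaults; unknown names are an error.
#' @return an object of class \code{bci_config} (a validated named list).
#' @export
bci_config <- function(...) {
  cfg <- list(
    K = 6L,
    J = 15L,
    soa = 0.175,
    stimulus_duration = 0.040,
    trials_per_block = 30L,
    n_pairs = 5L,
    em_iter = 5L,
    lambda_init = 1,
    beta_init = 100,
    beta_cap = 200,
    lambda_floor = 1e-10,
    mu_target = 1,
    mu_nontarget = -1,
    w_init_sd = NULL,            # NULL -> 1/sqrt(dim) at pool init
    window = c(-0.2, 0.7),
    baseline = c(-0.2, 0),
    intervals = default_intervals(),
    lowpass_cutoff = 40,
    outlier_factor = 2.5,
    outlier_prob = 0.9,
    bug_compat = FALSE,          # reproduce a known log-density constant error
    selection = "loglik"         # or "mse": expected-squared-error selection
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("config overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  validate_config(structure(cfg, class = "bci_config"))
}

#' Validate a run configuration
#'
#' @param cfg a \code{bci_config} or plain named list.
#' @return the validated config (invisibly usable), or an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  ref <- bci_config_names()
  unknown <- setdiff(names(cfg), ref)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(ref, names(cfg))
  if (length(missing))
    stop("missing config keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (cfg$K < 2) stop("K must be >= 2", call. = FALSE)
  if (cfg$J < 1) stop("J must be >= 1", call. = FALSE)
  if (cfg$soa <= 0) stop("soa must be positive", call. = FALSE)
  if (cfg$n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (cfg$em_iter < 0) stop("em_iter must be >= 0", call. = FALSE)
  if (cfg$lambda_init <= 0 || cfg$beta_init <= 0 || cfg$beta_cap <= 0)
    stop("precisions must be positive", call. = FALSE)
  if (cfg$mu_target == cfg$mu_nontarget)
    stop("mu_target and mu_nontarget must differ", call. = FALSE)
  if (length(cfg$window) != 2 || diff(cfg$window) <= 0)
    stop("window must be an increasing pair of seconds", call. = FALSE)
  iv <- cfg$intervals
  if (!is.matrix(iv) || ncol(iv) != 2 || any(iv[, 2] <= iv[, 1]))
    stop("intervals must be an n x 2 matrix of increasing ms pairs",
         call. = FALSE)
  if (any(iv / 1000 < cfg$window[1]) || any(iv / 1000 > cfg$window[2]))
    stop("feature intervals must lie within the epoch window", call. = FALSE)
  if (!cfg$selection %in% c("loglik", "mse"))
    stop("selection must be 'loglik' or 'mse'", call. = FALSE)
  structure(cfg, class = "bci_config")
}

bci_config_names <- function() {
  c("K", "J", "soa", "stimulus_duration", "trials_per_block", "n_pairs",
    "em_iter", "lambda_init", "beta_init", "beta_cap", "lambda_floor",
    "mu_target", "mu_nontarget", "w_init_sd", "window", "baseline",
    "intervals", "lowpass_cutoff", "outlier_factor", "outlier_prob",
    "bug_compat", "selection")
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return \code{read_config} returns a validated \code{bci_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$intervals))
    raw$intervals <- matrix(unlist(raw$intervals), ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("start", "end")))
  cfg <- bci_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown config keys in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a \code{bci_config}.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- unclass(cfg)
  out$intervals <- lapply(seq_len(nrow(cfg$intervals)),
                          function(i) as.numeric(cfg$intervals[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.bci_config <- function(x, ...) {
  cat("<bci_config>\n")
  cat(sprintf("  paradigm: K=%d stimuli, J=%d iterations, SOA %.3f s, %d trials/block\n",
              x$K, x$J, x$soa, x$trials_per_block))
  cat(sprintf("  decoder:  %d pairs, %d EM iter/trial, lambda0=%g, beta0=%g (cap %g)\n",
              x$n_pairs, x$em_iter, x$lambda_init, x$beta_init, x$beta_cap))
  cat(sprintf("  features: %d intervals, window [%g, %g] s\n",
              nrow(x$intervals), x$window[1], x$window[2]))
  invisible(x)
}
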