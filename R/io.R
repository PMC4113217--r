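SESSION_FORMAT_VERSION <- 1L

#' Write / read a session (or any package object) container file
#'
#' The canonical on-disk container is R serialization (RDS) wrapped in a
#' versioned envelope, so the round trip \code{read_session(write_session(x))}
#' is lossless and a reader refuses containers written by an unknown future
#' format version with a clear error instead of mis-parsing them.
#'
#' @param x the object to store (e.g. a \code{bci_session},
#'   \code{classifier_pool}, \code{lda_model} or \code{run_record}).
#' @param path file path.
#' @return \code{write_session} returns \code{path} invisibly;
#'   \code{read_session} returns the stored object.
#' @export
write_session <- function(x, path) {
  env <- list(format = "zerotrainbci-container",
              version = SESSION_FORMAT_VERSION,
              class = class(x)[1],
              payload = x)
  saveRDS(env, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  env <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable container file '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(env) || !identical(env$format, "zerotrainbci-container"))
    stop("not a zerotrainbci container: missing format tag in '", path, "'",
         call. = FALSE)
  if (is.null(env$version))
    stop("container '", path, "' has no version field", call. = FALSE)
  if (env$version > SESSION_FORMAT_VERSION)
    stop("container '", path, "' has format version ", env$version,
         "; this reader supports up to ", SESSION_FORMAT_VERSION,
         call. = FALSE)
  env$payload
}

#' Export a feature matrix as tidy CSV
#'
#' One row per epoch: trial, stimulus, label (if ground truth is available,
#' else NA) and the feature values.
#'
#' @param fm a \code{feature_matrix}.
#' @param path output CSV path.
#' @param attended optional per-trial ground-truth attended stimuli.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(fm, path, attended = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  attended <- attended %||% attr(fm, "attended")
  trial <- attr(fm, "trial"); stim <- attr(fm, "stimulus")
  label <- if (is.null(attended)) NA_character_
           else ifelse(stim == attended[trial], "target", "nontarget")
  X <- unclass_matrix(fm)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- data.frame(trial = trial, stimulus = stim, label = label, X,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
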