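#' zerotrainbci: calibration-free unsupervised ERP speller decoding
#'
#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a named sub-seed from a session seed
#'
#' All randomness in the package flows from one session seed through named
#' substreams (e.g. \code{"pool"}, \code{"generator"}, \code{"block3"}), so a
#' run is exactly replayable from \code{(config, seed)} while independent
#' components do not share a stream.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return an integer in \code{[0, 2^31 - 1)} usable with \code{set.seed}.
#' @export
sub_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
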