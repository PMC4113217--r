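#' Error-raster plot of online (and posthoc) selections
#'
#' One row per run, one cell per trial: filled dark cells mark selection
#' errors, light cells correct trials — the view that makes the unsupervised
#' warm-up visible as a front-loaded error band.
#'
#' @param correct a logical matrix, runs x trials (TRUE = correct), or a
#'   single logical vector.
#' @param main plot title.
#' @param runs optional run labels.
#' @return invisibly, the matrix plotted.
#' @export
plot_error_raster <- function(correct, main = "selection errors",
                              runs = NULL) {
  if (is.vector(correct)) correct <- matrix(correct, nrow = 1)
  nR <- nrow(correct); nT <- ncol(correct)
  graphics::image(x = seq_len(nT), y = seq_len(nR),
                  z = t(!correct)[, rev(seq_len(nR)), drop = FALSE],
                  col = c("#d9ead3", "#1c1c1c"), zlim = c(0, 1),
                  xlab = "trial", ylab = "run", axes = FALSE, main = main)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nR),
                 labels = rev(runs %||% seq_len(nR)), las = 1)
  graphics::box()
  invisible(correct)
}

#' Plot per-run selection accuracies by method
#'
#' Grouped points per run (e.g. subject or block) for each method, with the
#' chance level marked — the block-performance comparison view.
#'
#' @param acc a runs x methods numeric matrix of accuracies.
#' @param chance chance level to mark (default 1/6).
#' @param main plot title.
#' @return invisibly, \code{acc}.
#' @export
plot_block_accuracy <- function(acc, chance = 1 / 6,
                                main = "selection accuracy") {
  stopifnot(is.matrix(acc))
  nM <- ncol(acc)
  graphics::matplot(acc, type = "b", pch = seq_len(nM), lty = 1,
                    ylim = c(0, 1), xlab = "run", ylab = "accuracy",
                    main = main)
  graphics::abline(h = chance, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = colnames(acc) %||% paste("method", seq_len(nM)),
                   pch = seq_len(nM), col = seq_len(nM))
  invisible(acc)
}

#' Plot the sub-block performance course of an extended simulation
#'
#' Correct selections per 10-trial sub-block for each method over the
#' concatenated session — the extended-duration comparison view.
#'
#' @param record an \code{extended_record}.
#' @param main plot title.
#' @return invisibly, the sub-block accuracy matrix.
#' @export
plot_extended_course <- function(record, main = "extended session") {
  stopifnot(inherits(record, "extended_record"))
  acc <- record$subblock_accuracy * record$subblock_size
  graphics::matplot(acc, type = "b", pch = seq_len(ncol(acc)), lty = 1,
                    ylim = c(0, record$subblock_size),
                    xlab = sprintf("sub-block (%d trials each)",
                                   record$subblock_size),
                    ylab = "correct selections", main = main)
  graphics::abline(v = seq(0.5, nrow(acc) + 0.5, by = 3), lty = 3,
                   col = "grey")
  graphics::legend("bottomright", bty = "n", legend = colnames(acc),
                   pch = seq_len(ncol(acc)), col = seq_len(ncol(acc)))
  invisible(acc)
}
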