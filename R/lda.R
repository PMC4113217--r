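#' Ledoit-Wolf analytic shrinkage of a covariance matrix
#'
#' Shrinks the sample covariance toward the scaled identity (nu = mean
#' eigenvalue = tr(S)/D) with the analytically estimated optimal intensity:
#' the ratio of the estimated variance of the sample covariance entries to
#' the squared distance between sample covariance and target, clamped to
#' [0, 1].
#'
#' @param Z n x D matrix of (already centered) observations.
#' @param gamma optional fixed intensity in [0, 1]; NULL = analytic estimate.
#' @return list with \code{sigma} (the shrunk covariance), \code{gamma}
#'   (the intensity used) and \code{nu} (the target scale).
#' @export
shrink_covariance <- function(Z, gamma = NULL) {
  n <- nrow(Z); D <- ncol(Z)
  S <- crossprod(Z) / n
  nu <- sum(diag(S)) / D
  if (is.null(gamma)) {
    s2 <- sum(S^2)
    d2 <- s2 - 2 * nu * sum(diag(S)) + D * nu^2      # ||S - nu I||_F^2
    # (1/n^2) sum_i ||z_i z_i' - S||_F^2 = (1/n^2) sum_i (z_i'z_i)^2 - ||S||^2/n
    b2 <- sum(rowSums(Z^2)^2) / n^2 - s2 / n
    b2 <- min(b2, d2)
    gamma <- if (d2 > 0) b2 / d2 else 1
  }
  if (gamma < 0 || gamma > 1)
    stop("shrinkage intensity must lie in [0, 1]", call. = FALSE)
  sigma <- (1 - gamma) * S
  diag(sigma) <- diag(sigma) + gamma * nu
  list(sigma = sigma, gamma = gamma, nu = nu)
}

#' Train the supervised shrinkage-LDA baseline
#'
#' Binary linear discriminant analysis on labeled target/non-target epochs:
#' the pooled class-centered covariance is shrunk toward the scaled identity
#' with analytically estimated intensity, and the weight vector is
#' \eqn{w = \Sigma^{-1}(m_t - m_{nt})} with a bias centering the decision
#' value between the class means. Trained once on a labeled calibration block
#' (outlier-rejected epochs, un-normalized features without bias) and kept
#' fixed during online use.
#'
#' @param fm a \code{feature_matrix} (epochs x D, no bias column).
#' @param labels character or factor with levels "target"/"nontarget", or
#'   logical (TRUE = target), one per epoch.
#' @param gamma optional fixed shrinkage intensity; NULL = analytic.
#' @return an \code{lda_model}: list with \code{w}, \code{b}, \code{gamma},
#'   class means and the shrunk covariance.
#' @export
train_lda <- function(fm, labels, gamma = NULL) {
  X <- if (inherits(fm, "feature_matrix")) unclass_matrix(fm) else as.matrix(fm)
  is_t <- if (is.logical(labels)) labels else labels == "target"
  if (length(is_t) != nrow(X))
    stop("one label per epoch required", call. = FALSE)
  if (!any(is_t) || all(is_t))
    stop("both classes must be present", call. = FALSE)
  m_t <- colMeans(X[is_t, , drop = FALSE])
  m_nt <- colMeans(X[!is_t, , drop = FALSE])
  Z <- X
  Z[is_t, ] <- sweep(X[is_t, , drop = FALSE], 2, m_t, "-")
  Z[!is_t, ] <- sweep(X[!is_t, , drop = FALSE], 2, m_nt, "-")
  sh <- shrink_covariance(Z, gamma)
  w <- as.numeric(solve(sh$sigma, m_t - m_nt))
  b <- -sum(w * (m_t + m_nt)) / 2
  structure(list(w = w, b = b, gamma = sh$gamma, nu = sh$nu,
                 mean_target = m_t, mean_nontarget = m_nt,
                 sigma = sh$sigma),
            class = "lda_model")
}

#' Decision values of epochs under an LDA model
#'
#' @param model an \code{lda_model}.
#' @param X epochs x D matrix.
#' @return numeric vector of decision values (positive leans target).
#' @export
lda_scores <- function(model, X) {
  if (inherits(X, "feature_matrix")) X <- unclass_matrix(X)
  as.numeric(X %*% model$w + model$b)
}

#' Predict the attended stimulus of a trial with the supervised baseline
#'
#' Sums the decision values of each stimulus's epochs over the trial and
#' returns the argmax (ties to the lowest stimulus id). With equal epoch
#' counts per stimulus, summing and averaging are equivalent.
#'
#' @param model an \code{lda_model}.
#' @param F_trial epochs x D feature matrix of one trial (un-normalized,
#'   no bias).
#' @param stimulus presented stimulus id per epoch.
#' @param K number of stimuli.
#' @return the predicted stimulus id (integer).
#' @export
predict_trial <- function(model, F_trial, stimulus, K = 6) {
  s <- lda_scores(model, F_trial)
  tot <- rep(-Inf, K)
  agg <- rowsum(s, as.integer(stimulus))
  tot[as.integer(rownames(agg))] <- agg[, 1]
  as.integer(which.max(tot))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, shrinkage gamma %.3f (nu %.3g)\n",
              length(x$w), x$gamma, x$nu))
  invisible(x)
}
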