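#' Gaussian prior specification
#'
#' Zero-mean Gaussian prior over the full parameter vector (regression block
#' plus, for the Gaussian family, the log-variance nuisance), given by its
#' precision (inverse covariance) matrix \eqn{\Lambda}. A Gaussian prior with
#' precision \eqn{\lambda I} is the Bayesian counterpart of a ridge penalty
#' \eqn{\lambda \|\theta\|^2 / 2}.
#'
#' @param lambda scalar or per-parameter numeric vector of prior precisions
#'   (a diagonal \eqn{\Lambda}); ignored when \code{precision} is given.
#' @param names character vector of parameter names the prior applies to.
#' @param precision optional full symmetric positive-semidefinite precision
#'   matrix; its dimension must equal \code{length(names)}.
#' @return an object of class \code{bfi_prior} with elements \code{precision}
#'   (named matrix) and \code{names}.
#' @examples
#' bfi_prior(0.01, c("(Intercept)", "x1", "log_sigma2"))
#' @export
bfi_prior <- function(lambda = NULL, names = NULL, precision = NULL) {
  if (is.null(names) || !is.character(names) || anyDuplicated(names))
    stop("'names' must be a character vector of unique parameter names")
  p <- length(names)
  if (is.null(precision)) {
    if (is.null(lambda)) stop("supply 'lambda' or 'precision'")
    if (!is.numeric(lambda) || anyNA(lambda) || any(lambda < 0))
      stop("'lambda' must be non-negative numeric")
    if (length(lambda) == 1L) lambda <- rep(lambda, p)
    if (length(lambda) != p)
      stop("length of 'lambda' must be 1 or length(names)")
    precision <- diag(lambda, nrow = p)
  } else {
    precision <- as.matrix(precision)
    if (!all(dim(precision) == c(p, p)))
      stop("'precision' must be ", p, "x", p)
    if (max(abs(precision - t(precision))) > 1e-10 * max(1, max(abs(precision))))
      stop("'precision' must be symmetric")
    precision <- (precision + t(precision)) / 2
    ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(1, max(abs(ev))))
      stop("'precision' must be positive semidefinite")
  }
  dimnames(precision) <- list(names, names)
  structure(list(precision = precision, names = names), class = "bfi_prior")
}

#' @export
print.bfi_prior <- function(x, ...) {
  d <- diag(x$precision)
  off <- x$precision; diag(off) <- 0
  cat("Gaussian prior on", length(x$names), "parameters\n")
  if (all(off == 0)) {
    cat("  diagonal precision:", paste(signif(d, 4), collapse = ", "), "\n")
  } else {
    cat("  full precision matrix (showing diagonal):",
        paste(signif(d, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

# internal: reorder/validate a prior against a parameter-name vector
align_prior <- function(prior, names) {
  if (!inherits(prior, "bfi_prior")) stop("'prior' must be a bfi_prior")
  if (!setequal(prior$names, names))
    stop("prior parameter names do not match model parameters: prior has {",
         paste(prior$names, collapse = ", "), "}, model has {",
         paste(names, collapse = ", "), "}")
  idx <- match(names, prior$names)
  bfi_prior(names = names, precision = prior$precision[idx, idx, drop = FALSE])
}
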