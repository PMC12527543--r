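# Local MAP estimation: exact log posterior, analytic derivatives, Newton
# optimizer with step-halving, and the pooled-data reference fit.

# internal: split a named parameter vector into (beta, zeta) for a family
split_theta <- function(theta, family, X) {
  pn <- param_names(family, X)
  if (is.null(names(theta))) {
    if (length(theta) != length(pn))
      stop("parameter vector has length ", length(theta),
           ", expected ", length(pn))
    names(theta) <- pn
  }
  if (!identical(sort(names(theta)), sort(pn)))
    stop("parameter names do not match design columns: got {",
         paste(names(theta), collapse = ", "), "}, expected {",
         paste(pn, collapse = ", "), "}")
  theta <- theta[pn]
  list(theta = theta,
       beta = theta[colnames(X)],
       zeta = if (family$nuisance_dim > 0L) theta[[family$nuisance_name]] else NULL)
}

# internal: parameter names for a family/design: coefficients then nuisance
param_names <- function(family, X) {
  c(colnames(X), family$nuisance_name)
}

#' Log posterior density, gradient and Hessian
#'
#' Evaluates \eqn{\sum_i l(y_i \mid x_i^\top\beta, \zeta) -
#' \theta^\top\Lambda\theta/2} for one center, together with its exact
#' analytic gradient and Hessian in the \eqn{(\beta, \zeta)} parameterization
#' (\eqn{\zeta = \log\sigma^2} for the Gaussian family). Additive constants
#' (the \eqn{2\pi} terms) are dropped consistently, so differences of
#' returned values are exact.
#'
#' @param theta named numeric parameter vector (coefficient names matching
#'   the design columns, plus \code{"log_sigma2"} for the Gaussian family).
#' @param data a [local_dataset].
#' @param family a [bfi_family] or family name.
#' @param prior a [bfi_prior] over the same parameter names.
#' @return list with \code{value}, \code{gradient} (named vector) and
#'   \code{hessian} (named matrix).
#' @export
log_posterior <- function(theta, data, family, prior) {
  family <- as_bfi_family(family)
  family$validate_y(data$y)
  sp <- split_theta(theta, family, data$X)
  prior <- align_prior(prior, names(sp$theta))
  X <- data$X; y <- data$y
  eta <- drop(X %*% sp$beta)
  zeta <- sp$zeta

  ll <- sum(family$loglik(y, eta, zeta))
  d1 <- family$d_eta(y, eta, zeta)
  d2 <- family$d2_eta(y, eta, zeta)

  g_beta <- drop(crossprod(X, d1))
  H_bb <- crossprod(X, X * d2)

  if (family$nuisance_dim > 0L) {
    g <- c(g_beta, sum(family$d_zeta(y, eta, zeta)))
    dez <- family$d_eta_zeta(y, eta, zeta)
    H_bz <- drop(crossprod(X, dez))
    H <- rbind(cbind(H_bb, H_bz), c(H_bz, sum(family$d2_zeta(y, eta, zeta))))
  } else {
    g <- g_beta
    H <- H_bb
  }
  names(g) <- names(sp$theta)
  dimnames(H) <- list(names(sp$theta), names(sp$theta))

  Lam <- prior$precision
  list(value = ll - drop(sp$theta %*% Lam %*% sp$theta) / 2,
       gradient = g - drop(Lam %*% sp$theta),
       hessian = H - Lam)
}

#' Fit the local MAP estimate by Newton's method
#'
#' Maximizes the log posterior (ridge-penalized log-likelihood) over the full
#' \eqn{(\beta, \zeta)} vector with full Newton steps and step-halving line
#' search, until the max-abs gradient falls below \code{tol}. A strictly
#' positive-definite prior precision guarantees an interior maximum even
#' under logistic separation. The returned curvature is the exact negative
#' Hessian of the log posterior at the optimum, prior included — the
#' quantity a center shares for federated combination.
#'
#' @param data a [local_dataset].
#' @param family a [bfi_family] or family name.
#' @param prior a [bfi_prior] over the model's parameter names.
#' @param init optional named starting vector; defaults to zero coefficients
#'   (and \code{log(var(y))} for the Gaussian log-variance).
#' @param tol convergence tolerance on the max-abs gradient (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return an object of class \code{bfi_map} with elements \code{theta}
#'   (named MAP estimate), \code{curvature}, \code{n}, \code{prior},
#'   \code{family}, \code{center_id}, \code{converged}, \code{n_iter},
#'   \code{grad_norm}.
#' @export
map_fit <- function(data, family, prior, init = NULL,
                    tol = 1e-8, max_iter = 100L) {
  family <- as_bfi_family(family)
  family$validate_y(data$y)
  X <- data$X
  pn <- param_names(family, X)
  prior <- align_prior(prior, pn)

  # a direction the likelihood cannot see must carry prior mass: an all-zero
  # column, or a constant column collinear with the intercept
  lam_diag <- diag(prior$precision)
  has_icpt <- "(Intercept)" %in% colnames(X)
  for (j in seq_len(ncol(X))) {
    nm <- colnames(X)[j]
    degenerate <- all(X[, j] == 0) ||
      (nm != "(Intercept)" && stats::sd(X[, j]) == 0 && has_icpt)
    if (degenerate && lam_diag[nm] == 0)
      stop("flat direction: column '", nm,
           "' is constant and has zero prior precision")
  }

  if (is.null(init)) {
    theta <- stats::setNames(rep(0, length(pn)), pn)
    if (family$nuisance_dim > 0L) {
      v <- stats::var(data$y)
      theta[family$nuisance_name] <- if (is.finite(log(v))) log(v) else 0
    }
  } else {
    theta <- split_theta(init, family, X)$theta
  }

  lp <- log_posterior(theta, data, family, prior)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    g <- lp$gradient
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L

    A <- -lp$hessian
    # damped Cholesky: the prior usually makes A PD; far from the optimum the
    # gaussian-family zeta block can be indefinite
    damp <- 0
    repeat {
      R <- tryCatch(chol(A + diag(damp, nrow(A))), error = function(e) NULL)
      if (!is.null(R)) break
      damp <- if (damp == 0) 1e-8 * max(1, max(abs(diag(A)))) else damp * 10
      if (damp > 1e12 * max(1, max(abs(diag(A)))))
        stop("persistently non-positive-definite Hessian; posterior may be degenerate")
    }
    dir <- backsolve(R, forwardsolve(t(R), g))

    # accept any non-decrease up to rounding noise: near the optimum the
    # objective plateaus in double precision while Newton still contracts
    # the gradient quadratically
    slack <- 1e-12 * (abs(lp$value) + 1)
    step <- 1
    repeat {
      cand <- theta + step * dir
      lp_new <- tryCatch(log_posterior(cand, data, family, prior),
                         error = function(e) NULL)
      if (!is.null(lp_new) && is.finite(lp_new$value) &&
          lp_new$value >= lp$value - slack)
        break
      step <- step / 2
      if (step < 1e-12)
        stop("line search failed; posterior may be degenerate")
    }
    theta <- cand
    lp <- lp_new
  }
  if (!converged && max(abs(lp$gradient)) < tol) converged <- TRUE
  if (!converged)
    warning("map_fit did not converge after ", max_iter,
            " iterations (max-abs gradient ", signif(max(abs(lp$gradient)), 3),
            "); near-flat posterior?")

  structure(
    list(theta = theta, curvature = -lp$hessian, n = nrow(X), prior = prior,
         family = family, center_id = data$center_id,
         cluster = data$cluster, center_covariate = data$center_covariate,
         converged = converged, n_iter = iter,
         grad_norm = max(abs(lp$gradient)), log_posterior = lp$value),
    class = "bfi_map")
}

#' @export
print.bfi_map <- function(x, ...) {
  cat("Local MAP fit (", x$family$name, "), center ", x$center_id,
      ", n = ", x$n, "\n", sep = "")
  sds <- sqrt(diag(chol2inv(chol(x$curvature))))
  tab <- data.frame(estimate = x$theta, sd = sds)
  print(signif(tab, 5))
  cat(if (x$converged) "Converged" else "NOT converged",
      "in", x$n_iter, "Newton iterations; max|gradient| =",
      signif(x$grad_norm, 3), "\n")
  invisible(x)
}

#' Predict outcome means from a coefficient vector
#'
#' Applies the inverse link to \eqn{X\beta}: the identity for the Gaussian
#' family, the logistic function for binomial. Columns of \code{X} are
#' matched to coefficient names; a nuisance entry (\code{"log_sigma2"}) in
#' \code{theta} is ignored.
#'
#' @param theta named coefficient vector (may include the nuisance entry).
#' @param X design matrix with column names matching the coefficients.
#' @param family a [bfi_family] or family name.
#' @return numeric vector of predicted means (probabilities for binomial).
#' @export
predict_glm <- function(theta, X, family) {
  family <- as_bfi_family(family)
  X <- as.matrix(X)
  beta_names <- setdiff(names(theta), family$nuisance_name)
  if (!setequal(colnames(X), beta_names))
    stop("design columns {", paste(colnames(X), collapse = ", "),
         "} do not match coefficient names {",
         paste(beta_names, collapse = ", "), "}")
  eta <- drop(X[, beta_names, drop = FALSE] %*% theta[beta_names])
  family$linkinv(eta)
}

#' @export
#' @rdname predict_glm
#' @param object a fitted \code{bfi_map}.
#' @param newdata design matrix (or a [local_dataset]) to predict for.
#' @param ... unused.
predict.bfi_map <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "local_dataset")) newdata$X else newdata
  predict_glm(object$theta, X, object$family)
}

#' MAP fit on the pooled (fictive combined) data
#'
#' Stacks the centers' rows into one dataset and fits the MAP estimate under
#' the combined-analysis prior. This is the estimate federated combination
#' aims to reconstruct without ever forming the stacked data; it serves as
#' the reference in all performance comparisons.
#'
#' @param datasets list of [local_dataset] objects with identical design
#'   columns.
#' @param family a [bfi_family] or family name.
#' @param prior the combined-analysis [bfi_prior].
#' @param ... passed to [map_fit()].
#' @return a \code{bfi_map} with \code{center_id = "pooled"}.
#' @export
pooled_map_fit <- function(datasets, family, prior, ...) {
  stopifnot(length(datasets) >= 1L)
  cols <- colnames(datasets[[1]]$X)
  for (d in datasets)
    if (!identical(colnames(d$X), cols))
      stop("centers have different design columns; center ", d$center_id,
           " has {", paste(colnames(d$X), collapse = ", "), "}")
  X <- do.call(rbind, lapply(datasets, `[[`, "X"))
  y <- unlist(lapply(datasets, `[[`, "y"), use.names = FALSE)
  map_fit(local_dataset(X, y, center_id = "pooled"), family, prior, ...)
}
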