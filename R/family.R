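#' GLM family for federated MAP estimation
#'
#' Describes the per-observation log-density of the outcome given the linear
#' predictor, together with its exact first and second derivatives, in the
#' parameterization used throughout the package: regression coefficients
#' \eqn{\beta} on the linear-predictor scale and, for the Gaussian family, the
#' error variance as \eqn{\zeta = \log\sigma^2} so that Newton updates are
#' unconstrained and a mean-zero Gaussian prior can be placed on \eqn{\zeta}.
#'
#' Two families are provided:
#' \describe{
#'   \item{\code{"gaussian"}}{identity link, log-density
#'     \eqn{-\zeta/2 - (y-\eta)^2 e^{-\zeta}/2} (additive constants dropped).
#'     Has one nuisance parameter, named \code{"log_sigma2"}. Passing
#'     \code{fixed_sigma2} freezes the error variance at a known value, which
#'     removes the nuisance parameter and makes the log-likelihood exactly
#'     quadratic in \eqn{\beta}.}
#'   \item{\code{"binomial"}}{logit link, log-density
#'     \eqn{y\eta - \log(1+e^{\eta})}; no nuisance parameter.}
#' }
#'
#' The second derivative with respect to the linear predictor is non-positive
#' everywhere for both families, so the likelihood part of the posterior
#' curvature is positive semidefinite.
#'
#' @param name one of \code{"gaussian"}, \code{"binomial"}.
#' @param fixed_sigma2 optional known error variance for the Gaussian family;
#'   when supplied the family has no nuisance parameter.
#' @return an object of class \code{bfi_family}.
#' @examples
#' fam <- bfi_family("binomial")
#' fam$linkinv(0)  # 0.5
#' @export
bfi_family <- function(name = c("gaussian", "binomial"), fixed_sigma2 = NULL) {
  name <- match.arg(name)
  if (!is.null(fixed_sigma2)) {
    if (name != "gaussian")
      stop("'fixed_sigma2' only applies to the gaussian family")
    if (!is.numeric(fixed_sigma2) || length(fixed_sigma2) != 1L || fixed_sigma2 <= 0)
      stop("'fixed_sigma2' must be a single positive number")
  }

  fam <- switch(name,
    gaussian = {
      if (is.null(fixed_sigma2)) {
        list(
          name = "gaussian", link = "identity", nuisance_dim = 1L,
          nuisance_name = "log_sigma2",
          # l(y | eta, zeta) with zeta = log sigma^2; 2*pi constants dropped
          loglik   = function(y, eta, zeta) -zeta / 2 - (y - eta)^2 * exp(-zeta) / 2,
          d_eta    = function(y, eta, zeta) (y - eta) * exp(-zeta),
          d2_eta   = function(y, eta, zeta) rep(-exp(-zeta), length(y)),
          d_zeta   = function(y, eta, zeta) -0.5 + (y - eta)^2 * exp(-zeta) / 2,
          d2_zeta  = function(y, eta, zeta) -(y - eta)^2 * exp(-zeta) / 2,
          d_eta_zeta = function(y, eta, zeta) -(y - eta) * exp(-zeta),
          linkinv  = identity,
          validate_y = function(y) {
            if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
              stop("gaussian outcome must be finite numeric")
            invisible(TRUE)
          }
        )
      } else {
        zeta0 <- log(fixed_sigma2)
        list(
          name = "gaussian", link = "identity", nuisance_dim = 0L,
          nuisance_name = character(0), fixed_sigma2 = fixed_sigma2,
          loglik   = function(y, eta, zeta = NULL) -(y - eta)^2 * exp(-zeta0) / 2,
          d_eta    = function(y, eta, zeta = NULL) (y - eta) * exp(-zeta0),
          d2_eta   = function(y, eta, zeta = NULL) rep(-exp(-zeta0), length(y)),
          linkinv  = identity,
          validate_y = function(y) {
            if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
              stop("gaussian outcome must be finite numeric")
            invisible(TRUE)
          }
        )
      }
    },
    binomial = list(
      name = "binomial", link = "logit", nuisance_dim = 0L,
      nuisance_name = character(0),
      loglik   = function(y, eta, zeta = NULL) y * eta - log1p(exp(eta)),
      d_eta    = function(y, eta, zeta = NULL) y - stats::plogis(eta),
      d2_eta   = function(y, eta, zeta = NULL) {
        p <- stats::plogis(eta)
        -p * (1 - p)
      },
      linkinv  = stats::plogis,
      validate_y = function(y) {
        if (!all(y %in% c(0, 1)))
          stop("binomial outcome must be coded 0/1")
        invisible(TRUE)
      }
    )
  )
  class(fam) <- "bfi_family"
  fam
}

#' @export
print.bfi_family <- function(x, ...) {
  cat("GLM family:", x$name, "(", x$link, "link )\n")
  if (x$nuisance_dim > 0L)
    cat("  nuisance parameter:", x$nuisance_name, "\n")
  if (!is.null(x$fixed_sigma2))
    cat("  error variance fixed at", x$fixed_sigma2, "\n")
  invisible(x)
}

# internal: resolve a family given by name or object
as_bfi_family <- function(family) {
  if (inherits(family, "bfi_family")) return(family)
  if (is.character(family)) return(bfi_family(family))
  stop("'family' must be a bfi_family object or a family name")
}
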