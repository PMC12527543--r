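# Credible intervals, Wald tests, and the between-center heterogeneity
# diagnostics built from them.

# extract (estimate, sd) for one named parameter from a fit or estimate
est_sd <- function(object, parameter) {
  if (inherits(object, "bfi_estimate")) {
    th <- object$theta; sds <- object$sd
  } else if (inherits(object, "bfi_map")) {
    th <- object$theta
    sds <- stats::setNames(sqrt(diag(chol2inv(chol(object$curvature)))),
                           names(th))
  } else if (inherits(object, "local_summary")) {
    th <- object$theta_hat
    sds <- stats::setNames(sqrt(diag(chol2inv(chol(object$curvature)))),
                           names(th))
  } else stop("need a bfi_estimate, bfi_map or local_summary")
  if (!parameter %in% names(th))
    stop("unknown parameter '", parameter, "'; available: ",
         paste(names(th), collapse = ", "))
  c(estimate = unname(th[[parameter]]), sd = unname(sds[[parameter]]))
}

new_cred_int <- function(parameter, estimate, sd, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(parameter = parameter, estimate = estimate, sd = sd,
                 level = level, lower = estimate - z * sd,
                 upper = estimate + z * sd),
            class = "cred_int")
}

#' @export
print.cred_int <- function(x, ...) {
  cat(sprintf("%g%% credible interval for %s: %.5g  [%.5g, %.5g]  (sd %.4g)\n",
              100 * x$level, x$parameter, x$estimate, x$lower, x$upper, x$sd))
  invisible(x)
}

#' Approximate credible interval for one parameter
#'
#' From the Gaussian posterior approximation: \eqn{\hat\theta_k \pm
#' z_{\alpha/2}\,\mathrm{sd}_k}, with \eqn{\mathrm{sd}_k} the square root of
#' the k-th diagonal element of the inverse curvature.
#'
#' @param object a \code{bfi_estimate}, \code{bfi_map} or
#'   \code{local_summary}.
#' @param parameter parameter name (stacked name for heterogeneous
#'   estimates); \code{NULL} returns a data frame over all parameters.
#' @param level credibility level in (0, 1), default 0.95.
#' @return a \code{cred_int} object (or a data frame when
#'   \code{parameter = NULL}).
#' @export
credible_interval <- function(object, parameter = NULL, level = 0.95) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1))
    stop("'level' must be in (0, 1)")
  if (is.null(parameter)) {
    nms <- if (inherits(object, "bfi_estimate")) object$names
           else names(object$theta %||% object$theta_hat)
    rows <- lapply(nms, function(nm) {
      ci <- credible_interval(object, nm, level)
      data.frame(parameter = nm, estimate = ci$estimate, sd = ci$sd,
                 lower = ci$lower, upper = ci$upper)
    })
    out <- do.call(rbind, rows)
    attr(out, "level") <- level
    return(out)
  }
  es <- est_sd(object, parameter)
  new_cred_int(parameter, es[["estimate"]], es[["sd"]], level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald test for one parameter
#'
#' \eqn{z = (\hat\theta_k - \theta_0)/\mathrm{sd}_k}, with two-sided p-value
#' \eqn{2(1 - \Phi(|z|))} from the Gaussian posterior approximation.
#'
#' @inheritParams credible_interval
#' @param null_value hypothesized value (default 0).
#' @return list with \code{z}, \code{p}, \code{estimate}, \code{sd},
#'   \code{null_value}.
#' @export
wald_test <- function(object, parameter, null_value = 0) {
  es <- est_sd(object, parameter)
  z <- (es[["estimate"]] - null_value) / es[["sd"]]
  structure(list(parameter = parameter, estimate = es[["estimate"]],
                 sd = es[["sd"]], null_value = null_value,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "bfi_wald")
}

#' @export
print.bfi_wald <- function(x, ...) {
  cat(sprintf("Wald test %s = %g: z = %.4g, p = %.4g\n",
              x$parameter, x$null_value, x$z, x$p))
  invisible(x)
}

#' Credible interval for the difference of a parameter between two centers
#'
#' Compares a parameter's local MAP estimates in two centers:
#' \eqn{(\hat\theta_k - \hat\theta_l) \pm z_{\alpha/2}
#' \sqrt{sd_k^2 + sd_l^2}}, using each center's own curvature-based standard
#' deviation; the two estimators are independent because the centers' data
#' are. An interval excluding zero suggests that the parameter genuinely
#' differs between the centers.
#'
#' @param summary_k,summary_l [local_summary] objects for the two centers,
#'   fitted with the same model.
#' @param parameter parameter name.
#' @param level credibility level (default 0.95).
#' @return a \code{cred_int} for the difference (center k minus center l).
#' @export
diff_credible_interval <- function(summary_k, summary_l, parameter,
                                   level = 0.95) {
  if (!identical(summary_k$family, summary_l$family) ||
      !setequal(summary_k$names, summary_l$names))
    stop("the two centers did not fit the same model")
  ek <- est_sd(summary_k, parameter)
  el <- est_sd(summary_l, parameter)
  new_cred_int(
    paste0(parameter, ": ", summary_k$center_id, " - ", summary_l$center_id),
    ek[["estimate"]] - el[["estimate"]],
    sqrt(ek[["sd"]]^2 + el[["sd"]]^2),
    level)
}

#' Leave-one-out heterogeneity check
#'
#' For each center \eqn{l} (or one requested center), combines the remaining
#' centers' summaries under homogeneity and forms the credible interval for
#' the difference between the leave-one-out federated estimate and center
#' l's local MAP estimate, with standard deviation
#' \eqn{\sqrt{sd_{BFI(-l)}^2 + sd_l^2}}. An interval excluding zero flags the
#' center as incompatible with the others for that parameter. Intervals are
#' reported per comparison without multiplicity correction; the number of
#' comparisons is included in the result.
#'
#' @param summaries list of at least two [local_summary] objects.
#' @param prior the combined-analysis [bfi_prior] used for each leave-one-out
#'   combination.
#' @param parameter parameter name to check.
#' @param level credibility level (default 0.95).
#' @param center optional single center id; default checks every center.
#' @return data frame, one row per checked center: \code{center_id},
#'   \code{difference} (BFI-without-center minus center), \code{sd},
#'   \code{lower}, \code{upper}, \code{flagged}; the number of comparisons is
#'   attached as attribute \code{"comparisons"}.
#' @export
loo_heterogeneity_check <- function(summaries, prior, parameter,
                                    level = 0.95, center = NULL) {
  summaries <- validate_summaries(summaries)
  if (length(summaries) < 2L)
    stop("leave-one-out check needs at least two centers")
  ids <- vapply(summaries, `[[`, character(1), "center_id")
  check_ids <- if (is.null(center)) ids else {
    if (!center %in% ids) stop("unknown center '", center, "'")
    center
  }
  rows <- lapply(check_ids, function(cid) {
    rest <- summaries[ids != cid]
    est <- bfi_combine(rest, prior)
    eb <- est_sd(est, parameter)
    el <- est_sd(summaries[[which(ids == cid)]], parameter)
    d <- eb[["estimate"]] - el[["estimate"]]
    s <- sqrt(eb[["sd"]]^2 + el[["sd"]]^2)
    z <- stats::qnorm(1 - (1 - level) / 2)
    data.frame(center_id = cid, difference = d, sd = s,
               lower = d - z * s, upper = d + z * s,
               flagged = (d - z * s > 0) | (d + z * s < 0))
  })
  out <- do.call(rbind, rows)
  attr(out, "comparisons") <- nrow(out)
  attr(out, "parameter") <- parameter
  attr(out, "level") <- level
  out
}
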