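# One-shot baseline estimators the federated estimate is compared against.

#' Sample-size weighted average (WAV) of local MAP estimates
#'
#' The weighted average estimator with weights \eqn{w_\ell = n_\ell / n}:
#' shared parameters are averaged over all centers; a cluster-specific
#' parameter is averaged over that cluster's centers only; a center-specific
#' parameter is simply that center's own local MAP estimate. The log-variance
#' nuisance is averaged on its (log) scale, like every other coordinate of
#' the parameter vector. Output names follow the same stacked convention as
#' [bfi_combine()], so the two estimators are directly comparable.
#'
#' @param summaries list of [local_summary] objects.
#' @param spec a [het_spec()] or \code{NULL} (fully shared model).
#' @return an object of class \code{baseline_estimate} with elements
#'   \code{theta} (named stacked vector), \code{method = "wav"},
#'   \code{weights}.
#' @export
wav_combine <- function(summaries, spec = NULL) {
  summaries <- validate_summaries(summaries)
  spec <- if (is.null(spec)) het_spec() else spec
  pn <- summaries[[1]]$names
  ids <- vapply(summaries, `[[`, character(1), "center_id")
  ns <- vapply(summaries, `[[`, numeric(1), "n")
  names(ns) <- ids
  layout <- stacked_layout(pn, ids, spec)
  Th <- do.call(rbind, lapply(summaries, `[[`, "theta_hat"))  # L x p
  rownames(Th) <- ids

  theta <- stats::setNames(numeric(length(layout$stacked)), layout$stacked)
  for (i in seq_along(layout$stacked)) {
    nm <- layout$orig[i]; u <- layout$unit[i]
    members <- if (u == "") {
      ids                                   # shared: all centers
    } else if (nm %in% layout$center_specific) {
      u                                     # that center's own estimate
    } else {
      ids[unname(spec$cluster_map[ids]) == u]  # centers in the cluster
    }
    if (!length(members)) stop("empty cluster '", u, "'")
    w <- ns[members] / sum(ns[members])
    theta[i] <- sum(w * Th[members, nm])
  }
  structure(list(theta = theta, method = "wav",
                 weights = ns / sum(ns), centers = ids, spec = spec),
            class = "baseline_estimate")
}

#' Single-center baseline estimate
#'
#' The local MAP estimate of the center with the largest sample size (ties
#' broken by lexicographic center id). Only defined when all parameters are
#' shared: with center- or cluster-specific parameters a single center cannot
#' estimate the other units' copies.
#'
#' @param summaries list of [local_summary] objects.
#' @param spec a [het_spec()] or \code{NULL}; must be empty.
#' @return a \code{baseline_estimate} with \code{method = "single_center"}.
#' @export
single_center_estimate <- function(summaries, spec = NULL) {
  if (!is_empty_spec(spec))
    stop("the single-center estimator cannot be defined with center- or ",
         "cluster-specific parameters")
  summaries <- validate_summaries(summaries)
  ids <- vapply(summaries, `[[`, character(1), "center_id")
  ns <- vapply(summaries, `[[`, numeric(1), "n")
  ord <- order(-ns, ids, method = "radix")
  pick <- ord[1]
  structure(list(theta = summaries[[pick]]$theta_hat,
                 method = "single_center",
                 center_id = unname(ids[pick]),
                 weights = stats::setNames(1, ids[pick]), centers = ids),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat("Baseline estimate (", x$method,
      if (x$method == "single_center") paste0(", center ", x$center_id), ")\n",
      sep = "")
  print(signif(x$theta, 5))
  invisible(x)
}
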