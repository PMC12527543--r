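# One-shot federated combination. Each center shares only (theta_hat, A_hat,
# Lambda, n); the server maximizes the sum of the centers' second-order
# posterior expansions after replacing the sum of local priors by the
# combined-analysis prior. Heterogeneity (center-specific, cluster-specific
# parameters) is expressed by mapping each center's expansion onto a stacked
# parameter vector; the resulting block-arrow quadratic system is solved by a
# dense Cholesky factorization.

# C-locale sort, independent of LC_COLLATE
sort_c <- function(x) x[order(x, method = "radix")]

#' Heterogeneity specification
#'
#' Declares which parameters of the aggregated model are allowed to differ
#' per center, which differ per cluster of centers, and how centers map to
#' clusters. An empty specification is the homogeneous model. Putting the
#' nuisance name \code{"log_sigma2"} in \code{center_specific} gives each
#' center its own error variance; putting a covariate name there gives a
#' center-by-covariate interaction.
#'
#' @param center_specific character vector of parameter names allowed to
#'   differ per center (e.g. \code{"(Intercept)"}).
#' @param cluster_specific character vector of parameter names that differ
#'   per cluster.
#' @param cluster_map named character vector mapping center ids to cluster
#'   labels; required when \code{cluster_specific} is non-empty.
#' @return an object of class \code{het_spec}.
#' @export
het_spec <- function(center_specific = character(),
                     cluster_specific = character(),
                     cluster_map = NULL) {
  center_specific <- as.character(center_specific)
  cluster_specific <- as.character(cluster_specific)
  if (length(intersect(center_specific, cluster_specific)))
    stop("a parameter cannot be both center-specific and cluster-specific")
  if (length(cluster_specific) && is.null(cluster_map))
    stop("'cluster_map' (center id -> cluster label) is required when ",
         "parameters are cluster-specific")
  if (!is.null(cluster_map)) {
    if (is.null(names(cluster_map)))
      stop("'cluster_map' must be a named vector (names are center ids)")
    cluster_map <- stats::setNames(as.character(cluster_map), names(cluster_map))
  }
  structure(list(center_specific = sort_c(center_specific),
                 cluster_specific = sort_c(cluster_specific),
                 cluster_map = cluster_map),
            class = "het_spec")
}

is_empty_spec <- function(spec) {
  is.null(spec) ||
    (length(spec$center_specific) == 0L && length(spec$cluster_specific) == 0L)
}

#' @export
print.het_spec <- function(x, ...) {
  if (is_empty_spec(x)) {
    cat("Homogeneous model (no center- or cluster-specific parameters)\n")
  } else {
    if (length(x$center_specific))
      cat("Center-specific: ", paste(x$center_specific, collapse = ", "), "\n")
    if (length(x$cluster_specific))
      cat("Cluster-specific:", paste(x$cluster_specific, collapse = ", "),
          "(", length(unique(x$cluster_map)), "clusters )\n")
  }
  invisible(x)
}

#' Build the shareable one-shot summary of a local fit
#'
#' Packages exactly the quantities a center sends to the central server: the
#' MAP estimate, the posterior curvature (negative Hessian at the MAP, prior
#' included), the local prior precision, the sample size, and center
#' metadata. The payload size is O(p^2), independent of the number of
#' subjects; no subject-level data appear in it.
#'
#' @param fit a converged [map_fit()] result.
#' @param moments optional per-covariate moments for pooled standardization:
#'   a named list, each element a list with \code{n}, \code{mean}, \code{sd}.
#' @return an object of class \code{local_summary}.
#' @export
make_local_summary <- function(fit, moments = NULL) {
  if (!inherits(fit, "bfi_map")) stop("'fit' must come from map_fit()")
  if (!fit$converged)
    stop("refusing to share an unconverged fit (max|gradient| = ",
         signif(fit$grad_norm, 3), ")")
  s <- structure(
    list(schema_version = "1",
         center_id = fit$center_id,
         family = fit$family$name,
         fixed_sigma2 = fit$family$fixed_sigma2,
         names = names(fit$theta),
         n = as.numeric(fit$n),
         theta_hat = fit$theta,
         curvature = fit$curvature,
         prior_precision = fit$prior$precision,
         cluster = fit$cluster,
         center_covariate = fit$center_covariate,
         moments = moments),
    class = "local_summary")
  validate_summaries(list(s))[[1]]
}

#' @export
print.local_summary <- function(x, ...) {
  cat("Local summary, center ", x$center_id, " (", x$family, "), n = ", x$n,
      "\n  parameters: ", paste(x$names, collapse = ", "), "\n", sep = "")
  if (!is.null(x$cluster)) cat("  cluster:", x$cluster, "\n")
  invisible(x)
}

#' Validate and align a set of local summaries
#'
#' Checks that the summaries come from the same model (same family, same
#' parameter-name set — reordering permuted parameter vectors to a common
#' order), that each curvature is symmetric positive definite, and that the
#' likelihood part of each curvature (curvature minus prior precision) is
#' positive semidefinite. Returns the aligned summaries.
#'
#' @param summaries list of [make_local_summary()] payloads.
#' @return the input list, with every summary's parameters in the first
#'   summary's order.
#' @export
validate_summaries <- function(summaries) {
  if (!length(summaries)) stop("need at least one summary")
  for (s in summaries) {
    if (!inherits(s, "local_summary")) stop("not a local_summary object")
    if (!identical(s$schema_version, "1"))
      stop("unknown summary schema version '", s$schema_version, "'")
  }
  fam <- summaries[[1]]$family
  ref_names <- summaries[[1]]$names
  ids <- vapply(summaries, `[[`, character(1), "center_id")
  if (anyDuplicated(ids))
    stop("duplicate center ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  out <- lapply(summaries, function(s) {
    if (!identical(s$family, fam))
      stop("family mismatch: center ", s$center_id, " fitted '", s$family,
           "', expected '", fam, "'")
    if (!setequal(s$names, ref_names))
      stop("parameter-name mismatch: center ", s$center_id, " has {",
           paste(s$names, collapse = ", "), "}, expected {",
           paste(ref_names, collapse = ", "), "}")
    idx <- match(ref_names, s$names)
    s$names <- ref_names
    s$theta_hat <- stats::setNames(s$theta_hat[idx], ref_names)
    s$curvature <- s$curvature[idx, idx, drop = FALSE]
    s$prior_precision <- s$prior_precision[idx, idx, drop = FALSE]
    dimnames(s$curvature) <- dimnames(s$prior_precision) <-
      list(ref_names, ref_names)
    A <- s$curvature
    if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
      stop("curvature of center ", s$center_id, " is not symmetric")
    if (is.null(tryCatch(chol(A), error = function(e) NULL)))
      stop("curvature of center ", s$center_id, " is not positive definite")
    M <- A - s$prior_precision
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(1, max(abs(ev))))
      stop("curvature minus prior of center ", s$center_id,
           " is not positive semidefinite; summary looks inconsistent")
    s
  })
  names(out) <- ids
  out
}

# ---- stacked-parameter bookkeeping -----------------------------------------

# stacked name for a copy of parameter `nm` belonging to unit `u`
stacked_name <- function(nm, u) {
  if (!length(nm) || !length(u)) return(character(0))
  paste0(nm, "[", u, "]")
}

# For each center, the map from original parameter names to stacked names,
# plus the stacked-name vector in the fixed output convention:
# center blocks (centers sorted), then cluster blocks (labels sorted), then
# shared parameters; alphabetical within each block.
stacked_layout <- function(param_names, centers, spec) {
  spec <- if (is.null(spec)) het_spec() else spec
  cs <- intersect(sort_c(param_names), spec$center_specific)
  ks <- intersect(sort_c(param_names), spec$cluster_specific)
  if (length(setdiff(spec$center_specific, param_names)))
    stop("center-specific parameter(s) not in the model: ",
         paste(setdiff(spec$center_specific, param_names), collapse = ", "))
  if (length(setdiff(spec$cluster_specific, param_names)))
    stop("cluster-specific parameter(s) not in the model: ",
         paste(setdiff(spec$cluster_specific, param_names), collapse = ", "))
  shared <- sort_c(setdiff(param_names, c(cs, ks)))
  centers <- sort_c(centers)
  clusters <- character(0)
  if (length(ks)) {
    missing_map <- setdiff(centers, names(spec$cluster_map))
    if (length(missing_map))
      stop("no cluster label for center(s): ",
           paste(missing_map, collapse = ", "))
    clusters <- sort_c(unique(unname(spec$cluster_map[centers])))
  }
  stacked <- c(
    unlist(lapply(centers, function(cid) stacked_name(cs, cid)),
           use.names = FALSE),
    unlist(lapply(clusters, function(k) stacked_name(ks, k)),
           use.names = FALSE),
    shared)
  # per-center map original name -> stacked name
  maps <- stats::setNames(lapply(centers, function(cid) {
    m <- param_names
    m[match(cs, param_names)] <- stacked_name(cs, cid)
    if (length(ks))
      m[match(ks, param_names)] <- stacked_name(ks, spec$cluster_map[[cid]])
    stats::setNames(m, param_names)
  }), centers)
  # unit tag per stacked coordinate ("" = shared)
  unit <- rep("", length(stacked))
  orig <- stacked
  is_copy <- grepl("\\[.*\\]$", stacked)
  unit[is_copy] <- sub("^.*\\[(.*)\\]$", "\\1", stacked[is_copy])
  orig[is_copy] <- sub("\\[.*\\]$", "", stacked[is_copy])
  list(stacked = stacked, maps = maps, orig = orig, unit = unit,
       centers = centers, clusters = clusters,
       center_specific = cs, cluster_specific = ks, shared = shared)
}

# Map the combined prior (given over the original parameter names) onto the
# stacked vector: each unit's copies get the parameter's marginal precision
# sub-block; cross-precision between coordinates living in different units is
# required to be zero (it has no well-defined placement over copies).
stacked_prior_precision <- function(prior, layout, param_names) {
  prior <- align_prior(prior, param_names)
  Lam <- prior$precision
  q <- length(layout$stacked)
  out <- matrix(0, q, q, dimnames = list(layout$stacked, layout$stacked))
  for (i in seq_len(q)) for (j in seq_len(q)) {
    lij <- Lam[layout$orig[i], layout$orig[j]]
    if (layout$unit[i] == layout$unit[j]) {
      out[i, j] <- lij
    } else if (layout$orig[i] == layout$orig[j]) {
      # copies of the same parameter in different units: independent under
      # the combined prior, each with the parameter's marginal precision
      next
    } else if (lij != 0) {
      stop("combined prior has non-zero precision between '", layout$orig[i],
           "' and '", layout$orig[j], "', which live in different blocks of ",
           "the heterogeneous model; use a block-diagonal (e.g. diagonal) prior")
    }
  }
  out
}

#' Accumulate local summaries into a combination state
#'
#' Builds (or updates) the sufficient state of the federated combination: the
#' sum of the centers' prior-corrected curvature contributions and linear
#' terms, mapped onto the stacked parameter vector of the requested
#' heterogeneity structure. The state is additive — accumulating centers in
#' any order or grouping, or adding a late center to a stored state, yields
#' exactly the same final estimate as a from-scratch combination.
#'
#' @param summaries list of [local_summary] objects.
#' @param spec a [het_spec()] (or \code{NULL} for the homogeneous model).
#' @param state optional previous \code{bfi_state} to update.
#' @return an object of class \code{bfi_state}.
#' @export
bfi_accumulate <- function(summaries, spec = NULL, state = NULL) {
  summaries <- validate_summaries(summaries)
  spec <- if (is.null(spec)) het_spec() else spec
  pn <- summaries[[1]]$names
  ids <- vapply(summaries, `[[`, character(1), "center_id")

  if (is.null(state)) {
    centers_df <- data.frame(center_id = character(0), n = integer(0),
                             stringsAsFactors = FALSE)
    prev_ids <- character(0)
  } else {
    if (!inherits(state, "bfi_state")) stop("'state' must be a bfi_state")
    if (!identical(state$param_names, pn))
      stop("state was built for parameters {",
           paste(state$param_names, collapse = ", "), "}")
    if (!identical(unclass(state$spec), unclass(spec)))
      stop("state was built under a different heterogeneity specification")
    if (!identical(state$family, summaries[[1]]$family))
      stop("state was built for family '", state$family, "'")
    centers_df <- state$centers
    prev_ids <- centers_df$center_id
  }
  if (length(intersect(ids, prev_ids)))
    stop("center(s) already in the state: ",
         paste(intersect(ids, prev_ids), collapse = ", "))

  all_ids <- c(prev_ids, ids)
  layout <- stacked_layout(pn, all_ids, spec)
  q <- length(layout$stacked)
  A <- matrix(0, q, q, dimnames = list(layout$stacked, layout$stacked))
  b <- stats::setNames(rep(0, q), layout$stacked)

  # re-embed a previous (possibly smaller) stacked system
  if (!is.null(state)) {
    old <- state$layout$stacked
    A[old, old] <- state$A
    b[old] <- state$b
  }
  for (s in summaries) {
    map <- layout$maps[[s$center_id]]
    M <- s$curvature - s$prior_precision      # likelihood curvature
    lin <- drop(s$curvature %*% s$theta_hat)  # A_hat_l %*% theta_hat_l
    A[map, map] <- A[map, map] + M
    b[map] <- b[map] + lin
  }
  centers_df <- rbind(centers_df,
                      data.frame(center_id = ids,
                                 n = vapply(summaries, `[[`, numeric(1), "n"),
                                 stringsAsFactors = FALSE))
  structure(list(schema_version = "1",
                 param_names = pn, family = summaries[[1]]$family,
                 fixed_sigma2 = summaries[[1]]$fixed_sigma2,
                 spec = spec, layout = layout, A = A, b = b,
                 centers = centers_df),
            class = "bfi_state")
}

#' @export
print.bfi_state <- function(x, ...) {
  cat("BFI combination state:", nrow(x$centers), "center(s) accumulated,",
      length(x$layout$stacked), "stacked parameters\n")
  invisible(x)
}

#' Finalize a combination state into the BFI estimate
#'
#' Adds the combined-analysis prior to the accumulated curvature and solves
#' the stacked quadratic system by Cholesky factorization. Fails (rather than
#' regularizing) if the combined curvature is not positive definite, which
#' signals an incompatible prior configuration or an unidentified direction.
#'
#' @param state a [bfi_accumulate()] state.
#' @param prior the combined-analysis [bfi_prior] over the original
#'   parameter names (each center/cluster copy receives the parameter's
#'   marginal precision, independently across copies).
#' @return an object of class \code{bfi_estimate}.
#' @export
bfi_finalize <- function(state, prior) {
  if (!inherits(state, "bfi_state")) stop("'state' must be a bfi_state")
  Lam <- stacked_prior_precision(prior, state$layout, state$param_names)
  A <- state$A + Lam
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R))
    stop("combined curvature is not positive definite; check that the ",
         "combined prior is compatible with the local priors and that every ",
         "shared parameter is identified")
  theta <- drop(backsolve(R, forwardsolve(t(R), state$b)))
  V <- chol2inv(R)
  sds <- sqrt(diag(V))
  nm <- state$layout$stacked
  structure(
    list(names = nm,
         theta = stats::setNames(theta, nm),
         curvature = A,
         vcov = structure(V, dimnames = list(nm, nm)),
         sd = stats::setNames(sds, nm),
         param_names = state$param_names,
         family = state$family, fixed_sigma2 = state$fixed_sigma2,
         spec = state$spec, layout = state$layout,
         centers = state$centers, n_total = sum(state$centers$n),
         coding = "absolute"),
    class = "bfi_estimate")
}

#' One-shot BFI combination of local summaries
#'
#' Combines the centers' shared summaries into the federated estimate of the
#' model the pooled-data analysis would have fitted. With an empty
#' heterogeneity specification this is
#' \deqn{\hat A_{BFI} = \sum_\ell \hat A_\ell - \sum_\ell \Lambda_\ell +
#'   \Lambda, \qquad
#'   \hat\theta_{BFI} = \hat A_{BFI}^{-1} \sum_\ell \hat A_\ell
#'   \hat\theta_\ell,}
#' the maximizer of the sum of the centers' second-order posterior expansions
#' with the sum of local priors replaced by the combined prior. Center- or
#' cluster-specific parameters declared in \code{spec} are given one copy per
#' center/cluster in a stacked parameter vector; each center's expansion
#' contributes to its own blocks and to the shared block, and the resulting
#' block-arrow system is solved exactly. The inverse of the returned
#' curvature estimates the covariance matrix of the estimator.
#'
#' @inheritParams bfi_accumulate
#' @param prior the combined-analysis [bfi_prior].
#' @return a \code{bfi_estimate}: stacked names (center blocks, cluster
#'   blocks, then shared), estimates, combined curvature, standard
#'   deviations, and provenance.
#' @examples
#' # two one-subject... see vignette for worked examples
#' @export
bfi_combine <- function(summaries, prior, spec = NULL) {
  bfi_finalize(bfi_accumulate(summaries, spec), prior)
}

#' @export
print.bfi_estimate <- function(x, ...) {
  cat("BFI estimate (", x$family, "), ", nrow(x$centers), " centers, n = ",
      x$n_total, "\n", sep = "")
  if (!is_empty_spec(x$spec)) print(x$spec)
  tab <- data.frame(estimate = x$theta, sd = x$sd)
  print(signif(tab, 5))
  invisible(x)
}

#' Coefficients of the aggregated model for one center
#'
#' Resolves the stacked BFI parameter vector back to a plain coefficient
#' vector for a given center: center-specific copies for that center,
#' cluster-specific copies for its cluster, shared values otherwise.
#'
#' @param estimate a \code{bfi_estimate}.
#' @param center_id center identifier.
#' @param cluster cluster label; only needed when the estimate has
#'   cluster-specific parameters and the center was not part of the
#'   combination's cluster map.
#' @return named numeric vector over the original parameter names.
#' @export
center_coefficients <- function(estimate, center_id, cluster = NULL) {
  stopifnot(inherits(estimate, "bfi_estimate"))
  lay <- estimate$layout
  th <- resolve_absolute(estimate)
  out <- stats::setNames(numeric(length(estimate$param_names)),
                         estimate$param_names)
  for (nm in estimate$param_names) {
    key <- if (nm %in% lay$center_specific) {
      if (!center_id %in% lay$centers)
        stop("center '", center_id, "' was not part of the combination")
      stacked_name(nm, center_id)
    } else if (nm %in% lay$cluster_specific) {
      k <- if (!is.null(cluster)) as.character(cluster)
           else estimate$spec$cluster_map[[center_id]]
      if (is.null(k)) stop("no cluster label known for center '", center_id, "'")
      stacked_name(nm, k)
    } else nm
    out[nm] <- th[[key]]
  }
  out
}

# theta in absolute (per-unit) coding regardless of the estimate's coding
resolve_absolute <- function(estimate) {
  if (identical(estimate$coding, "absolute")) return(estimate$theta)
  undo_reference_coding(estimate)$theta
}

#' @export
#' @rdname predict_glm
predict.bfi_estimate <- function(object, newdata, ...) {
  if (!inherits(newdata, "local_dataset"))
    stop("predict for a bfi_estimate needs a local_dataset (the center ",
         "determines which intercept copies apply)")
  th <- center_coefficients(object, newdata$center_id, newdata$cluster)
  predict_glm(th, newdata$X, bfi_restore_family(object))
}

# rebuild the family object carried implicitly by an estimate or summary
bfi_restore_family <- function(x) {
  bfi_family(x$family, fixed_sigma2 = x$fixed_sigma2)
}

# ---- reference coding -------------------------------------------------------

#' Rewrite per-unit copies as a general value plus contrasts
#'
#' Reparameterizes the center- (or cluster-) specific copies of one parameter
#' as a general value — the reference unit's copy — plus per-unit contrasts
#' \eqn{\gamma_j^* = \gamma_j - \gamma_{ref}}. The transformation is linear,
#' so the curvature transforms by congruence with the reparameterization
#' Jacobian and predictions are unchanged. \code{undo_reference_coding}
#' inverts it.
#'
#' @param estimate a \code{bfi_estimate} with per-unit copies of
#'   \code{parameter}.
#' @param reference the unit (center id or cluster label) whose copy becomes
#'   the general value.
#' @param parameter which parameter to recode (default the intercept).
#' @return a \code{bfi_estimate} in reference coding: the general value keeps
#'   the plain parameter name; the remaining units' entries become contrasts
#'   relative to the reference (the reference's own contrast, identically
#'   zero, is dropped).
#' @export
to_reference_coding <- function(estimate, reference,
                                parameter = "(Intercept)") {
  stopifnot(inherits(estimate, "bfi_estimate"))
  if (!identical(estimate$coding, "absolute"))
    stop("estimate is already in reference coding")
  lay <- estimate$layout
  units <- if (parameter %in% lay$center_specific) lay$centers
           else if (parameter %in% lay$cluster_specific) lay$clusters
           else stop("'", parameter, "' has no per-unit copies in this estimate")
  reference <- as.character(reference)
  if (!reference %in% units)
    stop("reference unit '", reference, "' not found among {",
         paste(units, collapse = ", "), "}")

  old <- estimate$names
  copies <- stacked_name(parameter, units)
  ref_copy <- stacked_name(parameter, reference)
  new <- old
  new[old == ref_copy] <- parameter  # general value takes the plain name

  # theta_old = J %*% theta_new: each non-reference copy = general + contrast
  q <- length(old)
  J <- diag(q); dimnames(J) <- list(old, new)
  for (cp in setdiff(copies, ref_copy)) J[cp, parameter] <- 1

  theta_new <- estimate$theta
  names(theta_new) <- new
  for (cp in setdiff(copies, ref_copy))
    theta_new[cp] <- estimate$theta[[cp]] - estimate$theta[[ref_copy]]

  A_new <- t(J) %*% estimate$curvature %*% J
  dimnames(A_new) <- list(new, new)
  V <- chol2inv(chol(A_new))
  out <- estimate
  out$names <- new
  out$theta <- theta_new
  out$curvature <- A_new
  out$vcov <- structure(V, dimnames = list(new, new))
  out$sd <- stats::setNames(sqrt(diag(V)), new)
  out$coding <- "reference"
  out$reference <- list(parameter = parameter, unit = reference,
                        units = units)
  out
}

#' @rdname to_reference_coding
#' @export
undo_reference_coding <- function(estimate) {
  stopifnot(inherits(estimate, "bfi_estimate"))
  if (!identical(estimate$coding, "reference"))
    stop("estimate is not in reference coding")
  ref <- estimate$reference
  parameter <- ref$parameter
  new <- estimate$names
  old <- new
  old[new == parameter] <- stacked_name(parameter, ref$unit)
  copies_other <- stacked_name(parameter, setdiff(ref$units, ref$unit))

  theta_old <- estimate$theta
  names(theta_old) <- old
  for (cp in copies_other)
    theta_old[cp] <- estimate$theta[[cp]] + estimate$theta[[parameter]]

  q <- length(new)
  Jinv <- diag(q); dimnames(Jinv) <- list(new, old)
  for (cp in copies_other) Jinv[cp, stacked_name(parameter, ref$unit)] <- -1
  A_old <- t(Jinv) %*% estimate$curvature %*% Jinv
  dimnames(A_old) <- list(old, old)
  V <- chol2inv(chol(A_old))
  out <- estimate
  out$names <- old
  out$theta <- theta_old
  out$curvature <- A_old
  out$vcov <- structure(V, dimnames = list(old, old))
  out$sd <- stats::setNames(sqrt(diag(V)), old)
  out$coding <- "absolute"
  out$reference <- NULL
  # restore the canonical stacked order
  ord <- match(out$layout$stacked, out$names)
  out$names <- out$names[ord]
  out$theta <- out$theta[ord]
  out$curvature <- out$curvature[ord, ord]
  out$vcov <- out$vcov[ord, ord]
  out$sd <- out$sd[ord]
  out
}

# ---- center-level continuous covariate -------------------------------------

#' Regress center-specific intercepts on a center-level covariate
#'
#' A covariate that is constant within every center (e.g. hospital size as a
#' number of beds) cannot enter any local model; its effect hides in the
#' center-specific intercepts. This fits the least-squares line through the
#' points \eqn{(z_\ell, \hat\gamma_\ell)}, estimating the aggregated model's
#' global intercept (the line's intercept) and the covariate's coefficient
#' (its slope). Uncertainty in the \eqn{\hat\gamma_\ell} is propagated by
#' drawing each intercept from its approximate Gaussian posterior
#' \eqn{N(\hat\gamma_\ell, sd_\ell^2)} independently, refitting the line B
#' times, and averaging the B estimates.
#'
#' @param estimate a \code{bfi_estimate} with center-specific intercepts.
#' @param z named numeric vector: center id -> covariate value; at least two
#'   distinct values.
#' @param B number of Monte-Carlo draws (default 1000); \code{B = 0} gives
#'   the plain least-squares fit with no uncertainty propagation.
#' @param seed integer seed for the draws.
#' @param parameter which center-specific parameter to regress (default the
#'   intercept).
#' @return an object of class \code{center_covariate_fit} with elements
#'   \code{intercept}, \code{slope} (the reported averages), \code{draws}
#'   (B x 2 matrix, \code{NULL} when \code{B = 0}), \code{points}.
#' @export
center_covariate_fit <- function(estimate, z, B = 1000L, seed = 1L,
                                 parameter = "(Intercept)") {
  stopifnot(inherits(estimate, "bfi_estimate"))
  lay <- estimate$layout
  if (!parameter %in% lay$center_specific)
    stop("'", parameter, "' is not center-specific in this estimate")
  centers <- lay$centers
  if (is.null(names(z)) || length(setdiff(centers, names(z))))
    stop("'z' must be named with a value for every center")
  z <- z[centers]
  if (length(unique(z)) < 2L)
    stop("all centers have the same covariate value; slope unidentified")
  keys <- stacked_name(parameter, centers)
  gam <- estimate$theta[keys]
  sds <- estimate$sd[keys]
  pts <- data.frame(center_id = centers, z = unname(z),
                    gamma_hat = unname(gam), sd = unname(sds))

  ls_fit <- function(g) {
    cf <- stats::coef(stats::lm(g ~ z))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  if (B == 0L) {
    est <- ls_fit(unname(gam))
    draws <- NULL
  } else {
    if (B < 1L) stop("'B' must be >= 0")
    draws <- with_seed(seed, {
      t(vapply(seq_len(B), function(b) {
        ls_fit(stats::rnorm(length(gam), unname(gam), unname(sds)))
      }, numeric(2)))
    })
    colnames(draws) <- c("intercept", "slope")
    est <- colMeans(draws)
  }
  structure(list(intercept = unname(est["intercept"]),
                 slope = unname(est["slope"]),
                 B = as.integer(B), draws = draws, points = pts,
                 parameter = parameter),
            class = "center_covariate_fit")
}

#' @export
print.center_covariate_fit <- function(x, ...) {
  cat("Center-level covariate fit on ", nrow(x$points), " ", x$parameter,
      " estimates (B = ", x$B, " draws)\n", sep = "")
  cat("  intercept:", signif(x$intercept, 5),
      "  slope:", signif(x$slope, 5), "\n")
  if (!is.null(x$draws))
    cat("  MC sd of draws: intercept", signif(stats::sd(x$draws[, 1]), 3),
        ", slope", signif(stats::sd(x$draws[, 2]), 3), "\n")
  invisible(x)
}

# ---- pooled reference under heterogeneity ----------------------------------

#' Pooled MAP fit of the heterogeneous (dummy-coded) model
#'
#' The pooled-data counterpart of a heterogeneous combination: stacks all
#' centers and replaces each center-/cluster-specific coefficient by per-unit
#' dummy-interaction columns matching the stacked parameter convention, then
#' fits the MAP under the combined prior mapped onto the stacked names. Used
#' as the reference the federated estimate is compared against. Center-
#' specific error variances have no single-design representation and are not
#' supported here.
#'
#' @inheritParams pooled_map_fit
#' @param spec a [het_spec()].
#' @return a \code{bfi_map} on the stacked design.
#' @export
pooled_het_fit <- function(datasets, family, prior, spec, ...) {
  family <- as_bfi_family(family)
  if (family$nuisance_name %in% c(spec$center_specific, spec$cluster_specific) &&
      length(family$nuisance_name))
    stop("pooled reference with center-specific '", family$nuisance_name,
         "' is not expressible as a single design; not supported")
  ids <- vapply(datasets, `[[`, character(1), "center_id")
  pn <- param_names(family, datasets[[1]]$X)
  layout <- stacked_layout(pn, ids, spec)
  Xs <- lapply(datasets, function(d) {
    map <- layout$maps[[d$center_id]]
    beta_stacked <- setdiff(layout$stacked, family$nuisance_name)
    Xn <- matrix(0, nrow(d$X), length(beta_stacked),
                 dimnames = list(NULL, beta_stacked))
    for (nm in colnames(d$X)) Xn[, map[[nm]]] <- d$X[, nm]
    Xn
  })
  X <- do.call(rbind, Xs)
  y <- unlist(lapply(datasets, `[[`, "y"), use.names = FALSE)
  Lam <- stacked_prior_precision(align_prior(prior, pn), layout, pn)
  sp_prior <- bfi_prior(names = layout$stacked, precision = Lam)
  map_fit(local_dataset(X, y, center_id = "pooled"), family, sp_prior, ...)
}
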