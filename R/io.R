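# Serialization of the artifacts that cross center boundaries: the local
# summary (the only payload a center ever shares) and the combination state.
# Matrices are written row-major with explicit dimensions; floating point at
# 17 significant digits so values round-trip exactly.

mat_to_payload <- function(M) {
  list(nrow = nrow(M), ncol = ncol(M), rownames = rownames(M),
       colnames = colnames(M), data = as.vector(t(M)))
}

payload_to_mat <- function(p) {
  M <- matrix(as.numeric(p$data), nrow = p$nrow, ncol = p$ncol, byrow = TRUE)
  dimnames(M) <- list(unlist(p$rownames), unlist(p$colnames))
  M
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
}

#' Write / read a local summary as JSON
#'
#' The summary file is the only artifact that leaves a center: parameter
#' names, MAP estimate, curvature, prior precision, sample size and
#' metadata — size O(p^2), no subject-level rows. Files are schema-versioned
#' and unknown versions are refused rather than coerced.
#'
#' @param summary a [local_summary].
#' @param path file path.
#' @return \code{write_local_summary} returns \code{path} invisibly;
#'   \code{read_local_summary} returns the validated [local_summary].
#' @export
write_local_summary <- function(summary, path) {
  stopifnot(inherits(summary, "local_summary"))
  payload <- list(
    schema_version = summary$schema_version,
    center_id = summary$center_id,
    family = summary$family,
    fixed_sigma2 = summary$fixed_sigma2,
    names = summary$names,
    n = summary$n,
    theta_hat = unname(summary$theta_hat),
    curvature = mat_to_payload(summary$curvature),
    prior_precision = mat_to_payload(summary$prior_precision),
    cluster = summary$cluster,
    center_covariate = summary$center_covariate,
    moments = summary$moments)
  json_write(payload, path)
  invisible(path)
}

#' @rdname write_local_summary
#' @export
read_local_summary <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema_version, "1"))
    stop("unknown summary schema version '", p$schema_version,
         "' in ", path)
  s <- structure(
    list(schema_version = p$schema_version,
         center_id = p$center_id,
         family = p$family,
         fixed_sigma2 = p$fixed_sigma2,
         names = p$names,
         n = as.numeric(p$n),
         theta_hat = stats::setNames(as.numeric(p$theta_hat), p$names),
         curvature = payload_to_mat(p$curvature),
         prior_precision = payload_to_mat(p$prior_precision),
         cluster = p$cluster,
         center_covariate = p$center_covariate,
         moments = p$moments),
    class = "local_summary")
  validate_summaries(list(s))[[1]]
}

#' Write / read a combination state as JSON
#'
#' The state holds the accumulated sums of the combination (stacked
#' curvature and linear term) plus provenance — everything needed to add
#' late centers and finalize, nothing subject-level.
#'
#' @param state a [bfi_accumulate()] state.
#' @param path file path.
#' @export
write_bfi_state <- function(state, path) {
  stopifnot(inherits(state, "bfi_state"))
  payload <- list(
    schema_version = state$schema_version,
    param_names = state$param_names,
    family = state$family,
    fixed_sigma2 = state$fixed_sigma2,
    spec = list(center_specific = state$spec$center_specific,
                cluster_specific = state$spec$cluster_specific,
                cluster_map = as.list(state$spec$cluster_map)),
    centers = state$centers,
    A = mat_to_payload(state$A),
    b = unname(state$b))
  json_write(payload, path)
  invisible(path)
}

#' @rdname write_bfi_state
#' @export
read_bfi_state <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema_version, "1"))
    stop("unknown state schema version '", p$schema_version, "' in ", path)
  cm <- NULL
  if (length(p$spec$cluster_map))
    cm <- unlist(p$spec$cluster_map)
  spec <- het_spec(center_specific = unlist(p$spec$center_specific) %||% character(),
                   cluster_specific = unlist(p$spec$cluster_specific) %||% character(),
                   cluster_map = cm)
  centers <- as.data.frame(p$centers)
  layout <- stacked_layout(p$param_names, centers$center_id, spec)
  A <- payload_to_mat(p$A)
  structure(list(schema_version = p$schema_version,
                 param_names = p$param_names,
                 family = p$family, fixed_sigma2 = p$fixed_sigma2,
                 spec = spec, layout = layout,
                 A = A[layout$stacked, layout$stacked, drop = FALSE],
                 b = stats::setNames(as.numeric(p$b),
                                     unlist(p$A$rownames))[layout$stacked],
                 centers = centers),
            class = "bfi_state")
}
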