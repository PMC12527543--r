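#' Per-center dataset
#'
#' Container for one center's subject-level data: a design matrix \code{X}
#' (first column all ones when the model has an intercept), an outcome vector
#' \code{y}, and center metadata. Objects of this class never leave the
#' center; only the fitted summary produced by [make_local_summary()] is
#' shared.
#'
#' @param X numeric matrix, one row per subject, with unique column names.
#'   An all-ones column named \code{"(Intercept)"} encodes the intercept.
#' @param y outcome vector: real for the Gaussian family, 0/1 for binomial.
#' @param center_id character scalar identifying the center.
#' @param cluster optional cluster label (e.g. hospital-size class).
#' @param center_covariate optional real scalar: a center-level covariate
#'   that is constant within the center (so cannot enter the local model).
#' @return an object of class \code{local_dataset}.
#' @export
local_dataset <- function(X, y, center_id, cluster = NULL,
                          center_covariate = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X)))
    stop("covariate matrix must be finite numeric with no missing values")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("covariate columns must have unique names")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (nrow(X) < 1L) stop("dataset must contain at least one subject")
  if (anyNA(y) || any(!is.finite(y)))
    stop("outcome contains missing or non-finite values")
  if (!is.character(center_id) || length(center_id) != 1L)
    stop("'center_id' must be a character scalar")
  if (!is.null(cluster) && (length(cluster) != 1L))
    stop("'cluster' must be a single label")
  if (!is.null(center_covariate) &&
      (!is.numeric(center_covariate) || length(center_covariate) != 1L))
    stop("'center_covariate' must be a single number")
  structure(
    list(X = X, y = y, center_id = center_id,
         cluster = if (is.null(cluster)) NULL else as.character(cluster),
         center_covariate = center_covariate),
    class = "local_dataset")
}

#' @export
print.local_dataset <- function(x, ...) {
  cat("Local dataset, center ", x$center_id, ": ", nrow(x$X), " subjects, ",
      ncol(x$X), " design columns (",
      paste(colnames(x$X), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$cluster)) cat("  cluster:", x$cluster, "\n")
  if (!is.null(x$center_covariate))
    cat("  center-level covariate:", x$center_covariate, "\n")
  invisible(x)
}

#' Read per-center datasets from a CSV file
#'
#' Reads a subject-level CSV (header required, one row per subject) and splits
#' it into one [local_dataset] per center. Missing cells are an error; no
#' imputation is attempted. Covariate columns are used as-is, so factors must
#' already be coded numerically (e.g. 0/1 dummies).
#'
#' @param path CSV file path.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names.
#' @param center_col name of the column holding center identifiers.
#' @param cluster_col optional column with a cluster label, constant within
#'   each center.
#' @param z_col optional column with a continuous center-level covariate,
#'   constant within each center.
#' @param intercept add an all-ones \code{"(Intercept)"} first column
#'   (default \code{TRUE}).
#' @return named list of [local_dataset] objects, ordered by center id.
#' @export
read_center_data <- function(path, outcome, covariates, center_col,
                             cluster_col = NULL, z_col = NULL,
                             intercept = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c(outcome, covariates, center_col, cluster_col, z_col)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(df[needed]))
    stop("missing values in columns ",
         paste(needed[vapply(df[needed], anyNA, logical(1))], collapse = ", "),
         "; no imputation is performed")
  centers <- sort(unique(as.character(df[[center_col]])))
  out <- lapply(centers, function(cid) {
    rows <- as.character(df[[center_col]]) == cid
    sub <- df[rows, , drop = FALSE]
    X <- as.matrix(sub[covariates])
    storage.mode(X) <- "double"
    if (intercept)
      X <- cbind(`(Intercept)` = 1, X)
    cl <- NULL
    if (!is.null(cluster_col)) {
      cl <- unique(as.character(sub[[cluster_col]]))
      if (length(cl) != 1L)
        stop("cluster label not constant within center ", cid)
    }
    z <- NULL
    if (!is.null(z_col)) {
      z <- unique(as.numeric(sub[[z_col]]))
      if (length(z) != 1L)
        stop("center-level covariate not constant within center ", cid)
    }
    local_dataset(X, sub[[outcome]], center_id = cid, cluster = cl,
                  center_covariate = z)
  })
  names(out) <- centers
  out
}

#' Write a list of per-center datasets to a single CSV file
#'
#' Inverse of [read_center_data()]: stacks the centers into one table with a
#' center column (and cluster / center-covariate columns when present).
#'
#' @param datasets list of [local_dataset] objects.
#' @param path output CSV path.
#' @param outcome name for the outcome column (default \code{"y"}).
#' @return invisibly, the written data frame.
#' @export
write_center_data <- function(datasets, path, outcome = "y") {
  stopifnot(length(datasets) >= 1L)
  tabs <- lapply(datasets, function(d) {
    keep <- setdiff(colnames(d$X), "(Intercept)")
    tab <- as.data.frame(d$X[, keep, drop = FALSE])
    tab[[outcome]] <- d$y
    tab$center <- d$center_id
    if (!is.null(d$cluster)) tab$cluster <- d$cluster
    if (!is.null(d$center_covariate)) tab$z <- d$center_covariate
    tab
  })
  df <- do.call(rbind, tabs)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Reconstruct pooled mean and standard deviation from local moments
#'
#' Combines per-center sample sizes, means and standard deviations of a
#' column into the mean and standard deviation of the (never materialized)
#' concatenated column, using the exact pooled sum-of-squares decomposition
#' with denominator \eqn{n - 1}. Standardizing each center's column with the
#' returned values is identical to standardizing the pooled column directly,
#' so centers can share three numbers per covariate instead of the data.
#'
#' @param moments data frame (or list of lists) with components \code{n},
#'   \code{mean}, \code{sd} — one entry per center; \code{n >= 2} per center.
#' @return list with elements \code{mean}, \code{sd}, \code{n} (total).
#' @examples
#' m <- data.frame(n = c(2, 2), mean = c(1.5, 3.5), sd = c(sd(1:2), sd(3:4)))
#' pooled_standardization(m)  # mean 2.5, sd = sd(1:4)
#' @export
pooled_standardization <- function(moments) {
  if (is.data.frame(moments)) {
    n <- moments$n; m <- moments$mean; s <- moments$sd
  } else {
    n <- vapply(moments, `[[`, numeric(1), "n")
    m <- vapply(moments, `[[`, numeric(1), "mean")
    s <- vapply(moments, `[[`, numeric(1), "sd")
  }
  if (any(n < 2)) stop("each center needs n >= 2 to reconstruct the pooled sd")
  N <- sum(n)
  mu <- sum(n * m) / N
  ss <- sum((n - 1) * s^2 + n * (m - mu)^2)
  if (ss <= 0) stop("pooled variance is zero; column is constant")
  list(mean = mu, sd = sqrt(ss / (N - 1)), n = N)
}

#' Standardize columns across centers using pooled moments
#'
#' Standardizes the named design columns (and optionally the outcome) of
#' every center with the pooled mean and standard deviation reconstructed
#' from the centers' local moments by [pooled_standardization()] — exactly
#' the values a standardization of the concatenated data would use, obtained
#' without pooling any subject-level rows.
#'
#' @param datasets list of [local_dataset] objects with identical columns.
#' @param columns design columns to standardize.
#' @param outcome also standardize the outcome (default FALSE).
#' @return list of [local_dataset] objects; the pooled moments used are
#'   attached as attribute \code{"moments"}.
#' @export
standardize_centers <- function(datasets, columns, outcome = FALSE) {
  used <- list()
  for (v in columns) {
    mom <- data.frame(
      n = vapply(datasets, function(d) nrow(d$X), numeric(1)),
      mean = vapply(datasets, function(d) mean(d$X[, v]), numeric(1)),
      sd = vapply(datasets, function(d) stats::sd(d$X[, v]), numeric(1)))
    ps <- pooled_standardization(mom)
    used[[v]] <- ps
    datasets <- lapply(datasets, function(d) {
      d$X[, v] <- (d$X[, v] - ps$mean) / ps$sd
      d
    })
  }
  if (outcome) {
    mom <- data.frame(
      n = vapply(datasets, function(d) nrow(d$X), numeric(1)),
      mean = vapply(datasets, function(d) mean(d$y), numeric(1)),
      sd = vapply(datasets, function(d) stats::sd(d$y), numeric(1)))
    ps <- pooled_standardization(mom)
    used[[".outcome"]] <- ps
    datasets <- lapply(datasets, function(d) {
      d$y <- (d$y - ps$mean) / ps$sd
      d
    })
  }
  attr(datasets, "moments") <- used
  datasets
}
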