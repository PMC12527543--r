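# Shared fixtures and independent oracles. Everything is generated in code;
# oracles never call the combination code paths they check.

# random gaussian-outcome centers with named columns
make_gaussian_centers <- function(L, n, p, seed, beta = NULL, sigma = 1,
                                  intercepts = NULL) {
  withr::with_seed(seed, {
    vars <- paste0("x", seq_len(p))
    if (is.null(beta)) beta <- stats::setNames(stats::rnorm(p), vars)
    lapply(seq_len(L), function(l) {
      X <- cbind(`(Intercept)` = 1,
                 matrix(stats::rnorm(n[l] * p), n[l], p,
                        dimnames = list(NULL, vars)))
      icpt <- if (is.null(intercepts)) 0.5 else intercepts[l]
      y <- icpt + drop(X[, vars, drop = FALSE] %*% beta) +
        stats::rnorm(n[l], 0, sigma)
      local_dataset(X, y, center_id = sprintf("C%02d", l))
    })
  })
}

make_logistic_centers <- function(L, n, seed,
                                  beta = c(`(Intercept)` = -1, x1 = 0.5,
                                           x2 = -0.5, x3 = 1),
                                  intercepts = NULL) {
  withr::with_seed(seed, {
    lapply(seq_len(L), function(l) {
      X <- cbind(`(Intercept)` = 1, x1 = stats::rnorm(n[l]),
                 x2 = stats::rnorm(n[l], 1, 2),
                 x3 = stats::rbinom(n[l], 1, 0.5))
      b <- beta
      if (!is.null(intercepts)) b[["(Intercept)"]] <- intercepts[l]
      y <- stats::rbinom(n[l], 1, stats::plogis(drop(X %*% b[colnames(X)])))
      local_dataset(X, y, center_id = sprintf("C%02d", l))
    })
  })
}

# fit all centers and return summaries (lambda_local scalar or vector)
fit_summaries <- function(datasets, family, lambda_local) {
  family <- bfiglm::bfi_family(if (is.character(family)) family else family$name,
                               fixed_sigma2 = if (!is.character(family))
                                 family$fixed_sigma2 else NULL)
  lambda_local <- rep_len(lambda_local, length(datasets))
  lapply(seq_along(datasets), function(l) {
    d <- datasets[[l]]
    pn <- c(colnames(d$X),
            if (family$nuisance_dim > 0) family$nuisance_name)
    make_local_summary(map_fit(d, family, bfi_prior(lambda_local[l], pn)))
  })
}

# closed-form ridge / penalized LS oracle for gaussian with known sigma^2:
# argmax of -sum (y - X b)^2 / (2 s2) - b' Lambda b / 2
ridge_oracle <- function(X, y, Lambda, sigma2 = 1) {
  A <- crossprod(X) / sigma2 + Lambda
  unname(drop(solve(A, crossprod(X, y) / sigma2)))
}

# dummy-coded stacked design for per-unit copies of some columns, built
# independently of the package's layout code (same naming convention)
stack_dummy_design <- function(datasets, specific, unit_of) {
  ids <- vapply(datasets, function(d) d$center_id, character(1))
  units <- sort(unique(vapply(ids, unit_of, character(1))), method = "radix")
  shared <- setdiff(colnames(datasets[[1]]$X), specific)
  shared <- shared[order(shared, method = "radix")]
  sp <- specific[order(specific, method = "radix")]
  cols <- c(unlist(lapply(units, function(u) paste0(sp, "[", u, "]"))), shared)
  Xs <- lapply(datasets, function(d) {
    u <- unit_of(d$center_id)
    M <- matrix(0, nrow(d$X), length(cols), dimnames = list(NULL, cols))
    for (s in sp) M[, paste0(s, "[", u, "]")] <- d$X[, s]
    for (s in shared) M[, s] <- d$X[, s]
    M
  })
  list(X = do.call(rbind, Xs),
       y = unlist(lapply(datasets, function(d) d$y), use.names = FALSE),
       cols = cols)
}

# expand a diagonal-lambda prior onto stacked columns (marginal precision on
# every copy)
stack_dummy_lambda <- function(cols, lambda) diag(lambda, length(cols))
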