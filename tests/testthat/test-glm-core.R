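# Local model machinery: log posterior derivatives, Newton MAP fitting,
# prediction, pooled reference fit, pooled standardization.

test_that("log_posterior derivatives match finite differences for both families", {
  skip_if_not_installed("pracma")
  cases <- list(
    list(family = "gaussian", n = 3, seed = 11),
    list(family = "gaussian", n = 25, seed = 12),
    list(family = "binomial", n = 6, seed = 13),
    list(family = "binomial", n = 40, seed = 14))
  for (cs in cases) {
    fam <- bfi_family(cs$family)
    d <- withr::with_seed(cs$seed, {
      X <- cbind(`(Intercept)` = 1, x1 = rnorm(cs$n), x2 = rnorm(cs$n))
      y <- if (cs$family == "binomial") rbinom(cs$n, 1, 0.5)
           else rnorm(cs$n, 1, 1.5)
      local_dataset(X, y, "A")
    })
    pn <- c(colnames(d$X), fam$nuisance_name)
    prior <- bfi_prior(0.3, pn)
    theta <- withr::with_seed(cs$seed + 1,
                              stats::setNames(rnorm(length(pn), 0, 0.7), pn))
    lp <- log_posterior(theta, d, fam, prior)
    f <- function(v) log_posterior(stats::setNames(v, pn), d, fam, prior)$value
    g_num <- pracma::grad(f, unname(theta))
    H_num <- pracma::hessian(f, unname(theta))
    expect_equal(unname(lp$gradient), g_num, tolerance = 1e-6)
    expect_equal(unname(lp$hessian), H_num, tolerance = 1e-5)
  }
})

test_that("prior term vanishes from the gradient at zero and contributes -Lambda to the Hessian", {
  d <- withr::with_seed(5, {
    X <- cbind(`(Intercept)` = 1, x = rnorm(8))
    local_dataset(X, rbinom(8, 1, 0.5), "A")
  })
  fam <- bfi_family("binomial")
  pn <- colnames(d$X)
  theta0 <- stats::setNames(rep(0, 2), pn)
  lp0 <- log_posterior(theta0, d, fam, bfi_prior(0, pn))
  lp1 <- log_posterior(theta0, d, fam, bfi_prior(1, pn))
  expect_equal(lp1$gradient, lp0$gradient)             # quadratic at its center
  expect_equal(lp1$hessian, lp0$hessian - diag(2),
               ignore_attr = TRUE)
})

test_that("an overwhelming prior pins the MAP estimate at the prior mean", {
  d <- withr::with_seed(21, {
    X <- cbind(`(Intercept)` = 1, x = rnorm(20))
    local_dataset(X, rnorm(20, 3), "A")
  })
  fam <- bfi_family("gaussian")
  pn <- c(colnames(d$X), "log_sigma2")
  fit <- map_fit(d, fam, bfi_prior(1e8, pn))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta)), 1e-4)
})

test_that("logistic MAP matches a dense grid-search oracle on a printed dataset", {
  X <- cbind(`(Intercept)` = 1, x = c(-1, 0, 1, -1, 0, 1))
  y <- c(0, 0, 0, 1, 1, 1)
  d <- local_dataset(X, y, "A")
  prior <- bfi_prior(0.01, colnames(X))
  fit <- map_fit(d, "binomial", prior)

  # independent oracle: direct evaluation of the log posterior on a grid,
  # coarse pass then refinement to step 1e-3
  obj2 <- function(b0, b1) {
    eta <- cbind(1, X[, "x"]) %*% rbind(b0, b1)
    colSums(y * eta - log1p(exp(eta))) - 0.01 * (b0^2 + b1^2) / 2
  }
  coarse <- seq(-5, 5, by = 0.01)
  gr <- expand.grid(b0 = coarse, b1 = coarse)
  v <- obj2(gr$b0, gr$b1)
  best <- gr[which.max(v), ]
  fine0 <- seq(best$b0 - 0.02, best$b0 + 0.02, by = 1e-3)
  fine1 <- seq(best$b1 - 0.02, best$b1 + 0.02, by = 1e-3)
  gf <- expand.grid(b0 = fine0, b1 = fine1)
  vf <- obj2(gf$b0, gf$b1)
  bestf <- gf[which.max(vf), ]
  expect_lt(max(abs(unname(fit$theta) - c(bestf$b0, bestf$b1))), 2e-3)
})

test_that("gaussian MAP satisfies the closed-form ridge stationarity at the fitted variance", {
  d <- withr::with_seed(31, {
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(40), x2 = rnorm(40))
    y <- 1 - 2 * X[, "x1"] + 0.5 * X[, "x2"] + rnorm(40, 0, 0.8)
    local_dataset(X, y, "A")
  })
  pn <- c(colnames(d$X), "log_sigma2")
  prior <- bfi_prior(c(0.5, 0.5, 0.5, 0.2), pn)
  fit <- map_fit(d, "gaussian", prior)
  s2 <- exp(fit$theta[["log_sigma2"]])
  beta_oracle <- ridge_oracle(d$X, d$y, diag(0.5, 3), sigma2 = s2)
  expect_equal(unname(fit$theta[colnames(d$X)]), beta_oracle,
               tolerance = 1e-8)
})

test_that("MAP fitting is row-order invariant and the likelihood curvature is additive in rows", {
  d <- withr::with_seed(41, {
    X <- cbind(`(Intercept)` = 1, x = rnorm(30))
    local_dataset(X, rbinom(30, 1, plogis(X[, "x"])), "A")
  })
  prior <- bfi_prior(0.1, colnames(d$X))
  fit <- map_fit(d, "binomial", prior)
  perm <- withr::with_seed(42, sample.int(30))
  d_perm <- local_dataset(d$X[perm, ], d$y[perm], "A")
  fit_perm <- map_fit(d_perm, "binomial", prior)
  expect_equal(fit_perm$theta, fit$theta, tolerance = 1e-10)
  expect_equal(fit_perm$curvature, fit$curvature, tolerance = 1e-10)

  # at any fixed theta, doubling the rows doubles the likelihood curvature
  theta <- stats::setNames(c(0.3, -0.2), colnames(d$X))
  d2 <- local_dataset(rbind(d$X, d$X), c(d$y, d$y), "A")
  H1 <- log_posterior(theta, d, "binomial", prior)$hessian
  H2 <- log_posterior(theta, d2, "binomial", prior)$hessian
  Lam <- diag(0.1, 2)
  expect_equal(H2 + Lam, 2 * (H1 + Lam), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("with a vanishing prior the gaussian coefficient estimate approaches least squares", {
  n <- 1e4
  d <- withr::with_seed(51, {
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
    y <- 2 + X[, "x1"] - 3 * X[, "x2"] + rnorm(n)
    local_dataset(X, y, "A")
  })
  pn <- c(colnames(d$X), "log_sigma2")
  fit <- map_fit(d, "gaussian", bfi_prior(1e-10, pn))
  ols <- stats::coef(stats::lm(d$y ~ d$X[, "x1"] + d$X[, "x2"]))
  expect_equal(unname(fit$theta[colnames(d$X)]), unname(ols),
               tolerance = 1e-4)
})

test_that("prediction applies the inverse link and is monotone for the logit", {
  fam <- bfi_family("binomial")
  X <- cbind(`(Intercept)` = 1, x = c(0, 0))
  expect_equal(predict_glm(c(`(Intercept)` = 0, x = 0), X, fam), c(0.5, 0.5))
  expect_equal(
    predict_glm(c(`(Intercept)` = 1, x = 2),
                cbind(`(Intercept)` = 1, x = 3), "gaussian"),
    7)
  # duplicated rows give identical predictions; logit predictions are
  # monotone in a positively weighted covariate
  for (seed in 1:3) {
    theta <- withr::with_seed(seed, c(`(Intercept)` = rnorm(1),
                                      x = abs(rnorm(1)) + 0.1))
    xs <- sort(withr::with_seed(seed + 10, rnorm(20)))
    Xs <- cbind(`(Intercept)` = 1, x = xs)
    p <- predict_glm(theta, Xs, fam)
    expect_true(all(diff(p) > 0))
    expect_equal(p[1], predict_glm(theta, Xs[c(1, 1), ], fam)[2])
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(predict_glm(c(a = 1), cbind(b = 1), "gaussian"),
               "do not match")
})

test_that("the pooled fit equals row-stacked fitting and is center-order invariant", {
  ds <- make_gaussian_centers(3, c(20, 30, 25), p = 2, seed = 61)
  pn <- c(colnames(ds[[1]]$X), "log_sigma2")
  prior <- bfi_prior(0.05, pn)
  f1 <- pooled_map_fit(ds, "gaussian", prior)
  f2 <- pooled_map_fit(rev(ds), "gaussian", prior)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
  f_single <- pooled_map_fit(ds[1], "gaussian", prior)
  f_direct <- map_fit(ds[[1]], "gaussian", prior)
  expect_equal(f_single$theta, f_direct$theta)
  # all-quadratic case: matches the closed-form pooled ridge exactly
  famf <- bfi_family("gaussian", fixed_sigma2 = 1)
  priorf <- bfi_prior(0.3, colnames(ds[[1]]$X))
  fp <- pooled_map_fit(ds, famf, priorf)
  Xall <- do.call(rbind, lapply(ds, function(d) d$X))
  yall <- unlist(lapply(ds, function(d) d$y))
  expect_equal(unname(fp$theta), ridge_oracle(Xall, yall, diag(0.3, 3)),
               tolerance = 1e-9)
})

test_that("pooled standardization reproduces moments of the concatenated column", {
  x1 <- c(1, 2); x2 <- c(3, 4)
  ps <- pooled_standardization(data.frame(
    n = c(2, 2), mean = c(mean(x1), mean(x2)), sd = c(sd(x1), sd(x2))))
  expect_equal(ps$mean, 2.5)
  expect_equal(ps$sd, sd(c(x1, x2)))
  # random case, unequal sizes
  cols <- withr::with_seed(71, list(rnorm(13, 5, 2), rnorm(7, -1), rnorm(29)))
  ps2 <- pooled_standardization(data.frame(
    n = lengths(cols), mean = sapply(cols, mean), sd = sapply(cols, sd)))
  expect_equal(ps2$mean, mean(unlist(cols)))
  expect_equal(ps2$sd, sd(unlist(cols)))
  # single center is the identity
  ps3 <- pooled_standardization(data.frame(n = 13, mean = mean(cols[[1]]),
                                           sd = sd(cols[[1]])))
  expect_equal(ps3$sd, sd(cols[[1]]))
  # degenerate constant column
  expect_error(pooled_standardization(data.frame(n = c(5, 5), mean = c(1, 1),
                                                 sd = c(0, 0))),
               "zero")
})

test_that("standardizing centers with pooled moments equals standardizing the pooled column", {
  ds <- make_gaussian_centers(3, c(10, 15, 20), p = 2, seed = 81)
  std <- standardize_centers(ds, c("x1", "x2"), outcome = TRUE)
  pooled_x1 <- unlist(lapply(ds, function(d) d$X[, "x1"]))
  direct <- (pooled_x1 - mean(pooled_x1)) / sd(pooled_x1)
  expect_equal(unlist(lapply(std, function(d) d$X[, "x1"])), direct,
               ignore_attr = TRUE)
  pooled_y <- unlist(lapply(ds, function(d) d$y))
  expect_equal(unlist(lapply(std, function(d) d$y)),
               (pooled_y - mean(pooled_y)) / sd(pooled_y),
               ignore_attr = TRUE)
})

test_that("degenerate designs are refused unless the prior regularizes them", {
  X <- cbind(`(Intercept)` = 1, flat = rep(2, 10), x = rnorm(10))
  d <- withr::with_seed(91, local_dataset(X, rnorm(10), "A"))
  pn <- c(colnames(X), "log_sigma2")
  expect_error(map_fit(d, "gaussian", bfi_prior(c(0.1, 0, 0.1, 0.1), pn)),
               "flat direction")
  fit <- map_fit(d, "gaussian", bfi_prior(0.1, pn))
  expect_true(fit$converged)
})
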