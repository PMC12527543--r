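# Summary construction/validation and the one-shot combination under
# homogeneity, center-specific, and cluster-specific parameters.

test_that("local summaries round-trip through JSON bit-exactly and carry no rows", {
  ds <- make_gaussian_centers(1, 17, p = 2, seed = 101)
  su <- fit_summaries(ds, "gaussian", 0.2)[[1]]
  f <- withr::local_tempfile(fileext = ".json")
  write_local_summary(su, f)
  back <- read_local_summary(f)
  expect_identical(back$theta_hat, su$theta_hat)
  expect_identical(back$curvature, su$curvature)
  expect_identical(back$prior_precision, su$prior_precision)
  expect_identical(back$n, su$n)
  expect_identical(back$names, su$names)
  # payload is O(p^2): no component scales with the 17 subjects
  expect_false(any(vapply(su, function(x)
    is.numeric(x) && length(x) >= 17, logical(1))))
  expect_false(any(grepl("\"y\"|subjects", readLines(f))))
})

test_that("summary validation rejects tampered or mismatched payloads", {
  ds <- make_gaussian_centers(2, c(15, 18), p = 2, seed = 111)
  su <- fit_summaries(ds, "gaussian", 0.2)
  bad <- su[[1]]
  bad$curvature[1, 2] <- bad$curvature[1, 2] + 1   # breaks symmetry
  expect_error(validate_summaries(list(bad)), "not symmetric")
  neg <- su[[1]]
  neg$curvature <- -neg$curvature
  expect_error(validate_summaries(list(neg)), "positive definite")
  dropped <- su[[2]]
  keep <- setdiff(dropped$names, "log_sigma2")
  dropped$names <- keep
  dropped$theta_hat <- dropped$theta_hat[keep]
  dropped$curvature <- dropped$curvature[keep, keep]
  dropped$prior_precision <- dropped$prior_precision[keep, keep]
  expect_error(validate_summaries(list(su[[1]], dropped)), "mismatch")
  wrongfam <- su[[2]]
  wrongfam$family <- "binomial"
  expect_error(validate_summaries(list(su[[1]], wrongfam)), "family mismatch")
  # permuted parameter order is aligned, not rejected
  perm <- su[[2]]
  idx <- c(3, 1, 4, 2)
  perm$names <- perm$names[idx]
  perm$theta_hat <- perm$theta_hat[idx]
  perm$curvature <- perm$curvature[idx, idx]
  perm$prior_precision <- perm$prior_precision[idx, idx]
  aligned <- validate_summaries(list(su[[1]], perm))
  expect_identical(aligned[[2]]$names, su[[1]]$names)
  expect_equal(aligned[[2]]$theta_hat, su[[2]]$theta_hat)
  expect_silent(validate_summaries(su[1]))
})

test_that("an unconverged fit is refused as a shareable summary", {
  d <- make_gaussian_centers(1, 30, p = 1, seed = 121)[[1]]
  fit <- map_fit(d, "gaussian", bfi_prior(0.1, c(colnames(d$X), "log_sigma2")))
  fit$converged <- FALSE
  expect_error(make_local_summary(fit), "unconverged")
})

test_that("homogeneous combination reproduces the pooled least-squares slope on a printed example", {
  # two centers, no intercept, known variance, flat prior: exactly quadratic,
  # pooled slope = (1*1 + 1*3 + 2*2 + 2*2) / (1 + 1 + 4 + 4) = 10/7
  fam <- bfi_family("gaussian", fixed_sigma2 = 1)
  d1 <- local_dataset(cbind(x = c(1, 1)), c(1, 3), "A")
  d2 <- local_dataset(cbind(x = c(1, 2)), c(2, 2), "B")
  prior <- bfi_prior(0, "x")
  su <- lapply(list(d1, d2), function(d)
    make_local_summary(map_fit(d, fam, prior)))
  est <- bfi_combine(su, prior)
  expect_equal(unname(est$theta[["x"]]), 10 / 7, tolerance = 1e-12)
})

test_that("a single center with matching priors is returned unchanged", {
  ds <- make_logistic_centers(1, 80, seed = 131)
  prior <- bfi_prior(0.1, colnames(ds[[1]]$X))
  su <- fit_summaries(ds, "binomial", 0.1)
  est <- bfi_combine(su, prior)
  expect_equal(est$theta[names(su[[1]]$theta_hat)], su[[1]]$theta_hat,
               tolerance = 1e-10)
  # and with a nonempty heterogeneity spec it is the local MAP on the copies
  est_s <- bfi_combine(su, prior, het_spec(center_specific = "(Intercept)"))
  expect_equal(unname(est_s$theta[["(Intercept)[C01]"]]),
               unname(su[[1]]$theta_hat[["(Intercept)"]]), tolerance = 1e-10)
})

test_that("combination is invariant to the order of the summaries", {
  ds <- make_logistic_centers(4, c(40, 60, 50, 70), seed = 141)
  su <- fit_summaries(ds, "binomial", c(0.01, 0.01, 0.1, 0.1))
  prior <- bfi_prior(0.05, colnames(ds[[1]]$X))
  e1 <- bfi_combine(su, prior)
  e2 <- bfi_combine(rev(su), prior)
  expect_equal(e1$theta, e2$theta)
  expect_equal(e1$curvature, e2$curvature)
})

test_that("combined curvature minus combined prior equals the sum of likelihood curvatures", {
  ds <- make_logistic_centers(3, c(30, 45, 60), seed = 151)
  su <- fit_summaries(ds, "binomial", c(0.02, 0.2, 0.05))
  prior <- bfi_prior(0.7, colnames(ds[[1]]$X))
  est <- bfi_combine(su, prior)
  lik_sum <- Reduce(`+`, lapply(su, function(s)
    s$curvature - s$prior_precision))
  expect_equal(est$curvature - diag(0.7, 4), lik_sum, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("stratified combination equals penalized LS on the dummy-coded design (exact case)", {
  fam <- bfi_family("gaussian", fixed_sigma2 = 1)
  lam <- 0.3
  ds <- make_gaussian_centers(2, c(12, 19), p = 2, seed = 161,
                              intercepts = c(0, 2))
  prior <- bfi_prior(lam, colnames(ds[[1]]$X))
  su <- fit_summaries(ds, fam, lam)
  est <- bfi_combine(su, prior, het_spec(center_specific = "(Intercept)"))
  sd_des <- stack_dummy_design(ds, "(Intercept)", identity)
  oracle <- ridge_oracle(sd_des$X, sd_des$y,
                         stack_dummy_lambda(sd_des$cols, lam))
  expect_equal(unname(est$theta[sd_des$cols]), oracle, tolerance = 1e-9)
})

test_that("clustered combination equals penalized LS with cluster dummies (exact case)", {
  fam <- bfi_family("gaussian", fixed_sigma2 = 1)
  lam <- 0.2
  ds <- make_gaussian_centers(4, c(15, 12, 18, 20), p = 2, seed = 171,
                              intercepts = c(0, 0, 1.5, 1.5))
  cm <- c(C01 = "k1", C02 = "k1", C03 = "k2", C04 = "k2")
  prior <- bfi_prior(lam, colnames(ds[[1]]$X))
  su <- fit_summaries(ds, fam, lam)
  est <- bfi_combine(su, prior,
                     het_spec(cluster_specific = "(Intercept)",
                              cluster_map = cm))
  sd_des <- stack_dummy_design(ds, "(Intercept)", function(id) cm[[id]])
  oracle <- ridge_oracle(sd_des$X, sd_des$y,
                         stack_dummy_lambda(sd_des$cols, lam))
  expect_equal(unname(est$theta[sd_des$cols]), oracle, tolerance = 1e-9)
})

test_that("clustered combination reduces to stratified at K = L and homogeneous at K = 1", {
  ds <- make_logistic_centers(4, c(50, 60, 40, 70), seed = 181)
  su <- fit_summaries(ds, "binomial", 0.05)
  prior <- bfi_prior(0.05, colnames(ds[[1]]$X))
  ids <- vapply(su, function(s) s$center_id, character(1))

  est_hom <- bfi_combine(su, prior)
  est_str <- bfi_combine(su, prior, het_spec(center_specific = "(Intercept)"))
  est_str2 <- bfi_combine(su, prior, het_spec())
  expect_equal(est_str2$theta, est_hom$theta)

  est_kL <- bfi_combine(su, prior,
                        het_spec(cluster_specific = "(Intercept)",
                                 cluster_map = stats::setNames(ids, ids)))
  expect_equal(unname(est_kL$theta), unname(est_str$theta))
  expect_equal(unname(diag(est_kL$curvature)), unname(diag(est_str$curvature)))

  est_k1 <- bfi_combine(su, prior,
                        het_spec(cluster_specific = "(Intercept)",
                                 cluster_map = stats::setNames(
                                   rep("all", 4), ids)))
  expect_equal(unname(est_k1$theta[c("(Intercept)[all]", "x1", "x2", "x3")]),
               unname(est_hom$theta[c("(Intercept)", "x1", "x2", "x3")]))
})

test_that("center-specific error variances are supported through the nuisance name", {
  ds <- make_gaussian_centers(3, c(40, 45, 50), p = 2, seed = 191)
  # inflate one center's noise
  ds[[3]]$y <- ds[[3]]$y + withr::with_seed(192, rnorm(50, 0, 3))
  pn <- c(colnames(ds[[1]]$X), "log_sigma2")
  prior <- bfi_prior(0.05, pn)
  su <- fit_summaries(ds, "gaussian", 0.05)
  est <- bfi_combine(su, prior, het_spec(center_specific = "log_sigma2"))
  expect_setequal(grep("log_sigma2", est$names, value = TRUE),
                  paste0("log_sigma2[", c("C01", "C02", "C03"), "]"))
  expect_gt(est$theta[["log_sigma2[C03]"]], est$theta[["log_sigma2[C01]"]])
})

test_that("a non-positive-definite combined curvature raises instead of regularizing", {
  ds <- make_gaussian_centers(1, 10, p = 1, seed = 201)
  fam <- bfi_family("gaussian", fixed_sigma2 = 1)
  su <- fit_summaries(ds, fam, 5)  # strong local prior
  # a summary whose curvature is all prior: subtracting the local prior and
  # adding a zero combined prior leaves nothing to invert
  bad <- su[[1]]
  bad$curvature <- bad$prior_precision
  bad <- validate_summaries(list(bad))[[1]]
  expect_error(bfi_combine(list(bad), bfi_prior(0, colnames(ds[[1]]$X))),
               "not positive definite")
})

test_that("accumulating in any grouping, or adding a late center, is exact", {
  ds <- make_logistic_centers(5, c(30, 40, 50, 60, 45), seed = 211)
  su <- fit_summaries(ds, "binomial", 0.03)
  prior <- bfi_prior(0.03, colnames(ds[[1]]$X))
  full <- bfi_combine(su, prior)

  st_a <- bfi_accumulate(su[1:2])
  st_b <- bfi_accumulate(su[3:5], state = st_a)
  expect_identical(bfi_finalize(st_b, prior)$theta, full$theta)

  st_c <- bfi_accumulate(su[c(4, 1, 3)])
  st_d <- bfi_accumulate(su[c(5, 2)], state = st_c)
  expect_equal(bfi_finalize(st_d, prior)$theta, full$theta,
               tolerance = 1e-12)

  # stratified state accumulates a brand-new center block exactly too
  spec <- het_spec(center_specific = "(Intercept)")
  full_s <- bfi_combine(su, prior, spec)
  st_e <- bfi_accumulate(su[1:4], spec)
  st_f <- bfi_accumulate(su[5], spec, state = st_e)
  expect_equal(bfi_finalize(st_f, prior)$theta, full_s$theta,
               tolerance = 1e-12)

  expect_error(bfi_accumulate(su[2], state = st_a), "already in the state")
})

test_that("combination state round-trips through JSON and keeps additivity exact", {
  ds <- make_gaussian_centers(3, c(20, 25, 30), p = 2, seed = 221)
  su <- fit_summaries(ds, "gaussian", 0.1)
  prior <- bfi_prior(0.1, c(colnames(ds[[1]]$X), "log_sigma2"))
  full <- bfi_combine(su, prior)
  f <- withr::local_tempfile(fileext = ".json")
  write_bfi_state(bfi_accumulate(su[1:2]), f)
  st <- read_bfi_state(f)
  st2 <- bfi_accumulate(su[3], state = st)
  expect_equal(bfi_finalize(st2, prior)$theta, full$theta, tolerance = 1e-12)
})

test_that("reference coding is a bijection that leaves predictions unchanged", {
  ds <- make_gaussian_centers(3, c(25, 30, 35), p = 2, seed = 231,
                              intercepts = c(0, 1, 2))
  fam <- bfi_family("gaussian", fixed_sigma2 = 1)
  prior <- bfi_prior(0.2, colnames(ds[[1]]$X))
  su <- fit_summaries(ds, fam, 0.2)
  est <- bfi_combine(su, prior, het_spec(center_specific = "(Intercept)"))
  rc <- to_reference_coding(est, "C02")
  # the general value takes the plain name; the reference's contrast is gone
  expect_true("(Intercept)" %in% rc$names)
  expect_false("(Intercept)[C02]" %in% rc$names)
  expect_equal(rc$theta[["(Intercept)"]], est$theta[["(Intercept)[C02]"]])
  expect_equal(rc$theta[["(Intercept)[C01]"]],
               est$theta[["(Intercept)[C01]"]] -
                 est$theta[["(Intercept)[C02]"]])
  back <- undo_reference_coding(rc)
  expect_equal(back$theta, est$theta, tolerance = 1e-12)
  expect_equal(back$sd, est$sd, tolerance = 1e-12)
  for (d in ds)
    expect_equal(predict(rc, d), predict(est, d), tolerance = 1e-12)
  expect_error(to_reference_coding(est, "nope"), "not found")
})

test_that("center covariate regression recovers a two-point line and is MC-unbiased", {
  ds <- make_gaussian_centers(2, c(400, 400), p = 1, seed = 241,
                              intercepts = c(1, 3))
  fam <- bfi_family("gaussian", fixed_sigma2 = 1)
  prior <- bfi_prior(0.01, colnames(ds[[1]]$X))
  su <- fit_summaries(ds, fam, 0.01)
  est <- bfi_combine(su, prior, het_spec(center_specific = "(Intercept)"))
  z <- c(C01 = 0, C02 = 1)

  # plain least squares through two points
  fit0 <- center_covariate_fit(est, z, B = 0)
  gam <- est$theta[c("(Intercept)[C01]", "(Intercept)[C02]")]
  expect_equal(fit0$intercept, unname(gam[1]), tolerance = 1e-12)
  expect_equal(fit0$slope, unname(gam[2] - gam[1]), tolerance = 1e-12)

  # degenerate noise: draws collapse onto the plain fit
  est0 <- est
  est0$sd[] <- 0
  fitd <- center_covariate_fit(est0, z, B = 25, seed = 7)
  expect_equal(fitd$slope, fit0$slope, tolerance = 1e-12)
  expect_equal(unname(apply(fitd$draws, 2, stats::sd)), c(0, 0))

  # MC averaging is unbiased for the B = 0 line
  fitB <- center_covariate_fit(est, z, B = 10000, seed = 8)
  mc_se <- stats::sd(fitB$draws[, "slope"]) / sqrt(fitB$B)
  expect_lt(abs(fitB$slope - fit0$slope), 3 * mc_se)
  # determinism in the seed
  fitB2 <- center_covariate_fit(est, z, B = 10000, seed = 8)
  expect_identical(fitB$slope, fitB2$slope)

  expect_error(center_covariate_fit(est, c(C01 = 1, C02 = 1), B = 0),
               "unidentified")
})
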