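# Scenario generators and the replicate harness: multicenter logistic /
# linear scenarios, MSE bookkeeping against the pooled-data reference, a
# 25-hospital nurses-stress style linear-regression generator, and the
# prediction-agreement experiment.

#' Multicenter simulation scenario
#'
#' Describes a multicenter GLM scenario: per-center sample sizes, covariate
#' laws (two Gaussian covariates and one Bernoulli covariate), true
#' parameters, the heterogeneity structure of the generating model, priors,
#' and the number of replicates. Defaults give a four-center logistic
#' scenario with true intercept -1 and slopes (0.5, -0.5, 1); the
#' \code{"small"} and \code{"large"} size presets are per-center samples of
#' (50, 100, 150, 200) and (400, 800, 1200, 1600).
#'
#' @param n per-center sample sizes, or a preset \code{"small"} /
#'   \code{"large"}; the number of centers is its length.
#' @param family \code{"binomial"} (logistic outcome) or \code{"gaussian"}.
#' @param true_beta named true coefficients for \code{(Intercept)}, and the
#'   covariates \code{x1}, \code{x2}, \code{x3}.
#' @param heterogeneity generating structure: \code{"homogeneous"},
#'   \code{"covariate_shift"} (covariate laws differ per center),
#'   \code{"center_intercepts"}, or \code{"clustered"}.
#' @param center_intercepts true per-center intercepts (used for
#'   \code{"center_intercepts"}).
#' @param cluster_map named center -> cluster label vector and
#' @param cluster_intercepts named true per-cluster intercepts (used for
#'   \code{"clustered"}).
#' @param x1_mean,x1_sd,x2_mean,x2_sd,x3_prob covariate laws, recycled to one
#'   value per center. Under \code{"covariate_shift"} the defaults vary per
#'   center; otherwise they are common.
#' @param sigma2 error variance of the Gaussian outcome (ignored for
#'   binomial).
#' @param lambda_local per-center prior precision scalar(s), recycled.
#' @param lambda_combined prior precision of the combined analysis.
#' @param B number of simulation replicates for [run_scenario()].
#' @param seed integer seed for the replicate stream.
#' @return an object of class \code{scenario_config}.
#' @export
scenario_config <- function(n = "small",
                            family = "binomial",
                            true_beta = c("(Intercept)" = -1, x1 = 0.5,
                                          x2 = -0.5, x3 = 1),
                            heterogeneity = c("homogeneous", "covariate_shift",
                                              "center_intercepts", "clustered"),
                            center_intercepts = NULL,
                            cluster_map = NULL,
                            cluster_intercepts = NULL,
                            x1_mean = NULL, x1_sd = 1,
                            x2_mean = 1, x2_sd = NULL,
                            x3_prob = NULL,
                            sigma2 = 1,
                            lambda_local = 0.01,
                            lambda_combined = 0.01,
                            B = 100L, seed = 1L) {
  heterogeneity <- match.arg(heterogeneity)
  if (is.character(n))
    n <- switch(match.arg(n, c("small", "large")),
                small = c(50L, 100L, 150L, 200L),
                large = c(400L, 800L, 1200L, 1600L))
  L <- length(n)
  if (any(n < 1)) stop("per-center sample sizes must be >= 1")
  centers <- sprintf("C%02d", seq_len(L))

  shift <- heterogeneity == "covariate_shift"
  rc <- function(x, default, default_shift) {
    v <- if (!is.null(x)) x else if (shift) default_shift else default
    rep_len(v, L)
  }
  x1_mean <- rc(x1_mean, 0,   seq(0, 1.5, length.out = L))
  x1_sd   <- rc(x1_sd,   1,   1)
  x2_mean <- rc(x2_mean, 1,   1)
  x2_sd   <- rc(x2_sd,   2,   seq(1, 2.5, length.out = L))
  x3_prob <- rc(x3_prob, 0.5, seq(0.3, 0.7, length.out = L))
  if (any(x3_prob <= 0 | x3_prob >= 1)) stop("Bernoulli probabilities must be in (0,1)")
  if (any(c(x1_sd, x2_sd) <= 0)) stop("covariate sds must be > 0")

  if (heterogeneity == "center_intercepts") {
    if (is.null(center_intercepts))
      center_intercepts <- seq(-1.5, 0, length.out = L)
    if (length(center_intercepts) != L)
      stop("'center_intercepts' must have one value per center")
    names(center_intercepts) <- centers
  }
  if (heterogeneity == "clustered") {
    if (is.null(cluster_map)) {
      if (L %% 2L) stop("default cluster map needs an even number of centers")
      cluster_map <- stats::setNames(
        rep(c("K1", "K2"), each = L / 2L), centers)
    } else names(cluster_map) <- centers
    if (is.null(cluster_intercepts)) {
      labs <- sort_c(unique(unname(cluster_map)))
      cluster_intercepts <- stats::setNames(
        seq(-1.5, -0.5, length.out = length(labs)), labs)
    }
  }
  structure(list(L = L, n = as.integer(n), centers = centers,
                 family = family, true_beta = true_beta,
                 heterogeneity = heterogeneity,
                 center_intercepts = center_intercepts,
                 cluster_map = cluster_map,
                 cluster_intercepts = cluster_intercepts,
                 x1_mean = x1_mean, x1_sd = x1_sd,
                 x2_mean = x2_mean, x2_sd = x2_sd, x3_prob = x3_prob,
                 sigma2 = sigma2,
                 lambda_local = rep_len(lambda_local, L),
                 lambda_combined = lambda_combined,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "scenario_config")
}

# heterogeneity spec implied by the generating model
scenario_spec <- function(config) {
  switch(config$heterogeneity,
         center_intercepts = het_spec(center_specific = "(Intercept)"),
         clustered = het_spec(cluster_specific = "(Intercept)",
                              cluster_map = config$cluster_map),
         het_spec())
}

# true parameter vector on the stacked names of the scenario's spec
scenario_truth <- function(config) {
  spec <- scenario_spec(config)
  fam <- bfi_family(config$family)
  pn <- c(names(config$true_beta), fam$nuisance_name)
  layout <- stacked_layout(pn, config$centers, spec)
  truth <- stats::setNames(numeric(length(layout$stacked)), layout$stacked)
  for (i in seq_along(layout$stacked)) {
    nm <- layout$orig[i]; u <- layout$unit[i]
    truth[i] <- if (nm == "log_sigma2") log(config$sigma2)
      else if (u == "") config$true_beta[[nm]]
      else if (config$heterogeneity == "center_intercepts")
        config$center_intercepts[[u]]
      else config$cluster_intercepts[[u]]
  }
  truth
}

#' Simulate one center's data under a scenario
#'
#' Draws the center's covariates from its configured laws (two Gaussian, one
#' Bernoulli) and the outcome from the scenario's family given the true
#' linear predictor; deterministic given \code{seed}.
#'
#' @param config a [scenario_config()].
#' @param center center index in \code{1:L}.
#' @param seed integer seed.
#' @return a [local_dataset] (with a cluster label under the clustered
#'   scenario).
#' @export
simulate_center <- function(config, center, seed) {
  stopifnot(inherits(config, "scenario_config"),
            center >= 1L, center <= config$L)
  l <- as.integer(center)
  n <- config$n[l]
  with_seed(seed, {
    x1 <- stats::rnorm(n, config$x1_mean[l], config$x1_sd[l])
    x2 <- stats::rnorm(n, config$x2_mean[l], config$x2_sd[l])
    x3 <- stats::rbinom(n, 1L, config$x3_prob[l])
    X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, x3 = x3)
    icept <- switch(config$heterogeneity,
      center_intercepts = config$center_intercepts[[l]],
      clustered = config$cluster_intercepts[[
        config$cluster_map[[config$centers[l]]]]],
      config$true_beta[["(Intercept)"]])
    slopes <- config$true_beta[c("x1", "x2", "x3")]
    eta <- icept + drop(X[, c("x1", "x2", "x3")] %*% slopes)
    y <- if (config$family == "binomial")
      stats::rbinom(n, 1L, stats::plogis(eta))
    else
      eta + stats::rnorm(n, 0, sqrt(config$sigma2))
    local_dataset(X, y, center_id = config$centers[l],
                  cluster = if (config$heterogeneity == "clustered")
                    config$cluster_map[[config$centers[l]]] else NULL)
  })
}

#' @rdname simulate_center
#' @export
simulate_scenario_data <- function(config, seed) {
  stats::setNames(
    lapply(seq_len(config$L), function(l)
      simulate_center(config, l, child_seed(seed, l))),
    config$centers)
}

# fit all local MAPs of a scenario replicate and return summaries
fit_local_summaries <- function(datasets, family, lambda_local) {
  fam <- as_bfi_family(family)
  lapply(seq_along(datasets), function(l) {
    d <- datasets[[l]]
    pn <- param_names(fam, d$X)
    make_local_summary(map_fit(d, fam, bfi_prior(lambda_local[l], pn)))
  })
}

#' Run a scenario's replicate study and tabulate MSEs
#'
#' For each of B replicates: simulates every center, fits the local MAP
#' estimates, combines them into the federated (BFI) estimate, the
#' weighted-average baseline and — when all parameters are shared — the
#' single-center baseline, and fits the pooled-data MAP reference on the
#' merged rows. Accumulates, per stacked coordinate,
#' \eqn{MSE_e = B^{-1}\sum_b (\hat\theta_{e,b} - \hat\theta_{pooled,b})^2}
#' for each estimator e, and for the federated estimator also
#' \eqn{MSET = B^{-1}\sum_b (\hat\theta_{BFI,b} - \theta_{true})^2} against
#' the generating values. A replicate whose fits fail to converge is redrawn
#' with a fresh seed (at most 5 retries).
#'
#' @param config a [scenario_config()].
#' @return a data frame of class \code{mse_table}: one row per stacked
#'   parameter with columns \code{mse_bfi}, \code{mse_wav},
#'   \code{mse_single} (NA when undefined), \code{mset_bfi}; attributes
#'   \code{B}, \code{config}, \code{retries}.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- scenario_spec(config)
  fam <- bfi_family(config$family)
  truth <- scenario_truth(config)
  single_ok <- is_empty_spec(spec)
  acc <- list(bfi = 0, wav = 0, single = 0, mset = 0)
  retries <- 0L
  b <- 1L
  while (b <= config$B) {
    seed_b <- child_seed(config$seed, 1000L + b + 100000L * retries)
    res <- tryCatch({
      datasets <- simulate_scenario_data(config, seed_b)
      summaries <- fit_local_summaries(datasets, fam, config$lambda_local)
      pn <- summaries[[1]]$names
      comb_prior <- bfi_prior(config$lambda_combined, pn)
      est <- bfi_combine(summaries, comb_prior, spec)
      wav <- wav_combine(summaries, spec)
      pooled <- if (single_ok)
        pooled_map_fit(datasets, fam, comb_prior)
      else
        pooled_het_fit(datasets, fam, comb_prior, spec)
      if (!pooled$converged) stop("pooled fit did not converge")
      sc <- if (single_ok) single_center_estimate(summaries) else NULL
      list(est = est, wav = wav, pooled = pooled, sc = sc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      retries <- retries + 1L
      if (retries > 5L)
        stop("replicate ", b, " failed after 5 retries: ",
             conditionMessage(res))
      message("replicate ", b, " redrawn (seed ",
              child_seed(config$seed, 1000L + b + 100000L * retries),
              "): ", conditionMessage(res))
      next
    }
    nm <- res$est$names
    ref <- res$pooled$theta[nm]
    acc$bfi <- acc$bfi + (res$est$theta[nm] - ref)^2
    acc$wav <- acc$wav + (res$wav$theta[nm] - ref)^2
    if (single_ok) acc$single <- acc$single + (res$sc$theta[nm] - ref)^2
    acc$mset <- acc$mset + (res$est$theta[nm] - truth[nm])^2
    b <- b + 1L
  }
  nm <- names(truth)
  out <- data.frame(parameter = nm,
                    mse_bfi = unname(acc$bfi[nm] / config$B),
                    mse_wav = unname(acc$wav[nm] / config$B),
                    mse_single = if (single_ok)
                      unname(acc$single[nm] / config$B) else NA_real_,
                    mset_bfi = unname(acc$mset[nm] / config$B))
  class(out) <- c("mse_table", "data.frame")
  attr(out, "B") <- config$B
  attr(out, "heterogeneity") <- config$heterogeneity
  attr(out, "retries") <- retries
  out
}

#' Nurses-stress style multicenter linear-regression data
#'
#' Generates a 25-hospital dataset emulating a study of job-related stress
#' among nurses: per-hospital sample sizes uniform on 36..52; hospitals
#' partitioned into 9 small, 12 medium and 4 large; subject covariates age
#' and experience (correlated Gaussians, correlation \code{age_exp_cor}),
#' gender and wardtype (Bernoulli with per-hospital prevalences); a Gaussian
#' stress outcome whose intercept increases with hospital-size class, plus a
#' per-hospital intercept perturbation and a per-hospital error variance.
#' All ranges follow the descriptive statistics of the emulated study; the
#' regression coefficients and noise levels are package defaults documented
#' in the methods vignette.
#'
#' @param seed integer seed.
#' @param n_hospitals number of hospitals (default 25).
#' @param cluster_sizes named integer vector partitioning the hospitals into
#'   size classes (must sum to \code{n_hospitals}).
#' @param cluster_effects named baseline stress level per size class.
#' @param center_sd sd of the per-hospital intercept perturbation.
#' @param beta subject-covariate coefficients (age and experience per year,
#'   gender and wardtype as 0/1 contrasts).
#' @param sigma_range range of per-hospital error sds (uniform draw).
#' @return named list of [local_dataset] objects with cluster labels.
#' @export
generate_nurses_like <- function(seed,
                                 n_hospitals = 25L,
                                 cluster_sizes = c(small = 9L, medium = 12L,
                                                   large = 4L),
                                 cluster_effects = c(small = 3.7,
                                                     medium = 4.3,
                                                     large = 5.0),
                                 center_sd = 0.2,
                                 beta = c(age = 0.02, experience = -0.03,
                                          gender = 0.2, wardtype = 0.05),
                                 sigma_range = c(0.5, 1.0)) {
  if (sum(cluster_sizes) != n_hospitals)
    stop("'cluster_sizes' must sum to 'n_hospitals'")
  with_seed(seed, {
    ids <- sprintf("H%02d", seq_len(n_hospitals))
    labels <- sample(rep(names(cluster_sizes), cluster_sizes))
    out <- lapply(seq_len(n_hospitals), function(l) {
      n <- sample(36:52, 1L)
      mu_age <- stats::runif(1, 39.2, 46.3)
      mu_exp <- stats::runif(1, 14.9, 18.5)
      p_fem <- stats::runif(1, 0.61, 0.85)
      p_ward <- stats::runif(1, 0.48, 0.51)
      # correlated (age, experience): experience rises with age
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      r <- 0.6
      age <- mu_age + 8 * z1
      experience <- mu_exp + 6 * (r * z1 + sqrt(1 - r^2) * z2)
      gender <- stats::rbinom(n, 1L, p_fem)
      wardtype <- stats::rbinom(n, 1L, p_ward)
      X <- cbind(`(Intercept)` = 1, age = age, experience = experience,
                 gender = gender, wardtype = wardtype)
      icept <- cluster_effects[[labels[l]]] + stats::rnorm(1, 0, center_sd)
      sigma <- stats::runif(1, sigma_range[1], sigma_range[2])
      y <- icept + drop(X[, names(beta)] %*% beta) + stats::rnorm(n, 0, sigma)
      local_dataset(X, y, center_id = ids[l], cluster = labels[l])
    })
    stats::setNames(out, ids)
  })
}

#' Re-randomize subjects over centers
#'
#' Permutes all subjects (covariate rows and outcomes together) uniformly
#' across the centers, keeping each center's sample size fixed. The
#' resulting center populations are exchangeable draws from one pooled
#' population — a homogeneous counterpart of the input, used to show that a
#' prediction disagreement disappears when heterogeneity is removed.
#'
#' @param datasets list of [local_dataset] objects with identical columns.
#' @param seed integer seed.
#' @return list of [local_dataset] objects with the same ids, sizes and
#'   cluster labels, but randomly reassigned subjects.
#' @export
randomize_over_centers <- function(datasets, seed) {
  X <- do.call(rbind, lapply(datasets, `[[`, "X"))
  y <- unlist(lapply(datasets, `[[`, "y"), use.names = FALSE)
  with_seed(seed, {
    perm <- sample.int(length(y))
    X <- X[perm, , drop = FALSE]; y <- y[perm]
    offset <- 0L
    out <- lapply(datasets, function(d) {
      idx <- offset + seq_len(nrow(d$X))
      offset <<- offset + nrow(d$X)
      local_dataset(X[idx, , drop = FALSE], y[idx], center_id = d$center_id,
                    cluster = d$cluster,
                    center_covariate = d$center_covariate)
    })
    stats::setNames(out, names(datasets))
  })
}

#' Prediction-agreement experiment
#'
#' Repeats, \code{repeats} times: hold out approximately
#' \code{test_fraction} of each center's subjects as a test set; fit the
#' local MAP models on the training parts and combine them into the
#' federated estimate; predict the test outcomes; in parallel, fit the MAP
#' model on the merged training rows (the pooled reference, dummy-coded when
#' the model has cluster- or center-specific parameters) and predict the
#' same test rows. The paired predictions quantify how closely federated
#' estimation reproduces the pooled analysis at the prediction level.
#'
#' @param datasets list of Gaussian-outcome [local_dataset] objects.
#' @param spec a [het_spec()] for the aggregated model (\code{NULL} for the
#'   homogeneous model).
#' @param lambda scalar prior precision used locally and combined.
#' @param repeats number of split repetitions (default 50).
#' @param test_fraction held-out fraction per center (default 0.10).
#' @param seed integer seed.
#' @return an object of class \code{prediction_agreement}: \code{pairs}
#'   (data frame with \code{rep}, \code{center_id}, \code{y},
#'   \code{pred_bfi}, \code{pred_pooled}) and \code{mean_sq_disagreement}.
#' @export
prediction_agreement_experiment <- function(datasets, spec = NULL,
                                            lambda = 0.01, repeats = 50L,
                                            test_fraction = 0.10, seed = 1L) {
  spec <- if (is.null(spec)) het_spec() else spec
  fam <- bfi_family("gaussian")
  pn <- param_names(fam, datasets[[1]]$X)
  prior <- bfi_prior(lambda, pn)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    split <- with_seed(child_seed(seed, r), {
      lapply(datasets, function(d) {
        n <- nrow(d$X)
        n_test <- max(1L, round(test_fraction * n))
        test <- sample.int(n, n_test)
        list(train = local_dataset(d$X[-test, , drop = FALSE], d$y[-test],
                                   d$center_id, d$cluster, d$center_covariate),
             test = local_dataset(d$X[test, , drop = FALSE], d$y[test],
                                  d$center_id, d$cluster, d$center_covariate))
      })
    })
    train <- lapply(split, `[[`, "train")
    test <- lapply(split, `[[`, "test")
    summaries <- fit_local_summaries(train, fam, rep(lambda, length(train)))
    est <- bfi_combine(summaries, prior, spec)
    pooled <- if (is_empty_spec(spec)) pooled_map_fit(train, fam, prior)
              else pooled_het_fit(train, fam, prior, spec)
    layout <- est$layout
    rr <- lapply(test, function(d) {
      p_bfi <- predict(est, d)
      th_pool <- pooled$theta
      beta_names <- setdiff(names(th_pool), fam$nuisance_name)
      if (is_empty_spec(spec)) {
        p_pool <- predict_glm(th_pool, d$X, fam)
      } else {
        map <- layout$maps[[d$center_id]]
        Xs <- matrix(0, nrow(d$X), length(beta_names),
                     dimnames = list(NULL, beta_names))
        for (nm in colnames(d$X)) Xs[, map[[nm]]] <- d$X[, nm]
        p_pool <- predict_glm(th_pool[beta_names], Xs, fam)
      }
      data.frame(rep = r, center_id = d$center_id, y = d$y,
                 pred_bfi = p_bfi, pred_pooled = p_pool)
    })
    rows[[r]] <- do.call(rbind, rr)
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 mean_sq_disagreement =
                   mean((pairs$pred_bfi - pairs$pred_pooled)^2),
                 repeats = repeats, test_fraction = test_fraction),
            class = "prediction_agreement")
}

#' @export
print.prediction_agreement <- function(x, ...) {
  cat("Prediction-agreement experiment:", x$repeats, "repeats,",
      sprintf("%.0f%%", 100 * x$test_fraction), "test split\n")
  cat("  mean squared disagreement (federated vs pooled):",
      signif(x$mean_sq_disagreement, 4), "\n")
  invisible(x)
}

#' @export
#' @importFrom graphics abline
plot.prediction_agreement <- function(x, ...) {
  plot(x$pairs$pred_pooled, x$pairs$pred_bfi,
       xlab = "pooled-data MAP prediction",
       ylab = "federated (BFI) prediction",
       pch = 16, cex = 0.4, col = "#00000055", ...)
  abline(0, 1, col = "goldenrod", lwd = 2)
  invisible(x)
}
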