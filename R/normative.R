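# Warped Bayesian linear regression normative models: per node x metric,
# response regressed on a cubic B-spline basis of age plus sex, with a
# sinh-arcsinh likelihood warp fitted by profile marginal likelihood.

warp_forward <- function(y_std, epsilon, delta) {
  sinh(delta * asinh(y_std) - epsilon)
}

warp_log_jacobian <- function(y_std, epsilon, delta) {
  log(delta) + log(cosh(delta * asinh(y_std) - epsilon)) -
    0.5 * log1p(y_std^2)
}

warp_inverse <- function(t, epsilon, delta) {
  sinh((asinh(t) + epsilon) / delta)
}

design_matrix <- function(age, sex, knots, boundary, degree = 3L) {
  B <- splines::bs(age, knots = knots, degree = degree,
                   Boundary.knots = boundary, intercept = FALSE)
  cbind(1, B, sex = sex)
}

# Empirical-Bayes Gaussian linear regression: evidence-maximizing (alpha,
# beta) by fixed point, returning posterior and log marginal likelihood.
blr_evidence <- function(X, t, max_iter = 50L) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  Xtt <- crossprod(X, t)
  alpha <- 1e-3; beta <- 1 / max(stats::var(t), 1e-12)
  ev <- -Inf
  for (it in seq_len(max_iter)) {
    A <- alpha * diag(p) + beta * XtX
    Sigma <- chol2inv(chol(A))
    m <- beta * Sigma %*% Xtt
    rss <- sum((t - X %*% m)^2)
    gam <- p - alpha * sum(diag(Sigma))
    alpha_new <- gam / max(sum(m^2), 1e-12)
    beta_new <- max(n - gam, 1e-6) / max(rss, 1e-12)
    if (abs(log(alpha_new / alpha)) < 1e-8 &&
        abs(log(beta_new / beta)) < 1e-8) {
      alpha <- alpha_new; beta <- beta_new; break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  A <- alpha * diag(p) + beta * XtX
  cholA <- chol(A)
  Sigma <- chol2inv(cholA)
  m <- beta * Sigma %*% Xtt
  rss <- sum((t - X %*% m)^2)
  ev <- 0.5 * (p * log(alpha) + n * log(beta) - beta * rss -
                 alpha * sum(m^2) - 2 * sum(log(diag(cholA))) -
                 n * log(2 * pi))
  list(m = as.numeric(m), Sigma = Sigma, alpha = alpha, beta = beta,
       evidence = ev)
}

#' Fit a normative model for one nodal phenotype
#'
#' Warped Bayesian linear regression of a response on age and sex in a
#' reference (control) sample. The standardized response is mapped through a
#' sinh-arcsinh warp `t = sinh(delta * asinh(y_std) - epsilon)` and modeled
#' by empirical-Bayes Bayesian linear regression on a cubic B-spline age
#' basis (interior knots at training-age quantiles) plus sex. The warp
#' parameters are chosen by bounded quasi-Newton maximization of the profile
#' marginal likelihood including the warp Jacobian; if that optimization does
#' not converge the model falls back to the identity warp (`epsilon = 0,
#' delta = 1`) with a flag.
#'
#' @param y Numeric response vector (one node x metric phenotype).
#' @param age,sex Covariate vectors (years; sex coded 0/1).
#' @param n_knots Number of interior spline knots (default 5).
#' @param degree Spline degree (default cubic).
#' @param warp Fit the sinh-arcsinh warp (default TRUE); FALSE fixes the
#'   identity warp.
#' @param min_train Minimum training-sample floor (default 50).
#' @return Object of class `normative_model`.
#' @export
fit_normative <- function(y, age, sex, n_knots = 5L, degree = 3L,
                          warp = TRUE, min_train = 50L) {
  stopifnot(length(y) == length(age), length(y) == length(sex))
  if (length(y) < min_train)
    stop(sprintf("need at least %d training controls, got %d",
                 min_train, length(y)))
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd < 1e-12) stop("degenerate response: zero variance")
  y_std <- (y - y_mean) / y_sd
  boundary <- range(age)
  probs <- seq_len(n_knots) / (n_knots + 1)
  knots <- unique(stats::quantile(age, probs, names = FALSE))
  X <- design_matrix(age, sex, knots, boundary, degree)

  fit_given_warp <- function(par) {
    eps <- par[1]; delta <- exp(par[2])
    t <- warp_forward(y_std, eps, delta)
    if (any(!is.finite(t))) return(list(obj = Inf))
    fit <- blr_evidence(X, t)
    obj <- -(fit$evidence + sum(warp_log_jacobian(y_std, eps, delta)))
    list(obj = obj, fit = fit)
  }

  epsilon <- 0; delta <- 1; converged <- TRUE
  if (warp) {
    opt <- tryCatch(
      stats::optim(c(0, 0), function(p) fit_given_warp(p)$obj,
                   method = "L-BFGS-B",
                   lower = c(-2, log(0.25)), upper = c(2, log(4)),
                   control = list(factr = 1e9, maxit = 60)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      epsilon <- opt$par[1]; delta <- exp(opt$par[2])
      converged <- opt$convergence %in% c(0L, 1L)
    } else {
      converged <- FALSE
    }
    if (!converged) { epsilon <- 0; delta <- 1 }
  }
  t <- warp_forward(y_std, epsilon, delta)
  fit <- blr_evidence(X, t)

  structure(list(coefficients = fit$m, Sigma = fit$Sigma,
                 alpha = fit$alpha, beta = fit$beta,
                 warp = list(epsilon = epsilon, delta = delta,
                             converged = converged),
                 y_mean = y_mean, y_sd = y_sd,
                 knots = knots, boundary = boundary, degree = degree,
                 n_train = length(y),
                 calibration = list(offset = 0, scale = 1)),
            class = "normative_model")
}

predictive_moments <- function(model, age, sex) {
  X <- design_matrix(age, sex, model$knots, model$boundary, model$degree)
  mu <- as.numeric(X %*% model$coefficients)
  var_pred <- rowSums((X %*% model$Sigma) * X) + 1 / model$beta
  list(mu = mu, sd = sqrt(var_pred))
}

#' Deviation z-score under a normative model
#'
#' `z = (t(y) - mu_pred) / sqrt(sigma2_pred + sigma2_noise)` in warped space,
#' then shifted/scaled by any site calibration stored in the model. Monotone
#' increasing in `y` at fixed covariates. Ages outside the training range
#' (plus a tolerance band of `band_frac` times the range on each side) are
#' rejected.
#'
#' @param model A `normative_model`.
#' @param y,age,sex Held-out observations and covariates.
#' @param band_frac Extrapolation tolerance as a fraction of the training age
#'   range (default 0.1); the age basis itself is evaluated at the clamped
#'   age, so the band only controls how far outside the training support a
#'   prediction is still accepted.
#' @return Numeric z-scores.
#' @export
deviation_z <- function(model, y, age, sex, band_frac = 0.1) {
  if (isTRUE(model$degenerate)) return(rep(0, length(y)))
  span <- diff(model$boundary)
  lo <- model$boundary[1] - band_frac * span
  hi <- model$boundary[2] + band_frac * span
  if (any(age < lo | age > hi))
    stop("age outside the tolerance band around the training range")
  y_std <- (y - model$y_mean) / model$y_sd
  t <- warp_forward(y_std, model$warp$epsilon, model$warp$delta)
  pm <- predictive_moments(model, pmin(pmax(age, model$boundary[1]),
                                       model$boundary[2]), sex)
  z <- (t - pm$mu) / pm$sd
  (z - model$calibration$offset) / model$calibration$scale
}

#' Recalibrate a normative model to a new site
#'
#' Transfer strategy for applying a pretrained reference model to a new
#' cohort: the predictive distribution's offset and scale are re-estimated
#' from adaptation controls' warped-space residual z-scores; the original
#' coefficients are untouched. Recalibrated z on the adaptation controls has
#' mean ~ 0 and SD ~ 1, and recalibrating twice on the same data equals
#' recalibrating once.
#'
#' @param model A `normative_model`.
#' @param y,age,sex Adaptation controls from the new site (>= 20).
#' @param site Optional site label used in error messages.
#' @return The recalibrated `normative_model`.
#' @export
transfer_recalibrate <- function(model, y, age, sex, site = "new site") {
  if (isTRUE(model$degenerate)) return(model)
  if (length(y) < 20)
    stop(sprintf("too few adaptation controls (%d) for site %s",
                 length(y), site))
  raw <- model
  raw$calibration <- list(offset = 0, scale = 1)
  z <- deviation_z(raw, y, age, sex)
  model$calibration <- list(offset = mean(z), scale = stats::sd(z))
  model
}

#' Fit normative models for every node x metric phenotype
#'
#' @param topo Subjects x nodes x metrics array (training controls only).
#' @param age,sex Covariates aligned to the first array dimension.
#' @param ... Passed to [fit_normative()].
#' @return List of lists of `normative_model` (metrics within nodes), class
#'   `normative_model_set`. A phenotype that is constant across all training
#'   controls (for example a participation coefficient pinned at 0 by an
#'   isolated node) carries no normative information; it gets a degenerate
#'   placeholder model whose deviations are all 0, with a warning.
#' @export
fit_normative_batch <- function(topo, age, sex, ...) {
  stopifnot(length(dim(topo)) == 3)
  metrics <- dimnames(topo)[[3]]
  models <- lapply(seq_len(dim(topo)[2]), function(node)
    stats::setNames(lapply(seq_along(metrics), function(m) {
      y <- topo[, node, m]
      if (stats::sd(y) < 1e-12) {
        warning(sprintf(
          "node %d %s constant across controls; deviations set to 0",
          node, metrics[m]))
        structure(list(degenerate = TRUE, y_mean = mean(y),
                       boundary = range(age),
                       calibration = list(offset = 0, scale = 1)),
                  class = "normative_model")
      } else {
        fit_normative(y, age, sex, ...)
      }
    }), metrics))
  structure(list(models = models, metrics = metrics),
            class = "normative_model_set")
}

#' Recalibrate a whole model set to a new site
#'
#' @param model_set A `normative_model_set`.
#' @param topo Adaptation controls' subjects x nodes x metrics array.
#' @param age,sex Adaptation covariates.
#' @param site Site label for error messages.
#' @return Recalibrated `normative_model_set`.
#' @export
transfer_recalibrate_batch <- function(model_set, topo, age, sex,
                                       site = "new site") {
  for (node in seq_along(model_set$models))
    for (m in seq_along(model_set$metrics))
      model_set$models[[node]][[m]] <-
        transfer_recalibrate(model_set$models[[node]][[m]],
                             topo[, node, m], age, sex, site)
  model_set
}

#' Deviation tensor for a batch of subjects
#'
#' Scores every subject at every node x metric, with extreme-deviation masks
#' at `|z| >= threshold` (default 2, i.e. beyond ~2 SD of the normative
#' predictive distribution).
#'
#' @param model_set A `normative_model_set`.
#' @param topo Subjects x nodes x metrics array.
#' @param age,sex Covariates.
#' @param threshold Extreme-deviation threshold on |z| (default 2).
#' @return List with `z` (subjects x nodes x metrics), `extreme_pos`,
#'   `extreme_neg` (mutually exclusive logical arrays), and `threshold`.
#' @export
deviation_tensor <- function(model_set, topo, age, sex, threshold = 2) {
  z <- array(NA_real_, dim = dim(topo), dimnames = dimnames(topo))
  for (node in seq_len(dim(topo)[2]))
    for (m in seq_along(model_set$metrics))
      z[, node, m] <- deviation_z(model_set$models[[node]][[m]],
                                  topo[, node, m], age, sex)
  list(z = z, extreme_pos = z >= threshold, extreme_neg = z <= -threshold,
       threshold = threshold)
}

#' Check for residual site effects in deviations
#'
#' Two-fold cross-validated linear SVM balanced accuracy predicting site from
#' flattened deviations. Accuracy near chance (1 / number of sites) indicates
#' successful harmonization.
#'
#' @param z Subjects x features matrix (flattened deviation tensor).
#' @param sites Site labels.
#' @param seed Fold seed.
#' @return Balanced accuracy (mean per-site recall).
#' @export
check_site_effects <- function(z, sites, seed = 1L) {
  sites <- factor(sites)
  if (nlevels(sites) < 2) stop("need at least 2 sites")
  z <- as.matrix(z)
  n <- nrow(z)
  folds <- with_seed(seed, sample(rep_len(1:2, n)))
  pred <- factor(rep(NA_character_, n), levels = levels(sites))
  for (f in 1:2) {
    fit <- e1071::svm(z[folds != f, , drop = FALSE], sites[folds != f],
                      kernel = "linear", scale = FALSE)
    pred[folds == f] <- stats::predict(fit, z[folds == f, , drop = FALSE])
  }
  recalls <- vapply(levels(sites), function(s)
    mean(pred[sites == s] == s), numeric(1))
  mean(recalls)
}
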