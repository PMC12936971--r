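sim_identity_data <- function(n, seed = 1, sd = 0.2) {
  set.seed(seed)
  age <- runif(n, 6, 18)
  sex <- rbinom(n, 1, 0.5)
  mu <- 2 + 0.3 * plogis((age - 11) / 1.5) + 0.1 * sex
  list(y = mu + rnorm(n, 0, sd), age = age, sex = sex, mu = mu)
}

test_that("warp round-trip is identity across the support", {
  y <- seq(-4, 4, length.out = 401)
  for (par in list(c(0, 1), c(0.5, 1.3), c(-0.8, 0.6))) {
    t <- msnbiotypes:::warp_forward(y, par[1], par[2])
    back <- msnbiotypes:::warp_inverse(t, par[1], par[2])
    expect_equal(back, y, tolerance = 1e-9)
  }
})

test_that("the fitted mean curve tracks the generative truth", {
  d <- sim_identity_data(5000, seed = 2)
  m <- fit_normative(d$y, d$age, d$sex)
  grid_age <- seq(7.5, 16.5, length.out = 50)  # interior grid; spline tails are noisier
  pm <- msnbiotypes:::predictive_moments(m, grid_age, rep(0, 50))
  mu_true <- 2 + 0.3 * plogis((grid_age - 11) / 1.5)
  # back-transform predictions into the response scale
  mu_hat <- msnbiotypes:::warp_inverse(pm$mu, m$warp$epsilon,
                                       m$warp$delta) * m$y_sd + m$y_mean
  # average tracking error within a 0.05 SD band (pointwise estimation
  # noise at n = 5000 is ~0.04 SD, so the maximum over a grid is larger)
  expect_lt(mean(abs(mu_hat - mu_true)), 0.05 * sd(d$y))
  expect_lt(max(abs(mu_hat - mu_true)), 0.1 * sd(d$y))
})

test_that("deviation z-scores are calibrated, centred, and monotone", {
  d <- sim_identity_data(5000, seed = 3)
  m <- fit_normative(d$y[1:2500], d$age[1:2500], d$sex[1:2500])
  idx <- 2501:5000
  z <- deviation_z(m, d$y[idx], d$age[idx], d$sex[idx])
  expect_lt(abs(mean(abs(z) >= 2) - 2 * pnorm(-2)), 0.01)
  # observations at the predicted median score near zero
  pm <- msnbiotypes:::predictive_moments(m, 12, 1)
  y_med <- msnbiotypes:::warp_inverse(pm$mu, m$warp$epsilon,
                                      m$warp$delta) * m$y_sd + m$y_mean
  expect_lt(abs(deviation_z(m, y_med, 12, 1)), 0.05)
  # strictly increasing in y at fixed covariates
  set.seed(4)
  for (i in 1:10) {
    a <- runif(1, 7, 17); s <- rbinom(1, 1, 0.5)
    ys <- sort(runif(8, 1.5, 3))
    zs <- deviation_z(m, ys, rep(a, 8), rep(s, 8))
    expect_true(all(diff(zs) > 0))
  }
  expect_error(deviation_z(m, 2, 25, 0), "tolerance band")
})

test_that("skewed responses recover their warp and identity warp is exact", {
  set.seed(5)
  n <- 5000
  age <- runif(n, 6, 18); sex <- rbinom(n, 1, 0.5)
  base <- sinh((asinh(rnorm(n)) + 0.5) / 1)      # epsilon 0.5, delta 1
  y <- 2 + 0.3 * plogis((age - 11) / 1.5) + 0.2 * base
  m <- fit_normative(y, age, sex)
  expect_gte(m$warp$epsilon, 0.3)
  expect_lte(m$warp$epsilon, 0.7)
  # with the warp disabled the model reduces to plain Bayesian regression
  d <- sim_identity_data(800, seed = 6)
  m0 <- fit_normative(d$y, d$age, d$sex, warp = FALSE)
  expect_equal(m0$warp$epsilon, 0)
  expect_equal(m0$warp$delta, 1)
  X <- msnbiotypes:::design_matrix(d$age, d$sex, m0$knots, m0$boundary,
                                   m0$degree)
  fit <- msnbiotypes:::blr_evidence(X, (d$y - m0$y_mean) / m0$y_sd)
  expect_equal(m0$coefficients, fit$m, tolerance = 1e-9)
  expect_error(fit_normative(d$y[1:30], d$age[1:30], d$sex[1:30]),
               "at least 50")
})

test_that("transfer recalibration restores control calibration", {
  d <- sim_identity_data(2000, seed = 7)
  m <- fit_normative(d$y, d$age, d$sex)
  # null transfer: adaptation data from the training distribution
  d2 <- sim_identity_data(400, seed = 8)
  m_null <- transfer_recalibrate(m, d2$y, d2$age, d2$sex)
  expect_lt(abs(m_null$calibration$offset), 0.15)
  expect_lt(abs(m_null$calibration$scale - 1), 0.1)
  # site with a +2 SD mean shift
  d3 <- sim_identity_data(200, seed = 9)
  y_shift <- d3$y + 2 * sd(d$y)
  m_sh <- transfer_recalibrate(m, y_shift, d3$age, d3$sex, site = "siteX")
  z <- deviation_z(m_sh, y_shift, d3$age, d3$sex)
  expect_lt(abs(mean(z)), 0.1)
  # idempotent on the same data
  m_sh2 <- transfer_recalibrate(m_sh, y_shift, d3$age, d3$sex)
  z2 <- deviation_z(m_sh2, y_shift, d3$age, d3$sex)
  expect_equal(z, z2, tolerance = 1e-9)
  expect_error(transfer_recalibrate(m, y_shift[1:10], d3$age[1:10],
                                    d3$sex[1:10], site = "tiny"), "tiny")
})

test_that("site-effect screening behaves under null and injected shifts", {
  set.seed(10)
  z <- matrix(rnorm(200 * 20), 200, 20)
  sites <- rep(c("a", "b"), each = 100)
  acc_null <- check_site_effects(z, sample(sites), seed = 1)
  expect_lt(abs(acc_null - 0.5), 0.12)
  z_shift <- z; z_shift[sites == "b", ] <- z_shift[sites == "b", ] + 1
  acc_shift <- check_site_effects(z_shift, sites, seed = 1)
  expect_gt(acc_shift, 0.8)
  expect_identical(check_site_effects(z, sites, seed = 2),
                   check_site_effects(z, sites, seed = 2))
  expect_error(check_site_effects(z, rep("a", 200)), "2 sites")
})

test_that("Phi(z) of held-out controls is uniform for a well-specified model", {
  pass <- 0L
  for (s in 1:10) {
    d <- sim_identity_data(4000, seed = 20 + s)
    m <- fit_normative(d$y[1:2000], d$age[1:2000], d$sex[1:2000])
    z <- deviation_z(m, d$y[2001:4000], d$age[2001:4000], d$sex[2001:4000])
    if (stats::ks.test(pnorm(z), "punif")$p.value > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 9)
})
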