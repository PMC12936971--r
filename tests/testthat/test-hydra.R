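# independent reference for the single-face objective, optimized generically
ref_l2svm <- function(X, y, u, C) {
  obj <- function(par) {
    w <- par[-length(par)]; b <- par[length(par)]
    xi <- pmax(0, 1 - y * (X %*% w + b))
    0.5 * sum(w^2) + C * sum(u * xi^2)
  }
  fit <- optim(rep(0, ncol(X) + 1), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  list(w = fit$par[-length(fit$par)], b = fit$par[length(fit$par)])
}

test_that("k = 1 reduces to a single max-margin classifier", {
  d <- planted_features(60, 40, 12, 1, block = 4, shift = 2, seed = 1)
  m <- fit_hydra(d$X, d$y, k = 1, n_restarts = 2, seed = 1, C = 0.5)
  Xs <- scale(d$X)
  u <- ifelse(d$y, 1 / sum(d$y), 1 / sum(!d$y))
  ref <- ref_l2svm(Xs, ifelse(d$y, 1, -1), u, 0.5)
  dec_pkg <- Xs %*% m$W[, 1] + m$b[1]
  dec_ref <- Xs %*% ref$w + ref$b
  expect_lt(max(abs(dec_pkg - dec_ref)), 1e-4)
  expect_true(all(m$case_labels == 1))
})

test_that("well-separated planted case clusters are recovered", {
  d <- planted_features(150, 150, 40, 2, block = 10, shift = 2.5, seed = 2)
  m <- fit_hydra(d$X, d$y, k = 2, n_restarts = 5, seed = 3)
  expect_gte(adjusted_rand_index(m$case_labels, d$biotype), 0.95)
  # mixed informed + random restarts cap the mean pairwise agreement well
  # below 1 even when recovery is exact; require clearly-above-chance
  expect_gte(m$stability_ari, 0.4)
  # the alternating objective never increases between recorded iterations
  expect_true(all(diff(m$objective_trace) <= 1e-6 * pmax(1,
    abs(m$objective_trace[-length(m$objective_trace)]))))
  # duplicating every subject leaves the clustering unchanged
  d2 <- list(X = rbind(d$X, d$X), y = c(d$y, d$y))
  m2 <- fit_hydra(d2$X, d2$y, k = 2, n_restarts = 5, seed = 3)
  expect_gte(adjusted_rand_index(m2$case_labels[seq_along(d$biotype)],
                                 m$case_labels), 0.95)
  expect_error(fit_hydra(d$X, rep(TRUE, 300), 2), "both")
  expect_error(fit_hydra(d$X, d$y, k = 200), "exceed")
})

test_that("expression scores are affine, aligned by name, and self-consistent", {
  d <- planted_features(100, 80, 20, 2, block = 6, shift = 2, seed = 4)
  m <- fit_hydra(d$X, d$y, k = 2, n_restarts = 4, seed = 5)
  es <- expression_scores(m, d$X[d$y, , drop = FALSE])
  expect_gte(mean(es$assignment == m$case_labels), 0.95)
  # affine in x: score(a x1 + (1-a) x2) = a s1 + (1-a) s2
  x1 <- d$X[5, , drop = FALSE]; x2 <- d$X[160, , drop = FALSE]
  mix <- 0.3 * x1 + 0.7 * x2
  colnames(mix) <- colnames(d$X)
  s_mix <- expression_scores(m, mix)$scores
  s_lin <- 0.3 * expression_scores(m, x1)$scores +
    0.7 * expression_scores(m, x2)$scores
  expect_equal(s_mix, s_lin, tolerance = 1e-10)
  # feature mismatch errors name the offending columns
  bad <- d$X[1:3, ]; colnames(bad)[1] <- "other"
  expect_error(expression_scores(m, bad), "missing.*f001")
  # normalized variant rescales by the face norms
  es_n <- expression_scores(m, d$X[1:5, ], normalized = TRUE)
  expect_equal(es_n$scores[, 1] * sqrt(sum(m$W[, 1]^2)),
               expression_scores(m, d$X[1:5, ])$scores[, 1],
               tolerance = 1e-10)
})

test_that("cross-validated k selection finds the planted count", {
  d <- planted_features(120, 120, 40, 3, block = 8, shift = 2.5, seed = 6)
  cv <- cv_select_k(d$X, d$y, k_grid = 2:4, n_folds = 5, seed = 7,
                    n_restarts = 3)
  expect_equal(cv$chosen_k, 3)
  expect_gte(cv$ari["k3"], max(cv$ari[c("k2", "k4")]))
  m3 <- cv$full_models[["k3"]]
  expect_gte(adjusted_rand_index(m3$case_labels, d$biotype), 0.9)
})

test_that("permutation validation separates structure from noise", {
  d <- planted_features(80, 80, 24, 2, block = 8, shift = 2.5, seed = 8)
  pv <- permutation_validate(d$X, d$y, k = 2, n_perm = 19, seed = 9,
                             n_restarts = 3)
  expect_lte(pv$p, 0.05)
  expect_gte(pv$p, 1 / 20)
  expect_gt(pv$observed, quantile(pv$null, 0.95))
})

test_that("split-half agreement peaks at the planted count", {
  d <- planted_features(100, 100, 30, 2, block = 9, shift = 2.5, seed = 10)
  agree <- split_half_validate(d$X, d$y, k_grid = 2:3, n_splits = 2,
                               seed = 11, n_restarts = 3)
  expect_true(all(agree >= -1 & agree <= 1))
  expect_equal(unname(which.max(agree)), 1)     # k = 2 wins
  agree2 <- split_half_validate(d$X, d$y, k_grid = 2:3, n_splits = 2,
                                seed = 11, n_restarts = 3)
  expect_identical(agree, agree2)
})

test_that("a serialized model transfers losslessly through JSON", {
  d <- planted_features(60, 50, 10, 2, block = 3, shift = 2.5, seed = 12)
  m <- fit_hydra(d$X, d$y, k = 2, n_restarts = 3, seed = 13)
  path <- tempfile(fileext = ".json")
  save_hydra(m, path)
  m2 <- load_hydra(path)
  expect_equal(m2$W, m$W, tolerance = 1e-12)
  expect_equal(m2$case_labels, m$case_labels)
  es1 <- expression_scores(m, d$X)$assignment
  es2 <- expression_scores(m2, d$X)$assignment
  expect_identical(es1, es2)
})
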