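test_that("map fusion standardizes, averages, and handles degeneracy", {
  set.seed(1)
  m <- rnorm(30)
  fused <- fuse_maps(list(m, m, m))
  expect_equal(as.vector(fused), as.numeric(scale(m)), tolerance = 1e-12)
  expect_warning(f2 <- fuse_maps(list(m, rep(0, 30))), "zero-variance")
  expect_equal(as.vector(f2), as.numeric(scale(m)), tolerance = 1e-12)
  # permutation equivariance
  perm <- sample(30)
  maps <- list(rnorm(30), rnorm(30), rnorm(30))
  expect_equal(as.vector(fuse_maps(lapply(maps, function(x) x[perm]))),
               as.vector(fuse_maps(maps))[perm], tolerance = 1e-12)
  # alternative aggregations stay available
  expect_equal(as.vector(fuse_maps(maps, "sum")), Reduce(`+`, maps))
})

test_that("annotation correlations hit trivial cases and control FDR", {
  geom <- data.frame(region_index = 1:50, fibonacci_sphere(50))
  set.seed(2)
  fused <- generate_annotation_maps(geom, 1, smoothness = 0.5,
                                    seed = 10)$map001
  ann <- generate_annotation_maps(geom, 19, smoothness = 0.5, seed = 11)
  ann$self <- fused
  res <- annotation_correlation(fused, ann, geom, n_surrogates = 199,
                                seed = 12)
  self_row <- res[res$annotation == "self", ]
  expect_equal(self_row$r, 1)
  expect_equal(self_row$p_spin, 1 / 200)
  # Spearman correlation is invariant to monotone transforms
  res2 <- annotation_correlation(exp(fused), ann, geom, n_surrogates = 199,
                                 seed = 12)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  # independent smooth nulls: expect at most ~1 FDR-significant hit
  null_res <- res[res$annotation != "self", ]
  expect_lte(sum(null_res$q < 0.05), 2)
})

test_that("PLS decoding identifies a planted term and is scale-stable", {
  geom <- data.frame(region_index = 1:100, fibonacci_sphere(100))
  set.seed(3)
  terms <- generate_annotation_maps(geom, 8, smoothness = 0.4, seed = 20)
  term_mat <- as.matrix(terms[, -1])
  fused <- term_mat[, 3] + rnorm(100, 0, 0.01)
  res <- pls_decode(fused, term_mat, geom, n_boot = 200, n_surrogates = 199,
                    seed = 21)
  expect_equal(which.max(abs(res$terms$z)), 3)
  expect_gt(res$explained_variance, 0.9)
  expect_lt(res$p_spin, 0.05)
  # predictor scaling leaves weights' correlation structure unchanged
  res10 <- pls_decode(fused, term_mat * 10, geom, n_boot = 200,
                      n_surrogates = 199, seed = 21)
  expect_equal(res10$weights, res$weights, tolerance = 1e-10)
  expect_error(pls_decode(fused[1:20], term_mat[1:20, ],
                          geom[1:20, ], n_boot = 10, n_surrogates = 100),
               "30 nodes")
  expect_error(pls_decode(fused, term_mat[, 1, drop = FALSE], geom),
               "2 term")
})

test_that("spin nulls respect smooth-map autocorrelation where naive tests fail", {
  geom <- data.frame(region_index = 1:80, fibonacci_sphere(80))
  perms <- spin_permutations(geom, 199, seed = 30)
  set.seed(31)
  spin_rej <- naive_rej <- logical(60)
  for (i in seq_len(60)) {
    a <- generate_annotation_maps(geom, 1, smoothness = 0.8,
                                  seed = 1000 + i)$map001
    b <- generate_annotation_maps(geom, 1, smoothness = 0.8,
                                  seed = 5000 + i)$map001
    spin_rej[i] <- spin_test(a, b, geom, perms = perms)$p < 0.05
    naive_rej[i] <- cor.test(a, b, method = "spearman",
                             exact = FALSE)$p.value < 0.05
  }
  expect_lte(mean(spin_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 60) + 0.02)
  expect_gt(mean(naive_rej), mean(spin_rej))   # parametric p is anticonservative
})
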