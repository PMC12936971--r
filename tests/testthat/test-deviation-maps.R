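test_that("overlap and difference maps count correctly", {
  z <- array(0, dim = c(10, 4, 1), dimnames = list(NULL, NULL, "degree"))
  z[1:3, 2, 1] <- 2.5
  z[4, 3, 1] <- -2.1
  devs <- devs_from_z(z)
  om <- overlap_map(devs, rep(TRUE, 10), "degree")
  expect_equal(om, c(0, 0.3, 0.1, 0))
  pos <- overlap_map(devs, rep(TRUE, 10), "degree", "positive")
  neg <- overlap_map(devs, rep(TRUE, 10), "degree", "negative")
  expect_equal(om, pos + neg)                 # masks are exclusive
  expect_error(overlap_map(devs, rep(FALSE, 10), "degree"), "empty")
  expect_equal(difference_map(om, om), rep(0, 4))
  expect_equal(difference_map(0.10, 0.0221), 7.79)
  expect_equal(difference_map(om, neg), -difference_map(neg, om))
})

test_that("group permutation test is calibrated with the add-one rule", {
  set.seed(1)
  z <- array(rnorm(200 * 12 * 1, sd = 1.3), dim = c(200, 12, 1),
             dimnames = list(NULL, NULL, "degree"))
  devs <- devs_from_z(z)
  labels <- rep(c(TRUE, FALSE), each = 100)
  res <- group_permutation_test(devs, labels, "degree", n_perm = 499,
                                seed = 5)
  expect_true(all(res$p >= 1 / 500 & res$p <= 1))
  # labels independent of deviations: p roughly uniform over nodes
  expect_gt(suppressWarnings(
    stats::ks.test(res$p, "punif"))$p.value, 0.01)
  expect_error(group_permutation_test(devs, labels, "degree", n_perm = 50),
               "at least 100")
  # within-site shuffling keeps group sizes per site
  site <- rep(c("a", "b"), times = 100)
  res2 <- group_permutation_test(devs, labels, "degree", n_perm = 199,
                                 seed = 6, site = site)
  expect_true(all(res2$p > 0 & res2$p <= 1))
})

test_that("spin test preserves value multisets and hits its trivial cases", {
  geom <- data.frame(region_index = 1:40, fibonacci_sphere(40))
  set.seed(2)
  map_a <- rnorm(40); map_b <- rnorm(40)
  perms <- spin_permutations(geom, 200, seed = 3)
  # rotation only reassigns: each surrogate is a draw from the same multiset
  expect_true(all(map_a[perms[1, ]] %in% map_a))
  # identity mapping reproduces the observed statistic exactly
  id_perm <- matrix(1:40, 1)
  res_id <- spin_test(map_a, map_b, geom, perms = id_perm)
  expect_equal(res_id$observed, cor(map_a, map_b, method = "spearman"))
  # a map against itself: r = 1 and the smallest attainable p
  res_self <- spin_test(map_a, map_a, geom, perms = perms)
  expect_equal(res_self$observed, 1)
  expect_equal(res_self$p, 1 / 201)
  # duplicate coordinates are rejected
  bad <- geom; bad[2, 2:4] <- bad[1, 2:4]
  expect_error(spin_test(map_a, map_b, bad, n_surrogates = 100), "duplicate")
  # per-node difference mode returns one p per node, bounded below
  res_d <- spin_test(map_a, map_b, geom, stat = "difference", perms = perms)
  expect_length(res_d$p, 40)
  expect_true(all(res_d$p >= 1 / 201))
})

test_that("spin test rejects at the nominal rate on independent maps", {
  geom <- data.frame(region_index = 1:60, fibonacci_sphere(60))
  perms <- spin_permutations(geom, 199, seed = 8)
  set.seed(9)
  rej <- replicate(200, {
    a <- rnorm(60); b <- rnorm(60)
    spin_test(a, b, geom, perms = perms)$p < 0.05
  })
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.01)
})

test_that("BH adjustment matches the hand-computed step-up", {
  res <- fdr_bh(c(0.01, 0.02, 0.04, 0.5), q_level = 0.05)
  expect_equal(res$q, c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(fdr_bh(rep(1, 6))$reject))
  set.seed(3)
  p <- runif(30)
  expect_true(all(fdr_bh(p)$q >= p))
})

test_that("proportion and burden effect sizes match closed forms", {
  expect_equal(cohen_h(0.25, 0.09), 2 * asin(0.5) - 2 * asin(0.3))
  expect_lt(abs(cohen_h(0.25, 0.09) - 0.4378), 1e-4)
  expect_equal(cohen_h(0.4, 0.4), 0)
  expect_equal(cohen_h(0.3, 0.1), -cohen_h(0.1, 0.3))

  # identical groups: d = 0
  z <- array(rnorm(100 * 6), dim = c(100, 6, 1),
             dimnames = list(NULL, NULL, "degree"))
  z <- z[c(1:50, 1:50), , , drop = FALSE]
  devs <- devs_from_z(z)
  burden <- extreme_burden_compare(devs, rep(c(TRUE, FALSE), each = 50))
  expect_equal(burden$cohen_d, 0)
  # planted mean shift of one extreme node at count SD 3 recovers d ~ 1/3
  set.seed(11)
  counts_case <- rnorm(500, 5, 3); counts_ctrl <- rnorm(500, 4, 3)
  d_hat <- (mean(counts_case) - mean(counts_ctrl)) /
    sqrt((var(counts_case) + var(counts_ctrl)) / 2)
  expect_lt(abs(d_hat - 1 / 3), 0.1)
  # per-subject counts are integers within [0, R]
  cnt <- rowSums(devs$extreme_pos[, , 1] | devs$extreme_neg[, , 1])
  expect_true(all(cnt == round(cnt) & cnt >= 0 & cnt <= 6))
})

test_that("biotype chi-squared tests match contingency oracles", {
  # equal extreme frequencies across biotypes give a null statistic
  z <- array(0, dim = c(30, 2, 1), dimnames = list(NULL, NULL, "degree"))
  z[c(1:3, 11:13, 21:23), 1, 1] <- 3
  devs <- devs_from_z(z)
  bt <- rep(1:3, each = 10)
  res <- suppressWarnings(biotype_node_chisq(devs, bt, "degree"))
  expect_equal(res$chisq[1], 0, tolerance = 1e-12)
  expect_equal(res$chisq[2], 0)
  # hand-checked 2x2 table [[20,80],[5,95]] without continuity correction
  z2 <- array(0, dim = c(200, 1, 1), dimnames = list(NULL, NULL, "degree"))
  z2[c(1:20, 101:105), 1, 1] <- 3
  devs2 <- devs_from_z(z2)
  bt2 <- rep(1:2, each = 100)
  res2 <- biotype_node_chisq(devs2, bt2, "degree")
  oracle <- stats::chisq.test(matrix(c(20, 5, 80, 95), 2), correct = FALSE)
  expect_equal(res2$chisq[1], unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(res2$chisq[1], 200 * (20 * 95 - 80 * 5)^2 /
                 (100 * 100 * 25 * 175), tolerance = 1e-10)
})
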