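test_that("generator is bit-identical under a fixed seed", {
  spec <- cohort_spec(n_controls = 20L, n_cases = 15L, n_regions = 12L,
                      n_samples_per_region = 30L, k_true = 2L, seed = 3L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ground_truth$biotype_nodes, b$ground_truth$biotype_nodes)
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(cohort_spec(n_regions = 6), "at least 8")
  expect_error(cohort_spec(k_true = 0), "at least 1")
  expect_error(cohort_spec(effect_size = -1), "non-negative")
  expect_error(cohort_spec(n_cases = 2, k_true = 3), "exceed")
  expect_error(cohort_spec(n_regions = 8, k_true = 5), "disjoint")
  expect_error(cohort_spec(age_range = c(4, 18)), "within")
})

test_that("cohort table respects its invariants", {
  sim <- small_chain()$sim
  co <- sim$cohort
  expect_true(all(co$inattention >= 0 & co$inattention <= 1))
  expect_true(all(co$hyperactivity >= 0 & co$hyperactivity <= 1))
  expect_true(all(is.na(co$true_biotype[co$group == "control"])))
  expect_true(all(!is.na(co$true_biotype[co$group == "case"])))
  expect_true(all(vapply(sim$samples, function(m) all(m > 0), logical(1))))
  # node geometry on the unit sphere, modules partition all regions
  norms <- sqrt(rowSums(as.matrix(sim$geometry[, c("x", "y", "z")])^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_true(all(sim$geometry$true_module >= 1))
  # biotype node sets disjoint
  nodes <- sim$ground_truth$biotype_nodes
  expect_equal(anyDuplicated(unlist(nodes)), 0)
})

test_that("zero effect size leaves case and control distributions identical", {
  rejections <- 0L
  for (s in 1:20) {
    spec <- cohort_spec(n_controls = 100L, n_cases = 100L, n_regions = 10L,
                        n_samples_per_region = 20L, k_true = 2L,
                        effect_size = 0, n_sites = 1L, seed = 100L + s)
    sim <- generate_cohort(spec)
    means <- t(vapply(sim$samples, rowMeans, numeric(10)))
    grp <- sim$cohort$group
    p <- suppressWarnings(
      stats::ks.test(means[grp == "case", 1], means[grp == "control", 1]))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4)  # ~1% expected; binomial(20, .01) upper tail
})

test_that("a template validation cohort shares the planted structure", {
  spec <- cohort_spec(n_controls = 15L, n_cases = 15L, n_regions = 16L,
                      n_samples_per_region = 20L, k_true = 2L, seed = 5L)
  a <- generate_cohort(spec)
  spec_v <- cohort_spec(n_controls = 10L, n_cases = 12L, n_regions = 16L,
                        n_samples_per_region = 20L, k_true = 2L, seed = 99L)
  v <- generate_cohort(spec_v, template = a$ground_truth)
  expect_identical(v$ground_truth$biotype_nodes, a$ground_truth$biotype_nodes)
  expect_identical(v$ground_truth$region_params, a$ground_truth$region_params)
  expect_false(identical(v$cohort$age, a$cohort$age[1:22]))
  bad_spec <- cohort_spec(n_regions = 20L, k_true = 2L, seed = 1L)
  expect_error(generate_cohort(bad_spec, template = a$ground_truth),
               "n_regions")
})

test_that("annotation maps: determinism, linkage, and white-noise limit", {
  geom <- small_chain()$sim$geometry
  m1 <- generate_annotation_maps(geom, 3, smoothness = 0.5, seed = 11)
  m2 <- generate_annotation_maps(geom, 3, smoothness = 0.5, seed = 11)
  expect_identical(m1, m2)
  expect_error(generate_annotation_maps(geom, 2, smoothness = 0), "positive")

  # linked map reproduces the requested spatial correlation
  geom_big <- data.frame(region_index = 1:1000, fibonacci_sphere(1000))
  target <- generate_annotation_maps(geom_big, 1, smoothness = 0.4,
                                     seed = 2)$map001
  linked <- generate_annotation_maps(geom_big, 1, smoothness = 0.4,
                                     link = list(target = target, rho = 0.99),
                                     seed = 3)$map001
  expect_gte(stats::cor(linked, target), 0.9)
  expect_error(generate_annotation_maps(geom_big, 1, smoothness = 0.4,
                                        link = list(target = target, rho = 1),
                                        seed = 3), "rho")

  # vanishing correlation length: neighbouring nodes uncorrelated
  maps <- generate_annotation_maps(geom_big, 30, smoothness = 1e-4, seed = 4)
  vals <- as.matrix(maps[, -1])
  nn_cor <- stats::cor(as.vector(vals[-1, ]), as.vector(vals[-1000, ]))
  expect_lt(abs(nn_cor), 0.05)
})
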