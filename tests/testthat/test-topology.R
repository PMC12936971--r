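test_that("proportional thresholding keeps exactly the strongest edges", {
  set.seed(1)
  S <- matrix(0, 4, 4)
  S[upper.tri(S)] <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  S <- S + t(S); diag(S) <- 1
  th <- threshold_network(S, 0.5)
  A <- th$adjacency
  expect_equal(sum(A[upper.tri(A)] > 0), 3)
  expect_setequal(A[upper.tri(A)][A[upper.tri(A)] > 0], c(0.9, 0.8, 0.7))
  # sparsity 1 keeps everything; thresholding is idempotent
  full <- threshold_network(S, 1)$adjacency
  expect_equal(sum(full[upper.tri(full)] > 0), 6)
  again <- threshold_network(A + diag(4), 0.5)$adjacency
  expect_equal(again, A)
  expect_error(threshold_network(S, 0), "sparsity")
})

test_that("hub metrics match hand values", {
  # degree
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 0.5; A[1, 3] <- A[3, 1] <- 0.3
  expect_equal(degree_centrality(A)[1], 0.8)
  expect_equal(degree_centrality(matrix(0, 4, 4)), rep(0, 4))
  # nodal efficiency on the path graph A - B - C with unit weights
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 1; P[2, 3] <- P[3, 2] <- 1
  expect_equal(nodal_efficiency(P), c(0.75, 1, 0.75))
  K <- matrix(1, 5, 5); diag(K) <- 0
  expect_equal(nodal_efficiency(K), rep(1, 5))
  # participation coefficient
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- 1                      # node 1 only inside module 1
  B[3, 4] <- B[4, 3] <- 1
  part <- c(1, 1, 2, 2)
  expect_equal(participation_coefficient(B, part), rep(0, 4))
  C <- matrix(0, 3, 3)
  C[1, 2] <- C[2, 1] <- 1; C[1, 3] <- C[3, 1] <- 1  # node 1 split equally
  expect_equal(participation_coefficient(C, c(1, 1, 2))[1], 0.5)
  iso <- matrix(0, 3, 3); iso[2, 3] <- iso[3, 2] <- 1
  expect_equal(participation_coefficient(iso, c(1, 2, 2))[1], 0)
})

test_that("metrics agree with brute-force references on random graphs", {
  for (s in 1:25) {
    R <- sample(4:10, 1)
    A <- random_graph(R, density = runif(1, 0.3, 0.9), seed = s)
    part <- sample(1:3, R, replace = TRUE)
    expect_equal(degree_centrality(A), ref_degree(A), tolerance = 1e-12)
    expect_equal(nodal_efficiency(A), ref_efficiency(A), tolerance = 1e-10)
    expect_equal(participation_coefficient(A, part),
                 ref_participation(A, part), tolerance = 1e-12)
  }
})

test_that("metrics are permutation-equivariant and monotone in edge weight", {
  A <- random_graph(8, density = 0.6, seed = 9)
  part <- c(1, 1, 2, 2, 3, 3, 1, 2)
  perm <- sample(8)
  Ap <- A[perm, perm]
  expect_equal(degree_centrality(Ap), degree_centrality(A)[perm])
  expect_equal(nodal_efficiency(Ap), nodal_efficiency(A)[perm],
               tolerance = 1e-12)
  expect_equal(participation_coefficient(Ap, part[perm]),
               participation_coefficient(A, part)[perm], tolerance = 1e-12)
  # weakening all edges at a node cannot raise its degree or efficiency
  B <- A; B[3, ] <- 0.5 * B[3, ]; B[, 3] <- 0.5 * B[, 3]
  expect_lte(degree_centrality(B)[3], degree_centrality(A)[3])
  expect_lte(nodal_efficiency(B)[3], nodal_efficiency(A)[3] + 1e-12)
})

test_that("consensus partition recovers planted structure deterministically", {
  # two disconnected cliques
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 0.8; A[5:8, 5:8] <- 0.8; diag(A) <- 0
  lab <- consensus_partition(list(A), seed = 3)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  expect_identical(lab, consensus_partition(list(A), seed = 3))
  # planted modules in the synthetic chain are recovered on control graphs
  ch <- small_chain()
  expect_gte(adjusted_rand_index(ch$partition,
                                 ch$sim$geometry$true_module), 0.9)
})
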