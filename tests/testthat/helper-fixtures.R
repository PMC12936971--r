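# Shared fixtures and independent reference implementations used as oracles.

# Floyd-Warshall all-pairs shortest paths on a weighted adjacency matrix,
# edge length 1/weight; independent oracle for nodal efficiency.
fw_distances <- function(A) {
  R <- nrow(A)
  D <- matrix(Inf, R, R)
  diag(D) <- 0
  D[A > 0] <- 1 / A[A > 0]
  for (k in seq_len(R))
    for (i in seq_len(R))
      for (j in seq_len(R))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Naive per-node reference metrics.
ref_degree <- function(A) rowSums(A)
ref_efficiency <- function(A) {
  D <- fw_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  rowSums(inv) / (nrow(A) - 1)
}
ref_participation <- function(A, part) {
  k <- rowSums(A)
  sapply(seq_len(nrow(A)), function(i) {
    if (k[i] == 0) return(0)
    1 - sum(sapply(unique(part), function(m)
      (sum(A[i, part == m]) / k[i])^2))
  })
}

# random symmetric weighted adjacency with given density
random_graph <- function(R, density = 0.5, seed = 1) {
  set.seed(seed)
  A <- matrix(0, R, R)
  ut <- upper.tri(A)
  w <- runif(sum(ut))
  w[runif(sum(ut)) > density] <- 0
  A[ut] <- w
  A + t(A)
}

# Small planted-feature dataset for HYDRA-style tests: controls N(0, I),
# cases shifted by -shift on their biotype's feature block.
planted_features <- function(n_ctrl, n_case, p, k, block = 10, shift = 1.5,
                             seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_ctrl + n_case) * p), n_ctrl + n_case, p)
  bt <- rep_len(seq_len(k), n_case)
  blocks <- split(seq_len(k * block), rep(seq_len(k), each = block))
  for (i in seq_len(n_case))
    X[n_ctrl + i, blocks[[bt[i]]]] <- X[n_ctrl + i, blocks[[bt[i]]]] - shift
  colnames(X) <- sprintf("f%03d", seq_len(p))
  list(X = X, y = c(rep(FALSE, n_ctrl), rep(TRUE, n_case)), biotype = bt,
       blocks = blocks)
}

# Tiny deviation tensor built directly from a z array.
devs_from_z <- function(z, threshold = 2) {
  list(z = z, extreme_pos = z >= threshold, extreme_neg = z <= -threshold,
       threshold = threshold)
}

# One moderate planted cohort chain, built lazily and cached for the session
# (several test files probe different stages of the same chain).
.chain_cache <- new.env(parent = emptyenv())
small_chain <- function() {
  if (!is.null(.chain_cache$chain)) return(.chain_cache$chain)
  spec <- cohort_spec(n_controls = 120L, n_cases = 90L, n_regions = 24L,
                      n_sites = 2L, n_samples_per_region = 150L,
                      k_true = 2L, effect_size = 3, seed = 42L)
  sim <- generate_cohort(spec)
  msns <- build_msn_batch(sim$samples, method = "kde")
  ctrl <- sim$cohort$group == "control"
  graphs <- lapply(msns[ctrl], function(m)
    threshold_network(m, 0.3)$adjacency)
  partition <- consensus_partition(graphs, seed = 7L)
  topo <- topology_profile_batch(msns, partition, 0.3)
  models <- fit_normative_batch(topo[ctrl, , ], sim$cohort$age[ctrl],
                                sim$cohort$sex[ctrl])
  devs <- deviation_tensor(models, topo, sim$cohort$age, sim$cohort$sex)
  .chain_cache$chain <- list(spec = spec, sim = sim, msns = msns,
                             ctrl = ctrl, partition = partition,
                             topo = topo, models = models, devs = devs)
  .chain_cache$chain
}
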