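#' Proportionally threshold a similarity matrix
#'
#' Keeps the top `sparsity * R * (R - 1) / 2` off-diagonal edges by weight
#' (ties at the cutoff broken by smaller (i, j) lexicographic order) and
#' zeroes the rest. The result stays symmetric with a zero diagonal.
#'
#' @param matrix R x R symmetric similarity matrix.
#' @param sparsity Retained edge fraction in (0, 1\].
#' @return List with `adjacency` (thresholded weighted matrix) and
#'   `connected` (logical; FALSE flags a disconnected result, which nodal
#'   efficiency handles via zero inverse distance).
#' @export
threshold_network <- function(matrix, sparsity = 0.3) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  R <- nrow(matrix)
  ut <- upper.tri(matrix)
  w <- matrix[ut]
  idx <- which(ut, arr.ind = TRUE)
  m <- round(sparsity * R * (R - 1) / 2)
  # order by weight desc, then lexicographic (i, j) for ties at the cutoff
  ord <- order(-w, idx[, 1], idx[, 2])
  keep <- ord[seq_len(min(m, length(ord)))]
  A <- base::matrix(0, R, R)
  A[cbind(idx[keep, 1], idx[keep, 2])] <- w[keep]
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  list(adjacency = A, connected = igraph::is_connected(g))
}

#' Weighted degree centrality (node strength)
#'
#' @param adjacency Symmetric non-negative weighted adjacency matrix.
#' @return Per-node strength (sum of incident edge weights).
#' @export
degree_centrality <- function(adjacency) {
  stopifnot(all(adjacency >= 0))
  rowSums(adjacency)
}

#' Nodal efficiency
#'
#' Mean inverse shortest-path length from each node to all others, with edge
#' lengths `1 / weight` (standard for similarity-weighted networks) and
#' `1 / d = 0` for unreachable pairs.
#'
#' @param adjacency Symmetric non-negative weighted adjacency matrix.
#' @return Per-node efficiency.
#' @export
nodal_efficiency <- function(adjacency) {
  R <- nrow(adjacency)
  if (R < 2) return(rep(0, R))
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           weighted = TRUE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  rowSums(inv) / (R - 1)
}

#' Participation coefficient
#'
#' Guimera-Amaral participation coefficient
#' `PC(i) = 1 - sum_s (k_is / k_i)^2` on a fixed community partition, where
#' `k_is` is node i's strength into module s. Isolated nodes get 0 by
#' convention.
#'
#' @param adjacency Symmetric non-negative weighted adjacency matrix.
#' @param partition Integer community labels covering all nodes.
#' @return Per-node coefficient in \[0, 1 - 1/M\] for M modules.
#' @export
participation_coefficient <- function(adjacency, partition) {
  stopifnot(length(partition) == nrow(adjacency))
  k <- rowSums(adjacency)
  mods <- sort(unique(partition))
  k_is <- vapply(mods, function(m)
    rowSums(adjacency[, partition == m, drop = FALSE]), numeric(nrow(adjacency)))
  pc <- 1 - rowSums((k_is / pmax(k, .Machine$double.eps))^2)
  pc[k == 0] <- 0
  pc
}

#' Consensus community partition of the mean control network
#'
#' Modularity-maximizing (Louvain) partition of a mean network, made stable
#' by consensus over `n_reps` seeded restarts: co-assignment frequencies are
#' clustered again until the partition is reproducible. Used as the single
#' fixed partition for all subjects' participation coefficients, so the
#' metric is comparable across subjects.
#'
#' @param graphs List of weighted adjacency matrices (typically training
#'   controls' thresholded MSNs).
#' @param gamma Resolution parameter of modularity.
#' @param n_reps Number of seeded Louvain restarts.
#' @param seed Integer seed; output is deterministic given it.
#' @return Integer community labels.
#' @export
consensus_partition <- function(graphs, gamma = 1, n_reps = 20L, seed = 1L) {
  stopifnot(length(graphs) >= 1)
  A <- Reduce(`+`, graphs) / length(graphs)
  R <- nrow(A)
  run_louvain <- function(W, rep_seed) {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    with_seed(rep_seed, igraph::membership(
      igraph::cluster_louvain(g, resolution = gamma)))
  }
  labels <- vapply(seq_len(n_reps), function(r)
    as.integer(run_louvain(A, derive_seed(seed, paste0("louvain", r)))),
    integer(R))
  co <- matrix(0, R, R)
  for (r in seq_len(n_reps)) co <- co + outer(labels[, r], labels[, r], `==`)
  co <- co / n_reps
  # one consensus pass: cluster the co-assignment matrix itself
  as.integer(run_louvain(co, derive_seed(seed, "consensus")))
}

#' Topology profile of one subject
#'
#' The three hubness metrics of one subject's MSN after proportional
#' thresholding.
#'
#' @param msn R x R similarity matrix.
#' @param partition Fixed community labels (from [consensus_partition()]).
#' @param sparsity Retained edge fraction.
#' @return Nodes x 3 matrix with columns `degree`, `efficiency`,
#'   `participation`.
#' @export
topology_profile <- function(msn, partition, sparsity = 0.3) {
  A <- threshold_network(msn, sparsity)$adjacency
  cbind(degree = degree_centrality(A),
        efficiency = nodal_efficiency(A),
        participation = participation_coefficient(A, partition))
}

#' Topology profiles for a batch of subjects
#'
#' @param msns Named list of similarity matrices.
#' @param partition Fixed community labels.
#' @param sparsity Retained edge fraction.
#' @return Subjects x nodes x 3 array (dimnames carry subject ids and metric
#'   names).
#' @export
topology_profile_batch <- function(msns, partition, sparsity = 0.3) {
  R <- nrow(msns[[1]])
  out <- array(NA_real_, dim = c(length(msns), R, 3),
               dimnames = list(names(msns), NULL,
                               c("degree", "efficiency", "participation")))
  for (s in seq_along(msns))
    out[s, , ] <- topology_profile(msns[[s]], partition, sparsity)
  out
}
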