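#' Discretized density estimate on a shared grid
#'
#' Histogram density of a positive sample vector on a shared evaluation grid
#' (bin edges), floor-regularized so every bin has strictly positive mass and
#' Kullback-Leibler divergences stay finite.
#'
#' @param values Numeric sample vector (>= 10 samples, non-constant).
#' @param grid Numeric vector of bin edges covering the pooled sample range.
#' @param floor_eps Probability floor added to every bin before
#'   renormalization; with `G` bins the minimum probability is
#'   `floor_eps / (1 + floor_eps * G)`.
#' @param method `"histogram"` (default) or `"kde"` (Gaussian kernel density
#'   evaluated at the bin midpoints, bandwidth by Silverman's rule). The
#'   kernel estimate is preferable when the sample count per region is not
#'   much larger than the bin count, where raw histograms leave many empty
#'   floor-valued bins that dominate the divergence.
#' @return Probability vector of length `length(grid) - 1`, summing to 1,
#'   strictly positive.
#' @export
estimate_density <- function(values, grid, floor_eps = 1e-10,
                             method = c("histogram", "kde")) {
  method <- match.arg(method)
  if (length(values) < 10) stop("need at least 10 samples")
  if (max(values) == min(values))
    stop("degenerate distribution: all samples equal")
  if (min(values) < grid[1] || max(values) > grid[length(grid)])
    stop("grid does not cover the sample range")
  G <- length(grid) - 1L
  if (method == "histogram") {
    counts <- tabulate(findInterval(values, grid, rightmost.closed = TRUE),
                       nbins = G)
    p <- counts / sum(counts)
  } else {
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    d <- stats::density(values, bw = "nrd0", n = G,
                        from = mids[1], to = mids[G])
    p <- d$y / sum(d$y)
  }
  p <- p + floor_eps
  p / sum(p)
}

#' Kullback-Leibler divergence similarity
#'
#' `exp(-(KL(p||q) + KL(q||p)))`: 1 iff the distributions are identical,
#' decreasing toward 0 as they diverge, symmetric in its arguments.
#'
#' @param p,q Strictly positive probability vectors of equal length, each
#'   summing to 1.
#' @return Similarity in (0, 1\].
#' @export
kls_similarity <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p <= 0) || any(q <= 0))
    stop("zero entries: regularize densities upstream")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must sum to 1")
  exp(-(sum(p * log(p / q)) + sum(q * log(q / p))))
}

#' Build one subject's morphometric similarity network
#'
#' Pairwise KLS similarity between all region pairs of one subject. Densities
#' are histograms on a common grid spanning the subject's pooled sample range
#' (individualized network construction), floor-regularized.
#'
#' @param samples Regions x samples numeric matrix of positive values.
#' @param n_bins Number of shared histogram bins (default 128).
#' @param floor_eps Probability floor, see [estimate_density()].
#' @param method Density estimator, see [estimate_density()].
#' @return R x R symmetric similarity matrix, unit diagonal, entries in
#'   (0, 1\].
#' @export
build_msn <- function(samples, n_bins = 128L, floor_eps = 1e-10,
                      method = c("histogram", "kde")) {
  method <- match.arg(method)
  stopifnot(is.matrix(samples), nrow(samples) >= 2)
  R <- nrow(samples)
  rng <- range(samples)
  grid <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  P <- matrix(0, R, n_bins)
  for (r in seq_len(R)) {
    P[r, ] <- tryCatch(estimate_density(samples[r, ], grid, floor_eps,
                                        method = method),
                       error = function(e)
                         stop(sprintf("region %d: %s", r, conditionMessage(e)),
                              call. = FALSE))
  }
  # KL(p_i || p_j) = sum_g p_i log p_i - sum_g p_i log p_j, vectorized
  logP <- log(P)
  self_ent <- rowSums(P * logP)
  cross <- P %*% t(logP)
  KL <- self_ent - cross
  S <- exp(-(KL + t(KL)))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Build MSNs for every subject in a sample collection
#'
#' @param samples Named list of regions x samples matrices (one per subject).
#' @param n_bins,floor_eps,method Passed to [build_msn()].
#' @return Named list of similarity matrices.
#' @export
build_msn_batch <- function(samples, n_bins = 128L, floor_eps = 1e-10,
                            method = c("histogram", "kde")) {
  method <- match.arg(method)
  lapply(samples, build_msn, n_bins = n_bins, floor_eps = floor_eps,
         method = method)
}
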