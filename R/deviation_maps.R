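# Extreme-deviation cartography: per-node overlap proportions, group
# difference maps, group-based and spatial (spin) permutation nulls, FDR, and
# proportion effect sizes.

extreme_mask <- function(devs, metric, direction = c("either", "positive",
                                                     "negative")) {
  direction <- match.arg(direction)
  pos <- devs$extreme_pos[, , metric, drop = FALSE]
  neg <- devs$extreme_neg[, , metric, drop = FALSE]
  m <- switch(direction, positive = pos, negative = neg, either = pos | neg)
  matrix(m, dim(m)[1], dim(m)[2])
}

#' Per-node extreme-deviation overlap map
#'
#' Fraction of a group's subjects with an extreme deviation at each node.
#'
#' @param devs Deviation tensor from [deviation_tensor()].
#' @param members Logical or integer index of the group's subjects.
#' @param metric Metric name or index.
#' @param direction `"positive"`, `"negative"`, or `"either"`.
#' @return Per-node proportions in \[0, 1\].
#' @export
overlap_map <- function(devs, members, metric,
                        direction = c("either", "positive", "negative")) {
  mask <- extreme_mask(devs, metric, match.arg(direction))[members, ,
                                                           drop = FALSE]
  if (nrow(mask) == 0) stop("empty group")
  colMeans(mask)
}

#' Case-control difference of overlap maps
#'
#' Case proportion minus control proportion, in percentage points.
#'
#' @param case_map,control_map Per-node proportions.
#' @return Per-node differences (percentage points).
#' @export
difference_map <- function(case_map, control_map) {
  100 * (case_map - control_map)
}

#' Group-based permutation test for overlap-difference maps
#'
#' Permutes group labels (preserving group sizes, optionally within site) and
#' recomputes the per-node overlap difference, giving two-sided add-one
#' p-values `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' @param devs Deviation tensor.
#' @param labels Logical vector, TRUE = case.
#' @param metric Metric name or index.
#' @param direction Extreme-deviation direction.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param site Optional site labels; when given, labels are shuffled within
#'   site.
#' @return List with `observed` (percentage points) and `p` per node.
#' @export
group_permutation_test <- function(devs, labels, metric,
                                   direction = "either", n_perm = 1000L,
                                   seed = 1L, site = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  labels <- as.logical(labels)
  mask <- extreme_mask(devs, metric, direction)
  obs <- difference_map(colMeans(mask[labels, , drop = FALSE]),
                        colMeans(mask[!labels, , drop = FALSE]))
  n <- length(labels)
  with_seed(seed, {
    exceed <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      if (is.null(site)) {
        perm <- sample(labels)
      } else {
        perm <- labels
        for (s in unique(site)) {
          idx <- which(site == s)
          perm[idx] <- labels[idx][sample.int(length(idx))]
        }
      }
      null_d <- difference_map(colMeans(mask[perm, , drop = FALSE]),
                               colMeans(mask[!perm, , drop = FALSE]))
      exceed <- exceed + (abs(null_d) >= abs(obs) - 1e-12)
    }
    list(observed = obs, p = (1 + exceed) / (n_perm + 1))
  })
}

#' Spin-test rotation permutations
#'
#' Random 3-D rotations of the node coordinates with one-sided
#' nearest-neighbor reassignment: surrogate node i reads the value of the
#' original node closest to i's rotated position (duplicates permitted).
#' Rotations are drawn uniformly (QR of a Gaussian matrix, determinant +1).
#'
#' @param geometry Node geometry (`x`, `y`, `z` unit-sphere columns).
#' @param n_surrogates Number of rotations.
#' @param seed Integer seed.
#' @return `n_surrogates` x nodes matrix of source indices.
#' @export
spin_permutations <- function(geometry, n_surrogates, seed = 1L) {
  coords <- as.matrix(geometry[, c("x", "y", "z")])
  if (anyDuplicated(round(coords, 9)))
    stop("duplicate coordinates: nearest-neighbor mapping ill-defined")
  with_seed(seed, {
    idx <- matrix(0L, n_surrogates, nrow(coords))
    for (s in seq_len(n_surrogates)) {
      qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
      Q <- qr.Q(qr_d)
      Q <- Q %*% diag(sign(diag(qr.R(qr_d))))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      rot <- coords %*% t(Q)
      # nearest original node to each rotated position
      idx[s, ] <- max.col(rot %*% t(coords), ties.method = "first")
    }
    idx
  })
}

#' Spatial (spin) permutation test
#'
#' Builds a spatial-autocorrelation-preserving null by randomly rotating the
#' spherical node layout of `map_a` and reassigning values by nearest
#' neighbor. With `stat = "correlation"` returns a single two-sided add-one
#' p for the (rank or product-moment) correlation of the two maps; with
#' `stat = "difference"` returns per-node two-sided p-values for the
#' difference map `map_a - map_b` against its rotated nulls.
#'
#' @param map_a,map_b Per-node value vectors aligned to `geometry`.
#' @param geometry Node geometry.
#' @param n_surrogates Number of rotations (>= 100).
#' @param seed Integer seed.
#' @param stat `"correlation"` or `"difference"`.
#' @param method Correlation method (`"spearman"` default, or `"pearson"`).
#' @param perms Optional precomputed matrix from [spin_permutations()]
#'   (rotations can be shared across many tests on the same geometry).
#' @return List with `observed` and `p` (scalar for correlation, per node
#'   for difference).
#' @export
spin_test <- function(map_a, map_b, geometry, n_surrogates = 1000L,
                      seed = 1L, stat = c("correlation", "difference"),
                      method = c("spearman", "pearson"), perms = NULL) {
  stat <- match.arg(stat)
  method <- match.arg(method)
  stopifnot(length(map_a) == nrow(geometry),
            length(map_b) == nrow(geometry))
  if (is.null(perms)) {
    if (n_surrogates < 100) stop("n_surrogates must be at least 100")
    perms <- spin_permutations(geometry, n_surrogates, seed)
  }
  n_s <- nrow(perms)
  if (stat == "correlation") {
    obs <- stats::cor(map_a, map_b, method = method)
    null_r <- vapply(seq_len(n_s), function(s)
      stats::cor(map_a[perms[s, ]], map_b, method = method), numeric(1))
    list(observed = obs, p = (1 + sum(abs(null_r) >= abs(obs) - 1e-12)) /
           (n_s + 1))
  } else {
    d <- map_a - map_b
    null_mat <- matrix(d[t(perms)], ncol = n_s)   # nodes x surrogates
    exceed <- rowSums(abs(null_mat) >= abs(d) - 1e-12)
    list(observed = d, p = (1 + exceed) / (n_s + 1))
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity, plus the rejection set at a
#' target level.
#'
#' @param p Vector of p-values.
#' @param q_level Target FDR level (default 0.05).
#' @return List with `q` (adjusted values) and `reject` (logical).
#' @export
fdr_bh <- function(p, q_level = 0.05) {
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q < q_level)
}

#' Cohen's h for two proportions
#'
#' `h = 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))`.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @return Effect size h.
#' @export
cohen_h <- function(p1, p2) {
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Cohen's d (pooled SD)
#' @param x,y Numeric vectors.
#' @return Effect size d (mean(x) - mean(y), pooled SD).
#' @export
cohen_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Compare per-subject extreme-deviation burden between groups
#'
#' Counts each subject's extreme nodes per metric and compares groups by
#' two-sample t-test with pooled-SD Cohen's d.
#'
#' @param devs Deviation tensor.
#' @param labels Logical vector, TRUE = case.
#' @return data.frame per metric: group means/SDs, t, Cohen d, p.
#' @export
extreme_burden_compare <- function(devs, labels) {
  labels <- as.logical(labels)
  metrics <- dimnames(devs$z)[[3]]
  out <- lapply(seq_along(metrics), function(m) {
    counts <- rowSums(extreme_mask(devs, m, "either"))
    tt <- stats::t.test(counts[labels], counts[!labels], var.equal = TRUE)
    data.frame(metric = metrics[m],
               mean_case = mean(counts[labels]),
               sd_case = stats::sd(counts[labels]),
               mean_control = mean(counts[!labels]),
               sd_control = stats::sd(counts[!labels]),
               t = unname(tt$statistic),
               cohen_d = cohen_d(counts[labels], counts[!labels]),
               p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Per-node chi-squared test of extreme-deviation frequency across biotypes
#'
#' k x 2 contingency (extreme vs not, per biotype) chi-squared per node
#' without continuity correction, BH-adjusted across nodes. Cells with
#' expected count < 5 trigger a warning and a Fisher exact-test fallback for
#' that node.
#'
#' @param devs Deviation tensor.
#' @param biotype_labels Integer biotype per subject (NA for subjects not
#'   included, e.g. controls).
#' @param metric Metric name or index.
#' @param direction Extreme-deviation direction.
#' @return data.frame per node: chisq, p, q.
#' @export
biotype_node_chisq <- function(devs, biotype_labels, metric,
                               direction = "either") {
  keep <- !is.na(biotype_labels)
  mask <- extreme_mask(devs, metric, direction)[keep, , drop = FALSE]
  bt <- factor(biotype_labels[keep])
  res <- lapply(seq_len(ncol(mask)), function(j) {
    tab <- table(bt, factor(mask[, j], levels = c(FALSE, TRUE)))
    if (sum(tab[, 2]) == 0 || sum(tab[, 1]) == 0)
      return(data.frame(node = j, chisq = 0, p = 1))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      warning(sprintf("node %d: expected count < 5, exact-test fallback", j))
      p <- stats::fisher.test(tab)$p.value
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      p <- ct$p.value; chi <- ct$statistic
    }
    data.frame(node = j, chisq = unname(chi), p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
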