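# Multimodal fusion: multiset CCA (SSQCOR criterion, deflationary) linking
# the metric-wise deviation matrices, followed by joint ICA on the
# concatenated associated maps.

#' Multiset canonical correlation analysis (SSQCOR, deflationary)
#'
#' Finds, component by component, one canonical vector per modality
#' maximizing the sum of squared correlations among the modality variates
#' (SSQCOR criterion), by alternating generalized-eigenvector updates with
#' deflation of the extracted variate from each modality's subject space.
#' Canonical variate matrices `D_k` are orthonormal per modality; associated
#' maps `C_k` are least-squares back-projections onto the original data.
#'
#' @param X_k List of subjects x nodes matrices (same subjects across
#'   modalities).
#' @param n_components Number of components; reduced (with a message) if it
#'   exceeds any modality's rank.
#' @return List with `D_k` (list of subjects x components), `C_k` (list of
#'   components x nodes), `explained_variance` (modalities x components,
#'   cumulative reconstruction R^2), and `n_components`.
#' @export
mcca <- function(X_k, n_components) {
  stopifnot(is.list(X_k), length(X_k) >= 2)
  n <- nrow(X_k[[1]])
  stopifnot(all(vapply(X_k, nrow, 1L) == n))
  Xc <- lapply(X_k, function(X) scale(X, center = TRUE, scale = FALSE))
  ranks <- vapply(Xc, function(X) qr(X)$rank, 1L)
  m_max <- min(ranks)
  if (n_components > m_max) {
    message(sprintf("rank-deficient input: reducing components %d -> %d",
                    n_components, m_max))
    n_components <- m_max
  }
  K <- length(Xc)
  Xd <- Xc                                       # deflated working copies
  D_k <- lapply(Xc, function(X) matrix(0, n, 0))
  total_ss <- vapply(Xc, function(X) sum(X^2), numeric(1))
  ev <- matrix(0, K, n_components)

  for (comp in seq_len(n_components)) {
    Ckk <- lapply(Xd, crossprod)
    for (k in seq_len(K))
      Ckk[[k]] <- Ckk[[k]] + diag(1e-8 * mean(diag(Ckk[[k]])) + 1e-12,
                                  ncol(Ckk[[k]]))
    # init: leading right singular vector of each modality
    w <- lapply(Xd, function(X) svd(X, nu = 0, nv = 1)$v[, 1])
    d <- mapply(function(X, wk) X %*% wk, Xd, w, SIMPLIFY = FALSE)
    d <- lapply(d, function(v) v / max(sqrt(sum(v^2)), 1e-12))
    obj_old <- -Inf
    for (it in 1:100) {
      for (k in seq_len(K)) {
        # maximize sum_j!=k (w_k' X_k' d_j)^2 s.t. w_k' C_kk w_k = 1
        M <- matrix(0, ncol(Xd[[k]]), ncol(Xd[[k]]))
        for (j in seq_len(K)) if (j != k) {
          v <- crossprod(Xd[[k]], d[[j]])
          M <- M + tcrossprod(v)
        }
        eg <- eigen(solve(Ckk[[k]], M), symmetric = FALSE)
        wk <- Re(eg$vectors[, which.max(Re(eg$values))])
        dk <- Xd[[k]] %*% wk
        nrm <- sqrt(sum(dk^2))
        if (nrm > 1e-12) { d[[k]] <- dk / nrm; w[[k]] <- wk / nrm }
      }
      obj <- 0
      for (a in seq_len(K - 1)) for (b in (a + 1):K)
        obj <- obj + sum(d[[a]] * d[[b]])^2
      if (abs(obj - obj_old) < 1e-10 * max(1, abs(obj))) break
      obj_old <- obj
    }
    for (k in seq_len(K)) {
      D_k[[k]] <- cbind(D_k[[k]], d[[k]])
      proj <- tcrossprod(d[[k]]) %*% Xd[[k]]
      Xd[[k]] <- Xd[[k]] - proj
      ev[k, comp] <- 1 - sum(Xd[[k]]^2) / total_ss[k]
    }
  }
  C_k <- mapply(function(D, X) crossprod(D, X), D_k, Xc, SIMPLIFY = FALSE)
  list(D_k = D_k, C_k = C_k, explained_variance = ev,
       n_components = n_components)
}

#' Smallest component count reaching an explained-variance floor
#'
#' Runs the multiset CCA once at the maximum feasible order and returns the
#' smallest component count whose cumulative reconstruction explained
#' variance exceeds `variance_floor` in every modality.
#'
#' @param X_k List of subjects x nodes matrices.
#' @param variance_floor Per-modality explained-variance floor (default 0.8).
#' @param max_components Upper bound on the search (default: min rank).
#' @return List with `n_components`, `explained_variance` matrix, and the
#'   `mcca` fit at the selected order.
#' @export
select_component_count <- function(X_k, variance_floor = 0.8,
                                   max_components = NULL) {
  m_max <- min(vapply(X_k, function(X)
    qr(scale(X, center = TRUE, scale = FALSE))$rank, 1L))
  if (!is.null(max_components)) m_max <- min(m_max, max_components)
  fit <- mcca(X_k, m_max)
  ok <- apply(fit$explained_variance >= variance_floor, 2, all)
  n_components <- if (any(ok)) min(which(ok)) else fit$n_components
  list(n_components = n_components,
       explained_variance = fit$explained_variance,
       fit = fit)
}

# Symmetric FastICA with logcosh contrast; rows of X are mixed signals.
fastica_core <- function(X, seed, n_restarts = 20L, max_iter = 200L,
                         tol = 1e-7) {
  nc <- nrow(X); N <- ncol(X)
  Xc <- X - rowMeans(X)
  ev <- eigen(tcrossprod(Xc) / N, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-10
  Kw <- diag(1 / sqrt(ev$values[keep]), sum(keep)) %*%
    t(ev$vectors[, keep, drop = FALSE])
  Z <- Kw %*% Xc
  nc_w <- nrow(Z)
  g_const <- 0.37457                             # E[logcosh] of a standard normal
  best <- NULL; best_obj <- -Inf
  for (r in seq_len(n_restarts)) {
    W <- with_seed(derive_seed(seed, paste0("ica", r)), {
      M <- matrix(stats::rnorm(nc_w * nc_w), nc_w)
      sv <- svd(M); sv$u %*% t(sv$v)
    })
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      W_new <- G %*% t(Z) / N - diag(rowMeans(1 - G^2)) %*% W
      sv <- svd(W_new)
      W_new <- sv$u %*% t(sv$v)
      delta <- max(abs(1 - abs(rowSums(W_new * W))))
      W <- W_new
      if (delta < tol) break
    }
    obj <- sum((rowMeans(log(cosh(W %*% Z))) - g_const)^2)
    if (obj > best_obj) { best_obj <- obj; best <- W }
  }
  S <- best %*% Z
  negent <- (rowMeans(log(cosh(S))) - g_const)^2
  list(S = S, W = best %*% Kw, negentropy = negent)
}

#' Joint independent component analysis of concatenated associated maps
#'
#' Runs symmetric FastICA (logcosh negentropy contrast, symmetric
#' decorrelation, seeded restarts keeping the best objective) on the maps
#' concatenated along the node axis, then splits the sources back into
#' per-modality blocks. Each source is scaled so its largest-magnitude
#' element is positive. Sources whose excess kurtosis is within
#' `gaussian_z` sampling standard errors of zero are flagged as low
#' non-Gaussianity (ICA is not identifiable for Gaussian sources).
#'
#' @param C_k List of components x nodes associated maps (one per modality).
#' @param seed Integer seed.
#' @param n_restarts Seeded restarts (default 20).
#' @param gaussian_z Kurtosis flag threshold in SE units (default 2).
#' @return List with `S_k` (per-modality source blocks), `S` (full sources),
#'   `W` (unmixing matrix), `low_nongaussianity` (logical per source).
#' @export
jica <- function(C_k, seed = 1L, n_restarts = 20L, gaussian_z = 2) {
  stopifnot(is.list(C_k))
  blocks <- vapply(C_k, ncol, 1L)
  C_cat <- do.call(cbind, C_k)
  fit <- fastica_core(C_cat, seed, n_restarts)
  S <- fit$S
  flip <- apply(S, 1, function(s) sign(s[which.max(abs(s))]))
  S <- S * flip
  W <- fit$W * flip
  ends <- cumsum(blocks); starts <- c(1, utils::head(ends, -1) + 1)
  S_k <- mapply(function(a, b) S[, a:b, drop = FALSE], starts, ends,
                SIMPLIFY = FALSE)
  # sources have unit variance after whitening; excess kurtosis near zero
  # (within gaussian_z sampling SEs) marks a non-identifiable source
  n_obs <- ncol(S)
  kurt <- rowMeans(S^4) / rowMeans(S^2)^2 - 3
  list(S_k = S_k, S = S, W = W,
       low_nongaussianity = abs(kurt) < gaussian_z * sqrt(24 / n_obs),
       kurtosis = kurt, negentropy = fit$negentropy)
}

#' Full mCCA + jICA fusion of metric-wise deviation matrices
#'
#' @param X_k List of subjects x nodes matrices (one per metric).
#' @param n_components Number of joint components (see
#'   [select_component_count()]).
#' @param seed Integer seed for the ICA restarts.
#' @return `fusion_result` list: `D_k`, `C_k`, `S_k`, `W`, `A_k`
#'   (subject-wise mixing coefficients, `D_k %*% pinv(W)`),
#'   `explained_variance`.
#' @export
mcca_jica <- function(X_k, n_components, seed = 1L) {
  mfit <- mcca(X_k, n_components)
  jfit <- jica(mfit$C_k, seed = seed)
  Winv <- MASS::ginv(jfit$W)
  A_k <- lapply(mfit$D_k, function(D) D %*% Winv)
  structure(list(D_k = mfit$D_k, C_k = mfit$C_k, S_k = jfit$S_k,
                 S = jfit$S, W = jfit$W, A_k = A_k,
                 low_nongaussianity = jfit$low_nongaussianity,
                 explained_variance = mfit$explained_variance,
                 n_components = mfit$n_components),
            class = "fusion_result")
}

#' Group tests on mixing coefficients
#'
#' Two-sample t-test (and pooled-SD Cohen's d) per component per modality on
#' the subject-wise mixing coefficients. A joint group-differentiating
#' component is one significant (p < alpha) in every modality.
#'
#' @param A_k List of subjects x components mixing-coefficient matrices.
#' @param labels Logical vector, TRUE = case.
#' @param alpha Significance level for the joint flag (default 0.05).
#' @return List with `table` (data.frame: component, modality, t, cohen_d,
#'   p) and `joint` (logical per component).
#' @export
component_group_test <- function(A_k, labels, alpha = 0.05) {
  labels <- as.logical(labels)
  K <- length(A_k); nc <- ncol(A_k[[1]])
  rows <- list()
  for (k in seq_len(K)) for (comp in seq_len(nc)) {
    a <- A_k[[k]][, comp]
    tt <- stats::t.test(a[labels], a[!labels], var.equal = TRUE)
    rows[[length(rows) + 1]] <-
      data.frame(component = comp, modality = k,
                 t = unname(tt$statistic),
                 cohen_d = cohen_d(a[labels], a[!labels]),
                 p = tt$p.value)
  }
  tab <- do.call(rbind, rows)
  joint <- vapply(seq_len(nc), function(comp)
    all(tab$p[tab$component == comp] < alpha), logical(1))
  list(table = tab, joint = joint)
}
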