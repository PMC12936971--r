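# HYDRA: semi-supervised discriminative clustering. K linear max-margin
# hyperplanes jointly separate controls from cases and form a convex
# polytope around the control distribution; each face defines a case
# biotype. Faces are weighted L2-loss linear SVMs solved by a compiled
# Newton method; case-to-face assignment and face refits alternate to a
# fixed point, with seeded restarts and spectral consensus.

# One face: all controls negative (weight 1/n_controls each), assigned cases
# positive (weight 1/n_cases each, a global constant so the summed objective
# is monotone under reassignment).
fit_face <- function(Xc, Xa, C, u_ctrl, u_case, w0 = NULL, b0 = 0) {
  X <- rbind(Xc, Xa)
  y <- c(rep(-1, nrow(Xc)), rep(1, nrow(Xa)))
  u <- c(rep(u_ctrl, nrow(Xc)), rep(u_case, nrow(Xa)))
  if (is.null(w0)) w0 <- numeric(ncol(X))
  .wsvm_fit(X, y, u, C, w0, b0)
}

hydra_objective <- function(Xctrl, Xcase, assign, W, b, C, u_ctrl, u_case) {
  J <- 0.5 * sum(W^2)
  dc <- Xctrl %*% W + matrix(b, nrow(Xctrl), length(b), byrow = TRUE)
  J <- J + C * u_ctrl * sum(pmax(0, 1 + dc)^2)
  da <- Xcase %*% W + matrix(b, nrow(Xcase), length(b), byrow = TRUE)
  di <- da[cbind(seq_len(nrow(Xcase)), assign)]
  J + C * u_case * sum(pmax(0, 1 - di)^2)
}

hydra_alternate <- function(Xctrl, Xcase, assign, k, C, max_iter) {
  n_ctrl <- nrow(Xctrl); n_case <- nrow(Xcase); p <- ncol(Xctrl)
  u_ctrl <- 1 / n_ctrl; u_case <- 1 / n_case
  W <- matrix(0, p, k); b <- numeric(k)
  J_prev <- Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    reseeded <- FALSE
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      if (length(idx) == 0) {
        # re-seed an empty face with the case farthest inside the polytope;
        # this repair step may raise the objective, so monotonicity is only
        # asserted across uninterrupted alternating iterations
        d <- Xcase %*% W + matrix(b, n_case, k, byrow = TRUE)
        far <- which.min(apply(d, 1, max))
        assign[far] <- j
        idx <- far
        reseeded <- TRUE
      }
      fit <- fit_face(Xctrl, Xcase[idx, , drop = FALSE], C, u_ctrl, u_case,
                      w0 = W[, j], b0 = b[j])
      W[, j] <- fit$w; b[j] <- fit$b
    }
    d <- Xcase %*% W + matrix(b, n_case, k, byrow = TRUE)
    new_assign <- max.col(d, ties.method = "first")
    J <- hydra_objective(Xctrl, Xcase, new_assign, W, b, C, u_ctrl, u_case)
    trace <- c(trace, J)
    if (!reseeded && J > J_prev + 1e-6 * max(1, abs(J_prev)))
      stop("internal error: HYDRA objective increased")
    if (reseeded) J_prev <- Inf
    if (identical(new_assign, assign) || abs(J_prev - J) <
        1e-9 * max(1, abs(J))) {
      assign <- new_assign
      break
    }
    assign <- new_assign
    J_prev <- J
  }
  list(W = W, b = b, assign = assign, objective = J, trace = trace)
}

spectral_consensus <- function(co, k, seed) {
  if (k == 1) return(rep(1L, nrow(co)))
  d <- pmax(rowSums(co), 1e-12)
  Lsym <- co / sqrt(outer(d, d))
  eg <- eigen(Lsym, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  with_seed(seed, suppressWarnings(
    stats::kmeans(U, k, nstart = 20, iter.max = 100))$cluster)
}

#' Fit a HYDRA polytope model
#'
#' Alternating optimization: given case-to-face assignments each face is fit
#' as a weighted linear max-margin classifier (all controls negative,
#' assigned cases positive); each case is then reassigned to the face with
#' the largest decision value; iterated to a fixed point. This is repeated
#' from `n_restarts` seeded initializations — up to three informed starts
#' (k-means on the extreme-deviation mask, k-means on the negative feature
#' part, and average-linkage clustering of negative-part correlations) plus
#' random balanced assignments; final labels come from spectral consensus
#' over the co-assignment matrix,
#' followed by one final alternating refit from the consensus labels so the
#' returned polytope is consistent with the returned labels. Features are
#' standardized with training statistics stored in the model. The summed
#' regularized-margin objective is non-increasing across uninterrupted
#' alternating iterations and asserted at every step (the empty-face repair
#' rule may raise it and resets the assertion).
#'
#' @param X Subjects x features matrix of deviations (column names become
#'   `feature_names`).
#' @param y Logical (or 0/1) vector, TRUE = case.
#' @param k Number of biotypes (faces), >= 1 and <= number of cases.
#' @param n_restarts Seeded restarts (default 10).
#' @param seed Integer seed.
#' @param C Margin-tradeoff regularization constant (default 0.25; small
#'   enough that the margin term forces faces to specialize rather than
#'   collapse onto one direction).
#' @param max_iter Maximum alternating iterations (default 100).
#' @return Object of class `hydra_model`: hyperplanes `W` (features x k) and
#'   `b`, `case_labels`, `consensus_matrix`, `stability_ari` (mean pairwise
#'   ARI across restarts, with pairs involving a collapsed, effectively
#'   single-face solution scored 0), scaler, seeds, feature names.
#' @export
fit_hydra <- function(X, y, k, n_restarts = 10L, seed = 1L, C = 0.25,
                      max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (!any(y) || all(y)) stop("both controls and cases must be present")
  if (k < 1) stop("k must be >= 1")
  if (k > sum(y)) stop("k cannot exceed the number of cases")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  Xctrl <- Xs[!y, , drop = FALSE]
  Xcase <- Xs[y, , drop = FALSE]
  n_case <- nrow(Xcase)

  # Informed initializations anchor the consensus. The biotype signal lives
  # in each case's strongly negative deviations (extreme under-coupling), so
  # clusterings of the thresholded / negative part of the features land much
  # closer to the polytope's basin of attraction than raw k-means, which is
  # blinded by shared variance across all case deviations. Remaining
  # restarts are random balanced assignments.
  informed_inits <- function() {
    out <- list()
    if (k > 1 && n_case > 2 * k) {
      km <- function(M, tag) tryCatch(
        with_seed(derive_seed(seed, tag),
                  as.integer(suppressWarnings(
                    stats::kmeans(M, k, nstart = 10,
                                  iter.max = 100))$cluster)),
        error = function(e) NULL)
      out$extreme <- km((Xcase <= -2) * 1, "init_extreme")
      out$negpart <- km(pmin(Xcase, 0), "init_negpart")
      out$hclust <- tryCatch({
        cm <- stats::cor(t(pmin(Xcase, 0)))
        cm[!is.finite(cm)] <- 0
        as.integer(stats::cutree(stats::hclust(stats::as.dist(1 - cm),
                                               method = "average"), k))
      }, error = function(e) NULL)
    }
    Filter(Negate(is.null), out)
  }
  inits <- informed_inits()
  restart_labels <- matrix(0L, n_case, n_restarts)
  objectives <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- if (r <= length(inits)) {
      inits[[r]]
    } else {
      with_seed(derive_seed(seed, paste0("restart", r)),
                sample(rep_len(seq_len(k), n_case)))
    }
    fit <- hydra_alternate(Xctrl, Xcase, init, k, C, max_iter)
    restart_labels[, r] <- fit$assign
    objectives[r] <- fit$objective
  }
  # A restart that collapses onto (nearly) one face carries no clustering
  # signal; pairwise agreement involving it is scored 0 so that mutually
  # degenerate solutions cannot masquerade as stable structure.
  effective_k <- apply(restart_labels, 2, function(l)
    sum(table(l) / length(l) > 0.05))
  stability_ari <- if (n_restarts > 1 && k > 1) {
    prs <- utils::combn(n_restarts, 2)
    mean(vapply(seq_len(ncol(prs)), function(i) {
      a <- prs[1, i]; b <- prs[2, i]
      if (effective_k[a] < 2 || effective_k[b] < 2) return(0)
      adjusted_rand_index(restart_labels[, a], restart_labels[, b])
    }, numeric(1)))
  } else 1
  co <- matrix(0, n_case, n_case)
  for (r in seq_len(n_restarts))
    co <- co + outer(restart_labels[, r], restart_labels[, r], `==`)
  co <- co / n_restarts
  consensus <- spectral_consensus(co, k, derive_seed(seed, "spectral"))
  final <- hydra_alternate(Xctrl, Xcase, as.integer(consensus), k, C,
                           max_iter)
  feature_names <- colnames(X)
  if (is.null(feature_names))
    feature_names <- sprintf("f%04d", seq_len(ncol(X)))
  structure(list(k = as.integer(k), W = final$W, b = final$b,
                 case_labels = final$assign, consensus_matrix = co,
                 stability_ari = stability_ari,
                 objective = final$objective,
                 objective_trace = final$trace,
                 center = center, scale = scl,
                 feature_names = feature_names,
                 C = C, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "hydra_model")
}

#' Expression scores against a fitted polytope
#'
#' `E_ij = w_j'x_i + b_j` after applying the model's stored standardization;
#' optionally normalized by `||w_j||`. Assignment is the row argmax with ties
#' broken by the lowest face index. Feature columns are aligned by name to
#' the model's feature names.
#'
#' @param model A `hydra_model`.
#' @param X_new Subjects x features matrix with column names.
#' @param normalized Divide each face's score by `||w_j||` (default FALSE).
#' @return List with `scores` (subjects x k) and `assignment`.
#' @export
expression_scores <- function(model, X_new, normalized = FALSE) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    missing <- setdiff(model$feature_names, colnames(X_new))
    extra <- setdiff(colnames(X_new), model$feature_names)
    if (length(missing) || length(extra))
      stop(sprintf("feature mismatch; missing: [%s]; extra: [%s]",
                   paste(missing, collapse = ", "),
                   paste(extra, collapse = ", ")))
    X_new <- X_new[, model$feature_names, drop = FALSE]
  } else if (ncol(X_new) != length(model$feature_names)) {
    stop("feature mismatch: unnamed input with wrong number of columns")
  }
  Xs <- sweep(sweep(X_new, 2, model$center), 2, model$scale, "/")
  E <- Xs %*% model$W + matrix(model$b, nrow(Xs), model$k, byrow = TRUE)
  if (normalized) E <- sweep(E, 2, sqrt(colSums(model$W^2)), "/")
  list(scores = E, assignment = max.col(E, ties.method = "first"))
}

#' Nested cross-validated selection of the biotype count
#'
#' For each candidate `k`, fits a consensus model on the full data and, in
#' `n_folds` folds, refits on a seeded subsample (`subsample`, default 70%)
#' of the training cases; every fold model then assigns the complete case
#' set by expression scores. Per-k stability is the mean pairwise ARI
#' between the fold models' assignments — a partition that depends on which
#' subjects were seen in training (for instance an overfit extra face whose
#' membership follows sampling noise) scores poorly. The chosen `k`
#' maximizes mean pairwise ARI; `tie_band > 0` optionally switches to a
#' parsimony tie-break (smallest candidate within the band of the maximum),
#' which can be preferable when underfit merges are known to be unstable.
#'
#' @param X,y As in [fit_hydra()].
#' @param k_grid Candidate biotype counts (default 2:4).
#' @param n_folds Folds (default 10).
#' @param seed Integer seed.
#' @param n_restarts Restarts per fit (default 5).
#' @param C Regularization constant.
#' @param subsample Fraction of training subjects (cases and controls) used
#'   per fold fit (default 0.7).
#' @param tie_band Optional parsimony tolerance; 0 (default) is plain
#'   argmax.
#' @return List with `ari` (named per-k mean pairwise ARI), `chosen_k`, and
#'   `full_models` (per-k full-data fits).
#' @export
cv_select_k <- function(X, y, k_grid = 2:4, n_folds = 10L, seed = 1L,
                        n_restarts = 5L, C = 0.25, subsample = 0.7,
                        tie_band = 0) {
  X <- as.matrix(X); y <- as.logical(y)
  case_idx <- which(y)
  folds_case <- with_seed(derive_seed(seed, "folds"),
                          sample(rep_len(seq_len(n_folds), length(case_idx))))
  ari <- stats::setNames(numeric(length(k_grid)), paste0("k", k_grid))
  full_models <- list()
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    full <- fit_hydra(X, y, k, n_restarts = n_restarts,
                      seed = derive_seed(seed, paste0("full", k)), C = C)
    full_models[[paste0("k", k)]] <- full
    fold_assign <- matrix(0L, length(case_idx), n_folds)
    for (f in seq_len(n_folds)) {
      held <- case_idx[folds_case == f]
      keep <- setdiff(seq_len(nrow(X)), held)
      yk <- y[keep]
      ck <- which(yk); nk <- which(!yk)
      keep2 <- with_seed(derive_seed(seed, sprintf("sub%dk%d", f, k)),
                         sort(c(sample(ck, round(subsample * length(ck))),
                                sample(nk, round(subsample * length(nk))))))
      fit <- fit_hydra(X[keep, , drop = FALSE][keep2, , drop = FALSE],
                       yk[keep2], k, n_restarts = n_restarts,
                       seed = derive_seed(seed, sprintf("f%dk%d", f, k)),
                       C = C)
      fold_assign[, f] <-
        expression_scores(fit, X[case_idx, , drop = FALSE])$assignment
    }
    prs <- utils::combn(n_folds, 2)
    ari[ki] <- mean(vapply(seq_len(ncol(prs)), function(i)
      adjusted_rand_index(fold_assign[, prs[1, i]],
                          fold_assign[, prs[2, i]]), numeric(1)))
  }
  eligible <- which(ari >= max(ari) - tie_band)
  list(ari = ari, chosen_k = k_grid[min(eligible)],
       full_models = full_models)
}

#' Permutation test of clustering stability
#'
#' Null distribution of the restart-stability ARI obtained by independently
#' permuting each feature column across cases (destroying the multivariate
#' coupling that defines subgroups while preserving every node's marginal
#' deviation distribution), refitting HYDRA, and recording the stability
#' ARI; add-one p-value for the observed statistic.
#'
#' @param X,y,k,C As in [fit_hydra()].
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param n_restarts Restarts per fit (default 5).
#' @return List with `observed`, `null` (vector), `p`.
#' @export
permutation_validate <- function(X, y, k, n_perm = 100L, seed = 1L,
                                 n_restarts = 5L, C = 0.25) {
  X <- as.matrix(X); y <- as.logical(y)
  obs <- fit_hydra(X, y, k, n_restarts = n_restarts,
                   seed = derive_seed(seed, "obs"), C = C)$stability_ari
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[y, ] <- with_seed(derive_seed(seed, paste0("perm", b)),
                         apply(X[y, , drop = FALSE], 2, sample))
    colnames(Xp) <- colnames(X)
    null[b] <- fit_hydra(Xp, y, k, n_restarts = n_restarts,
                         seed = derive_seed(seed, paste0("permfit", b)),
                         C = C)$stability_ari
  }
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs - 1e-12)) / (n_perm + 1))
}

#' Split-half cross-validation of the biotype count
#'
#' Random half-splits (stratified by group); HYDRA is fit on each half and
#' each half's model assigns the other half's cases via expression scores.
#' Per-split agreement is the mean ARI between a half's own labels and the
#' other model's assignments of that half.
#'
#' @param X,y,C As in [fit_hydra()].
#' @param k_grid Candidate biotype counts.
#' @param n_splits Number of random splits (default 5).
#' @param seed Integer seed.
#' @param n_restarts Restarts per fit (default 5).
#' @return Named per-k mean agreement (ARI).
#' @export
split_half_validate <- function(X, y, k_grid = 2:4, n_splits = 5L,
                                seed = 1L, n_restarts = 5L, C = 0.25) {
  X <- as.matrix(X); y <- as.logical(y)
  agree <- stats::setNames(numeric(length(k_grid)), paste0("k", k_grid))
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    vals <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      half <- with_seed(derive_seed(seed, paste0("split", s)), {
        h <- logical(length(y))
        for (g in unique(y)) {
          idx <- which(y == g)
          h[sample(idx, floor(length(idx) / 2))] <- TRUE
        }
        h
      })
      fa <- fit_hydra(X[half, , drop = FALSE], y[half], k,
                      n_restarts = n_restarts,
                      seed = derive_seed(seed, sprintf("ha%dk%d", s, k)),
                      C = C)
      fb <- fit_hydra(X[!half, , drop = FALSE], y[!half], k,
                      n_restarts = n_restarts,
                      seed = derive_seed(seed, sprintf("hb%dk%d", s, k)),
                      C = C)
      cases_a <- which(y & half); cases_b <- which(y & !half)
      pred_b <- expression_scores(fa, X[cases_b, , drop = FALSE])$assignment
      pred_a <- expression_scores(fb, X[cases_a, , drop = FALSE])$assignment
      vals[s] <- mean(c(adjusted_rand_index(pred_b, fb$case_labels),
                        adjusted_rand_index(pred_a, fa$case_labels)))
    }
    agree[ki] <- mean(vals)
  }
  agree
}

#' Serialize / restore a HYDRA model as JSON
#'
#' The JSON file is the "pretrained model" transferred to validation cohorts.
#'
#' @param model A `hydra_model`.
#' @param path Output path.
#' @return `path` (invisibly) / the restored `hydra_model`.
#' @export
save_hydra <- function(model, path) {
  obj <- model
  obj$W <- unclass(obj$W)
  write_json(unclass(obj), path)
}

#' @rdname save_hydra
#' @export
load_hydra <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W <- matrix(unlist(obj$W), ncol = obj$k)
  obj$case_labels <- as.integer(obj$case_labels)
  obj$consensus_matrix <- as.matrix(obj$consensus_matrix)
  structure(obj, class = "hydra_model")
}
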