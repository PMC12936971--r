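# Spatial decoding of deviation maps: fusion across metrics, annotation-map
# correlations under spin nulls with FDR across the annotation set, and PLS
# regression against cognitive-term maps with spin significance and
# bootstrap term loadings.

#' Fuse metric-wise difference maps
#'
#' Aggregates the per-metric extreme-deviation difference maps into one fused
#' topological deviation map. Default: z-score each map across nodes (making
#' the metrics commensurate), then average. Maps with zero variance are
#' excluded with a warning. Alternative aggregations: `"sum"` (plain sum),
#' `"maxabs"` (signed value of largest magnitude per node).
#'
#' @param diff_maps List (or matrix columns) of per-node difference maps.
#' @param aggregation `"zmean"` (default), `"sum"`, or `"maxabs"`.
#' @return Per-node fused map with attribute `aggregation`.
#' @export
fuse_maps <- function(diff_maps, aggregation = c("zmean", "sum", "maxabs")) {
  aggregation <- match.arg(aggregation)
  M <- if (is.list(diff_maps)) do.call(cbind, diff_maps) else
    as.matrix(diff_maps)
  if (aggregation == "zmean") {
    sds <- apply(M, 2, stats::sd)
    if (any(sds < 1e-12)) {
      warning("excluding zero-variance map(s) from fusion")
      M <- M[, sds >= 1e-12, drop = FALSE]
      if (ncol(M) == 0) stop("no non-degenerate maps to fuse")
    }
    fused <- rowMeans(scale(M))
  } else if (aggregation == "sum") {
    fused <- rowSums(M)
  } else {
    fused <- apply(M, 1, function(v) v[which.max(abs(v))])
  }
  attr(fused, "aggregation") <- aggregation
  fused
}

#' Correlate a fused map with annotation maps under spin nulls
#'
#' Per annotation map: rank (default) or product-moment spatial correlation
#' with the fused map, spin-test p-value (rotation surrogates shared across
#' the annotation set), and BH adjustment across annotations ("spin-FDR").
#'
#' @param fused Per-node fused deviation map.
#' @param annotations data.frame from [generate_annotation_maps()] (or any
#'   data.frame with `region_index` plus one column per map).
#' @param geometry Node geometry.
#' @param n_surrogates Spin surrogates (default 1000).
#' @param seed Integer seed.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame: annotation, r, p_spin, q.
#' @export
annotation_correlation <- function(fused, annotations, geometry,
                                   n_surrogates = 1000L, seed = 1L,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  map_cols <- setdiff(colnames(annotations), "region_index")
  perms <- spin_permutations(geometry, n_surrogates, seed)
  rows <- lapply(map_cols, function(nm) {
    res <- spin_test(fused, annotations[[nm]], geometry,
                     stat = "correlation", method = method, perms = perms)
    data.frame(annotation = nm, r = res$observed, p_spin = res$p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p_spin, method = "BH")
  out
}

#' PLS decoding of a fused map against term maps
#'
#' First partial-least-squares component of the fused map (response) on the
#' term maps (predictors, standardized): the component weight vector is the
#' normalized covariance `X'y`, the canonical first PLS direction for a
#' single response. Reports the response variance explained by the component
#' scores, a spin p-value for that explained variance (rotating the fused
#' map), and bootstrap term stability over nodes (`Z = weight / bootstrap
#' SE`, with per-resample sign alignment to the observed weights).
#'
#' @param fused Per-node fused deviation map.
#' @param term_maps Nodes x terms matrix (>= 2 terms, named columns).
#' @param geometry Node geometry.
#' @param n_boot Bootstrap resamples over nodes (default 1000).
#' @param n_surrogates Spin surrogates (default 1000).
#' @param seed Integer seed.
#' @return List with `weights`, `scores`, `explained_variance`, `p_spin`,
#'   and `terms` (data.frame: term, weight, boot_se, z).
#' @export
pls_decode <- function(fused, term_maps, geometry, n_boot = 1000L,
                       n_surrogates = 1000L, seed = 1L) {
  term_maps <- as.matrix(term_maps)
  if (ncol(term_maps) < 2) stop("need at least 2 term maps")
  n <- length(fused)
  if (n < 30) stop("need at least 30 nodes for stable node bootstrap")
  stopifnot(nrow(term_maps) == n, nrow(geometry) == n)

  pls1 <- function(y, X) {
    Xs <- scale(X); ys <- as.numeric(scale(y))
    w <- crossprod(Xs, ys)
    w <- w / sqrt(sum(w^2))
    t1 <- as.numeric(Xs %*% w)
    ev <- summary(stats::lm(ys ~ t1))$r.squared
    list(w = as.numeric(w), scores = t1, ev = ev)
  }
  obs <- pls1(fused, term_maps)

  perms <- spin_permutations(geometry, n_surrogates, seed)
  null_ev <- vapply(seq_len(n_surrogates), function(s)
    pls1(fused[perms[s, ]], term_maps)$ev, numeric(1))
  p_spin <- (1 + sum(null_ev >= obs$ev - 1e-12)) / (n_surrogates + 1)

  boot_w <- with_seed(derive_seed(seed, "boot"), {
    out <- matrix(NA_real_, n_boot, ncol(term_maps))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      if (stats::sd(fused[idx]) < 1e-12) next
      wb <- pls1(fused[idx], term_maps[idx, , drop = FALSE])$w
      if (sum(wb * obs$w) < 0) wb <- -wb       # sign alignment
      out[b, ] <- wb
    }
    out[stats::complete.cases(out), , drop = FALSE]
  })
  se <- apply(boot_w, 2, stats::sd)
  terms <- data.frame(term = colnames(term_maps),
                      weight = obs$w, boot_se = se, z = obs$w / se)
  list(weights = obs$w, scores = obs$scores, explained_variance = obs$ev,
       p_spin = p_spin, terms = terms)
}
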