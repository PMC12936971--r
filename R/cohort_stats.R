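# Clinical-profile statistics across biotypes.

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based H with tie correction (via [stats::kruskal.test()]) and the
#' H-based effect size `eta^2 = (H - k + 1) / (n - k)`. All-equal
#' observations give H = 0 by convention.
#'
#' @param scores Numeric outcome per subject.
#' @param groups Group labels (k groups).
#' @return List: `H`, `eta_squared`, `p`, `df`.
#' @export
kruskal_wallis <- function(scores, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(scores)
  if (max(scores) == min(scores))
    return(list(H = 0, eta_squared = (0 - k + 1) / (n - k), p = 1,
                df = k - 1))
  kt <- stats::kruskal.test(scores, groups)
  H <- unname(kt$statistic)
  list(H = H, eta_squared = (H - k + 1) / (n - k), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Post-hoc pairwise comparisons with multiplicity adjustment
#'
#' Pairwise two-sample t-tests (pooled SD) with Cohen's d, adjusted across
#' pairs by Holm's method by default (`"bonferroni"` and `"BH"` available).
#'
#' @param scores Numeric outcome per subject.
#' @param groups Group labels.
#' @param adjust Adjustment method (default `"holm"`).
#' @return data.frame: pair, t, cohen_d, p, adjusted_p.
#' @export
posthoc_pairwise <- function(scores, groups, adjust = c("holm", "bonferroni",
                                                        "BH")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  lv <- levels(groups)
  prs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- scores[groups == prs[1, i]]; b <- scores[groups == prs[2, i]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(pair = sprintf("biotype_%s_vs_%s", prs[1, i], prs[2, i]),
               t = unname(tt$statistic), cohen_d = cohen_d(a, b),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Rescale raw scores to the unit interval
#'
#' `(x - lo) / (hi - lo)`, clipped to \[0, 1\]; out-of-range inputs are
#' counted and reported via a message.
#'
#' @param raw Numeric vector.
#' @param lo,hi Scale anchors (`hi > lo`).
#' @return Rescaled scores in \[0, 1\].
#' @export
rescale_scores <- function(raw, lo, hi) {
  if (hi <= lo) stop("degenerate scale: hi must exceed lo")
  x <- (raw - lo) / (hi - lo)
  n_out <- sum(x < 0 | x > 1)
  if (n_out > 0)
    message(sprintf("%d score(s) outside [%g, %g] clipped", n_out, lo, hi))
  pmin(1, pmax(0, x))
}
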