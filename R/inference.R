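#' One-sided two-sample rank-sum (Mann-Whitney) test
#'
#' Compares per-site diversity values between two groups of sites.  The
#' statistic U counts, for `alternative = "greater"`, the (x, y) pairs with
#' `x > y` (ties counted 1/2), so U ranges over \[0, n1*n2\] and large U
#' supports "x stochastically greater than y".  The null distribution is
#' the exact enumeration when both samples are small and untied, and the
#' normal approximation with tie and continuity corrections otherwise
#' (delegated to [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors (nonempty).
#' @param alternative `"greater"` (x tends larger, default), `"less"`, or
#'   `"two.sided"`.
#' @param exact force exact enumeration (`TRUE`/`FALSE`); default `NULL`
#'   uses enumeration when `n1 + n2 <= 12` and there are no ties.
#' @return list of class `"divpart_test"`: `statistic` (U), `p_value`,
#'   `alternative`, `method`, `n1`, `n2`.
#' @export
#' @examples
#' rank_sum_test(c(3, 4), c(1, 2), alternative = "greater")  # U = 4, p = 1/6
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided"),
                          exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 alternative = alternative,
                 method = if (exact && !ties) "exact rank-sum"
                          else "normal approximation (tie/continuity corrected)",
                 n1 = length(x), n2 = length(y)),
            class = "divpart_test")
}

#' @export
print.divpart_test <- function(x, ...) {
  cat(sprintf("%s: U = %.4g, p = %.4g (alternative: %s; n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$alternative, x$n1, x$n2))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements of two site-by-site
#' distance matrices, with significance from seeded joint row/column
#' permutations: `p = (1 + #{permuted r >= observed r}) / (n_perm + 1)`.
#' Delegates to [vegan::mantel()].
#'
#' @param d1,d2 symmetric distance matrices (or `dist` objects) over the
#'   same sites.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param method correlation method passed to [vegan::mantel()].
#' @return list of class `"divpart_test"`: `statistic` (Mantel r),
#'   `p_value`, `n_permutations`, `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        method = "pearson") {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("distance matrices cover different site sets")
  v1 <- m1[lower.tri(m1)]; v2 <- m2[lower.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant distance matrix: Mantel r undefined")
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                      method = method, permutations = n_perm)
  structure(list(statistic = unname(mt$statistic), p_value = mt$signif,
                 alternative = "greater",
                 method = paste("Mantel permutation test,", method),
                 n1 = nrow(m1), n2 = nrow(m1),
                 n_permutations = n_perm),
            class = "divpart_test")
}

#' Sorensen (binary Bray-Curtis) composition distance between sites
#'
#' Convenience wrapper around [vegan::vegdist()] on presence/absence,
#' the default composition dissimilarity for the Mantel autocorrelation
#' check.
#'
#' @param cm a `community_matrix`.
#' @param method `"sorensen"` (binary Bray-Curtis) or `"jaccard"`.
#' @return a `dist` object over sites.
#' @export
composition_dist <- function(cm, method = c("sorensen", "jaccard")) {
  method <- match.arg(method)
  vd <- switch(method,
               sorensen = vegan::vegdist(unclass(cm), method = "bray",
                                         binary = TRUE),
               jaccard  = vegan::vegdist(unclass(cm), method = "jaccard",
                                         binary = TRUE))
  vd
}
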