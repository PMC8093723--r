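#' Sample coverage of an abundance sample
#'
#' Estimates the completeness of a sample — the fraction of the total
#' community abundance accounted for by the species present in it — from the
#' numbers of singletons and doubletons:
#' \deqn{\hat C_n = 1 - \frac{f_1}{n}\,
#'   \frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' where \eqn{f_1} and \eqn{f_2} are the numbers of species observed exactly
#' once and twice and \eqn{n} is the sample size.  With no singletons the
#' sample is estimated complete (\eqn{\hat C_n = 1}).  The degenerate sample
#' of a single individual (\eqn{n = 1}, \eqn{f_1 = 1}) leaves the second
#' factor 0/0; it is defined as maximally incomplete, \eqn{\hat C_n = 0},
#' with a warning, matching the limiting behavior of the estimator.
#'
#' @param counts nonnegative integer vector of species counts (zeros
#'   allowed and ignored).
#' @return object of class `"coverage_estimate"`: list with `n`, `f1`, `f2`,
#'   and `c_hat` in \[0, 1\].
#' @seealso [coverage_report()], [format_coverage_pct()]
#' @export
#' @examples
#' sample_coverage(c(1, 1, 2, 5))  # c_hat ~ 0.8025
sample_coverage <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be nonnegative integers")
  x <- counts[counts > 0]
  if (length(x) == 0) stop("all-zero abundance vector")
  n <- sum(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) {
    c_hat <- 1
  } else if (n == 1) {
    warning("sample of a single individual: coverage defined as 0")
    c_hat <- 0
  } else {
    c_hat <- 1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  }
  structure(list(n = n, f1 = f1, f2 = f2, c_hat = c_hat),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("Sample coverage: %.4f (n = %d, f1 = %d, f2 = %d)\n",
              x$c_hat, x$n, x$f1, x$f2))
  invisible(x)
}

#' Report coverage as a percentage
#'
#' Percentages are rounded half-up to the integer, except values above 99%
#' which keep one decimal so nearly complete samples remain distinguishable
#' from complete ones (98 vs 99.7).
#'
#' @param c_hat coverage in \[0, 1\] (vectorized).
#' @return numeric percentage(s).
#' @export
format_coverage_pct <- function(c_hat) {
  p <- 100 * c_hat
  ifelse(p > 99, round_half_up(p, 1), round_half_up(p, 0))
}

#' Per-site and per-category coverage table
#'
#' One row per site plus, when metadata are supplied, one row per depth
#' category computed on the pooled counts.
#'
#' @param cm a `community_matrix`.
#' @param meta optional site metadata (see [read_site_metadata()]).
#' @return data.frame with columns `unit`, `level` ("site" or "category"),
#'   `depth_m`, `n`, `f1`, `f2`, `c_hat`, `coverage_pct`.
#' @export
coverage_report <- function(cm, meta = NULL) {
  row_of <- function(unit, level, depth, counts) {
    ce <- sample_coverage(counts)
    data.frame(unit = unit, level = level, depth_m = depth,
               n = ce$n, f1 = ce$f1, f2 = ce$f2, c_hat = ce$c_hat,
               coverage_pct = format_coverage_pct(ce$c_hat))
  }
  depth <- rep(NA_real_, nrow(cm))
  if (!is.null(meta)) depth <- match_metadata(cm, meta)$depth_m
  out <- do.call(rbind, lapply(seq_len(nrow(cm)), function(i)
    row_of(rownames(cm)[i], "site", depth[i], unclass(cm)[i, ])))
  if (!is.null(meta)) {
    pooled <- pool_by_category(cm, meta)
    out <- rbind(out, do.call(rbind, lapply(rownames(pooled), function(g)
      row_of(g, "category", NA_real_, unclass(pooled)[g, ]))))
  }
  rownames(out) <- NULL
  out
}
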