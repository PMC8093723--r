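#' Pairwise Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' For two presence sets with `a` shared species, `b` exclusive to the
#' first and `c` exclusive to the second:
#' \deqn{\beta_{sor} = \frac{b + c}{2a + b + c}, \quad
#'       \beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}, \quad
#'       \beta_{sne} = \beta_{sor} - \beta_{sim}}
#' The Simpson component \eqn{\beta_{sim}} captures spatial turnover
#' (species replacement) independent of richness difference; the remainder
#' \eqn{\beta_{sne}} captures nestedness-resultant dissimilarity.  The
#' three always satisfy the additive partition and
#' \eqn{0 \le \beta_{sim} \le \beta_{sor} \le 1}.
#'
#' @param x,y communities: character vectors of species names, or named
#'   count/logical vectors (presence = count \eqn{\ge} 1).  Both must be
#'   nonempty.
#' @return named list with `a`, `b`, `c`, `beta_sor`, `beta_sim`,
#'   `beta_sne`.
#' @export
#' @examples
#' baselga_pair(c("s1", "s2", "s3"), c("s1", "s2", "s3", "s4", "s5"))
baselga_pair <- function(x, y) {
  as_set <- function(v) {
    if (is.character(v)) return(unique(v))
    if (is.null(names(v))) stop("count/logical communities must be named")
    names(v)[as.numeric(v) >= 1 | (is.logical(v) & v)]
  }
  sx <- as_set(x); sy <- as_set(y)
  if (length(sx) == 0 || length(sy) == 0)
    stop("empty community: pairwise beta undefined")
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  c_ <- length(setdiff(sy, sx))
  beta_sor <- if (b + c_ == 0) 0 else (b + c_) / (2 * a + b + c_)
  m <- min(b, c_)
  beta_sim <- if (m == 0) 0 else m / (a + m)
  list(a = a, b = b, c = c_, beta_sor = beta_sor, beta_sim = beta_sim,
       beta_sne = beta_sor - beta_sim)
}

#' All within-set pairwise beta components of a community matrix
#'
#' @param cm a `community_matrix`.
#' @param sites optional site subset (names or indices).
#' @return data.frame with one row per unordered site pair: `site1`,
#'   `site2`, `beta_sor`, `beta_sim`, `beta_sne`.
#' @export
pairwise_beta <- function(cm, sites = NULL) {
  m <- unclass(cm)
  if (!is.null(sites)) m <- m[sites, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two sites")
  prs <- combn(rownames(m), 2)
  rows <- apply(prs, 2, function(pr) {
    bp <- baselga_pair(m[pr[1], ], m[pr[2], ])
    data.frame(site1 = pr[1], site2 = pr[2], beta_sor = bp$beta_sor,
               beta_sim = bp$beta_sim, beta_sne = bp$beta_sne)
  })
  do.call(rbind, rows)
}

## beta components for every cross pair between two site groups
cross_pairwise_beta <- function(cm, sites1, sites2) {
  m <- unclass(cm)
  rows <- list()
  for (s1 in sites1) for (s2 in sites2) {
    bp <- baselga_pair(m[s1, ], m[s2, ])
    rows[[length(rows) + 1L]] <- data.frame(
      site1 = s1, site2 = s2, beta_sor = bp$beta_sor,
      beta_sim = bp$beta_sim, beta_sne = bp$beta_sne)
  }
  do.call(rbind, rows)
}

#' Mean and bootstrap CI of pairwise beta components per pair set
#'
#' Summarizes turnover, nestedness, and total pairwise beta over three pair
#' sets: within-shallow pairs, within-deep pairs, and shallow-by-deep cross
#' pairs.  Confidence intervals are seeded percentile bootstraps over pairs
#' (site pairs are not independent, so the intervals are descriptive rather
#' than strictly inferential).
#'
#' @param cm a `community_matrix`.
#' @param meta site metadata with `depth_category`.
#' @param pair_sets subset of `c("within_shallow", "within_deep", "cross")`.
#' @param n_boot number of bootstrap resamples (default 9999).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return data.frame: `pair_set`, `component`, `mean`, `ci_low`, `ci_high`,
#'   `n_pairs`.
#' @export
regional_pairwise_summary <- function(cm, meta,
                                      pair_sets = c("within_shallow",
                                                    "within_deep", "cross"),
                                      n_boot = 9999, seed = NULL,
                                      conf = 0.95) {
  pair_sets <- match.arg(pair_sets, several.ok = TRUE)
  meta <- match_metadata(cm, meta)
  sh <- rownames(cm)[meta$depth_category == "shallow"]
  dp <- rownames(cm)[meta$depth_category == "deep"]
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (ps in pair_sets) {
    tab <- switch(ps,
      within_shallow = { if (length(sh) < 2) stop("fewer than 2 shallow sites")
                         pairwise_beta(cm, sh) },
      within_deep    = { if (length(dp) < 2) stop("fewer than 2 deep sites")
                         pairwise_beta(cm, dp) },
      cross          = { if (!length(sh) || !length(dp)) stop("missing category")
                         cross_pairwise_beta(cm, sh, dp) })
    np <- nrow(tab)
    for (comp in c("beta_sim", "beta_sne", "beta_sor")) {
      v <- tab[[comp]]
      bm <- replicate(n_boot, mean(v[sample.int(np, np, replace = TRUE)]))
      ci <- quantile(bm, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        pair_set = ps, component = comp, mean = mean(v),
        ci_low = ci[1], ci_high = ci[2], n_pairs = np)
    }
  }
  do.call(rbind, out)
}
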