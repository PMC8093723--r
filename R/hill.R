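#' Taxonomic Hill number of order q
#'
#' The Hill number
#' \deqn{{}^qD = \Big(\sum_{i=1}^S p_i^q\Big)^{1/(1-q)}}
#' expresses diversity as the equivalent number of equally abundant species.
#' `q` tunes the weight given to abundance: `q = 0` counts species
#' (richness, "rare" species), `q = 1` is the exponential of Shannon entropy
#' ("typical" species, evaluated by the analytic limit), and `q = 2` is the
#' inverse Simpson concentration ("dominant" species).  Zero-abundance
#' entries are excluded; the input is normalized to relative abundances.
#'
#' @param p abundance vector (counts or relative abundances; nonnegative,
#'   at least one positive entry).
#' @param q diversity order, scalar \eqn{\ge 0}.
#' @return positive scalar in effective-species units.
#' @export
#' @examples
#' hill_number(c(0.75, 0.25), 2)  # 1.6
#' hill_number(rep(1, 10), 0)     # 10
hill_number <- function(p, q) {
  if (length(q) != 1 || q < 0) stop("q must be a single value >= 0")
  p <- rel_abund(p)
  p <- p[p > 0]
  if (is_q_one(q)) exp(-sum(p * log(p))) else pow_back(sum(p^q), q)
}

#' Per-site Hill diversity
#'
#' Evaluates [hill_number()] on each site's own relative abundances.
#'
#' @param cm a `community_matrix`.
#' @param q diversity order.
#' @return named numeric vector, one value per site.
#' @export
alpha_per_site <- function(cm, q) {
  apply(unclass(cm), 1, hill_number, q = q)
}

## site weights and the weighted relative-abundance matrix z (sites x
## species, z_ij = w_j * p_ij) shared by all partition functions.
region_weights <- function(cm, sites = NULL, weighting = c("equal", "by_abundance")) {
  weighting <- match.arg(weighting)
  m <- unclass(cm)
  if (!is.null(sites)) {
    if (is.character(sites) && any(!sites %in% rownames(m)))
      stop("unknown site(s): ", paste(setdiff(sites, rownames(m)), collapse = ", "))
    m <- m[sites, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("empty region")
  tot <- rowSums(m)
  if (any(tot == 0)) stop("site with zero total abundance in region")
  w <- if (weighting == "equal") rep(1 / nrow(m), nrow(m)) else tot / sum(tot)
  z <- sweep(m / tot, 1, w, `*`)
  list(z = z, w = w, N = nrow(m), weighting = weighting)
}

#' Multiplicative alpha/beta/gamma partition of taxonomic diversity
#'
#' Partitions the Hill diversity of a region of sites into independent
#' components: gamma is the diversity of the (weighted) pooled assemblage,
#' alpha is the weighted within-site diversity
#' \deqn{{}^qD_\alpha = \Big(\frac{\sum_j\sum_i (w_j p_{ij})^q}
#'   {\sum_j w_j^q}\Big)^{1/(1-q)}}
#' (with the Shannon limit at `q = 1`), and beta = gamma / alpha is the
#' effective number of completely distinct communities in the region.  Under
#' the default equal site weights, beta lies in \[1, N\] for N sites.  Under
#' `weighting = "by_abundance"` sites are weighted by their total counts, so
#' gamma equals the diversity of the pooled raw counts.
#'
#' @param cm a `community_matrix`.
#' @param sites optional site names or indices defining the region
#'   (default: all sites).
#' @param q diversity order.
#' @param weighting `"equal"` (default) or `"by_abundance"`.
#' @return list with `gamma`, `alpha`, `beta`, `q`, `n_sites`, `weighting`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
#' regional_partition(as_community_matrix(m), q = 0)  # gamma 4, alpha 2, beta 2
regional_partition <- function(cm, sites = NULL, q, weighting = "equal") {
  if (length(q) != 1 || q < 0) stop("q must be a single value >= 0")
  rw <- region_weights(cm, sites, weighting)
  z <- rw$z; w <- rw$w
  p_pool <- colSums(z)
  gamma <- hill_number(p_pool, q)
  zp <- z[z > 0]
  alpha <- if (is_q_one(q)) {
    exp(-sum(zp * log(zp)) + sum(w * log(w)))
  } else {
    pow_back(sum(zp^q) / sum(w^q), q)
  }
  list(gamma = gamma, alpha = alpha, beta = gamma / alpha,
       q = q, n_sites = rw$N, weighting = rw$weighting)
}

#' Regional beta-diversity profiles over a grid of orders
#'
#' Evaluates the multiplicative regional beta diversity on a grid of `q`
#' values for each depth category, for one or more diversity dimensions.
#' Functional profiles need a species distance matrix `d`; phylogenetic
#' profiles need an (ultrametric) tree already reconciled with the matrix.
#'
#' @param cm a `community_matrix`.
#' @param meta site metadata with `depth_category`.
#' @param q_grid numeric vector of orders (default `seq(0, 2, 0.25)`).
#' @param dimensions subset of `c("taxonomic", "functional", "phylogenetic")`.
#' @param d species distance matrix (required for `"functional"`).
#' @param tree phylogeny covering the matrix species (required for
#'   `"phylogenetic"`).
#' @param weighting site weighting scheme.
#' @return tidy data.frame: `dimension`, `region`, `q`, `gamma`, `alpha`,
#'   `beta`, `n_sites`.
#' @export
beta_profile <- function(cm, meta, q_grid = seq(0, 2, by = 0.25),
                         dimensions = "taxonomic", d = NULL, tree = NULL,
                         weighting = "equal") {
  dimensions <- match.arg(dimensions,
                          c("taxonomic", "functional", "phylogenetic"),
                          several.ok = TRUE)
  meta <- match_metadata(cm, meta)
  regions <- split(rownames(cm), meta$depth_category)
  regions <- regions[lengths(regions) > 0]
  part_fun <- function(dim, sites, q) {
    switch(dim,
      taxonomic    = regional_partition(cm, sites, q, weighting),
      functional   = {
        if (is.null(d)) stop("functional profile needs a distance matrix d")
        functional_partition(cm, d, sites, q, weighting)
      },
      phylogenetic = {
        if (is.null(tree)) stop("phylogenetic profile needs a tree")
        phylo_partition(cm, tree, sites, q, weighting)
      })
  }
  rows <- list()
  for (dim in dimensions)
    for (rg in names(regions))
      for (q in q_grid) {
        pt <- part_fun(dim, regions[[rg]], q)
        rows[[length(rows) + 1L]] <- data.frame(
          dimension = dim, region = rg, q = q, gamma = pt$gamma,
          alpha = pt$alpha, beta = pt$beta, n_sites = pt$n_sites)
      }
  do.call(rbind, rows)
}
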