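#' Gower distance between species from categorical traits
#'
#' Pairwise functional dissimilarity as the mean over usable traits of the
#' per-trait dissimilarity: nominal traits contribute a 0/1 mismatch and
#' ordinal traits `|rank_i - rank_j| / (levels - 1)`, ranked over the full
#' closed level set (so the divisor does not depend on which levels happen
#' to be observed).  Traits missing for either species of a pair are
#' excluded from that pair's mean (pairwise deletion, never zero-filled).
#' By default `size_class` is treated as ordinal — body-size classes are
#' ordered length intervals — and the other five traits as nominal; pass
#' `ordinal = character(0)` to treat all six as nominal.
#'
#' @param traits validated trait table (see [as_trait_table()]).
#' @param ordinal character vector of trait names to rank (default
#'   `"size_class"`).
#' @return symmetric species-by-species matrix with entries in \[0, 1\] and
#'   zero diagonal.
#' @export
gower_distance <- function(traits, ordinal = "size_class") {
  if (nrow(traits) < 2) stop("need at least two species")
  lv <- trait_levels()
  bad <- setdiff(ordinal, names(lv))
  if (length(bad)) stop("unknown trait(s) in ordinal: ", paste(bad, collapse = ", "))
  S <- nrow(traits)
  num <- matrix(0, S, S)
  den <- matrix(0, S, S)
  for (tr in names(lv)) {
    v <- traits[[tr]]
    ok <- !is.na(v)
    use <- outer(ok, ok, `&`)
    if (tr %in% ordinal) {
      r <- as.integer(v)
      dtr <- abs(outer(r, r, `-`)) / (length(lv[[tr]]) - 1)
    } else {
      dtr <- outer(as.integer(v), as.integer(v), `!=`) * 1
    }
    dtr[!use] <- 0
    num <- num + dtr
    den <- den + use
  }
  if (any(den[upper.tri(den)] == 0))
    stop("species pair with no shared non-missing trait")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(traits), rownames(traits))
  d
}

#' Write / read a square distance matrix as TSV
#'
#' @param d symmetric matrix with dimnames.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(species = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12))
    stop("not a symmetric square matrix")
  m
}

## align an abundance vector with a distance matrix, keep positive species
align_pd <- function(p, d) {
  if (!is.null(names(p)) && !is.null(rownames(d))) {
    miss <- setdiff(names(p)[p > 0], rownames(d))
    if (length(miss)) stop("species missing from distance matrix: ",
                           paste(miss, collapse = ", "))
    d <- d[names(p), names(p), drop = FALSE]
  } else if (length(p) != nrow(d)) {
    stop("length of p does not match distance matrix")
  }
  keep <- p > 0
  list(p = rel_abund(p)[keep], d = d[keep, keep, drop = FALSE])
}

#' Functional Hill diversity of order q
#'
#' Attribute (distance-based) diversity built on Rao's quadratic entropy
#' \eqn{Q = \sum_{ij} d_{ij} p_i p_j}:
#' \deqn{{}^qFD(Q) = \Big(\sum_{i}\sum_{j} d_{ij}
#'   \big(p_i p_j / Q\big)^q\Big)^{1/(1-q)}}
#' with the analytic limit at `q = 1`.  At `q = 0` this is the total
#' functional distance summed over ordered pairs of co-occurring species.
#' A functionally monomorphic community (all distances zero) has `Q = 0`;
#' the value is defined as 0 with a warning rather than an error.
#'
#' @param p abundance vector (zero entries excluded after normalization).
#' @param d species distance matrix in \[0, 1\] (or any nonnegative
#'   symmetric matrix; the measure scales linearly in `d`).
#' @param q diversity order.
#' @return nonnegative scalar (effective total functional distance units).
#' @export
#' @examples
#' d <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
#' functional_hill(c(1, 1), d, q = 2)  # 2 * 0.4
functional_hill <- function(p, d, q) {
  if (length(q) != 1 || q < 0) stop("q must be a single value >= 0")
  al <- align_pd(p, d)
  p <- al$p; d <- al$d
  PP <- outer(p, p)
  Q <- sum(d * PP)
  if (Q <= 0) {
    warning("Rao Q = 0 (functionally monomorphic community): FD defined as 0")
    return(0)
  }
  r <- PP / Q
  if (is_q_one(q)) {
    term <- d * r * log(r)
    exp(-sum(term[d > 0]))
  } else {
    pow_back(sum(d * r^q), q)
  }
}

#' Multiplicative partition of functional diversity
#'
#' Attribute-diversity alpha/beta/gamma decomposition: gamma is the
#' functional Hill diversity of the weighted pooled assemblage (with Rao Q
#' evaluated at the pooled level), alpha aggregates within- and
#' between-site species pairs with weighted abundances, and
#' beta = gamma / alpha measures functional differentiation among
#' communities.  Note the units: functional beta compares effective numbers
#' of species *pairs*, so under equal weights it lies in \[1, N^2\] rather
#' than \[1, N\]; it equals 1 exactly for identical sites.
#'
#' @inheritParams regional_partition
#' @param d species distance matrix covering the matrix species.
#' @return list with `gamma`, `alpha`, `beta`, `q`, `n_sites`, `weighting`.
#' @export
functional_partition <- function(cm, d, sites = NULL, q, weighting = "equal") {
  if (length(q) != 1 || q < 0) stop("q must be a single value >= 0")
  rw <- region_weights(cm, sites, weighting)
  z <- rw$z; w <- rw$w
  sp <- colnames(z)
  if (!all(sp %in% rownames(d)))
    stop("species missing from distance matrix: ",
         paste(setdiff(sp, rownames(d)), collapse = ", "))
  d <- d[sp, sp, drop = FALSE]
  keep <- colSums(z) > 0
  z <- z[, keep, drop = FALSE]
  d <- d[keep, keep, drop = FALSE]
  p_pool <- colSums(z)
  Q <- drop(p_pool %*% d %*% p_pool)
  if (Q <= 0) {
    warning("Rao Q = 0 at the regional level: functional partition degenerate")
    return(list(gamma = 0, alpha = 0, beta = NA_real_, q = q,
                n_sites = rw$N, weighting = rw$weighting))
  }
  gamma <- functional_hill(p_pool, d, q)
  if (is_q_one(q)) {
    ## limit of [A(q)/B(q)]^{1/(1-q)}: the site double sum factorizes through
    ## s_i = sum_j z_ij log z_ij
    s <- colSums(ifelse(z > 0, z * log(z), 0))
    alpha <- exp(-(2 * drop(s %*% d %*% p_pool)) / Q + log(Q) +
                   2 * sum(w * log(w)))
  } else {
    u <- colSums(ifelse(z > 0, z^q, 0))   # 0^0 must not count absent species
    A <- drop(u %*% d %*% u) / Q^q
    B <- sum(w^q)^2
    alpha <- pow_back(A / B, q)
  }
  list(gamma = gamma, alpha = alpha, beta = gamma / alpha,
       q = q, n_sites = rw$N, weighting = rw$weighting)
}

#' Community-weighted means of categorical trait states
#'
#' For each site, trait, and trait state: the proportion of the site's
#' abundance carried by species bearing that state, among species with a
#' non-missing value for the trait (species with missing values are excluded
#' from that trait's denominator, with a message the first time).  Per site
#' and trait the values over states sum to 1; states absent from a site get
#' 0.
#'
#' @param cm a `community_matrix`.
#' @param traits validated trait table covering the matrix species.
#' @return tidy data.frame: `site`, `trait`, `state`, `value`.
#' @export
cwm <- function(cm, traits) {
  m <- unclass(cm)
  miss_sp <- setdiff(colnames(m), rownames(traits))
  if (length(miss_sp))
    stop("species missing from trait table: ", paste(miss_sp, collapse = ", "))
  traits <- traits[colnames(m), , drop = FALSE]
  lv <- trait_levels()
  rows <- list()
  for (tr in names(lv)) {
    v <- traits[[tr]]
    ok <- !is.na(v)
    if (!all(ok))
      message(sum(!ok), " species with missing ", tr,
              " excluded from its CWM denominator")
    sub <- m[, ok, drop = FALSE]
    tot <- rowSums(sub)
    for (st in lv[[tr]]) {
      in_state <- v[ok] == st
      val <- if (any(in_state)) rowSums(sub[, in_state, drop = FALSE]) / tot
             else rep(0, nrow(m))
      val[tot == 0] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        site = rownames(m), trait = tr, state = st, value = val)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
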