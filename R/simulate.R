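## depths (m) of the default survey design: 8 shallow + 14 deep reefs
## spanning 2-62 m, matching the study layout the simulator emulates.
default_depths <- function() {
  c(2.4, 2.6, 7.7, 9.1, 9.3, 18, 20.1, 24.5,
    30, 30, 30, 33, 33, 33, 34, 35, 35, 40, 44.7, 48, 54.4, 62.3)
}

#' Configuration of a synthetic metacommunity scenario
#'
#' Bundles the parameters of [simulate_metacommunity()].  The defaults
#' describe the reference study design: 8 shallow and 14 deep sites on a
#' 2-62 m depth gradient (site depths default to the survey's depth list,
#' so the shallow/deep split is exactly 8/14), 85 species with a
#' long-tailed lognormal regional abundance distribution, and roughly 170
#' expected individuals per fully suitable site — which yields realistic
#' numbers of singletons and doubletons per site.
#'
#' @param structure metacommunity structuring mechanism:
#'   `"species_sorting"` (Gaussian depth niches; turnover-dominated beta),
#'   `"mass_effects"` (one regional pool with depth-dependent richness
#'   thinning; nestedness-dominated beta between shallow and deep), or
#'   `"neutral"` (identical expectations everywhere).
#' @param n_shallow,n_deep numbers of shallow (< 30 m) and deep sites.
#' @param n_species regional species pool size.
#' @param depth_range range (m) from which site depths are drawn when
#'   `depths` is `NULL` and the site numbers differ from the default design.
#' @param depths optional explicit site depths (m).
#' @param niche_breadth Gaussian depth-niche standard deviation (m) for
#'   species sorting; the default 8 m is narrow relative to the 60 m
#'   gradient, so communities turn over along depth.
#' @param site_total expected number of individuals in a fully suitable
#'   site.
#' @param abundance_sdlog lognormal sdlog of the regional abundance
#'   distribution (1.2 gives strong dominance plus a rare tail).
#' @param thinning range of the fraction of the (abundance-ranked) species
#'   pool retained under mass effects, interpolated linearly from the
#'   shallowest to the deepest site; the default `(0.2, 1)` is strong
#'   thinning.
#' @param detection per-individual detection probability (binomial
#'   subsampling of counts; 1 = perfect detection).
#' @param seed integer seed.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(structure = c("species_sorting", "mass_effects",
                                          "neutral"),
                            n_shallow = 8, n_deep = 14, n_species = 85,
                            depth_range = c(2, 62), depths = NULL,
                            niche_breadth = 8, site_total = 170,
                            abundance_sdlog = 1.2, thinning = c(0.2, 1),
                            detection = 1, seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(n_shallow >= 1, n_deep >= 1, n_species >= 2,
            niche_breadth > 0, site_total > 0,
            detection > 0, detection <= 1,
            length(thinning) == 2, all(thinning > 0), all(thinning <= 1))
  if (!is.null(depths) && length(depths) != n_shallow + n_deep)
    stop("depths must have one entry per site")
  structure(list(structure = structure, n_shallow = n_shallow,
                 n_deep = n_deep, n_species = n_species,
                 depth_range = depth_range, depths = depths,
                 niche_breadth = niche_breadth, site_total = site_total,
                 abundance_sdlog = abundance_sdlog, thinning = thinning,
                 detection = detection, seed = seed),
            class = "scenario_config")
}

#' Simulate a depth-structured metacommunity
#'
#' Draws a site-by-species count matrix under the mechanism set in the
#' configuration.  All scenarios share a lognormal regional
#' relative-abundance vector `v` and Poisson observation on top of expected
#' counts; they differ in how expectations vary along depth:
#'
#' * `species_sorting`: each species has a Gaussian depth niche with a
#'   random optimum on the gradient and sd `niche_breadth`; site
#'   expectations are the niche-filtered regional abundances rescaled to
#'   `site_total` individuals per site.  Different depths select different
#'   species, so pairwise beta is turnover-dominated.
#' * `mass_effects`: every site draws from the same regional pool, but
#'   shallower (less suitable) sites retain only the most abundant fraction
#'   of the pool (linear thinning from `thinning[1]` at the shallowest to
#'   `thinning[2]` at the deepest site), without renormalization — poor
#'   sites hold fewer species *and* fewer individuals, and their
#'   composition is nested in that of rich sites, so cross-depth beta is
#'   nestedness-dominated.
#' * `neutral`: identical expectations at every site.
#'
#' A site left without any individuals by the Poisson draw receives one
#' individual of its highest-expectation species, so the result always
#' validates as a community matrix.
#'
#' @param cfg a [scenario_config()].
#' @return list with `counts` (a `community_matrix`), `meta` (site
#'   metadata data.frame), and `truth` (generator parameters, including
#'   the intended dominant pairwise-beta component).
#' @export
simulate_metacommunity <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_sites <- cfg$n_shallow + cfg$n_deep
  depths <- cfg$depths
  if (is.null(depths)) {
    if (cfg$n_shallow == 8 && cfg$n_deep == 14) depths <- default_depths()
    else depths <- sort(c(runif(cfg$n_shallow, cfg$depth_range[1], 29),
                          runif(cfg$n_deep, 30, cfg$depth_range[2])))
  }
  S <- cfg$n_species
  sp <- sprintf("sp%03d", seq_len(S))
  site <- sprintf("site%02d", seq_len(n_sites))
  v <- rel_abund(rlnorm(S, meanlog = 0, sdlog = cfg$abundance_sdlog))
  truth <- list(structure = cfg$structure, regional_abundance = v,
                depths = depths, config = cfg)
  E <- switch(cfg$structure,
    species_sorting = {
      opt <- runif(S, cfg$depth_range[1], cfg$depth_range[2])
      truth$depth_optimum <- opt
      truth$dominant_component <- "turnover"
      resp <- outer(depths, opt, function(d, o)
        exp(-(d - o)^2 / (2 * cfg$niche_breadth^2)))
      M <- sweep(resp, 2, v, `*`)
      cfg$site_total * M / rowSums(M)
    },
    mass_effects = {
      keep_frac <- cfg$thinning[1] + (cfg$thinning[2] - cfg$thinning[1]) *
        (depths - min(depths)) / (max(depths) - min(depths))
      rank_v <- rank(-v, ties.method = "first")
      keep <- t(vapply(keep_frac,
                       function(f) rank_v <= ceiling(f * S), logical(S)))
      truth$keep_fraction <- keep_frac
      truth$dominant_component <- "nestedness"
      cfg$site_total * sweep(keep * 1, 2, v, `*`)
    },
    neutral = {
      truth$dominant_component <- "none"
      matrix(cfg$site_total * v, nrow = n_sites, ncol = S, byrow = TRUE)
    })
  counts <- matrix(rpois(length(E), lambda = E), nrow = n_sites,
                   dimnames = list(site, sp))
  if (cfg$detection < 1)
    counts[] <- rbinom(length(counts), counts, cfg$detection)
  empty <- rowSums(counts) == 0
  if (any(empty))
    for (j in which(empty)) counts[j, which.max(E[j, ])] <- 1L
  meta <- data.frame(site_id = site, depth_m = depths,
                     depth_category = assign_depth_category(depths),
                     effort_min = NA_real_)
  list(counts = as_community_matrix(counts), meta = meta, truth = truth)
}

#' Simulate a categorical trait table
#'
#' Draws each of the six traits uniformly from its closed level set.  When
#' `deep_bias` marks deep-niche species, the spawning mode "ovoviviparous"
#' is made exclusive to (and common among) those species, creating a
#' depth-linked trait contrast detectable through community-weighted means;
#' with `deep_bias = NULL` there is no systematic trait-depth association.
#'
#' @param n_species number of species.
#' @param seed integer seed.
#' @param species_ids optional species names (default `sp001`, ...).
#' @param deep_bias optional logical vector (length `n_species`) flagging
#'   deep-niche species.
#' @return validated trait data.frame.
#' @export
simulate_traits <- function(n_species, seed = NULL, species_ids = NULL,
                            deep_bias = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(species_ids)) species_ids <- sprintf("sp%03d", seq_len(n_species))
  lv <- trait_levels()
  df <- data.frame(lapply(lv, function(x)
    sample(x, n_species, replace = TRUE)), check.names = FALSE)
  rownames(df) <- species_ids
  if (!is.null(deep_bias)) {
    stopifnot(length(deep_bias) == n_species)
    non_ovo <- setdiff(lv$spawning, "ovoviviparous")
    df$spawning[!deep_bias] <- sample(non_ovo, sum(!deep_bias), replace = TRUE)
    df$spawning[deep_bias] <- ifelse(runif(sum(deep_bias)) < 0.5,
                                     "ovoviviparous",
                                     sample(non_ovo, sum(deep_bias),
                                            replace = TRUE))
  }
  as_trait_table(df)
}

#' Simulate an ultrametric phylogeny
#'
#' Pure-birth (Yule) topology with branch lengths rescaled so that every
#' tip sits exactly at the configured root age.
#'
#' @param n_species number of tips (\eqn{\ge 2}).
#' @param seed integer seed.
#' @param root_age root age in time units (default 100).
#' @param species_ids optional tip names (default `sp001`, ...).
#' @return an [ape::phylo] object passing [validate_phylogeny()] and
#'   [check_ultrametric()].
#' @export
simulate_tree <- function(n_species, seed = NULL, root_age = 100,
                          species_ids = NULL) {
  if (n_species < 2) stop("need at least two species")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(species_ids)) species_ids <- sprintf("sp%03d", seq_len(n_species))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  ## force exact ultrametricity at root_age: stretch each tip's terminal
  ## branch to absorb its numerical depth error, then rescale
  dep <- ape::node.depth.edgelength(tree)
  tip_dep <- dep[seq_len(n_species)]
  target <- max(tip_dep)
  tip_edge <- match(seq_len(n_species), tree$edge[, 2])
  tree$edge.length[tip_edge] <- tree$edge.length[tip_edge] + (target - tip_dep)
  tree$edge.length <- tree$edge.length * (root_age / target)
  tree$tip.label <- species_ids
  validate_phylogeny(tree)
}
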