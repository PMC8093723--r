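#' Composition summary of a pooled two-category matrix
#'
#' Headline compositional numbers for a shallow/deep pooled community
#' matrix: total individuals, species and family counts, per-category
#' richness, shared and exclusive species, per-species percentage shares of
#' total abundance (rounded half-up to the integer, raw values retained),
#' and the cumulative share of the `top_k` most abundant species.
#'
#' @param pooled a two-row `community_matrix` (rows shallow, deep).
#' @param families optional named character vector mapping species to
#'   family.
#' @param top_k how many top-ranked species for the cumulative share.
#' @return list with `total_individuals`, `n_species`, `n_families`,
#'   `richness` (per category), `shared`, `shallow_only`, `deep_only`,
#'   `species_share_pct` (named, rounded), `species_share_raw`,
#'   `top_cumulative_pct`, `family_counts`.
#' @export
summarize_composition <- function(pooled, families = NULL, top_k = 10) {
  m <- unclass(pooled)
  if (nrow(m) != 2) stop("expected a two-category pooled matrix")
  tot <- colSums(m)
  share <- 100 * tot / sum(tot)
  ord <- order(tot, decreasing = TRUE)
  present <- m > 0
  out <- list(
    total_individuals = sum(m),
    n_species = ncol(m),
    richness = rowSums(present),
    shared = sum(present[1, ] & present[2, ]),
    shallow_only = sum(present[1, ] & !present[2, ]),
    deep_only = sum(present[2, ] & !present[1, ]),
    species_share_pct = round_half_up(share[ord], 0),
    species_share_raw = share[ord],
    top_cumulative_pct = round_half_up(sum(share[ord][seq_len(min(top_k, ncol(m)))]), 0),
    top_k = top_k)
  names(out$richness) <- rownames(m)
  if (!is.null(families)) {
    fam <- families[colnames(m)]
    out$n_families <- length(unique(fam[!is.na(fam)]))
    out$family_counts <- sort(table(fam), decreasing = TRUE)
  }
  out
}

## per-site alpha diversity for each dimension at each q, plus one-sided
## deep-greater rank-sum tests
alpha_block <- function(cm, meta, q_values, d = NULL, tree = NULL) {
  meta <- match_metadata(cm, meta)
  dims <- c("taxonomic",
            if (!is.null(d)) "functional",
            if (!is.null(tree)) "phylogenetic")
  values <- list(); tests <- list()
  for (dim in dims) for (q in q_values) {
    a <- switch(dim,
      taxonomic    = alpha_per_site(cm, q),
      functional   = vapply(seq_len(nrow(cm)), function(i)
        functional_hill(unclass(cm)[i, ], d, q), numeric(1)),
      phylogenetic = vapply(seq_len(nrow(cm)), function(i) {
        p <- unclass(cm)[i, ]
        phylo_hill(tree, p[p > 0], q)
      }, numeric(1)))
    names(a) <- rownames(cm)
    values[[length(values) + 1L]] <- data.frame(
      dimension = dim, q = q, site = rownames(cm),
      depth_category = meta$depth_category, alpha = unname(a))
    deep <- a[meta$depth_category == "deep"]
    shal <- a[meta$depth_category == "shallow"]
    if (length(deep) && length(shal)) {
      rt <- rank_sum_test(deep, shal, alternative = "greater")
      tests[[length(tests) + 1L]] <- data.frame(
        dimension = dim, q = q, statistic = rt$statistic,
        p_value = rt$p_value, n_deep = rt$n1, n_shallow = rt$n2)
    }
  }
  list(values = do.call(rbind, values),
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Run the full diversity-partitioning analysis
#'
#' Orchestrates every stage of the analysis on a site-by-species matrix:
#' coverage standardization report, per-site alpha diversity with
#' shallow-versus-deep rank-sum comparisons, regional gamma/alpha/beta
#' partitions at the reporting orders (under both site-weighting schemes),
#' regional beta profiles over a grid of orders, pairwise
#' turnover/nestedness summaries (within-shallow, within-deep, cross), CWM
#' trait-state comparisons, and a composition summary of the pooled
#' matrix.  Every number in the bundle is produced by the corresponding
#' module function.  When `out_dir` is given the bundle is also written as
#' tidy TSV files plus `results.json` and `manifest.json`; re-running with
#' the same inputs and seed reproduces the outputs byte for byte.
#'
#' @param counts a `community_matrix` (sites x species).
#' @param meta site metadata covering all sites.
#' @param traits optional trait table (enables the functional dimension
#'   and CWM analysis).
#' @param tree optional ultrametric phylogeny (enables the phylogenetic
#'   dimension; species absent from the tree are dropped with a warning
#'   via [reconcile_tree()]).
#' @param families optional species-to-family map for the composition
#'   summary.
#' @param q_values reporting orders (default `c(0, 1, 2)`).
#' @param q_grid beta-profile grid (default `seq(0, 2, 0.25)`).
#' @param n_boot bootstrap resamples for pairwise beta CIs.
#' @param seed integer seed recorded in the manifest and used for the
#'   bootstrap.
#' @param out_dir optional output directory.
#' @return the results bundle (list), invisibly when written to disk.
#' @export
run_analysis <- function(counts, meta, traits = NULL, tree = NULL,
                         families = NULL, q_values = c(0, 1, 2),
                         q_grid = seq(0, 2, by = 0.25), n_boot = 999,
                         seed = 1, out_dir = NULL) {
  counts <- as_community_matrix(counts)
  meta <- match_metadata(counts, meta)
  warnings_log <- character()
  d <- NULL
  if (!is.null(traits)) {
    miss <- setdiff(colnames(counts), rownames(traits))
    if (length(miss)) stop("stage functional: species without traits: ",
                           paste(miss, collapse = ", "))
    d <- gower_distance(traits)
  }
  phylo_counts <- counts; phylo_tree <- NULL
  if (!is.null(tree)) {
    rec <- withCallingHandlers(
      reconcile_tree(tree, counts),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    phylo_counts <- rec$counts
    phylo_tree <- rec$tree
  }

  pooled <- pool_by_category(counts, meta)
  coverage <- coverage_report(counts, meta)

  alpha <- alpha_block(counts, meta, q_values, d = d, tree = NULL)
  if (!is.null(phylo_tree)) {
    ph_meta <- meta[meta$site_id %in% rownames(phylo_counts), , drop = FALSE]
    ph <- alpha_block(phylo_counts, ph_meta, q_values, tree = phylo_tree)
    ph$values <- ph$values[ph$values$dimension == "phylogenetic", ]
    ph$tests <- ph$tests[ph$tests$dimension == "phylogenetic", ]
    alpha$values <- rbind(alpha$values, ph$values)
    alpha$tests <- rbind(alpha$tests, ph$tests)
  }

  regions <- split(meta$site_id, meta$depth_category)
  regions <- regions[lengths(regions) > 0]
  gam_rows <- list()
  for (wt in c("equal", "by_abundance"))
    for (rg in names(regions)) for (q in q_values) {
      pt <- regional_partition(counts, regions[[rg]], q, wt)
      gam_rows[[length(gam_rows) + 1L]] <- data.frame(
        dimension = "taxonomic", region = rg, q = q, weighting = wt,
        gamma = pt$gamma, alpha = pt$alpha, beta = pt$beta)
      if (!is.null(d)) {
        pf <- functional_partition(counts, d, regions[[rg]], q, wt)
        gam_rows[[length(gam_rows) + 1L]] <- data.frame(
          dimension = "functional", region = rg, q = q, weighting = wt,
          gamma = pf$gamma, alpha = pf$alpha, beta = pf$beta)
      }
      if (!is.null(phylo_tree)) {
        sites_ph <- intersect(regions[[rg]], rownames(phylo_counts))
        if (length(sites_ph)) {
          pp <- phylo_partition(phylo_counts, phylo_tree, sites_ph, q, wt)
          gam_rows[[length(gam_rows) + 1L]] <- data.frame(
            dimension = "phylogenetic", region = rg, q = q, weighting = wt,
            gamma = pp$gamma, alpha = pp$alpha, beta = pp$beta)
        }
      }
    }
  partitions <- do.call(rbind, gam_rows)

  profiles <- NULL
  if (length(regions) && all(lengths(regions) > 1)) {
    profiles <- beta_profile(counts, meta, q_grid, "taxonomic")
    if (!is.null(d))
      profiles <- rbind(profiles,
                        beta_profile(counts, meta, q_grid, "functional", d = d))
    if (!is.null(phylo_tree)) {
      ph_meta <- meta[meta$site_id %in% rownames(phylo_counts), , drop = FALSE]
      profiles <- rbind(profiles,
                        beta_profile(phylo_counts, ph_meta, q_grid,
                                     "phylogenetic", tree = phylo_tree))
    }
  }

  pairwise <- NULL
  if (length(regions) == 2 && all(lengths(regions) > 1))
    pairwise <- regional_pairwise_summary(counts, meta, n_boot = n_boot,
                                          seed = seed)

  cwm_tab <- NULL; cwm_tests <- NULL
  if (!is.null(traits)) {
    cwm_tab <- cwm(counts, traits)
    if (length(regions) == 2) {
      cat_of <- setNames(as.character(meta$depth_category), meta$site_id)
      tests <- list()
      for (key in unique(paste(cwm_tab$trait, cwm_tab$state))) {
        sub <- cwm_tab[paste(cwm_tab$trait, cwm_tab$state) == key, ]
        deep <- sub$value[cat_of[sub$site] == "deep"]
        shal <- sub$value[cat_of[sub$site] == "shallow"]
        if (length(deep) && length(shal)) {
          rt <- rank_sum_test(deep, shal, alternative = "greater")
          tests[[length(tests) + 1L]] <- data.frame(
            trait = sub$trait[1], state = sub$state[1],
            mean_shallow = mean(shal), mean_deep = mean(deep),
            statistic = rt$statistic, p_value = rt$p_value)
        }
      }
      cwm_tests <- do.call(rbind, tests)
    }
  }

  bundle <- list(
    coverage = coverage,
    alpha = alpha$values, alpha_tests = alpha$tests,
    partitions = partitions, beta_profiles = profiles,
    pairwise_beta = pairwise,
    cwm = cwm_tab, cwm_tests = cwm_tests,
    composition = summarize_composition(pooled, families),
    manifest = list(
      seed = seed, q_values = q_values, q_grid = q_grid, n_boot = n_boot,
      n_sites = nrow(counts), n_species = ncol(counts),
      dimensions = c("taxonomic",
                     if (!is.null(d)) "functional",
                     if (!is.null(phylo_tree)) "phylogenetic"),
      dropped_species = if (!is.null(tree)) setdiff(colnames(counts),
                                                    colnames(phylo_counts))
                        else character(),
      warnings = warnings_log,
      package_version = as.character(packageVersion("divpart"))))

  if (!is.null(out_dir)) {
    write_results(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a results bundle to disk
#'
#' Tidy TSV per table plus `results.json` (the full bundle) and
#' `manifest.json`.
#'
#' @param bundle output of [run_analysis()].
#' @param out_dir directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("coverage", "alpha", "alpha_tests", "partitions",
            "beta_profiles", "pairwise_beta", "cwm", "cwm_tests")
  for (tb in tabs)
    if (!is.null(bundle[[tb]]))
      write.table(bundle[[tb]], file.path(out_dir, paste0(tb, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
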