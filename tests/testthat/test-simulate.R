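test_that("simulators are deterministic under a fixed seed", {
  cfg <- scenario_config("species_sorting", seed = 123)
  s1 <- simulate_metacommunity(cfg)
  s2 <- simulate_metacommunity(cfg)
  expect_identical(unclass(s1$counts)[, ], unclass(s2$counts)[, ])
  expect_identical(s1$meta, s2$meta)
  expect_identical(simulate_traits(30, seed = 5), simulate_traits(30, seed = 5))
  t1 <- simulate_tree(15, seed = 5); t2 <- simulate_tree(15, seed = 5)
  expect_identical(t1$edge.length, t2$edge.length)
})

test_that("simulated outputs pass the package validators", {
  for (st in c("species_sorting", "mass_effects", "neutral")) {
    sim <- simulate_metacommunity(scenario_config(st, seed = 11))
    expect_s3_class(sim$counts, "community_matrix")
    expect_equal(dim(sim$counts), c(22L, 85L))
    expect_equal(as.vector(table(sim$meta$depth_category)), c(8L, 14L))
    expect_true(all(rowSums(sim$counts) > 0))
  }
  tt <- simulate_traits(40, seed = 2)
  expect_true(all(vapply(tt, is.factor, logical(1))))
  tree <- simulate_tree(40, seed = 2)
  expect_equal(length(tree$tip.label), 40L)
  expect_equal(nrow(tree$edge), 2L * 40L - 2L)   # rooted binary tree
  expect_true(check_ultrametric(tree, action = "silent"))
  expect_equal(attr(tree, "root_age"), 100, tolerance = 1e-9)
  expect_error(simulate_tree(1), "two species")
})

test_that("equal-abundance diversity on a simulated tree is bounded by richness", {
  tree <- simulate_tree(20, seed = 6)
  p <- setNames(rep(1, 20), tree$tip.label)
  for (q in c(0, 1, 2))
    expect_lte(phylo_hill(tree, p, q), 20 + 1e-10)
})

test_that("neutral metacommunities approach beta = 1 as counts grow", {
  cfg <- scenario_config("neutral", site_total = 5000, seed = 21)
  sim <- simulate_metacommunity(cfg)
  for (q in c(1, 2))
    expect_lt(regional_partition(sim$counts, q = q)$beta, 1.05)
})

test_that("scenario mechanisms leave their intended pairwise-beta signature", {
  sim_t <- simulate_metacommunity(scenario_config("species_sorting", seed = 31))
  pb <- pairwise_beta(sim_t$counts)
  expect_gt(mean(pb$beta_sim), mean(pb$beta_sne))
  expect_equal(sim_t$truth$dominant_component, "turnover")

  sim_n <- simulate_metacommunity(scenario_config("mass_effects", seed = 31))
  sh <- sim_n$meta$site_id[sim_n$meta$depth_category == "shallow"]
  dp <- sim_n$meta$site_id[sim_n$meta$depth_category == "deep"]
  cross <- divpart:::cross_pairwise_beta(sim_n$counts, sh, dp)
  expect_gt(mean(cross$beta_sne), mean(cross$beta_sim))
  expect_equal(sim_n$truth$dominant_component, "nestedness")

  # mass effects: shallow richness nested below deep richness
  expect_lt(mean(rowSums(unclass(sim_n$counts)[sh, ] > 0)),
            mean(rowSums(unclass(sim_n$counts)[dp, ] > 0)))
})

test_that("depth-linked trait bias creates a CWM contrast; no bias, none", {
  sim <- simulate_metacommunity(scenario_config("species_sorting", seed = 41))
  deep_sp <- sim$truth$depth_optimum >= 30
  tt <- simulate_traits(85, seed = 41, species_ids = colnames(sim$counts),
                        deep_bias = deep_sp)
  expect_true(all(tt$spawning[!deep_sp] != "ovoviviparous"))
  tab <- cwm(sim$counts, tt)
  ovo <- tab[tab$trait == "spawning" & tab$state == "ovoviviparous", ]
  cat_of <- setNames(as.character(sim$meta$depth_category), sim$meta$site_id)
  rt <- rank_sum_test(ovo$value[cat_of[ovo$site] == "deep"],
                      ovo$value[cat_of[ovo$site] == "shallow"], "greater")
  expect_lt(rt$p_value, 0.05)

  # without bias the contrast has no systematic direction: for a fixed
  # metacommunity, random trait assignment makes the sign of the deep-shallow
  # CWM difference symmetric over trait draws
  signs <- vapply(101:140, function(s) {
    tt0 <- simulate_traits(85, seed = s, species_ids = colnames(sim$counts))
    tab0 <- cwm(sim$counts, tt0)
    ovo0 <- tab0[tab0$trait == "spawning" & tab0$state == "ovoviviparous", ]
    mean(ovo0$value[cat_of[ovo0$site] == "deep"]) >
      mean(ovo0$value[cat_of[ovo0$site] == "shallow"])
  }, logical(1))
  expect_gt(mean(signs), 0.2)
  expect_lt(mean(signs), 0.8)
})

test_that("custom site layouts are honored", {
  cfg <- scenario_config("neutral", n_shallow = 3, n_deep = 4,
                         site_total = 80, seed = 51)
  sim <- simulate_metacommunity(cfg)
  expect_equal(nrow(sim$counts), 7L)
  expect_equal(sum(sim$meta$depth_category == "shallow"), 3L)
  expect_error(scenario_config("neutral", depths = c(1, 2)),
               "one entry per site")
})
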