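test_that("Gower distance reproduces hand-computed cases", {
  lv <- trait_levels()
  row <- function(...) setNames(list(...), names(lv))
  df <- as.data.frame(rbind(
    a = row("benthic", "generalist", "0-7", "roving", "herbivore", "brooding"),
    b = row("benthic", "generalist", "0-7", "roving", "herbivore", "brooding"),
    c = row("pelagic", "specialist", "0-7", "roving", "omnivore", "brooding"),
    d = row("benthic", "generalist", ">80", "roving", "herbivore", "brooding")))
  tt <- as_trait_table(df)
  d_nom <- gower_distance(tt, ordinal = character(0))
  expect_equal(d_nom["a", "b"], 0)              # identical rows
  expect_equal(d_nom["a", "c"], 3 / 6)          # 3 of 6 nominal mismatches
  expect_equal(d_nom["a", "d"], 1 / 6)          # nominal size mismatch
  d_ord <- gower_distance(tt)                   # size_class ranked
  expect_equal(d_ord["a", "d"], (5 / 5) / 6)    # extreme classes, 5 equal traits
  expect_equal(d_ord["a", "c"], 3 / 6)          # unaffected elsewhere
})

test_that("Gower distance satisfies its matrix invariants on random tables", {
  set.seed(43)
  for (i in 1:10) {
    tt <- simulate_traits(sample(4:15, 1), seed = i)
    d <- gower_distance(tt)
    expect_true(all(abs(d - t(d)) < 1e-12))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("Gower agrees with cluster::daisy when all traits are nominal", {
  skip_if_not_installed("cluster")
  set.seed(47)
  tt <- simulate_traits(12, seed = 9)
  tt_nom <- as.data.frame(lapply(tt, function(x)
    factor(as.character(x))), row.names = rownames(tt))
  ref <- as.matrix(cluster::daisy(tt_nom, metric = "gower"))
  d <- gower_distance(tt, ordinal = character(0))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)
})

test_that("missing traits are excluded pairwise, never zero-filled", {
  tt <- make_traits(c("a", "b", "c"))
  tt$trophic[1] <- NA
  d <- gower_distance(tt)
  # pair (a, b): mean over the 5 traits observed for both
  manual <- mean(vapply(setdiff(names(tt), c("trophic", "size_class")),
                        function(tr) as.numeric(tt[1, tr] != tt[2, tr]),
                        numeric(1)))
  manual <- (manual * 4 +
               abs(as.integer(tt$size_class[1]) - as.integer(tt$size_class[2])) / 5) / 5
  expect_equal(d["a", "b"], manual)
  # a pair with no shared trait is an error
  t2 <- make_traits(c("a", "b"))
  t2[1, 1:3] <- NA; t2[2, 4:6] <- NA
  expect_error(suppressWarnings(gower_distance(as_trait_table(t2))),
               "no shared")
})

test_that("functional Hill diversity matches closed forms and handles Q = 0", {
  dm <- function(x, sp) matrix(x, length(sp), length(sp),
                               dimnames = list(sp, sp))
  d <- dm(c(0, 0.4, 0.4, 0), c("A", "B"))
  expect_equal(functional_hill(c(A = 1, B = 1), d, 2), 0.8)   # 2d
  expect_equal(functional_hill(c(A = 1, B = 1), d, 0), 0.8)   # sum of d over pairs
  d0 <- dm(0, c("A", "B"))
  expect_warning(v <- functional_hill(c(A = 1, B = 1), d0, 1), "monomorphic")
  expect_equal(v, 0)
})

test_that("functional Hill diversity is relabel-invariant and scales in d", {
  set.seed(53)
  for (i in 1:10) {
    S <- sample(3:8, 1)
    sp <- paste0("s", seq_len(S))
    d <- matrix(runif(S * S), S, S, dimnames = list(sp, sp))
    d <- (d + t(d)) / 2; diag(d) <- 0
    p <- setNames(rand_counts(S) + 1, sp)
    q <- sample(c(0, 0.5, 2), 1)
    val <- functional_hill(p, d, q)
    perm <- sample(S)
    expect_equal(functional_hill(p[perm], d[perm, perm], q), val,
                 tolerance = 1e-10)
    expect_equal(functional_hill(p, 3 * d, 0), 3 * functional_hill(p, d, 0),
                 tolerance = 1e-10)
  }
})

test_that("functional partition is 1 for identical sites and > 1 for divergent ones", {
  sp <- paste0("s", 1:4)
  d <- matrix(0.6, 4, 4, dimnames = list(sp, sp)); diag(d) <- 0
  cm <- make_cm(matrix(rep(c(4, 3, 2, 1), each = 3), 3, 4), species = sp)
  for (q in c(0, 1, 2)) {
    pt <- functional_partition(cm, d, q = q)
    expect_equal(pt$beta, 1, tolerance = 1e-10)
    expect_equal(pt$gamma, functional_hill(c(4, 3, 2, 1), d, q),
                 tolerance = 1e-10)
  }
  # disjoint, trait-divergent species sets
  cm2 <- make_cm(matrix(c(2, 2, 0, 0, 0, 0, 2, 2), 2, byrow = TRUE),
                 species = sp)
  for (q in c(0, 1, 2))
    expect_gt(functional_partition(cm2, d, q = q)$beta, 1)
})

test_that("pooled fixture functional gamma is finite and positive", {
  fx <- reef_fish_counts()
  tt <- make_traits(colnames(fx$counts))
  d <- gower_distance(tt)
  for (rg in c("shallow", "deep")) {
    g <- functional_hill(unclass(fx$counts)[rg, ], d, 0)
    expect_true(is.finite(g) && g > 0)
  }
})

test_that("community-weighted means are abundance-weighted state proportions", {
  tt <- make_traits(c("h1", "h2", "pl"))
  tt$trophic <- factor(c("herbivore", "herbivore", "planktivore"),
                       levels = trait_levels()$trophic)
  cm <- make_cm(matrix(c(2, 1, 1, 0, 3, 0), 2, 3, byrow = TRUE),
                species = c("h1", "h2", "pl"))
  tab <- cwm(cm, tt)
  v <- function(site, state)
    tab$value[tab$site == site & tab$trait == "trophic" & tab$state == state]
  expect_equal(v("s1", "herbivore"), 0.75)
  expect_equal(v("s1", "planktivore"), 0.25)
  expect_equal(v("s2", "herbivore"), 1)        # 100% herbivore site
  expect_equal(v("s2", "planktivore"), 0)      # absent state -> 0
  # per site and trait the values sum to 1
  sums <- aggregate(value ~ site + trait, tab, sum)
  expect_true(all(abs(sums$value - 1) < 1e-12))
})
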