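test_that("Hill numbers reproduce closed-form cases", {
  for (q in c(0, 0.5, 1, 2))
    expect_equal(hill_number(rep(3, 7), q), 7)            # S equal species
  expect_equal(hill_number(c(0.75, 0.25), 2), 1.6)
  expect_equal(hill_number(c(9, 1), 0), 2)
  expect_equal(hill_number(c(9, 1), 2), 1 / 0.82, tolerance = 1e-12)
  expect_error(hill_number(c(1, 2), -0.5), "q must")
  expect_error(hill_number(c(0, 0), 1), "all-zero")
})

test_that("Hill numbers are continuous at q = 1", {
  set.seed(13)
  for (i in 1:20) {
    p <- rel_abund(rand_counts(12) + 0.5)
    h <- 1e-5
    two_sided <- (hill_number(p, 1 - h) + hill_number(p, 1 + h)) / 2
    expect_equal(two_sided, hill_number(p, 1), tolerance = 1e-8)
  }
})

test_that("Hill numbers are bounded and non-increasing in q", {
  set.seed(17)
  qs <- seq(0, 3, by = 0.25)
  for (i in 1:25) {
    x <- rand_counts(15) + rpois(15, 2)
    x[x == 0] <- 1
    prof <- sapply(qs, function(q) hill_number(x, q))
    expect_true(all(diff(prof) <= 1e-10))
    expect_true(all(prof >= 1 - 1e-12 & prof <= sum(x > 0) + 1e-12))
  }
})

test_that("Hill numbers agree with vegan's Renyi diversities", {
  set.seed(19)
  for (i in 1:10) {
    x <- rand_counts(20) + 1
    for (q in c(0, 0.5, 1, 2, 4)) {
      ref <- exp(as.numeric(vegan::renyi(x, scales = q)))
      expect_equal(hill_number(x, q), ref, tolerance = 1e-10)
    }
  }
})

test_that("per-site alpha evaluates each site's own abundances", {
  cm <- make_cm(matrix(c(10, 10, 9, 1), 2, 2, byrow = TRUE))
  expect_equal(unname(alpha_per_site(cm, 0)), c(2, 2))
  expect_equal(unname(alpha_per_site(cm, 2)), c(2, 1 / 0.82),
               tolerance = 1e-12)
})

test_that("regional partition honors its boundary cases", {
  # identical sites: beta = 1 at every q
  cm <- make_cm(matrix(rep(c(5, 3, 2), each = 4), 4, 3))
  for (q in c(0, 1, 2)) {
    pt <- regional_partition(cm, q = q)
    expect_equal(pt$beta, 1, tolerance = 1e-12)
    expect_equal(pt$gamma, hill_number(c(5, 3, 2), q), tolerance = 1e-12)
  }
  # N disjoint internally-even sites: beta = N
  N <- 5
  m <- matrix(0L, N, 2 * N)
  for (j in seq_len(N)) m[j, (2 * j - 1):(2 * j)] <- 4L
  cmd <- make_cm(m)
  for (q in c(0, 1, 2))
    expect_equal(regional_partition(cmd, q = q)$beta, N, tolerance = 1e-12)
  # derived two-site case
  cm2 <- make_cm(matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, byrow = TRUE),
                 species = c("A", "B", "C", "D"))
  pt <- regional_partition(cm2, q = 0)
  expect_equal(c(pt$gamma, pt$alpha, pt$beta), c(4, 2, 2))
  expect_error(regional_partition(cm2, sites = character(0), q = 0), "empty")
})

test_that("regional beta is bounded, relabel- and scale-invariant", {
  set.seed(23)
  for (i in 1:15) {
    N <- sample(2:6, 1)
    cm <- make_cm(matrix(rand_counts(N * 12, 5) + 1, N, 12))
    q <- sample(c(0, 0.5, 1, 2), 1)
    pt <- regional_partition(cm, q = q)
    expect_gte(pt$beta, 1 - 1e-10)
    expect_lte(pt$beta, N + 1e-10)
    # relabeling species leaves beta unchanged
    perm <- sample(ncol(cm))
    cmp <- make_cm(unclass(cm)[, perm])
    expect_equal(regional_partition(cmp, q = q)$beta, pt$beta,
                 tolerance = 1e-12)
    # multiplying all counts by a constant leaves the partition unchanged
    cms <- make_cm(unclass(cm) * 7L)
    pts <- regional_partition(cms, q = q)
    expect_equal(pts$beta, pt$beta, tolerance = 1e-12)
    expect_equal(pts$gamma, pt$gamma, tolerance = 1e-12)
  }
})

test_that("replicating assemblages into disjoint copies multiplies gamma", {
  set.seed(29)
  base <- matrix(rand_counts(8, 4) + 1, 2, 4)
  M <- 3
  big <- matrix(0L, 2 * M, 4 * M)
  for (k in seq_len(M))
    big[(2 * k - 1):(2 * k), (4 * k - 3):(4 * k)] <- base
  cm1 <- make_cm(base)
  cmM <- make_cm(big)
  for (q in c(0, 1, 2))
    expect_equal(regional_partition(cmM, q = q)$gamma,
                 M * regional_partition(cm1, q = q)$gamma,
                 tolerance = 1e-10)
})

test_that("gamma at q = 0 is weighting-invariant (richness of the union)", {
  set.seed(37)
  cm <- make_cm(matrix(rand_counts(40, 3), 4, 10))
  g_eq <- regional_partition(cm, q = 0, weighting = "equal")$gamma
  g_ab <- regional_partition(cm, q = 0, weighting = "by_abundance")$gamma
  expect_equal(g_eq, g_ab)
  expect_equal(g_eq, sum(colSums(unclass(cm)) > 0))
})

test_that("weighted alpha matches brute-force from its definition", {
  set.seed(41)
  # oracle: alpha = [(1/N) sum_j sum_i p_ij^q]^{1/(1-q)} under equal weights
  for (i in 1:10) {
    N <- sample(2:5, 1)
    m <- matrix(rand_counts(N * 6, 4) + 1, N, 6)
    cm <- make_cm(m)
    P <- m / rowSums(m)
    for (q in c(0, 0.5, 2)) {
      ora <- (sum(P^q) / N)^(1 / (1 - q))
      expect_equal(regional_partition(cm, q = q)$alpha, ora,
                   tolerance = 1e-10)
    }
    ora1 <- exp(mean(apply(P, 1, function(p) -sum(p * log(p)))))
    expect_equal(regional_partition(cm, q = 1)$alpha, ora1,
                 tolerance = 1e-10)
  }
})

test_that("beta profiles behave on constructed regions", {
  # identical sites in both categories: flat profile at 1
  cm <- make_cm(matrix(rep(c(6, 3, 1), each = 4), 4, 3))
  meta <- make_meta(cm, 2)
  prof <- beta_profile(cm, meta, q_grid = c(0, 0.5, 1, 1.5, 2))
  expect_true(all(abs(prof$beta - 1) < 1e-10))
  # turnover-dominated region: beta near N at q = 0
  N <- 4
  m <- matrix(0L, N, 2 * N)
  for (j in seq_len(N)) m[j, (2 * j - 1):(2 * j)] <- 3L
  cmd <- make_cm(m)
  prof2 <- beta_profile(cmd, make_meta(cmd, 2), q_grid = 0)
  expect_true(all(abs(prof2$beta - 2) < 1e-10))  # 2 disjoint sites per region
})
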