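# independent brute-force transcriptions of the diversity formulas,
# written as explicit loops so they share no code path with the package

oracle_hill <- function(p, q) {
  p <- p / sum(p)
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) {
    h <- 0
    for (pi in p) h <- h - pi * log(pi)
    return(exp(h))
  }
  s <- 0
  for (pi in p) s <- s + pi^q
  s^(1 / (1 - q))
}

oracle_functional_hill <- function(p, d, q) {
  p <- unname(p / sum(p))
  keep <- p > 0
  p <- p[keep]; d <- d[keep, keep, drop = FALSE]
  S <- length(p)
  Q <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) Q <- Q + d[i, j] * p[i] * p[j]
  if (Q <= 0) return(0)
  if (abs(q - 1) < 1e-12) {
    h <- 0
    for (i in seq_len(S)) for (j in seq_len(S)) {
      r <- p[i] * p[j] / Q
      if (d[i, j] > 0) h <- h - d[i, j] * r * log(r)
    }
    return(exp(h))
  }
  s <- 0
  for (i in seq_len(S)) for (j in seq_len(S))
    s <- s + d[i, j] * (p[i] * p[j] / Q)^q
  s^(1 / (1 - q))
}

# branch abundances via phangorn::Descendants (independent of the package's
# postorder accumulation), then the printed formula by explicit loop
oracle_phylo_hill <- function(tree, p, q) {
  p <- p / sum(p)
  Tage <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  s <- 0; h <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc[[e]]]
    a <- sum(p[names(p) %in% tips])
    if (a > 0) {
      L <- tree$edge.length[e]
      if (abs(q - 1) < 1e-12) h <- h - (L / Tage) * a * log(a)
      else s <- s + (L / Tage) * a^q
    }
  }
  if (abs(q - 1) < 1e-12) exp(h) else s^(1 / (1 - q))
}

oracle_baselga <- function(x, y) {
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  cc <- length(setdiff(y, x))
  sor <- if (b + cc == 0) 0 else (b + cc) / (2 * a + b + cc)
  sim <- if (min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  c(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim)
}

oracle_coverage <- function(counts) {
  x <- counts[counts > 0]
  n <- sum(x); f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  if (n == 1) return(0)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}
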