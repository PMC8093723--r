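# small in-code builders shared across test files

make_cm <- function(m, sites = NULL, species = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- sites %||% paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- species %||% paste0("sp", seq_len(ncol(m)))
  as_community_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random count vector with a long tail (guaranteed nonempty)
rand_counts <- function(S, lambda = 3) {
  x <- rpois(S, lambda = rexp(S, 1 / lambda))
  if (all(x == 0)) x[sample.int(S, 1)] <- 1L
  x
}

# metadata for a matrix whose first n_shallow rows are shallow
make_meta <- function(cm, n_shallow) {
  n <- nrow(cm)
  data.frame(site_id = rownames(cm),
             depth_m = c(seq(2, 25, length.out = n_shallow),
                         seq(31, 60, length.out = n - n_shallow)),
             depth_category = factor(rep(c("shallow", "deep"),
                                         c(n_shallow, n - n_shallow)),
                                     levels = c("shallow", "deep")),
             effort_min = NA_real_)
}

# a fully specified small trait table (all six traits, no NA)
make_traits <- function(species, seed = 42) {
  simulate_traits(length(species), seed = seed, species_ids = species)
}
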