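# divpart

Diversity partitioning of depth-structured reef communities.

`divpart` is an R package for community ecologists asking whether one part of
an environmental gradient (for example the deep, mesophotic half of a reef
system) contains the species, functions, and evolutionary lineages of
another (the shallow, disturbed half) — the kind of question posed by the
deep-reef refugia idea.  Given a site-by-species count matrix, site depths, a
categorical trait table, and a time-calibrated phylogeny, it:

- estimates **sample coverage** per site and per depth region from
  singletons and doubletons, so samples are standardized by completeness
  rather than size;
- computes **Hill-number diversity** of three kinds — taxonomic,
  functional (Gower distances + Rao quadratic entropy), and phylogenetic
  (branch lengths and branch abundances on an ultrametric tree) — at orders
  *q* = 0, 1, 2 (rare, typical, dominant species);
- partitions regional **gamma** diversity multiplicatively into independent
  **alpha** and **beta** components (beta = gamma/alpha, the effective
  number of completely distinct communities);
- decomposes pairwise Sørensen dissimilarity into **spatial turnover** and
  **nestedness** components with bootstrap summaries;
- compares per-site diversity and **community-weighted trait means**
  between depth categories with one-sided rank-sum tests, plus a Mantel
  check for spatial autocorrelation;
- ships a seeded **metacommunity simulator** (species sorting, mass
  effects, neutral) so every stage can be exercised against ground-truthed
  synthetic data.

## The measures

For relative abundances *p₁, …, p_S*, diversity of order *q* is the Hill
number

> ⁰·ᑫD = (Σᵢ pᵢᑫ)^(1/(1−q)),

with the Shannon limit exp(−Σ pᵢ ln pᵢ) at *q* = 1.  Functional diversity
uses pairwise Gower distances *d_ij* and Rao's Q = Σᵢⱼ d_ij pᵢpⱼ:

> ᑫFD(Q) = (Σᵢⱼ d_ij (pᵢpⱼ/Q)ᑫ)^(1/(1−q)),

and phylogenetic diversity uses branch lengths *Lᵢ* and branch abundances
*aᵢ* over the root age *T* of an ultrametric tree:

> ᑫD̄(T) = (Σᵢ (Lᵢ/T) aᵢᑫ)^(1/(1−q)).

Sample coverage is the Chao–Jost estimator
Ĉₙ = 1 − (f₁/n)·[(n−1)f₁ / ((n−1)f₁ + 2f₂)].  Pairwise beta uses the
Sørensen family: β_sor = (b+c)/(2a+b+c), turnover
β_sim = min(b,c)/(a+min(b,c)), nestedness β_sne = β_sor − β_sim.

## Worked example

The package ships the pooled shallow/deep census of a 22-reef survey
(2–62 m; 85 fish species, 3,821 individuals) as a fixture:

```r
library(divpart)

fx <- reef_fish_counts()
m  <- unclass(fx$counts)          # 2 x 85: rows "shallow", "deep"

hill_number(m["shallow", ], q = 0)   # 56   species in the shallow region
hill_number(m["deep",    ], q = 0)   # 70   species in the deep region

sample_coverage(m["shallow", ])
#> Sample coverage: 0.9780 (n = 727, f1 = 16, f2 = 6)
sample_coverage(m["deep", ])
#> Sample coverage: 0.9971 (n = 3094, f1 = 9, f2 = 7)

cs <- summarize_composition(fx$counts, fx$families)
cs$shared; cs$shallow_only; cs$deep_only   # 41 / 15 / 29 species
cs$species_share_pct[1:2]                  # top species: 23% and 18%
cs$top_cumulative_pct                      # top ten species: 70%
```

Both regions are sampled nearly completely (coverage 98% and 99.7%), so
their empirical Hill numbers are comparable; less than half the species
pool is shared between depth zones.

Site-level analyses need per-reef data; the simulator provides
ground-truthed stand-ins with the same survey layout (8 shallow + 14 deep
sites):

```r
sim <- simulate_metacommunity(scenario_config("species_sorting", seed = 1))
res <- run_analysis(sim$counts, sim$meta,
                    traits = simulate_traits(85, seed = 1,
                                             species_ids = colnames(sim$counts)),
                    tree   = simulate_tree(85, seed = 1,
                                           species_ids = colnames(sim$counts)),
                    q_grid = c(0, 1, 2), n_boot = 500, seed = 1)

subset(res$partitions, weighting == "equal" & q == 0 & dimension == "taxonomic")
#>    dimension  region q weighting gamma    alpha     beta
#>    taxonomic shallow 0     equal    47 31.37500 1.498008
#>    taxonomic    deep 0     equal    77 36.57143 2.105469

res$alpha_tests[res$alpha_tests$dimension == "taxonomic", ]
#>   dimension q statistic     p_value n_deep n_shallow
#>   taxonomic 0        94 0.005133268     14         8
#>   taxonomic 1        72 0.145047866     14         8
#>   taxonomic 2        54 0.567743003     14         8
```

Under species sorting the deep region holds more rare species (q = 0) at a
low rank-sum p, while typical and dominant species do not differ — and the
within-region pairwise beta is turnover-dominated
(`res$pairwise_beta`: mean β_sim ≈ 0.38 vs β_sne ≈ 0.04 among deep
sites).  `run_analysis(..., out_dir = "out")` writes every table as tidy
TSV plus `results.json` and `manifest.json`, byte-identical across reruns
with the same seed.

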