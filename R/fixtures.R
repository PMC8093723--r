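#' Packaged reef fish census: pooled shallow/deep counts
#'
#' The pooled species-by-depth-zone abundance table of the reference survey
#' of 22 southwestern Atlantic reefs (2-62 m): 85 fish species in 36
#' families, 3,821 individuals, with counts pooled into a shallow (< 30 m)
#' and a deep (>= 30 m) assemblage.
#'
#' @return list with `counts` (2-site `community_matrix`, rows `shallow`
#'   and `deep`), `families` (named character vector mapping species to
#'   family), and `iucn` (named vector of IUCN categories, `""` when
#'   unlisted).
#' @seealso [reef_sites()]
#' @export
reef_fish_counts <- function() {
  path <- system.file("extdata", "table2_shallow_deep.tsv",
                      package = "divpart", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   encoding = "UTF-8")
  m <- t(as.matrix(df[, c("shallow", "deep")]))
  colnames(m) <- df$species
  list(counts = as_community_matrix(m),
       families = setNames(df$family, df$species),
       iucn = setNames(ifelse(is.na(df$iucn), "", df$iucn), df$species))
}

#' Packaged reef fish census: per-reef depth and coverage table
#'
#' Depth, category, sampling effort (decimal minutes), and reported
#' per-reef sample coverage of the 22 surveyed reefs (8 shallow, 14 deep).
#' The per-reef species counts themselves are not part of the package; use
#' [simulate_metacommunity()] for site-level inputs.
#'
#' @return data.frame with columns `site_id`, `depth_m`, `depth_category`,
#'   `effort_min`, `coverage_pct`.
#' @export
reef_sites <- function() {
  path <- system.file("extdata", "table1_sites.tsv",
                      package = "divpart", mustWork = TRUE)
  read_site_metadata(path)
}
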