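#' Coerce and validate a site-by-species count matrix
#'
#' A community matrix holds nonnegative integer counts with sites as rows and
#' species as columns (abundance recorded as the maximum number of
#' conspecifics seen simultaneously, in census data of this kind).  Row and
#' column names must be unique and non-empty, and every site must contain at
#' least one individual.  Species columns that are all zero are permitted but
#' recorded in the `"empty_species"` attribute.
#'
#' @param x a numeric matrix or data.frame with dimnames.
#' @return an integer matrix of class `"community_matrix"`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 4, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB", "spC")))
#' cm <- as_community_matrix(m)
#' rowSums(cm)
as_community_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("counts must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community matrix needs site row names and species column names")
  rn <- trimws(rownames(x)); cn <- trimws(colnames(x))
  if (anyDuplicated(rn))
    stop("duplicated site name(s): ", paste(unique(rn[duplicated(rn)]), collapse = ", "))
  if (anyDuplicated(cn))
    stop("duplicated species name(s): ", paste(unique(cn[duplicated(cn)]), collapse = ", "))
  if (any(rn == "") || any(cn == "")) stop("empty site or species name")
  bad <- which(x < 0 | abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-integer count at site '", rn[bad[1, 1]],
         "', species '", cn[bad[1, 2]], "'")
  if (any(rowSums(x) == 0))
    stop("site(s) with no individuals: ",
         paste(rn[rowSums(x) == 0], collapse = ", "))
  storage.mode(x) <- "integer"
  dimnames(x) <- list(rn, cn)
  empty <- cn[colSums(x) == 0]
  structure(x, empty_species = empty, class = c("community_matrix", class(x)))
}

#' Read a site-by-species count table
#'
#' Reads a delimited text file into a validated community matrix.  The
#' delimiter is auto-detected (tab default, comma fallback).  By default the
#' first column holds site names and the header holds species names; set
#' `sites_as_rows = FALSE` for the transposed layout.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @param sites_as_rows logical; if `FALSE` the file is transposed on read.
#' @return a `community_matrix`.
#' @seealso [as_community_matrix()], [write_community_matrix()]
#' @export
read_community_matrix <- function(path, sep = NULL, sites_as_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, check.names = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  hdr <- trimws(names(df)[-1])
  if (anyDuplicated(hdr))   # data.frame subsetting would silently uniquify
    stop("duplicated species name(s): ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  first <- trimws(as.character(df[[1]]))
  if (anyDuplicated(first))
    stop("duplicated name(s) in first column: ",
         paste(unique(first[duplicated(first)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell in ", path)
  rownames(m) <- first
  if (!sites_as_rows) m <- t(m)
  as_community_matrix(m)
}

#' Write a community matrix to TSV
#'
#' @param cm a `community_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path) {
  df <- data.frame(site = rownames(cm), as.data.frame(unclass(cm)[, , drop = FALSE]),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign depth categories from depth in meters
#'
#' Sites at or below the surface side of the boundary are "shallow", sites at
#' `threshold` meters or deeper are "deep".  The default boundary of 30 m is
#' the conventional upper limit of mesophotic reefs; reefs recorded at
#' exactly 30 m are classified deep.
#'
#' @param depth_m numeric vector of depths (m, nonnegative).
#' @param threshold depth (m) at and beyond which a site is "deep".
#' @return factor with levels `shallow`, `deep`.
#' @export
assign_depth_category <- function(depth_m, threshold = 30) {
  if (any(depth_m < 0)) stop("negative depth")
  factor(ifelse(depth_m >= threshold, "deep", "shallow"),
         levels = c("shallow", "deep"))
}

#' Read a site metadata table
#'
#' Expects columns `site_id` and `depth_m`; `depth_category` and `effort_min`
#' are optional.  When `depth_category` is absent it is computed from
#' `depth_m` with [assign_depth_category()]; when present it is validated
#' against the closed set \{shallow, deep\}.
#'
#' @param path path to a TSV/CSV file.
#' @param sep delimiter, auto-detected when `NULL`.
#' @param threshold depth boundary passed to [assign_depth_category()].
#' @return data.frame with columns `site_id`, `depth_m`, `depth_category`,
#'   and `effort_min` (NA when absent).
#' @export
read_site_metadata <- function(path, sep = NULL, threshold = 30) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("site_id", "depth_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  df$site_id <- trimws(as.character(df$site_id))
  if (anyDuplicated(df$site_id))
    stop("duplicated site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  if (!is.numeric(df$depth_m) || any(df$depth_m < 0))
    stop("depth_m must be nonnegative numeric")
  if ("depth_category" %in% names(df)) {
    bad <- setdiff(unique(df$depth_category), c("shallow", "deep"))
    if (length(bad)) stop("unknown depth_category value(s): ", paste(bad, collapse = ", "))
    df$depth_category <- factor(df$depth_category, levels = c("shallow", "deep"))
  } else {
    df$depth_category <- assign_depth_category(df$depth_m, threshold)
  }
  if (!"effort_min" %in% names(df)) df$effort_min <- NA_real_
  df[, c("site_id", "depth_m", "depth_category", "effort_min",
         setdiff(names(df), c("site_id", "depth_m", "depth_category", "effort_min")))]
}

## match a metadata table against a community matrix; returns the metadata
## reordered to the matrix sites, erroring on any site without a record.
match_metadata <- function(cm, meta) {
  idx <- match(rownames(cm), meta$site_id)
  if (anyNA(idx))
    stop("site(s) without metadata: ",
         paste(rownames(cm)[is.na(idx)], collapse = ", "))
  meta[idx, , drop = FALSE]
}

#' Pool a community matrix by depth category
#'
#' Sums counts of all sites within each depth category, producing the two-row
#' (shallow, deep) regional matrix used for gamma diversity and pooled
#' coverage.  Total abundance and the species set are conserved.
#'
#' @param cm a `community_matrix`.
#' @param meta site metadata with `site_id` and `depth_category` (see
#'   [read_site_metadata()]); every site in `cm` must have a record.
#' @return a `community_matrix` with one row per category present.
#' @export
pool_by_category <- function(cm, meta) {
  meta <- match_metadata(cm, meta)
  g <- factor(meta$depth_category, levels = c("shallow", "deep"))
  pooled <- rowsum(unclass(cm), g)
  as_community_matrix(pooled[levels(g)[table(g) > 0], , drop = FALSE])
}
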