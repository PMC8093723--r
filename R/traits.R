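#' Closed level sets of the six categorical functional traits
#'
#' The functional profile of each species is described by six qualitative
#' traits covering habitat use, body size, mobility, trophic niche, and
#' reproduction: water-column position, habitat use, body-size class (ordered
#' total-length intervals, cm), mobility, trophic category, and spawning
#' mode.
#'
#' @return named list of character vectors; `size_class` is ordered.
#' @export
trait_levels <- function() {
  list(
    water_column = c("benthic", "pelagic", "benthopelagic"),
    habitat_use  = c("generalist", "intermediate generalist", "specialist"),
    size_class   = c("0-7", "7.1-15", "15.1-30", "30.1-50", "50.1-80", ">80"),
    mobility     = c("high mobility", "roving", "sedentary"),
    trophic      = c("herbivore", "macrocarnivore", "macroinvertivore",
                     "small invertivore", "omnivore", "planktivore"),
    spawning     = c("Balistidae type", "brooding", "demersal eggs",
                     "pelagic eggs", "ovoviviparous")
  )
}

#' Validate a species-by-trait table against the closed level sets
#'
#' @param df data.frame with species as row names and the six trait columns.
#' @return data.frame of factors (ordered for `size_class`); missing values
#'   are kept as `NA` and flagged with a warning, never dropped.
#' @export
as_trait_table <- function(df) {
  lv <- trait_levels()
  miss <- setdiff(names(lv), names(df))
  if (length(miss)) stop("missing trait column(s): ", paste(miss, collapse = ", "))
  if (is.null(rownames(df)) || anyDuplicated(rownames(df)))
    stop("trait table needs unique species row names")
  out <- df[, names(lv), drop = FALSE]
  for (tr in names(lv)) {
    v <- trimws(as.character(out[[tr]]))
    v[v == ""] <- NA
    bad <- setdiff(unique(v[!is.na(v)]), lv[[tr]])
    if (length(bad)) {
      sp <- rownames(out)[v %in% bad]
      stop("unknown ", tr, " value(s) ", paste(bad, collapse = ", "),
           " for species: ", paste(sp, collapse = ", "))
    }
    out[[tr]] <- factor(v, levels = lv[[tr]], ordered = tr == "size_class")
  }
  n_na <- sum(is.na(out))
  if (n_na > 0)
    warning(n_na, " missing trait value(s) flagged (kept as NA)")
  out
}

#' Read a species-by-trait table
#'
#' The first column holds species names; remaining columns are matched onto
#' the six traits, optionally through `col_map` when the file uses different
#' headers.
#'
#' @param path path to a TSV/CSV file.
#' @param sep delimiter, auto-detected when `NULL`.
#' @param col_map optional named character vector mapping file headers to
#'   trait names, e.g. `c(body_size = "size_class")`.
#' @return validated trait data.frame (see [as_trait_table()]).
#' @export
read_traits <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  sp <- trimws(as.character(df[[1]]))
  if (anyDuplicated(sp))
    stop("duplicated species in trait table: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- col_map[names(df)[hit]]
  }
  rownames(df) <- sp
  as_trait_table(df)
}

#' Write a trait table to TSV
#'
#' @param traits trait data.frame (see [as_trait_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  df <- data.frame(species = rownames(traits),
                   lapply(traits, as.character), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
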