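#' Taxonomic lineage maps
#'
#' Maps every taxon feature (typically a genus-level OTU summary) to a ranked
#' lineage phylum/class/order/family/genus. Where the sequencing pipeline
#' could not assign a taxon down to genus, the most detailed assignment
#' achieved is propagated downward as \code{"unclassified <parent>"}, so every
#' rank is always populated and aggregation/de-aggregation are total
#' functions.
#'
#' @name taxonomy
NULL

TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Construct a taxonomy map
#'
#' @param df data.frame with a \code{taxon_id} column plus lineage columns
#'   (any prefix of phylum/class/order/family/genus). Missing or empty lower
#'   ranks are filled as \code{"unclassified <parent>"}.
#' @return object of class \code{taxonomy_map}: a data.frame with columns
#'   \code{taxon_id} and the five ranks.
#' @export
taxonomy_map <- function(df) {
  if (!"taxon_id" %in% names(df)) stop("taxonomy needs a 'taxon_id' column")
  if (nrow(df) == 0L) stop("empty taxonomy")
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon ids: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  out <- data.frame(taxon_id = as.character(df$taxon_id),
                    stringsAsFactors = FALSE)
  prev <- NULL
  for (r in TAX_RANKS) {
    col <- if (r %in% names(df)) as.character(df[[r]]) else rep(NA_character_, nrow(df))
    col[!nzchar(col) | is.na(col)] <- NA_character_
    if (r == "phylum") {
      if (anyNA(col)) stop("taxon with empty phylum: ",
                           paste(out$taxon_id[is.na(col)], collapse = ", "))
    } else {
      fill <- is.na(col)
      parent <- out[[prev]][fill]
      col[fill] <- ifelse(startsWith(parent, "unclassified "),
                          parent, paste("unclassified", parent))
    }
    out[[r]] <- col
    prev <- r
  }
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Read a taxonomy table
#'
#' Accepts either explicit rank columns (\code{taxon_id}, \code{phylum}, ...,
#' \code{genus}) or a two-column file whose second column is a QIIME-style
#' lineage string such as
#' \code{"k__Bacteria;p__Firmicutes;c__Bacilli;o__;f__;g__Lactobacillus"}
#' (bare \code{";"}-separated lineages without rank prefixes also work; a
#' leading kingdom field is ignored).
#'
#' @param path TSV file path.
#' @param sep field separator.
#' @return a \code{\link{taxonomy_map}}.
#' @export
read_taxonomy <- function(path, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L) stop("empty taxonomy file: ", path)
  if (all(c("taxon_id", "phylum") %in% names(raw))) return(taxonomy_map(raw))
  if (ncol(raw) != 2L)
    stop("taxonomy must have rank columns or be (taxon_id, lineage-string)")
  lin <- strsplit(raw[[2]], ";", fixed = TRUE)
  parse_one <- function(parts) {
    parts <- trimws(parts)
    # strip QIIME rank prefixes ("p__Firmicutes" -> "Firmicutes")
    pref <- grepl("^[kpcofgs]__", parts)
    keyed <- any(pref)
    if (keyed) {
      keys <- substr(parts, 1, 1)
      vals <- sub("^[kpcofgs]__", "", parts)
      out <- stats::setNames(rep(NA_character_, 5), TAX_RANKS)
      for (i in seq_along(keys)) {
        r <- switch(keys[i], p = "phylum", c = "class", o = "order",
                    f = "family", g = "genus", NA_character_)
        if (!is.na(r) && nzchar(vals[i])) out[r] <- vals[i]
      }
      out
    } else {
      # positional: optionally drop a leading kingdom field
      if (length(parts) == 6L) parts <- parts[-1]
      length(parts) <- 5L
      parts[!nzchar(parts)] <- NA_character_
      stats::setNames(parts, TAX_RANKS)
    }
  }
  ranks <- t(vapply(lin, parse_one, character(5)))
  df <- data.frame(taxon_id = raw[[1]], ranks, stringsAsFactors = FALSE)
  taxonomy_map(df)
}

#' Genus-level members of a phylum
#'
#' Used by the de-summarization step: a phylum selected at the overview level
#' is split back into its member genera for the detailed genus-level network.
#'
#' @param taxmap a \code{\link{taxonomy_map}}.
#' @param phylum phylum name.
#' @return character vector of taxon ids whose lineage phylum matches;
#'   empty (with a warning) for an unknown phylum.
#' @export
members_of <- function(taxmap, phylum) {
  stopifnot(inherits(taxmap, "taxonomy_map"))
  hit <- taxmap$phylum == phylum
  if (!any(hit)) {
    warning("unknown phylum: ", phylum)
    return(character(0))
  }
  taxmap$taxon_id[hit]
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("taxonomy_map: %d taxa, %d phyla\n",
              nrow(x), length(unique(x$phylum))))
  invisible(x)
}
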