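#' Feature tables: the common container for all measurement layers
#'
#' A feature table holds a samples x features numeric matrix together with a
#' per-feature layer tag and (optionally) a per-sample group label. The four
#' layers correspond to the data types the pipeline integrates: host gene
#' expression on the 2^dCt scale (\code{host_gene}), taxon counts or
#' normalized abundances (\code{taxon}), gastrointestinal symptom domain
#' scores (\code{gi_symptom}) and psychological instrument scores
#' (\code{psych_symptom}).
#'
#' Validation is strict: duplicate sample or feature identifiers, non-finite
#' cells, and (for un-normalized taxon tables) negative or non-integer counts
#' are all hard errors. Missing values are rejected at ingestion rather than
#' imputed, since rank correlations computed on silently imputed data cannot
#' be audited.
#'
#' @param values numeric matrix, samples in rows, features in columns, both
#'   dimensions named.
#' @param layer a single layer tag recycled over features, or one tag per
#'   feature. One of \code{"host_gene"}, \code{"taxon"}, \code{"gi_symptom"},
#'   \code{"psych_symptom"}.
#' @param group optional per-sample label, \code{"patient"} or
#'   \code{"control"}, named by sample id or in sample order.
#' @param normalized logical; set by \code{\link{normalize_counts}} so that
#'   taxon tables carrying continuous normalized abundances skip the
#'   integer-count check.
#' @return an object of class \code{feature_table}.
#' @export
feature_table <- function(values, layer, group = NULL, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("feature table is empty")
  sn <- rownames(values); fn <- colnames(values)
  if (is.null(sn) || is.null(fn))
    stop("`values` must have sample (row) and feature (column) names")
  if (anyDuplicated(sn))
    stop("duplicate sample ids: ", paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyDuplicated(fn))
    stop("duplicate feature ids: ", paste(unique(fn[duplicated(fn)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values present; missing cells must be resolved before ingestion")
  layer <- as.character(layer)
  if (length(layer) == 1L) layer <- rep(layer, ncol(values))
  if (length(layer) != ncol(values))
    stop("`layer` must be length 1 or one tag per feature")
  bad <- setdiff(unique(layer), c("host_gene", "taxon", "gi_symptom", "psych_symptom"))
  if (length(bad)) stop("unknown layer tag(s): ", paste(bad, collapse = ", "))
  names(layer) <- fn
  if (!is.null(group)) {
    group <- as.character(group)
    if (is.null(names(group))) {
      if (length(group) != nrow(values)) stop("`group` length must match samples")
      names(group) <- sn
    }
    if (!all(sn %in% names(group))) stop("`group` is missing labels for some samples")
    group <- group[sn]
    badg <- setdiff(unique(group), c("patient", "control"))
    if (length(badg)) stop("group labels must be 'patient' or 'control', got: ",
                           paste(badg, collapse = ", "))
  }
  if (!normalized && any(layer == "taxon")) {
    tx <- values[, layer == "taxon", drop = FALSE]
    if (any(tx < 0)) stop("taxon counts must be non-negative")
    if (any(abs(tx - round(tx)) > 1e-8))
      stop("taxon counts must be integers before normalization")
  }
  structure(list(values = values, layer = layer, group = group,
                 normalized = normalized),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$layer), collapse = "+"),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

sample_ids <- function(tab) rownames(tab$values)
feature_ids <- function(tab) colnames(tab$values)

# Subset a feature table by sample ids and/or feature ids, preserving tags.
subset_table <- function(tab, samples = NULL, features = NULL) {
  v <- tab$values
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(v))
    if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(v))
    if (length(miss)) stop("unknown feature ids: ", paste(miss, collapse = ", "))
    v <- v[, features, drop = FALSE]
  }
  feature_table(v, tab$layer[colnames(v)],
                group = if (!is.null(tab$group)) tab$group[rownames(v)] else NULL,
                normalized = tab$normalized)
}

# Column-bind feature tables sharing the same samples (used to assemble the
# mucosal host-gene + phylum table for the integrative networks).
bind_tables <- function(...) {
  tabs <- list(...)
  sn <- sample_ids(tabs[[1]])
  for (t in tabs[-1])
    if (!identical(sample_ids(t), sn)) stop("tables must share an identical sample order")
  v <- do.call(cbind, lapply(tabs, function(t) t$values))
  layer <- do.call(c, lapply(tabs, function(t) t$layer))
  feature_table(v, layer, group = tabs[[1]]$group, normalized = TRUE)
}

#' Read a feature table from delimited text
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers (the layout written by \code{\link{write_feature_table}}).
#'
#' @param path path to a TSV/CSV file.
#' @param layer layer tag applied to every feature in the file.
#' @param sep field separator, tab by default.
#' @inheritParams feature_table
#' @return a validated \code{\link{feature_table}}.
#' @export
read_feature_table <- function(path, layer, sep = "\t", group = NULL,
                               normalized = FALSE) {
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty feature table: ", path)
  sn <- raw[[1]]
  fn <- colnames(raw)[-1]
  if (anyDuplicated(fn))
    stop("duplicate feature ids in header: ",
         paste(unique(fn[duplicated(fn)]), collapse = ", "))
  if (anyDuplicated(sn))
    stop("duplicate sample ids in first column: ",
         paste(unique(sn[duplicated(sn)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), length(fn), dimnames = list(sn, fn))
  for (j in seq_along(fn)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1]
      stop(sprintf("non-numeric cell at sample '%s', feature '%s': '%s'",
                   sn[i], fn[j], col[i]))
    }
    m[, j] <- num
  }
  feature_table(m, layer, group = group, normalized = normalized)
}

#' Write a feature table as delimited text
#'
#' Values are written with 17 significant digits so that
#' \code{read_feature_table(write_feature_table(x))} round-trips
#' bit-identically.
#'
#' @param tab a \code{\link{feature_table}}.
#' @param path output path.
#' @param sep field separator.
#' @export
write_feature_table <- function(tab, path, sep = "\t") {
  v <- tab$values
  cells <- matrix(sprintf("%.17g", v), nrow(v), dimnames = dimnames(v))
  df <- data.frame(sample_id = rownames(v), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
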