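#' qPCR expression from cycle thresholds
#'
#' Expression of a target gene relative to the average of the housekeeping
#' reference genes, on the 2^dCt scale: with Ct measured in cycles,
#' \deqn{2^{\Delta Ct} = 2^{\,\mathrm{mean}(Ct_{ref}) - \mathrm{mean}(Ct_{target})}}
#' i.e. \eqn{2^{-(Target-Reference)}}. The target is measured in triplicate
#' and the triplicates averaged; several reference genes are averaged on the
#' Ct scale (where dCt is defined) before exponentiation.
#'
#' @param target numeric vector of target-gene Ct values (the triplicate).
#' @param reference numeric vector of reference-gene Ct values (>= 1 gene).
#' @return positive scalar, the 2^dCt expression value.
#' @examples
#' delta_ct_expression(c(20.1, 20.0, 19.9), 18.0)  # 2^(18 - 20) = 0.25
#' @export
delta_ct_expression <- function(target, reference) {
  if (length(target) == 0L) stop("empty target Ct triplicate")
  if (length(reference) == 0L) stop("no reference Ct values")
  if (any(!is.finite(target)) || any(!is.finite(reference)) ||
      any(target <= 0) || any(reference <= 0))
    stop("Ct values must be finite and positive")
  2^(mean(reference) - mean(target))
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed by the median-of-ratios
#' method on the genus/OTU count table: each feature with a strictly
#' positive count in every sample contributes the ratio of the sample's
#' count to the feature's across-sample geometric mean, and a sample's size
#' factor is the median of its ratios. This is the construction used for
#' count normalization in differential-abundance tooling; here it feeds the
#' rank-correlation networks.
#'
#' @param counts a \code{feature_table} of integer taxon counts, or a bare
#'   samples x features count matrix.
#' @return named numeric vector of positive per-sample factors, with the set
#'   of reference features used in attribute \code{"reference_features"}.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "feature_table")) counts$values else counts
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("counts must be non-negative integers")
  all_pos <- colSums(m > 0) == nrow(m)
  if (!any(all_pos))
    stop("no feature has nonzero counts in every sample; median-of-ratios is ",
         "undefined (pseudo-reference fallback is disabled by default)")
  loggeo <- colMeans(log(m[, all_pos, drop = FALSE]))
  logratios <- sweep(log(m[, all_pos, drop = FALSE]), 2, loggeo)
  sf <- exp(apply(logratios, 1, stats::median))
  stepnet_log("size factors: %d/%d reference features, range [%.3g, %.3g]",
              sum(all_pos), ncol(m), min(sf), max(sf))
  attr(sf, "reference_features") <- colnames(m)[all_pos]
  sf
}

#' Normalize a count table by size factors
#'
#' Divides each sample's counts by its size factor. Normalized abundances are
#' left continuous (not re-rounded): the downstream statistic is rank-based,
#' so only the ordering within each feature matters.
#'
#' @param counts taxon-layer \code{feature_table} of integer counts.
#' @param sf size factors from \code{\link{size_factors_median_of_ratios}};
#'   computed from \code{counts} when omitted.
#' @return a normalized taxon \code{feature_table}.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  stopifnot(inherits(counts, "feature_table"))
  if (is.null(sf)) sf <- size_factors_median_of_ratios(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  v <- sweep(counts$values, 1, sf[rownames(counts$values)], "/")
  stepnet_log("normalize_counts: median-of-ratios applied to %d features", ncol(v))
  feature_table(v, counts$layer, group = counts$group, normalized = TRUE)
}

#' Remove features never observed
#'
#' Taxa that were screened for but produced no hits in any sample carry no
#' information and are removed before network analysis; removals are logged.
#'
#' @param tab a \code{feature_table}.
#' @return the table without all-zero features.
#' @export
drop_zero_hit_features <- function(tab) {
  stopifnot(inherits(tab, "feature_table"))
  zero <- colSums(tab$values != 0) == 0L
  if (!any(zero)) return(tab)
  if (all(zero)) stop("all features are zero")
  stepnet_log("drop_zero_hit_features: removing %d all-zero feature(s): %s",
              sum(zero), paste(colnames(tab$values)[zero], collapse = ", "))
  subset_table(tab, features = colnames(tab$values)[!zero])
}

#' Aggregate taxon abundances to a coarser rank
#'
#' The summarizing step of the pipeline: genus-level abundances are summed
#' into their phyla (phylogenetic relatedness as the grouping criterion),
#' reducing the taxon layer to a handful of summary variables for the
#' overview networks. Per-sample totals are conserved exactly.
#'
#' @param tab taxon-layer \code{feature_table} (counts or normalized).
#' @param taxmap \code{\link{taxonomy_map}} covering every feature.
#' @param rank \code{"phylum"} or \code{"genus"}.
#' @return a taxon \code{feature_table} whose features are rank names.
#' @export
aggregate_to_rank <- function(tab, taxmap, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(tab, "feature_table"), inherits(taxmap, "taxonomy_map"))
  ids <- feature_ids(tab)
  miss <- setdiff(ids, taxmap$taxon_id)
  if (length(miss))
    stop("features without taxonomy mapping: ", paste(utils::head(miss, 5), collapse = ", "))
  grp <- taxmap[[rank]][match(ids, taxmap$taxon_id)]
  levels <- unique(grp)
  out <- matrix(0, nrow(tab$values), length(levels),
                dimnames = list(rownames(tab$values), levels))
  for (g in levels)
    out[, g] <- rowSums(tab$values[, grp == g, drop = FALSE])
  stepnet_log("aggregate_to_rank: %d features -> %d %s-level features",
              length(ids), length(levels), rank)
  feature_table(out, "taxon", group = tab$group, normalized = tab$normalized)
}
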