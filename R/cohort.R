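#' Cohort datasets
#'
#' A cohort dataset bundles the four measurement tables (host-gene
#' expression, genus-level taxon counts, GI symptom scores, psychological
#' symptom scores), the taxonomy map, and the per-sample group labels.
#' The mucosal tables (expression, taxa) must cover the same samples;
#' symptom tables may be patient-only, mirroring study designs where healthy
#' controls are enrolled symptom-free.
#'
#' @param expression \code{feature_table} with layer \code{host_gene}.
#' @param taxa_genus \code{feature_table} with layer \code{taxon}
#'   (integer counts).
#' @param taxonomy \code{\link{taxonomy_map}} covering every taxon feature.
#' @param groups named character vector, sample id -> "patient"/"control".
#' @param gi_symptoms,psych_symptoms optional symptom
#'   \code{feature_table}s (layers \code{gi_symptom} / \code{psych_symptom}).
#' @return object of class \code{cohort_dataset}.
#' @export
cohort_dataset <- function(expression, taxa_genus, taxonomy, groups,
                           gi_symptoms = NULL, psych_symptoms = NULL) {
  stopifnot(inherits(expression, "feature_table"),
            inherits(taxa_genus, "feature_table"),
            inherits(taxonomy, "taxonomy_map"))
  miss <- setdiff(feature_ids(taxa_genus), taxonomy$taxon_id)
  if (length(miss))
    stop("taxa without taxonomy entries: ", paste(utils::head(miss, 5), collapse = ", "))
  if (!identical(sort(sample_ids(expression)), sort(sample_ids(taxa_genus))))
    stop("expression and taxon tables must cover the same samples; use align_cohort()")
  sn <- sample_ids(expression)
  if (!all(sn %in% names(groups))) stop("`groups` is missing labels for some samples")
  groups <- groups[sn]
  badg <- setdiff(unique(groups), c("patient", "control"))
  if (length(badg)) stop("group labels must be patient/control")
  for (st in list(gi_symptoms, psych_symptoms)) {
    if (!is.null(st) && length(setdiff(sample_ids(st), sn)))
      stop("symptom table contains samples absent from the mucosal tables")
  }
  structure(list(expression = expression, taxa_genus = taxa_genus,
                 taxonomy = taxonomy, gi_symptoms = gi_symptoms,
                 psych_symptoms = psych_symptoms, groups = groups),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "cohort_dataset: %d samples (%d patients / %d controls), %d genes, %d taxa\n",
    length(x$groups), sum(x$groups == "patient"), sum(x$groups == "control"),
    ncol(x$expression$values), ncol(x$taxa_genus$values)))
  invisible(x)
}

#' Align tables into a cohort by sample intersection
#'
#' The mucosal tables are restricted to their common sample set (dropped
#' samples are logged); symptom tables are restricted to whatever subset of
#' that sample set they cover, so patient-only questionnaires survive
#' alignment. Samples with partial data are dropped, never imputed.
#'
#' @inheritParams cohort_dataset
#' @return a \code{\link{cohort_dataset}}.
#' @export
align_cohort <- function(expression, taxa_genus, taxonomy, groups,
                         gi_symptoms = NULL, psych_symptoms = NULL) {
  common <- intersect(sample_ids(expression), sample_ids(taxa_genus))
  common <- intersect(common, names(groups))
  if (length(common) == 0L) stop("no samples shared across tables")
  drop_report <- function(tab, nm) {
    dropped <- setdiff(sample_ids(tab), common)
    if (length(dropped))
      stepnet_log("align_cohort: dropping %d sample(s) from %s: %s",
                  length(dropped), nm, paste(dropped, collapse = ", "))
  }
  drop_report(expression, "expression"); drop_report(taxa_genus, "taxa")
  keep_order <- sample_ids(expression)[sample_ids(expression) %in% common]
  expression <- subset_table(expression, samples = keep_order)
  taxa_genus <- subset_table(taxa_genus, samples = keep_order)
  clip <- function(tab, nm) {
    if (is.null(tab)) return(NULL)
    keep <- sample_ids(tab)[sample_ids(tab) %in% keep_order]
    dropped <- setdiff(sample_ids(tab), keep)
    if (length(dropped))
      stepnet_log("align_cohort: dropping %d sample(s) from %s: %s",
                  length(dropped), nm, paste(dropped, collapse = ", "))
    if (length(keep) == 0L) return(NULL)
    subset_table(tab, samples = keep)
  }
  cohort_dataset(expression, taxa_genus, taxonomy, groups,
                 gi_symptoms = clip(gi_symptoms, "gi_symptoms"),
                 psych_symptoms = clip(psych_symptoms, "psych_symptoms"))
}

# Drop samples from every member table of a cohort (outlier removal).
drop_samples <- function(dataset, samples) {
  if (length(samples) == 0L) return(dataset)
  keep <- setdiff(sample_ids(dataset$expression), samples)
  by_group <- table(dataset$groups[keep])
  if (any(!c("patient", "control") %in% names(by_group)) || any(by_group == 0))
    stop("removal would empty a group")
  clip <- function(tab) {
    if (is.null(tab)) return(NULL)
    k <- intersect(sample_ids(tab), keep)
    if (length(k) == 0L) return(NULL)
    subset_table(tab, samples = k)
  }
  cohort_dataset(subset_table(dataset$expression, samples = keep),
                 subset_table(dataset$taxa_genus, samples = keep),
                 dataset$taxonomy, dataset$groups[keep],
                 gi_symptoms = clip(dataset$gi_symptoms),
                 psych_symptoms = clip(dataset$psych_symptoms))
}
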