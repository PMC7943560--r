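#' Pipeline configuration
#'
#' Parameters of the stepwise integrative analysis. Defaults follow the
#' method's stated conventions: uncorrected alpha = 0.05; strength-density
#' threshold |rho| > 0.3; outlier rule "more than 10 score units outside the
#' 95\% confidence ellipse"; clusters of at least 3 nodes detected at
#' tau = 0.3; taxa attach to a cluster with >= 2 corroborating significant
#' edges; phyla with fewer than 3 genera are not de-summarized.
#'
#' @param alpha significance level in (0, 1).
#' @param strength_threshold |rho| threshold for the strength density.
#' @param outlier_margin score-unit margin of the outlier rule.
#' @param outlier_ci confidence level of the outlier ellipse.
#' @param cluster_min_size minimum cluster size.
#' @param cluster_tau |rho| threshold of the cluster-detection subgraph.
#' @param association_k minimum significant edges attaching a taxon to a
#'   cluster.
#' @param desummarize_min_genera minimum member genera for de-summarizing a
#'   phylum.
#' @param adjust p-value adjustment; \code{"none"} by default (the method's
#'   explicit choice), \code{"BH"} available.
#' @param seed integer seed fixed for the run.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(alpha = 0.05, strength_threshold = 0.3,
                            outlier_margin = 10, outlier_ci = 0.95,
                            cluster_min_size = 3L, cluster_tau = 0.3,
                            association_k = 2L, desummarize_min_genera = 3L,
                            adjust = "none", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, strength_threshold >= 0, outlier_margin >= 0,
            outlier_ci > 0, outlier_ci < 1, cluster_min_size >= 1,
            cluster_tau >= 0, association_k >= 1, desummarize_min_genera >= 1)
  structure(list(alpha = alpha, strength_threshold = strength_threshold,
                 outlier_margin = outlier_margin, outlier_ci = outlier_ci,
                 cluster_min_size = as.integer(cluster_min_size),
                 cluster_tau = cluster_tau,
                 association_k = as.integer(association_k),
                 desummarize_min_genera = as.integer(desummarize_min_genera),
                 adjust = adjust, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  fnv1a(paste(names(config), vapply(config, format, ""), collapse = ";"))
}

# -- step 1 -------------------------------------------------------------------

#' Step 1: data preparation and quality control
#'
#' Normalizes the genus counts (median-of-ratios), aggregates the normalized
#' abundances to phylum level, removes zero-hit features at both ranks, and
#' screens each group separately for strong multivariate outliers on the
#' combined host-gene + phylum table; flagged samples are removed everywhere.
#'
#' @param dataset a \code{\link{cohort_dataset}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with per-group entries (\code{patient}, \code{control}), each
#'   holding \code{expression}, \code{taxa_phylum}, \code{taxa_genus}
#'   (normalized), \code{gi_symptoms}, \code{psych_symptoms}, and
#'   \code{mucosal} (genes + phyla bound); plus \code{size_factors},
#'   \code{removed} (data.frame of removals) and \code{dataset} (the reduced
#'   cohort).
#' @export
run_step1_prepare <- function(dataset, config = pipeline_config()) {
  sf <- size_factors_median_of_ratios(dataset$taxa_genus)
  genus_norm <- normalize_counts(dataset$taxa_genus, sf)
  genus_norm <- drop_zero_hit_features(genus_norm)
  phylum <- aggregate_to_rank(genus_norm, dataset$taxonomy, "phylum")
  phylum <- drop_zero_hit_features(phylum)
  removed <- data.frame(sample_id = character(0), group = character(0),
                        exceedance = numeric(0), stringsAsFactors = FALSE)
  reports <- list()
  for (g in c("patient", "control")) {
    sg <- names(dataset$groups)[dataset$groups == g]
    if (length(sg) < 5L) next
    comb <- cbind(dataset$expression$values[sg, , drop = FALSE],
                  phylum$values[sg, , drop = FALSE])
    rep <- flag_strong_outliers(pca_scores(comb), ci = config$outlier_ci,
                                margin = config$outlier_margin)
    reports[[g]] <- rep
    if (nrow(rep$flagged))
      removed <- rbind(removed, data.frame(sample_id = rep$flagged$sample_id,
                                           group = g,
                                           exceedance = rep$flagged$exceedance,
                                           stringsAsFactors = FALSE))
  }
  ds <- if (nrow(removed)) do.call(remove_outliers, c(list(dataset), reports))
        else dataset
  keep <- sample_ids(ds$expression)
  genus_norm <- subset_table(genus_norm, samples = keep)
  phylum <- subset_table(phylum, samples = keep)
  per_group <- function(g) {
    sg <- keep[ds$groups[keep] == g]
    clip <- function(tab) {
      if (is.null(tab)) return(NULL)
      k <- intersect(sample_ids(tab), sg)
      if (length(k) == 0L) return(NULL)
      subset_table(tab, samples = k)
    }
    expr <- subset_table(ds$expression, samples = sg)
    phy <- subset_table(phylum, samples = sg)
    list(expression = expr, taxa_phylum = phy,
         taxa_genus = subset_table(genus_norm, samples = sg),
         gi_symptoms = clip(ds$gi_symptoms),
         psych_symptoms = clip(ds$psych_symptoms),
         mucosal = bind_tables(expr, phy))
  }
  list(patient = per_group("patient"), control = per_group("control"),
       size_factors = sf, removed = removed, reports = reports, dataset = ds)
}

# -- step 2 -------------------------------------------------------------------

#' Step 2: integrative networks at phylum level
#'
#' Concatenates host-gene expression and phylum abundances into one table per
#' group and builds both network views: the overview network (all pairs, the
#' layout-only picture of relative correlation strength) and the
#' significance-filtered network.
#'
#' @param prepared output of \code{\link{run_step1_prepare}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with per-group \code{overview} and \code{significant}
#'   networks.
#' @export
run_step2_phylum_networks <- function(prepared, config = pipeline_config()) {
  out <- list()
  for (g in c("patient", "control")) {
    nets <- correlation_networks(prepared[[g]]$mucosal, alpha = config$alpha,
                                 adjust = config$adjust)
    out[[g]] <- nets
  }
  out
}

# -- step 3 -------------------------------------------------------------------

#' Step 3: compare network characteristics between groups
#'
#' Tabulates both density statistics per group, intersects the significant
#' edge sets by (node pair, correlation sign), and matches clusters across
#' groups by Jaccard similarity of their member sets (threshold 0.5).
#' Clusters without a match in the other group are flagged patient- or
#' control-specific.
#'
#' @param net_patient,net_control significance-mode \code{corr_network}s over
#'   an identical node roster.
#' @param clusters_patient,clusters_control \code{cluster_set}s from
#'   \code{\link{detect_clusters}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{group_comparison}.
#' @export
run_step3_compare <- function(net_patient, net_control, clusters_patient,
                              clusters_control, config = pipeline_config()) {
  if (!identical(net_patient$nodes$id, net_control$nodes$id))
    stop("node rosters differ between groups")
  dens <- data.frame(
    group = c("patient", "control"),
    density_strength = c(density_strength(net_patient, config$strength_threshold),
                         density_strength(net_control, config$strength_threshold)),
    density_significant = c(density_significant(net_patient, config$alpha),
                            density_significant(net_control, config$alpha)),
    stringsAsFactors = FALSE)
  ekey <- function(net) {
    e <- net$edges[net$edges$significant, , drop = FALSE]
    sprintf("%s|%s|%s", e$from, e$to, ifelse(e$rho >= 0, "+", "-"))
  }
  kp <- ekey(net_patient); kc <- ekey(net_control)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  match_clusters <- function(A, B) {
    out <- list()
    for (ca in A$clusters) {
      best <- 0; bestb <- NULL
      for (cb in B$clusters) {
        j <- jaccard(ca$members, cb$members)
        if (j > best) { best <- j; bestb <- cb }
      }
      out[[ca$label]] <- list(cluster = ca, jaccard = best,
                              matched = best >= 0.5,
                              counterpart = if (best >= 0.5) bestb else NULL)
    }
    out
  }
  mp <- match_clusters(clusters_patient, clusters_control)
  mc <- match_clusters(clusters_control, clusters_patient)
  structure(list(
    densities = dens,
    shared_edges = intersect(kp, kc),
    unique_patient_edges = setdiff(kp, kc),
    unique_control_edges = setdiff(kc, kp),
    cluster_matches_patient = mp,
    cluster_matches_control = mc,
    patient_specific_clusters =
      lapply(Filter(function(m) !m$matched, mp), `[[`, "cluster"),
    control_specific_clusters =
      lapply(Filter(function(m) !m$matched, mc), `[[`, "cluster")),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison\n")
  print(x$densities, row.names = FALSE)
  cat(sprintf("shared significant edges: %d; patient-only: %d; control-only: %d\n",
              length(x$shared_edges), length(x$unique_patient_edges),
              length(x$unique_control_edges)))
  cat(sprintf("patient-specific clusters: %d; control-specific: %d\n",
              length(x$patient_specific_clusters),
              length(x$control_specific_clusters)))
  invisible(x)
}

# -- step 4 -------------------------------------------------------------------

#' Step 4: symptom layers and multilayer models
#'
#' Builds the GI-symptom and psychological-symptom within-layer networks for
#' the patient group, computes significant between-layer correlations
#' (mucosal-GI, mucosal-psych, GI-psych), and assembles the dual-layer
#' (mucosal + GI) and triangle (all three layers) models. With no
#' psychological table, only the dual-layer model is returned, with a
#' warning.
#'
#' @param prep_patient the \code{patient} element of
#'   \code{\link{run_step1_prepare}} output.
#' @param net_patient the patient significance-mode mucosal network from
#'   step 2.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{gi_net}, \code{psych_net} (or NULL),
#'   \code{between} (named list of between-edge tables), \code{dual},
#'   \code{triangle} (or NULL).
#' @export
run_step4_symptoms <- function(prep_patient, net_patient,
                               config = pipeline_config()) {
  gi <- prep_patient$gi_symptoms
  if (is.null(gi)) stop("step 4 requires a GI symptom table")
  psych <- prep_patient$psych_symptoms
  if (is.null(psych))
    warning("no psychological symptom table; building the dual-layer model only")
  muc <- prep_patient$mucosal
  common <- intersect(sample_ids(muc), sample_ids(gi))
  muc_c <- subset_table(muc, samples = common)
  gi_c <- subset_table(gi, samples = common)
  gi_nets <- correlation_networks(gi_c, alpha = config$alpha,
                                  adjust = config$adjust)
  between <- list("mucosal|gi" = between_layer_edges(muc_c, gi_c, config$alpha))
  psych_net <- NULL
  if (!is.null(psych)) {
    psych_c <- subset_table(psych, samples = common)
    psych_nets <- correlation_networks(psych_c, alpha = config$alpha,
                                       adjust = config$adjust)
    psych_net <- psych_nets$significant
    between[["mucosal|psych"]] <- between_layer_edges(muc_c, psych_c, config$alpha)
    between[["gi|psych"]] <- between_layer_edges(gi_c, psych_c, config$alpha)
  }
  dual <- compose_multilayer(net_patient, gi_nets$significant,
                             between = between["mucosal|gi"],
                             seed = child_seed(config$seed, 4))
  triangle <- if (!is.null(psych_net))
    compose_multilayer(net_patient, gi_nets$significant, psych_net,
                       between = between, seed = child_seed(config$seed, 5))
  list(gi_net = gi_nets$significant, psych_net = psych_net,
       between = between, dual = dual, triangle = triangle)
}

# -- step 5 -------------------------------------------------------------------

#' Step 5: select the most relevant variables
#'
#' Selects (a) members of patient-specific clusters, (b) taxa attached to
#' those clusters by at least \code{association_k} significant edges, and
#' (c) variables carrying at least one significant between-layer symptom
#' edge. Every selected variable carries its reason tag(s); selected
#' phylum-level taxa are queued for de-summarization.
#'
#' @param comparison a \code{group_comparison} from step 3.
#' @param symptoms step-4 output.
#' @param net_patient patient significance-mode mucosal network.
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{selection_result}: \code{selected}
#'   (data.frame variable, reasons), \code{phyla} (data.frame phylum,
#'   symptom_only) queued for de-summarization, and the per-cluster
#'   association tables in \code{associations}.
#' @export
run_step5_select <- function(comparison, symptoms, net_patient,
                             config = pipeline_config()) {
  reasons <- list()
  add <- function(vars, tag) {
    for (v in vars) reasons[[v]] <<- union(reasons[[v]], tag)
  }
  assoc <- list()
  for (cl in comparison$patient_specific_clusters) {
    add(cl$members, "patient_specific_cluster")
    a <- cluster_layer_associations(cl, net_patient, "taxon",
                                    k = config$association_k)
    assoc[[cl$label]] <- a
    add(a$node, "cluster_associated_taxon")
  }
  mucosal_nodes <- net_patient$nodes$id
  for (nm in c("mucosal|gi", "mucosal|psych")) {
    be <- symptoms$between[[nm]]
    if (!is.null(be) && nrow(be)) add(unique(be$a), "symptom_correlated")
  }
  sel <- data.frame(variable = names(reasons),
                    reasons = vapply(reasons, paste, "", collapse = "+"),
                    stringsAsFactors = FALSE)
  rownames(sel) <- NULL
  lay <- stats::setNames(net_patient$nodes$layer, net_patient$nodes$id)
  taxsel <- sel$variable[!is.na(lay[sel$variable]) & lay[sel$variable] == "taxon"]
  phyla <- data.frame(phylum = taxsel,
                      symptom_only = vapply(taxsel, function(v)
                        identical(reasons[[v]], "symptom_correlated"), TRUE),
                      stringsAsFactors = FALSE)
  rownames(phyla) <- NULL
  structure(list(selected = sel, phyla = phyla, associations = assoc),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d variable(s), %d phylum/a queued\n",
              nrow(x$selected), nrow(x$phyla)))
  if (nrow(x$selected)) print(x$selected, row.names = FALSE)
  invisible(x)
}

# -- steps 6-7 ----------------------------------------------------------------

#' Steps 6-7: de-summarize selected phyla and re-analyze at genus level
#'
#' Each queued phylum is split back into its member genera. Phyla with fewer
#' than \code{desummarize_min_genera} members are skipped
#' (\code{too_few_genera}); phyla whose association no longer reaches
#' significance on re-evaluation are skipped
#' (\code{no_significant_association}). For a cluster-associated phylum the
#' genus-level significance network spans the patient-specific cluster's
#' host genes plus the member genera; for a symptom-only phylum it spans the
#' symptom variables plus the member genera.
#'
#' @param selection a \code{selection_result} from step 5.
#' @param prep_patient the \code{patient} element of step-1 output.
#' @param taxonomy the cohort's \code{\link{taxonomy_map}}.
#' @param comparison the step-3 \code{group_comparison} (for cluster genes).
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{networks} (named per phylum, each a
#'   significance-mode \code{corr_network}) and \code{skipped} (data.frame
#'   phylum, reason).
#' @export
run_step6_7_desummarize <- function(selection, prep_patient, taxonomy,
                                    comparison, config = pipeline_config()) {
  skipped <- data.frame(phylum = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  networks <- list()
  cluster_genes <- unique(unlist(lapply(comparison$patient_specific_clusters,
                                        `[[`, "members")))
  genus_tab <- prep_patient$taxa_genus
  lay <- NULL
  if (nrow(selection$phyla)) for (r in seq_len(nrow(selection$phyla))) {
    ph <- selection$phyla$phylum[r]
    sym_only <- selection$phyla$symptom_only[r]
    members <- intersect(members_of(taxonomy, ph), feature_ids(genus_tab))
    if (length(members) < config$desummarize_min_genera) {
      stepnet_log("de-summarization: skipping %s (%d genus/era < %d)",
                  ph, length(members), config$desummarize_min_genera)
      skipped <- rbind(skipped, data.frame(phylum = ph,
                                           reason = "too_few_genera",
                                           stringsAsFactors = FALSE))
      next
    }
    genera_sub <- subset_table(genus_tab, features = members)
    if (sym_only) {
      parts <- Filter(Negate(is.null),
                      list(prep_patient$gi_symptoms, prep_patient$psych_symptoms))
      common <- Reduce(intersect, c(list(sample_ids(genera_sub)),
                                    lapply(parts, sample_ids)))
      tab <- do.call(bind_tables, c(list(subset_table(genera_sub, samples = common)),
                                    lapply(parts, subset_table, samples = common)))
    } else {
      genes_tab <- subset_table(prep_patient$expression,
                                features = intersect(cluster_genes,
                                                     feature_ids(prep_patient$expression)))
      tab <- bind_tables(genes_tab, genera_sub)
    }
    net <- correlation_networks(tab, alpha = config$alpha,
                                adjust = config$adjust)$significant
    # re-evaluation: does any member genus still connect significantly to the
    # non-taxon part of the plot?
    lay <- stats::setNames(net$nodes$layer, net$nodes$id)
    e <- net$edges
    crosses <- e[xor(lay[e$from] == "taxon" & e$from %in% members,
                     lay[e$to] == "taxon" & e$to %in% members), , drop = FALSE]
    if (nrow(crosses) == 0L) {
      stepnet_log("de-summarization: %s retains no significant association", ph)
      skipped <- rbind(skipped, data.frame(phylum = ph,
                                           reason = "no_significant_association",
                                           stringsAsFactors = FALSE))
      next
    }
    networks[[ph]] <- net
  }
  list(networks = networks, skipped = skipped)
}

# -- full run -----------------------------------------------------------------

#' Run the complete stepwise integrative analysis
#'
#' Executes steps 1-7 in order on a cohort dataset: preparation and QC,
#' phylum-level networks per group, group comparison, symptom layers,
#' variable selection, and genus-level de-summarization. The report records
#' every step together with the configuration, its hash and the seed;
#' re-running with identical inputs, configuration and seed reproduces the
#' report bit for bit.
#'
#' @param dataset a \code{\link{cohort_dataset}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, \code{report.json}, edge
#'   TSVs and GraphML files for every network are written there.
#' @return object of class \code{run_report}.
#' @export
run_all <- function(dataset, config = pipeline_config(), out_dir = NULL) {
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline failed at %s: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }
  prepared <- step("step1_prepare", run_step1_prepare(dataset, config))
  nets <- step("step2_phylum_networks", run_step2_phylum_networks(prepared, config))
  cl_p <- detect_clusters(nets$patient$significant, config$cluster_min_size,
                          config$cluster_tau, seed = child_seed(config$seed, 2))
  cl_c <- detect_clusters(nets$control$significant, config$cluster_min_size,
                          config$cluster_tau, seed = child_seed(config$seed, 3))
  comparison <- step("step3_compare",
                     run_step3_compare(nets$patient$significant,
                                       nets$control$significant,
                                       cl_p, cl_c, config))
  symptoms <- if (!is.null(prepared$patient$gi_symptoms))
    step("step4_symptoms",
         run_step4_symptoms(prepared$patient, nets$patient$significant, config))
  else NULL
  selection <- step("step5_select",
                    run_step5_select(comparison,
                                     symptoms %||% list(between = list()),
                                     nets$patient$significant, config))
  desum <- step("step6_7_desummarize",
                run_step6_7_desummarize(selection, prepared$patient,
                                        dataset$taxonomy, comparison, config))
  steps <- list(
    list(step = 1L, name = "prepare",
         removed = prepared$removed,
         n_patient = nrow(prepared$patient$mucosal$values),
         n_control = nrow(prepared$control$mucosal$values)),
    list(step = 2L, name = "phylum_networks",
         n_nodes = nrow(nets$patient$overview$nodes),
         overview_edges = nrow(nets$patient$overview$edges),
         significant_edges_patient = nrow(nets$patient$significant$edges),
         significant_edges_control = nrow(nets$control$significant$edges)),
    list(step = 3L, name = "compare", densities = comparison$densities,
         patient_specific_clusters =
           lapply(comparison$patient_specific_clusters, `[[`, "members"),
         control_specific_clusters =
           lapply(comparison$control_specific_clusters, `[[`, "members")),
    list(step = 4L, name = "symptoms",
         between_edge_counts = if (is.null(symptoms)) list() else
           lapply(symptoms$between, nrow)),
    list(step = 5L, name = "select", selected = selection$selected,
         phyla = selection$phyla),
    list(step = 6L, name = "desummarize_prepare",
         skipped = desum$skipped,
         desummarized = names(desum$networks)),
    list(step = 7L, name = "genus_networks",
         edges = lapply(desum$networks, function(n) nrow(n$edges))))
  report <- structure(list(steps = steps, config = unclass(config),
                           config_hash = config_hash(config),
                           seed = config$seed,
                           prepared = prepared, networks = nets,
                           clusters = list(patient = cl_p, control = cl_c),
                           comparison = comparison, symptoms = symptoms,
                           selection = selection, desummarized = desum),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: 7 steps, seed %d, config %s\n", x$seed, x$config_hash))
  print(x$comparison)
  invisible(x)
}

#' Write run artifacts
#'
#' Serializes the step records to \code{report.json} and every network to
#' edge-list TSV and GraphML under \code{out_dir}. Output is deterministic
#' for a fixed (dataset, config, seed).
#'
#' @param report a \code{run_report}.
#' @param out_dir output directory (created if needed).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(seed = report$seed, config = report$config,
             config_hash = report$config_hash, steps = report$steps)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dump_net <- function(net, name) {
    write_network(net, file.path(out_dir, paste0(name, ".edges.tsv")), "edge-tsv")
    write_network(net, file.path(out_dir, paste0(name, ".graphml")), "graphml")
  }
  for (g in c("patient", "control")) {
    dump_net(report$networks[[g]]$overview, sprintf("phylum_%s_overview", g))
    dump_net(report$networks[[g]]$significant, sprintf("phylum_%s_significant", g))
  }
  if (!is.null(report$symptoms)) {
    dump_net(report$symptoms$gi_net, "gi_symptoms")
    if (!is.null(report$symptoms$psych_net))
      dump_net(report$symptoms$psych_net, "psych_symptoms")
  }
  for (ph in names(report$desummarized$networks))
    dump_net(report$desummarized$networks[[ph]], sprintf("genus_%s", ph))
  invisible(out_dir)
}
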