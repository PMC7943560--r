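#' Detect intercorrelation clusters
#'
#' Formalizes the visual identification of clusters of close
#' intercorrelation: communities are found by seeded modularity maximization
#' (Louvain) on the subgraph of statistically significant edges with
#' \eqn{|\rho| \ge \tau}, using \eqn{|\rho|} as edge weight, and communities
#' smaller than \code{min_size} are discarded. An algorithmic criterion
#' replaces by-eye judgement so that cluster calls are reproducible.
#'
#' @param net a significance-filtered \code{corr_network} (overview networks
#'   are accepted; only their significant edges are used).
#' @param min_size smallest reported cluster, default 3.
#' @param tau strength threshold on \eqn{|\rho|} for the detection subgraph,
#'   default 0.3 (the strength-density threshold).
#' @param seed RNG seed for the community search.
#' @return object of class \code{cluster_set}: list of clusters, each with
#'   \code{members}, \code{mean_abs_rho} (mean \eqn{|\rho|} over within-
#'   cluster detection edges) and a \code{label}.
#' @export
detect_clusters <- function(net, min_size = 3L, tau = 0.3, seed = 1L) {
  e <- net$edges
  e <- e[e$significant & abs(e$rho) >= tau, , drop = FALSE]
  empty <- structure(list(clusters = list(), min_size = min_size, tau = tau),
                     class = "cluster_set")
  if (nrow(e) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(e[, c("from", "to", "rho")],
                                     directed = FALSE)
  igraph::E(g)$weight <- abs(e$rho)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  groups <- igraph::communities(cl)
  keep <- groups[vapply(groups, length, 1L) >= min_size]
  if (length(keep) == 0L) return(empty)
  # deterministic ordering: by size desc then first member
  ord <- order(-vapply(keep, length, 1L),
               vapply(keep, function(m) sort(m)[1], ""))
  keep <- keep[ord]
  clusters <- lapply(seq_along(keep), function(i) {
    m <- sort(keep[[i]])
    within <- e$from %in% m & e$to %in% m
    list(members = m,
         mean_abs_rho = mean(abs(e$rho[within])),
         label = sprintf("cluster_%d", i))
  })
  structure(list(clusters = clusters, min_size = min_size, tau = tau),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) (min size %d, tau %.2g)\n",
              length(x$clusters), x$min_size, x$tau))
  for (cl in x$clusters)
    cat(sprintf("  %s [mean |rho| %.2f]: %s\n", cl$label, cl$mean_abs_rho,
                paste(cl$members, collapse = ", ")))
  invisible(x)
}

#' Layer associations of a cluster
#'
#' Nodes of a target layer carrying at least \code{k} significant edges into
#' the cluster's members, each reported with its strongest connecting edge.
#' The default \code{k = 2} demands corroboration, so a single spurious edge
#' does not attach a taxon to a cluster; \code{k = 1} reproduces the loosest
#' reading.
#'
#' @param cluster a cluster from \code{\link{detect_clusters}} (or a bare
#'   character vector of member ids).
#' @param net the \code{corr_network} the cluster was detected in.
#' @param target_layer layer tag of candidate associated nodes.
#' @param k minimum number of significant edges into the cluster, default 2.
#' @return data.frame (node, n_edges, rho, p) sorted by \eqn{|\rho|}
#'   descending; rho/p are those of the strongest edge.
#' @export
cluster_layer_associations <- function(cluster, net, target_layer, k = 2L) {
  members <- if (is.list(cluster)) cluster$members else cluster
  e <- net$edges[net$edges$significant, , drop = FALSE]
  lay <- stats::setNames(net$nodes$layer, net$nodes$id)
  cand <- net$nodes$id[net$nodes$layer == target_layer]
  out <- data.frame(node = character(0), n_edges = integer(0),
                    rho = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  for (v in cand) {
    into <- (e$from == v & e$to %in% setdiff(members, v)) |
            (e$to == v & e$from %in% setdiff(members, v))
    if (sum(into) >= k) {
      sub <- e[into, , drop = FALSE]
      best <- which.max(abs(sub$rho))
      out <- rbind(out, data.frame(node = v, n_edges = sum(into),
                                   rho = sub$rho[best], p = sub$p[best],
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(-abs(out$rho)), , drop = FALSE]
}

#' Significant between-layer edges
#'
#' All cross-layer variable pairs with \eqn{p < \alpha}, computed with the
#' same midrank Spearman machinery as the within-layer networks. These are
#' the dotted edges joining the layers of a multilayer model.
#'
#' @param tableA,tableB \code{feature_table}s over the same samples
#'   (identical sets; order is reconciled automatically).
#' @param alpha significance level, default 0.05.
#' @return data.frame (a, b, rho, p) with \code{a} from \code{tableA}.
#' @export
between_layer_edges <- function(tableA, tableB, alpha = 0.05) {
  sa <- sample_ids(tableA); sb <- sample_ids(tableB)
  if (!setequal(sa, sb))
    stop("sample sets must match between layers (",
         length(setdiff(sa, sb)), " / ", length(setdiff(sb, sa)), " unmatched)")
  B <- tableB$values[sa, , drop = FALSE]
  sp <- spearman_cross(tableA$values, B)
  idx <- which(sp$p < alpha, arr.ind = TRUE)
  out <- data.frame(a = rownames(sp$rho)[idx[, 1]],
                    b = colnames(sp$rho)[idx[, 2]],
                    rho = sp$rho[idx], p = sp$p[idx], stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a multilayer model
#'
#' Joins two or three within-layer networks (mucosal = host genes + taxa;
#' GI symptoms; psychological symptoms) into one model. Each layer is laid
#' out independently with \code{\link{layout_weighted}} and anchored on the
#' canvas (two layers stacked vertically; three at triangle vertices).
#' Between-layer edges are significant cross-layer correlations only; they
#' are drawn dotted with their rho printed to 2 decimals and do not
#' participate in the force layout.
#'
#' @param mucosal,gi \code{corr_network}s for the mucosal and GI-symptom
#'   layers.
#' @param psych optional psychological-symptom \code{corr_network}; when
#'   absent a dual-layer model is built.
#' @param between named list of between-edge data.frames from
#'   \code{\link{between_layer_edges}}; names are "layerA|layerB" pairs
#'   among \code{mucosal}, \code{gi}, \code{psych}
#'   (e.g. \code{"mucosal|gi"}).
#' @param seed layout seed.
#' @return object of class \code{multilayer_model}: \code{layers} (each with
#'   the network, its coordinates and an anchor), \code{between}
#'   (data.frame layer_a, layer_b, a, b, rho, p), \code{seed}.
#' @export
compose_multilayer <- function(mucosal, gi, psych = NULL, between = list(),
                               seed = 1L) {
  nets <- list(mucosal = mucosal, gi = gi)
  if (!is.null(psych)) nets$psych <- psych
  anchors <- if (length(nets) == 2L)
    list(mucosal = c(0, 0), gi = c(0, 7)) else
    list(mucosal = c(0, 0), gi = c(8, 0), psych = c(4, 6.9))
  layers <- list()
  for (i in seq_along(nets)) {
    nm <- names(nets)[i]
    lo <- layout_weighted(nets[[nm]], seed = child_seed(seed, i))
    co <- lo$coords
    # normalize each layer into a radius-2 disc before anchoring
    if (nrow(co) > 1L) {
      co <- sweep(co, 2, colMeans(co))
      r <- max(sqrt(rowSums(co^2)))
      if (r > 0) co <- co * (2 / r)
    }
    co <- sweep(co, 2, anchors[[nm]], "+")
    layers[[nm]] <- list(net = nets[[nm]], coords = co, anchor = anchors[[nm]])
  }
  bdf <- data.frame(layer_a = character(0), layer_b = character(0),
                    a = character(0), b = character(0),
                    rho = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  for (nm in names(between)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% names(layers)))
      stop("between-edge list name must be '<layerA>|<layerB>', got: ", nm)
    be <- between[[nm]]
    if (is.null(be) || nrow(be) == 0L) next
    missA <- setdiff(be$a, layers[[pair[1]]]$net$nodes$id)
    missB <- setdiff(be$b, layers[[pair[2]]]$net$nodes$id)
    if (length(missA) || length(missB))
      stop("between-layer edge references missing node(s): ",
           paste(c(missA, missB), collapse = ", "))
    bdf <- rbind(bdf, data.frame(layer_a = pair[1], layer_b = pair[2],
                                 a = be$a, b = be$b, rho = be$rho, p = be$p,
                                 stringsAsFactors = FALSE))
  }
  structure(list(layers = layers, between = bdf, seed = seed),
            class = "multilayer_model")
}

#' @export
print.multilayer_model <- function(x, ...) {
  cat(sprintf("multilayer_model: %d layers (%s), %d between-layer edges\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$between)))
  invisible(x)
}
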