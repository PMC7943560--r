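#' Correlation networks
#'
#' A correlation network holds the full Spearman rho and p matrices, the node
#' roster (with layer tags and the numeric labels used in the plots), and an
#' edge list in one of two modes: \code{overview} keeps every variable pair
#' regardless of significance, so the force-directed layout reflects the
#' complete relative-correlation-strength structure; \code{significant}
#' retains only pairs with \eqn{p < \alpha} (strictly), the view used to
#' judge which intercorrelation patterns generalize. Significance is
#' deliberately uncorrected for multiple testing: the analysis is
#' exploratory and favors type-1 over type-2 error; a Benjamini-Hochberg
#' option exists but is off by default.
#'
#' Two density statistics summarize connectedness relative to the
#' \eqn{\binom{V}{2}} possible edges: \code{density_strength}, the fraction
#' of pairs with \eqn{|\rho|} above a strength threshold (0.3 by default),
#' and \code{density_significant}, the fraction with \eqn{p < \alpha}. Both
#' are computed from the full matrices, so they do not depend on the mode of
#' the edge list.
#'
#' @param rho symmetric Spearman correlation matrix (unit diagonal).
#' @param p matrix of two-sided p-values matching \code{rho}.
#' @param layers per-node layer tag (named or in column order).
#' @param alpha significance level, default 0.05.
#' @param mode \code{"significant"} (default) or \code{"overview"}.
#' @param adjust p-value adjustment passed to \code{\link[stats]{p.adjust}};
#'   default \code{"none"} (the method's explicit choice), \code{"BH"}
#'   available.
#' @return object of class \code{corr_network}: list with \code{nodes}
#'   (id, layer, label), \code{edges} (from, to, rho, p, significant),
#'   \code{rho}, \code{p}, \code{alpha}, \code{mode},
#'   \code{density_strength}, \code{density_significant}.
#' @export
build_network <- function(rho, p, layers, alpha = 0.05,
                          mode = c("significant", "overview"),
                          adjust = "none") {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(dim(rho), dim(p))) || nrow(rho) != ncol(rho))
    stop("rho and p must be square matrices of identical shape")
  ids <- colnames(rho)
  if (is.null(ids)) stop("rho must carry feature names")
  if (length(layers) != length(ids)) stop("one layer tag per node required")
  if (!is.null(names(layers))) layers <- layers[ids]
  if (adjust != "none") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  V <- length(ids)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = rho[idx], p = p[idx],
                      significant = p[idx] < alpha,
                      stringsAsFactors = FALSE)
  if (mode == "significant") edges <- edges[edges$significant, , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(nodes = data.frame(id = ids, layer = unname(layers),
                                           label = seq_len(V),
                                           stringsAsFactors = FALSE),
                        edges = edges, rho = rho, p = p, alpha = alpha,
                        mode = mode, adjust = adjust),
                   class = "corr_network")
  if (V >= 2L) {
    net$density_strength <- density_strength(net)
    net$density_significant <- density_significant(net)
  }
  net
}

#' Build both network views from a feature table
#'
#' Convenience wrapper running \code{\link{spearman_matrix}} once and
#' returning the overview and significance-filtered networks.
#'
#' @param tab a \code{feature_table}.
#' @inheritParams build_network
#' @return list with elements \code{overview} and \code{significant}.
#' @export
correlation_networks <- function(tab, alpha = 0.05, adjust = "none") {
  sp <- spearman_matrix(tab)
  list(overview = build_network(sp$rho, sp$p, tab$layer, alpha,
                                mode = "overview", adjust = adjust),
       significant = build_network(sp$rho, sp$p, tab$layer, alpha,
                                   mode = "significant", adjust = adjust))
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf(
    "corr_network (%s): %d nodes, %d edges; density |rho|>0.3: %.1f%%, p<%.2g: %.1f%%\n",
    x$mode, nrow(x$nodes), nrow(x$edges),
    100 * (x$density_strength %||% NA), x$alpha,
    100 * (x$density_significant %||% NA)))
  invisible(x)
}

#' Network density by correlation strength
#'
#' Fraction of all \eqn{\binom{V}{2}} variable pairs whose \eqn{|\rho|}
#' exceeds the strength threshold, computed from the full correlation matrix
#' (mode-independent).
#'
#' @param net a \code{corr_network}.
#' @param threshold strength threshold on \eqn{|\rho|}, default 0.3.
#' @return fraction in [0, 1].
#' @export
density_strength <- function(net, threshold = 0.3) {
  r <- net$rho
  if (ncol(r) < 2L) stop("density undefined for fewer than 2 nodes")
  mean(abs(r[upper.tri(r)]) > threshold)
}

#' Network density by statistical significance
#'
#' Fraction of all \eqn{\binom{V}{2}} variable pairs with \eqn{p < \alpha},
#' computed from the full p matrix (mode-independent).
#'
#' @param net a \code{corr_network}.
#' @param alpha significance level; defaults to the network's own.
#' @return fraction in [0, 1].
#' @export
density_significant <- function(net, alpha = net$alpha) {
  pm <- net$p
  if (ncol(pm) < 2L) stop("density undefined for fewer than 2 nodes")
  mean(pm[upper.tri(pm)] < alpha)
}

# igraph view of the network's current edge list; weight = |rho|.
as_igraph <- function(net, drop_zero = TRUE) {
  e <- net$edges
  if (drop_zero) e <- e[abs(e$rho) > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to", "rho", "p", "significant")],
    directed = FALSE, vertices = net$nodes)
  if (nrow(e)) igraph::E(g)$weight <- abs(e$rho)
  g
}

#' Weighted force-directed layout
#'
#' Fruchterman-Reingold layout with \eqn{|\rho|} as the attraction weight,
#' so strongly correlated variables are drawn close together and repulsion
#' keeps unrelated nodes apart -- relative correlation strength determines
#' node placement. The layout is seeded and therefore reproducible
#' bit-for-bit for a given (network, seed).
#'
#' @param net a \code{corr_network}.
#' @param seed integer RNG seed.
#' @param niter iterations, default 500.
#' @return object of class \code{layout_result}: list with \code{coords}
#'   (nodes x 2 matrix, row-named by node id) and \code{seed}.
#' @export
layout_weighted <- function(net, seed = 1L, niter = 500L) {
  V <- nrow(net$nodes)
  if (V == 0L) stop("network has no nodes")
  if (V == 1L) {
    co <- matrix(0, 1, 2, dimnames = list(net$nodes$id, c("x", "y")))
    return(structure(list(coords = co, seed = seed), class = "layout_result"))
  }
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  set.seed(seed)
  co <- igraph::layout_with_fr(g, niter = niter,
                               weights = if (length(w)) w else NULL)
  dimnames(co) <- list(net$nodes$id, c("x", "y"))
  stopifnot(all(is.finite(co)))
  structure(list(coords = co, seed = seed), class = "layout_result")
}

#' Write a correlation network to disk
#'
#' Three plain-text formats: \code{"edge-tsv"} (edge list with a node table
#' in a companion commented header), \code{"json"} (the complete object,
#' including the rho/p matrices, round-trippable), and \code{"graphml"}
#' (via igraph; nodes carry layer and label, edges rho, p and the
#' significance flag).
#'
#' @param net a \code{corr_network}.
#' @param path output path.
#' @param format one of \code{"edge-tsv"}, \code{"json"}, \code{"graphml"}.
#' @export
write_network <- function(net, path, format = c("edge-tsv", "json", "graphml")) {
  if (length(format) == 1L && !format %in% c("edge-tsv", "json", "graphml"))
    stop("unknown format: ", format)
  format <- match.arg(format)
  if (format == "edge-tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# corr_network mode=%s alpha=%.17g adjust=%s",
                       net$mode, net$alpha, net$adjust), con)
    writeLines(sprintf("# node\t%s\t%s\t%d", net$nodes$id, net$nodes$layer,
                       net$nodes$label), con)
    writeLines("from\tto\trho\tp\tsignificant", con)
    if (nrow(net$edges))
      writeLines(sprintf("%s\t%s\t%.17g\t%.17g\t%s", net$edges$from,
                         net$edges$to, net$edges$rho, net$edges$p,
                         net$edges$significant), con)
  } else if (format == "json") {
    obj <- list(nodes = net$nodes, edges = net$edges,
                rho = net$rho, p = net$p, ids = net$nodes$id,
                alpha = net$alpha, mode = net$mode, adjust = net$adjust)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  } else {
    g <- as_igraph(net, drop_zero = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a correlation network written by \code{\link{write_network}}
#'
#' @param path input path.
#' @param format \code{"edge-tsv"} or \code{"json"} (\code{"graphml"} files
#'   are re-read with \code{igraph::read_graph}).
#' @return a \code{corr_network}.
#' @export
read_network <- function(path, format = c("edge-tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    rho <- obj$rho; p <- obj$p
    dimnames(rho) <- dimnames(p) <- list(obj$ids, obj$ids)
    layers <- stats::setNames(obj$nodes$layer, obj$nodes$id)
    return(build_network(rho, p, layers, alpha = obj$alpha, mode = obj$mode))
  }
  lines <- readLines(path)
  meta <- lines[1]
  mode <- sub(".*mode=(\\S+).*", "\\1", meta)
  alpha <- as.numeric(sub(".*alpha=(\\S+).*", "\\1", meta))
  nodel <- grep("^# node\t", lines, value = TRUE)
  parts <- do.call(rbind, strsplit(sub("^# node\t", "", nodel), "\t"))
  nodes <- data.frame(id = parts[, 1], layer = parts[, 2],
                      label = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  body <- lines[(length(nodel) + 2L):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) > 1L) {
    ep <- do.call(rbind, strsplit(body[-1], "\t"))
    edges <- data.frame(from = ep[, 1], to = ep[, 2],
                        rho = as.numeric(ep[, 3]), p = as.numeric(ep[, 4]),
                        significant = as.logical(ep[, 5]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        rho = numeric(0), p = numeric(0),
                        significant = logical(0), stringsAsFactors = FALSE)
  }
  # edge-tsv carries the retained edge list only; rebuild matrices where the
  # list is complete (overview mode), otherwise leave them sparse (NA off-list)
  ids <- nodes$id
  V <- length(ids)
  rho <- matrix(NA_real_, V, V, dimnames = list(ids, ids)); diag(rho) <- 1
  pm <- matrix(NA_real_, V, V, dimnames = list(ids, ids)); diag(pm) <- 0
  if (nrow(edges)) {
    i <- match(edges$from, ids); j <- match(edges$to, ids)
    rho[cbind(i, j)] <- rho[cbind(j, i)] <- edges$rho
    pm[cbind(i, j)] <- pm[cbind(j, i)] <- edges$p
  }
  net <- structure(list(nodes = nodes, edges = edges, rho = rho, p = pm,
                        alpha = alpha, mode = mode, adjust = "none"),
                   class = "corr_network")
  if (!anyNA(rho)) {
    net$density_strength <- density_strength(net)
    net$density_significant <- density_significant(net)
  }
  net
}
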