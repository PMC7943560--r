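# Plotting: base-graphics renderings of the network views. Green edges are
# positive correlations, red negative; edge width is proportional to |rho|;
# node proximity encodes relative correlation strength via the weighted
# force-directed layout.

edge_col <- function(rho) ifelse(rho >= 0, "#2e7d32", "#c62828")

layer_col <- c(host_gene = "#ffd54f", taxon = "#90caf9",
               gi_symptom = "#ce93d8", psych_symptom = "#ffab91")

#' Plot a correlation network
#'
#' @param x a \code{corr_network}.
#' @param layout a \code{layout_result} from \code{\link{layout_weighted}}
#'   (computed at \code{seed} when omitted).
#' @param seed layout seed used when \code{layout} is missing.
#' @param labels plot numeric node labels (default) or ids.
#' @param ... ignored.
#' @export
plot.corr_network <- function(x, layout = NULL, seed = 1L,
                              labels = c("number", "id"), ...) {
  labels <- match.arg(labels)
  if (is.null(layout)) layout <- layout_weighted(x, seed = seed)
  co <- layout$coords
  graphics::plot(co, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s network (alpha = %g)", x$mode, x$alpha))
  e <- x$edges[abs(x$edges$rho) > 0, , drop = FALSE]
  if (nrow(e)) {
    i <- match(e$from, rownames(co)); j <- match(e$to, rownames(co))
    graphics::segments(co[i, 1], co[i, 2], co[j, 1], co[j, 2],
                       col = edge_col(e$rho), lwd = 0.5 + 3 * abs(e$rho))
  }
  graphics::points(co, pch = 21, cex = 2.2,
                   bg = layer_col[x$nodes$layer[match(rownames(co), x$nodes$id)]])
  graphics::text(co, labels = if (labels == "number")
    x$nodes$label[match(rownames(co), x$nodes$id)] else rownames(co),
    cex = 0.6)
  invisible(x)
}

#' Plot a multilayer model
#'
#' Within-layer edges are solid (green positive, red negative, width by
#' |rho|); between-layer edges are dotted grey with the rho value printed to
#' two decimals at the midpoint.
#'
#' @param x a \code{multilayer_model}.
#' @param ... ignored.
#' @export
plot.multilayer_model <- function(x, ...) {
  all_co <- do.call(rbind, lapply(x$layers, function(l) l$coords))
  graphics::plot(all_co, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%d-layer model", length(x$layers)))
  if (nrow(x$between)) {
    for (r in seq_len(nrow(x$between))) {
      b <- x$between[r, ]
      p1 <- x$layers[[b$layer_a]]$coords[b$a, ]
      p2 <- x$layers[[b$layer_b]]$coords[b$b, ]
      graphics::segments(p1[1], p1[2], p2[1], p2[2], col = "grey40", lty = 3)
      graphics::text((p1[1] + p2[1]) / 2, (p1[2] + p2[2]) / 2,
                     sprintf("%.2f", b$rho), cex = 0.55, col = "grey20")
    }
  }
  for (l in x$layers) {
    co <- l$coords
    e <- l$net$edges[abs(l$net$edges$rho) > 0, , drop = FALSE]
    if (nrow(e)) {
      i <- match(e$from, rownames(co)); j <- match(e$to, rownames(co))
      graphics::segments(co[i, 1], co[i, 2], co[j, 1], co[j, 2],
                         col = edge_col(e$rho), lwd = 0.5 + 3 * abs(e$rho))
    }
    graphics::points(co, pch = 21, cex = 2,
                     bg = layer_col[l$net$nodes$layer[match(rownames(co),
                                                            l$net$nodes$id)]])
    graphics::text(co, labels = l$net$nodes$label[match(rownames(co),
                                                        l$net$nodes$id)],
                   cex = 0.55)
  }
  invisible(x)
}

#' QC score plot with the confidence ellipse
#'
#' PC1/PC2 scores with the 95\% confidence ellipse and the flagging boundary
#' (ellipse + margin); flagged samples are labelled.
#'
#' @param x an \code{outlier_report}.
#' @param ... ignored.
#' @export
plot.outlier_report <- function(x, ...) {
  s2 <- x$pc_scores[, 1:2, drop = FALSE]
  ell <- x$ellipse
  th <- seq(0, 2 * pi, length.out = 181)
  U <- cbind(cos(th), sin(th))
  Sinv <- solve(ell$cov)
  rb <- sqrt(ell$crit / rowSums((U %*% Sinv) * U))
  bnd <- sweep(U * rb, 2, ell$center, "+")
  bnd2 <- sweep(U * (rb + ell$margin), 2, ell$center, "+")
  lim <- range(rbind(s2, bnd2))
  graphics::plot(s2, xlim = lim, ylim = lim, pch = 19, cex = 0.7,
                 xlab = "PC1", ylab = "PC2", main = "multivariate outlier screen")
  graphics::lines(bnd, col = "steelblue")
  graphics::lines(bnd2, col = "firebrick", lty = 2)
  if (nrow(x$flagged)) {
    idx <- match(x$flagged$sample_id, rownames(s2))
    graphics::points(s2[idx, , drop = FALSE], col = "firebrick", pch = 19)
    graphics::text(s2[idx, , drop = FALSE], labels = x$flagged$sample_id,
                   pos = 3, cex = 0.7, col = "firebrick")
  }
  invisible(x)
}
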