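#' PCA scores for multivariate outlier screening
#'
#' Principal component scores of a feature table, computed per group before
#' network analysis. Features are centered and standardized to unit variance
#' first, because gene expression, normalized counts and ordinal symptom
#' scores live on scales differing by orders of magnitude; without scaling
#' the count features would dominate the components and a fixed score-unit
#' outlier rule would be meaningless. Constant features are left centered
#' only (their standardized value is zero). A deterministic sign convention
#' (largest-magnitude loading positive) makes scores reproducible across
#' platforms.
#'
#' @param tab a \code{feature_table} or numeric samples x features matrix.
#' @param k number of components to return (default \code{min(n-1, p)}).
#' @param scale. standardize features to unit variance (default TRUE).
#' @return samples x k score matrix with attributes \code{"sdev"} (component
#'   standard deviations) and \code{"var_explained"}.
#' @export
pca_scores <- function(tab, k = NULL, scale. = TRUE) {
  m <- if (inherits(tab, "feature_table")) tab$values else tab
  n <- nrow(m); p <- ncol(m)
  if (n < 3L) stop("need at least 3 samples for PCA screening")
  kmax <- min(n - 1L, p)
  if (is.null(k)) k <- kmax
  if (k > kmax) stop(sprintf("k = %d exceeds min(n-1, p) = %d", k, kmax))
  sds <- apply(m, 2, stats::sd)
  sc <- if (scale.) ifelse(sds > 0, sds, 1) else FALSE
  pc <- stats::prcomp(m, center = TRUE, scale. = sc)
  # sign convention: the largest-|loading| entry of each rotation column is
  # made positive so the decomposition is unique
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "sdev") <- pc$sdev
  attr(scores, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  scores
}

#' Flag strong multivariate outliers on the PC1-PC2 plane
#'
#' A sample is a strong outlier when it lies more than \code{margin} score
#' units outside the 95\% confidence ellipse of the first two principal
#' components. The ellipse is the Hotelling-T2-style region
#' \eqn{x' S^{-1} x \le c} with
#' \eqn{c = 2(n-1)/(n-2)\,F_{2,n-2}(ci)} on the centered scores, and the
#' exceedance of a sample is the Euclidean distance between the sample and
#' the ellipse boundary along the ray from the center (positive outside the
#' ellipse). Screening is run separately per group; removal is the caller's
#' decision via \code{\link{remove_outliers}}.
#'
#' @param scores score matrix from \code{\link{pca_scores}} (>= 2 columns).
#' @param ci ellipse coverage, default 0.95.
#' @param margin flagging margin in score units beyond the ellipse, default 10.
#' @return an \code{outlier_report}: list with \code{pc_scores},
#'   \code{ellipse} (covariance, center, critical value), \code{exceedance}
#'   (named vector, negative inside the ellipse), \code{flagged} data.frame
#'   and \code{removed} logical vector (identical to flagged status;
#'   callers may veto).
#' @export
flag_strong_outliers <- function(scores, ci = 0.95, margin = 10) {
  if (ncol(scores) < 2L) stop("need at least 2 components")
  n <- nrow(scores)
  if (n < 5L) stop("outlier screening needs n >= 5 (confidence ellipse unstable)")
  s2 <- scores[, 1:2, drop = FALSE]
  ctr <- colMeans(s2)
  S <- stats::cov(s2)
  if (det(S) <= 0) stop("degenerate score covariance")
  crit <- 2 * (n - 1) / (n - 2) * stats::qf(ci, 2, n - 2)
  Sinv <- solve(S)
  dev <- sweep(s2, 2, ctr)
  r <- sqrt(rowSums(dev^2))                       # distance from center
  # boundary radius along each sample's ray: r_b^2 * (u' Sinv u) = crit
  quad <- rowSums((dev %*% Sinv) * dev)           # r^2 * (u' Sinv u)
  rb <- ifelse(r > 0, r * sqrt(crit / quad), sqrt(crit / max(diag(Sinv))))
  exceed <- r - rb
  names(exceed) <- rownames(scores)
  flag <- exceed > margin
  flagged <- data.frame(sample_id = rownames(scores)[flag],
                        exceedance = unname(exceed[flag]),
                        stringsAsFactors = FALSE)
  if (nrow(flagged))
    stepnet_log("outlier screen: flagged %s (exceedance %s score units)",
                paste(flagged$sample_id, collapse = ", "),
                paste(sprintf("%.1f", flagged$exceedance), collapse = ", "))
  structure(list(pc_scores = scores,
                 ellipse = list(center = ctr, cov = S, crit = crit, ci = ci,
                                margin = margin, scaled = TRUE),
                 exceedance = exceed,
                 flagged = flagged,
                 removed = stats::setNames(flag, rownames(scores))),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d samples screened, %d flagged (ci %.2f, margin %g)\n",
              nrow(x$pc_scores), nrow(x$flagged), x$ellipse$ci, x$ellipse$margin))
  invisible(x)
}

#' Remove flagged outliers from a cohort
#'
#' Drops every sample marked \code{removed} in the given reports from all
#' member tables of the dataset, logging exceedance values. Removing the last
#' sample of a group is refused.
#'
#' @param dataset a \code{\link{cohort_dataset}}.
#' @param ... one or more \code{outlier_report}s (typically one per group).
#' @return the reduced \code{cohort_dataset}.
#' @export
remove_outliers <- function(dataset, ...) {
  reports <- list(...)
  drop <- character(0)
  for (rep in reports) {
    stopifnot(inherits(rep, "outlier_report"))
    if (nrow(rep$flagged)) {
      stepnet_log("remove_outliers: dropping %s",
                  paste(sprintf("%s (%.1f units)", rep$flagged$sample_id,
                                rep$flagged$exceedance), collapse = ", "))
      drop <- c(drop, rep$flagged$sample_id)
    }
  }
  drop_samples(dataset, unique(drop))
}
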