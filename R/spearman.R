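#' All-pairs Spearman correlation with significance
#'
#' Spearman rank correlations between all feature pairs of a table, chosen
#' over product-moment correlation because the integrated layers (expression,
#' normalized counts, ordinal symptom scores) are on incommensurate scales
#' and generally non-normal; the rank statistic is invariant to any monotone
#' per-feature transform. Ties receive midranks. Two-sided p-values use the
#' t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df for
#' \eqn{n \ge 10}, and exact enumeration over all \eqn{n!} permutations of
#' one margin for \eqn{n < 10}.
#'
#' A constant feature has no ranks to correlate; its pairs are recorded as
#' \eqn{\rho = 0}, \eqn{p = 1} with a warning rather than failing the run
#' (all-zero-variance symptom columns in a control group are a legitimate
#' input).
#'
#' @param tab a \code{feature_table} or numeric samples x features matrix
#'   with at least 4 samples and no missing values.
#' @return list with entries \code{rho} (symmetric, unit diagonal), \code{p}
#'   (symmetric, zero diagonal) and \code{n}.
#' @export
spearman_matrix <- function(tab) {
  m <- if (inherits(tab, "feature_table")) tab$values else tab
  n <- nrow(m); p <- ncol(m)
  if (n < 4L) stop("need at least 4 samples for correlation analysis")
  if (any(!is.finite(m))) stop("missing values are not allowed")
  const <- apply(m, 2, function(x) max(x) == min(x))
  R <- apply(m, 2, rank)                    # midranks
  rho <- suppressWarnings(stats::cor(R))    # product-moment on ranks
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 1
  if (any(const))
    warning("constant feature(s): ", paste(colnames(m)[const], collapse = ", "),
            "; their correlations are recorded as rho = 0, p = 1")
  pm <- spearman_pvalues(rho, n, R, const)
  dimnames(pm) <- dimnames(rho)
  list(rho = rho, p = pm, n = n)
}

# p-value matrix for a rho matrix at sample size n. R (rank matrix) is only
# needed on the exact path.
spearman_pvalues <- function(rho, n, R = NULL, const = NULL) {
  p <- ncol(rho)
  if (is.null(const)) const <- rep(FALSE, p)
  if (n >= 10L) {
    r <- pmin(pmax(rho, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pm <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pm[abs(r) >= 1] <- 0
  } else {
    if (is.null(R)) stop("exact permutation p-values need the rank matrix")
    pm <- matrix(0, p, p)
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      pm[i, j] <- pm[j, i] <-
        if (const[i] || const[j]) 1 else spearman_perm_p(R[, i], R[, j])
    }
  }
  pm[const, ] <- 1; pm[, const] <- 1
  diag(pm) <- 0
  pm
}

# Exact two-sided permutation p-value for the Spearman correlation of two
# (mid)rank vectors: the proportion of the n! permutations of one margin
# whose |rho| reaches the observed |rho| (up to numerical slack).
spearman_perm_p <- function(r1, r2) {
  n <- length(r1)
  a <- r1 - mean(r1); b <- r2 - mean(r2)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(1)
  obs <- sum(a * b) / den
  P <- all_perms(n)
  aperm <- matrix(a[P], nrow(P))
  rhos <- as.vector(aperm %*% b) / den
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Cross-layer Spearman: every column of A against every column of B
# (same samples, same rank machinery as spearman_matrix).
spearman_cross <- function(A, B) {
  if (nrow(A) != nrow(B)) stop("sample sets must match")
  n <- nrow(A)
  if (n < 4L) stop("need at least 4 samples")
  constA <- apply(A, 2, function(x) max(x) == min(x))
  constB <- apply(B, 2, function(x) max(x) == min(x))
  RA <- apply(A, 2, rank); RB <- apply(B, 2, rank)
  rho <- suppressWarnings(stats::cor(RA, RB))
  rho[constA, ] <- 0; rho[, constB] <- 0
  if (n >= 10L) {
    r <- pmin(pmax(rho, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pm <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pm[abs(r) >= 1] <- 0
  } else {
    pm <- matrix(1, ncol(A), ncol(B))
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B)))
      pm[i, j] <- if (constA[i] || constB[j]) 1 else
        spearman_perm_p(RA[, i], RB[, j])
  }
  pm[constA, ] <- 1; pm[, constB] <- 1
  dimnames(pm) <- dimnames(rho)
  list(rho = rho, p = pm, n = n)
}
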