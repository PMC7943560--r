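# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# samples x features matrix of iid N(0,1), named.
rand_table <- function(n, p, seed, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s%02d", prefix, seq_len(p))))
  m
}

rand_counts <- function(n, p, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("t%02d", seq_len(p))))
  m
}

# tiny two-group cohort with g genes, t genera in 2 phyla
tiny_cohort <- function(seed = 1, n_pat = 8, n_con = 6, g = 4, t = 6) {
  set.seed(seed)
  sn <- c(sprintf("P%02d", seq_len(n_pat)), sprintf("C%02d", seq_len(n_con)))
  expr <- matrix(rlnorm(length(sn) * g), length(sn), g,
                 dimnames = list(sn, sprintf("G%d", seq_len(g))))
  counts <- matrix(rpois(length(sn) * t, 40), length(sn), t,
                   dimnames = list(sn, sprintf("T%d", seq_len(t))))
  tax <- taxonomy_map(data.frame(
    taxon_id = sprintf("T%d", seq_len(t)),
    phylum = rep(c("PhyA", "PhyB"), length.out = t),
    genus = sprintf("T%d", seq_len(t))))
  groups <- setNames(c(rep("patient", n_pat), rep("control", n_con)), sn)
  cohort_dataset(feature_table(expr, "host_gene", group = groups),
                 feature_table(counts, "taxon", group = groups),
                 tax, groups)
}

# independent midrank Spearman oracle: explicit ranks + product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force exact permutation p-value (recursive permutation enumeration,
# independent of the package's all_perms path)
oracle_perm_p <- function(x, y) {
  perm_list <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm_list(v[-i]), function(p) c(v[i], p))))
  }
  obs <- oracle_spearman(x, y)
  rhos <- vapply(perm_list(seq_along(y)),
                 function(p) oracle_spearman(x, y[p]), 0)
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# tiny correlation network from a given rho matrix (p from t-approximation
# at a notional n) for density/layout tests
net_from_rho <- function(rho, n = 30, alpha = 0.05, mode = "overview",
                         layers = "host_gene") {
  if (is.null(colnames(rho)))
    dimnames(rho) <- list(sprintf("v%02d", seq_len(ncol(rho))),
                          sprintf("v%02d", seq_len(ncol(rho))))
  r <- pmin(pmax(rho, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t), n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  dimnames(p) <- dimnames(rho)
  build_network(rho, p, rep(layers, length.out = ncol(rho)),
                alpha = alpha, mode = mode)
}
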