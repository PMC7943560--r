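# latent-Gaussian sampler used to plant block structure directly
plant_block_data <- function(n, p, block, r_within, seed,
                             extra = NULL) {
  S <- diag(p)
  S[block, block] <- r_within
  if (!is.null(extra)) for (e in extra) S[e$i, e$j] <- S[e$j, e$i] <- e$r
  diag(S) <- 1
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(S)
  dimnames(Z) <- list(sprintf("s%02d", 1:n), sprintf("v%02d", 1:p))
  Z
}

test_that("an empty or insignificant network yields an empty cluster set", {
  none <- net_from_rho(diag(5), mode = "significant")
  none$p[] <- 0.9; diag(none$p) <- 0
  none$edges <- none$edges[0, ]
  cs <- detect_clusters(none)
  expect_length(cs$clusters, 0)
})

test_that("a planted 4-node block amid noise is recovered as one cluster", {
  # with uncorrected alpha = 0.05 a noise node occasionally attaches to the
  # planted community through a spurious significant edge, so recovery is
  # judged by co-clustering: all four planted nodes land in one detected
  # cluster that stays dominated by them
  hits <- 0L
  for (seed in 1:50) {
    Z <- plant_block_data(40, 12, 1:4, latent_from_spearman(0.8), seed)
    net <- correlation_networks(feature_table(Z, "host_gene"))$significant
    cs <- detect_clusters(net, seed = seed)
    planted <- sprintf("v%02d", 1:4)
    hit <- any(vapply(cs$clusters, function(cl)
      all(planted %in% cl$members) && length(cl$members) <= 8, TRUE))
    hits <- hits + hit
  }
  expect_gte(hits / 50, 0.9)
})

test_that("two disjoint planted blocks give two disjoint clusters", {
  Z <- plant_block_data(60, 14, 1:4, latent_from_spearman(0.8), seed = 7)
  S_idx <- 5:10
  Z2 <- plant_block_data(60, 14, S_idx, latent_from_spearman(0.8), seed = 8)
  Z[, S_idx] <- Z2[, S_idx]
  net <- correlation_networks(feature_table(Z, "host_gene"))$significant
  cs <- detect_clusters(net, seed = 1)
  mem <- lapply(cs$clusters, `[[`, "members")
  has4 <- any(vapply(mem, function(m) all(sprintf("v%02d", 1:4) %in% m), TRUE))
  has6 <- any(vapply(mem, function(m) all(sprintf("v%02d", 5:10) %in% m), TRUE))
  expect_true(has4 && has6)
  expect_identical(anyDuplicated(unlist(mem)), 0L)
})

test_that("cluster sets are disjoint and respect min_size on random inputs", {
  for (seed in 1:10) {
    m <- rand_table(25, 15, seed = seed)
    net <- correlation_networks(feature_table(m, "host_gene"))$significant
    cs <- detect_clusters(net, min_size = 3, seed = seed)
    mem <- unlist(lapply(cs$clusters, `[[`, "members"))
    expect_identical(anyDuplicated(mem), 0L)
    for (cl in cs$clusters) {
      expect_gte(length(cl$members), 3)
      expect_gte(cl$mean_abs_rho, cs$tau)
    }
  }
})

test_that("a taxon coupled to all cluster genes is reported with negative rho", {
  detected <- 0L
  for (seed in 1:50) {
    # 4-gene block at Spearman 0.6 plus one taxon at -0.5 to each gene
    extra <- lapply(1:4, function(i)
      list(i = i, j = 9L, r = latent_from_spearman(-0.5)))
    Z <- plant_block_data(40, 9, 1:4, latent_from_spearman(0.6), seed,
                          extra = extra)
    vals <- cbind(exp(Z[, 1:8]), qnbinom(pnorm(Z[, 9]), mu = 60, size = 8))
    colnames(vals) <- c(sprintf("g%d", 1:8), "tax1")
    tab <- feature_table(vals, c(rep("host_gene", 8), "taxon"),
                         normalized = TRUE)
    net <- correlation_networks(tab)$significant
    a <- cluster_layer_associations(sprintf("g%d", 1:4), net, "taxon", k = 2)
    if ("tax1" %in% a$node && a$rho[a$node == "tax1"] < 0)
      detected <- detected + 1L
  }
  expect_gte(detected / 50, 0.9)
})

test_that("associations are monotone in the corroboration threshold k", {
  Z <- plant_block_data(40, 9, 1:4, latent_from_spearman(0.6), seed = 3,
                        extra = lapply(1:4, function(i)
                          list(i = i, j = 9L, r = latent_from_spearman(-0.5))))
  colnames(Z)[9] <- "tax1"
  tab <- feature_table(Z, c(rep("host_gene", 8), "taxon"), normalized = TRUE)
  net <- correlation_networks(tab)$significant
  a1 <- cluster_layer_associations(colnames(Z)[1:4], net, "taxon", k = 1)
  a2 <- cluster_layer_associations(colnames(Z)[1:4], net, "taxon", k = 2)
  expect_true(all(a2$node %in% a1$node))
  # a cluster with no cross-layer edges yields an empty list
  iso <- cluster_layer_associations(colnames(Z)[5:8], net, "taxon", k = 3)
  expect_identical(nrow(iso), 0L)
})

test_that("between-layer edges equal the brute-force cross-pair oracle", {
  A <- feature_table(rand_table(30, 5, seed = 4, prefix = "a"), "host_gene")
  B <- feature_table(rand_table(30, 4, seed = 5, prefix = "b"), "gi_symptom")
  be <- between_layer_edges(A, B, alpha = 0.2)
  expected <- 0L
  for (i in feature_ids(A)) for (j in feature_ids(B)) {
    ct <- cor.test(A$values[, i], B$values[, j], method = "spearman",
                   exact = FALSE)
    if (ct$p.value < 0.2) {
      expected <- expected + 1L
      row <- be[be$a == i & be$b == j, ]
      expect_identical(nrow(row), 1L)
      expect_equal(row$rho, unname(ct$estimate), tolerance = 1e-10)
    }
  }
  expect_identical(nrow(be), expected)

  # a symptom that is a monotone copy of a gene comes out at rho = 1
  Bc <- B; Bc$values[, 1] <- exp(A$values[, 1])
  be2 <- between_layer_edges(A, Bc)
  hit <- be2[be2$a == feature_ids(A)[1] & be2$b == feature_ids(B)[1], ]
  expect_equal(hit$rho, 1)

  # mismatched sample sets are refused
  B3 <- feature_table(rand_table(28, 4, seed = 6, prefix = "b"), "gi_symptom")
  expect_error(between_layer_edges(A, B3), "sample sets")
})

test_that("null between-layer edge rate is calibrated to alpha", {
  rate <- mean(vapply(1:200, function(seed) {
    A <- rand_table(30, 5, seed = 2000 + seed, prefix = "a")
    B <- rand_table(30, 4, seed = 7000 + seed, prefix = "b")
    nrow(between_layer_edges(feature_table(A, "host_gene"),
                             feature_table(B, "gi_symptom"))) / 20
  }, 0))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("a planted symptom-gene coupling is detected at the rank-test's power", {
  # single-pair detection of Spearman 0.4 at n = 42, alpha = 0.05 has
  # analytic power ~0.75 (Fisher-z: Phi((z(0.4) - z(rho_crit)) * sqrt(39) /
  # 1.06) = 0.75); the observed rate must be consistent with it, and the
  # detected edges must fall in the moderate-strength band
  rho_crit <- uniroot(function(r) {
    t <- r * sqrt(40 / (1 - r^2)); 2 * pt(-t, 40) - 0.05
  }, c(0.1, 0.9))$root
  power <- pnorm((atanh(0.4) - atanh(rho_crit)) * sqrt(39) / 1.06)
  detected <- 0L; in_band <- 0L
  for (seed in 1:50) {
    Z <- plant_block_data(42, 6, integer(0), 0, seed,
                          extra = list(list(i = 1L, j = 6L,
                                            r = latent_from_spearman(0.4))))
    A <- feature_table(exp(Z[, 1:5, drop = FALSE]), "host_gene")
    symp <- matrix(pmin(1 + floor(pnorm(Z[, 6]) * 7), 7), ncol = 1,
                   dimnames = list(rownames(Z), "satiety"))
    B <- feature_table(symp, "gi_symptom")
    be <- between_layer_edges(A, B)
    row <- be[be$a == colnames(Z)[1] & be$b == "satiety", ]
    if (nrow(row) == 1L) {
      detected <- detected + 1L
      if (abs(row$rho) >= 0.2 && abs(row$rho) <= 0.6) in_band <- in_band + 1L
    }
  }
  expect_gt(detected / 50, power - 0.15)
  expect_lt(detected / 50, power + 0.15)
  expect_gte(in_band / max(detected, 1L), 0.9)
})

test_that("multilayer composition anchors layers and validates between-edges", {
  m1 <- correlation_networks(feature_table(rand_table(20, 6, seed = 1), "host_gene"))$significant
  m2 <- correlation_networks(feature_table(rand_table(20, 4, seed = 2, prefix = "g"), "gi_symptom"))$significant
  m3 <- correlation_networks(feature_table(rand_table(20, 3, seed = 3, prefix = "q"), "psych_symptom"))$significant

  dual <- compose_multilayer(m1, m2, seed = 5)
  expect_named(dual$layers, c("mucosal", "gi"))
  expect_identical(nrow(dual$between), 0L)

  be <- data.frame(a = "f01", b = "g01", rho = -0.4, p = 0.01)
  tri <- compose_multilayer(m1, m2, m3,
                            between = list("mucosal|gi" = be), seed = 5)
  expect_length(tri$layers, 3)
  expect_identical(nrow(tri$between), 1L)
  # distinct anchors: layer centroids are far apart
  cent <- vapply(tri$layers, function(l) colMeans(l$coords), numeric(2))
  expect_gt(min(dist(t(cent))), 2)

  bad <- data.frame(a = "nope", b = "g01", rho = 0.5, p = 0.01)
  expect_error(compose_multilayer(m1, m2, between = list("mucosal|gi" = bad)),
               "missing node")
  expect_error(compose_multilayer(m1, m2, between = list("mucosal|wat" = be)),
               "layer")

  # determinism of the composed geometry at fixed seed
  tri2 <- compose_multilayer(m1, m2, m3,
                             between = list("mucosal|gi" = be), seed = 5)
  expect_identical(lapply(tri$layers, `[[`, "coords"),
                   lapply(tri2$layers, `[[`, "coords"))

  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 500, height = 500)
  expect_no_error(plot(tri))
  grDevices::dev.off()
})
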