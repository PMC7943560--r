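test_that("the copula calibration map has the right fixed points and slope", {
  expect_identical(latent_from_spearman(0), 0)
  expect_equal(latent_from_spearman(0.6), 2 * sin(0.1 * pi), tolerance = 1e-15)
  expect_equal(latent_from_spearman(-0.5), -2 * sin(0.5 * pi / 6),
               tolerance = 1e-15)
  # continuity towards the limits
  expect_equal(latent_from_spearman(0.999999), 1, tolerance = 1e-4)
  expect_error(latent_from_spearman(1), "< 1")
  expect_error(latent_from_spearman(-1.2), "< 1")
})

null_spec <- function(seed, n_pat = 40, n_con = 10, n_genes = 10, n_gen = 30) {
  genera <- data.frame(taxon_id = sprintf("T%02d", seq_len(n_gen)),
                       phylum = rep(sprintf("Phy%d", 1:5), length.out = n_gen),
                       stringsAsFactors = FALSE)
  sim_spec(n_pat, n_con, genes = sprintf("G%02d", seq_len(n_genes)),
           genera = genera,
           gi_symptoms = list(satiety = c(1, 7)),
           seed = seed)
}

test_that("a structureless spec generates near-zero pairwise Spearman", {
  spec <- null_spec(2, n_pat = 2000, n_con = 0, n_genes = 6, n_gen = 30)
  ds <- generate_cohort(spec)$dataset
  # library-size factors induce shared depth variation in raw counts, so
  # taxa enter after median-of-ratios normalization
  norm <- suppressMessages(normalize_counts(ds$taxa_genus))
  v <- cbind(ds$expression$values, norm$values)
  rho <- cor(apply(v, 2, rank))
  off <- rho[upper.tri(rho)]
  # per-pair null sd is 1/sqrt(n-1) ~ 0.022; the whole matrix must be
  # centered on zero and no pair may stray beyond ~4.5 standard errors
  # (630 pairs make a +-0.05 bound on the maximum a max-statistic, not a
  # per-pair one)
  # the tiny negative offset is the closure effect of dividing by a size
  # factor that contains each feature's own contribution
  expect_lt(abs(mean(off)), 0.03)
  expect_lt(mean(abs(off)), 0.03)
  expect_lt(max(abs(off)), 4.5 / sqrt(1999))
  # the gene marginals are untouched by normalization: direct +-0.05 check
  rg <- rho[1:6, 1:6]
  expect_lt(max(abs(rg[upper.tri(rg)])), 0.05)
})

test_that("planted blocks and links hit their Spearman targets at large n", {
  # enough unplanted genera that the size factors are driven by null
  # features, not by the coupled genus itself
  genera <- data.frame(taxon_id = c("TaxA", "TaxB", sprintf("N%02d", 1:20)),
                       phylum = c("P1", "P2", rep("P3", 20)),
                       stringsAsFactors = FALSE)
  spec <- sim_spec(2000, 0, genes = c("g1", "g2", "g3", "g4", "g5"),
                   genera = genera,
                   blocks = list(list(members = c("g1", "g2", "g3", "g4"),
                                      rho = 0.6, scope = "both")),
                   cross_links = data.frame(a = "TaxA", b = "g1", rho = -0.5,
                                            scope = "both",
                                            stringsAsFactors = FALSE),
                   seed = 4)
  ds <- generate_cohort(spec)$dataset
  e <- ds$expression$values
  for (pair in combn(paste0("g", 1:4), 2, simplify = FALSE)) {
    r <- cor(e[, pair[1]], e[, pair[2]], method = "spearman")
    expect_gt(r, 0.55); expect_lt(r, 0.65)
  }
  r_tax <- cor(ds$taxa_genus$values[, "TaxA"], e[, "g1"], method = "spearman")
  # library scaling perturbs raw-count ranks; normalized counts recover it
  norm <- suppressMessages(normalize_counts(ds$taxa_genus))
  r_tax <- cor(norm$values[, "TaxA"], e[, "g1"], method = "spearman")
  expect_gt(r_tax, -0.55); expect_lt(r_tax, -0.45)
  # unplanted pair stays null
  expect_lt(abs(cor(e[, "g5"], e[, "g1"], method = "spearman")), 0.05)
})

test_that("genus counts summed to a phylum reproduce the planted coupling", {
  genera <- data.frame(taxon_id = c("c1", "c2", "c3", sprintf("N%02d", 1:20)),
                       phylum = c("Chl", "Chl", "Chl", rep("Other", 20)),
                       stringsAsFactors = FALSE)
  links <- rbind(expand.grid(a = c("c1", "c2", "c3"), b = "g1", rho = -0.5,
                             scope = "both", stringsAsFactors = FALSE))
  spec <- sim_spec(1500, 0, genes = "g1", genera = genera,
                   blocks = list(list(members = c("c1", "c2", "c3"),
                                      rho = 0.6, scope = "both")),
                   cross_links = links, seed = 9)
  ds <- generate_cohort(spec)$dataset
  norm <- suppressMessages(normalize_counts(ds$taxa_genus))
  phy <- suppressMessages(aggregate_to_rank(norm, ds$taxonomy, "phylum"))
  r <- cor(phy$values[, "Chl"], ds$expression$values[, "g1"],
           method = "spearman")
  # the sum of three equally coupled genera correlates at least as strongly
  # as a single genus
  expect_lt(r, -0.45)
})

test_that("inconsistent correlation targets are rejected as non-PD", {
  genera <- data.frame(taxon_id = "T1", phylum = "P", stringsAsFactors = FALSE)
  links <- data.frame(a = c("g1", "g2", "g1"), b = c("g2", "g3", "g3"),
                      rho = c(0.9, 0.9, -0.9), scope = "both",
                      stringsAsFactors = FALSE)
  expect_error(sim_spec(10, 5, genes = c("g1", "g2", "g3"), genera = genera,
                        cross_links = links, seed = 1),
               "positive definite")
  expect_error(sim_spec(10, 5, genes = c("g1", "g2"), genera = genera,
                        cross_links = data.frame(a = "g1", b = "g2", rho = 1.2,
                                                 scope = "both"),
                        seed = 1),
               "\\(-1, 1\\)")
})

test_that("the pilot preset has the pilot cohort's dimensions", {
  spec <- preset_pilot(2)
  ds <- generate_cohort(spec)$dataset
  expect_identical(sum(ds$groups == "patient"), 42L)
  expect_identical(sum(ds$groups == "control"), 20L)
  expect_identical(ncol(ds$expression$values), 22L)
  expect_identical(ncol(ds$taxa_genus$values), 188L)
  expect_identical(length(unique(ds$taxonomy$phylum)), 11L)
  expect_identical(ncol(ds$gi_symptoms$values), 5L)
  expect_identical(ncol(ds$psych_symptoms$values), 4L)
})

test_that("symptom scores respect their instrument ranges", {
  ds <- generate_cohort(preset_pilot(3))$dataset
  gi <- ds$gi_symptoms$values
  expect_true(all(gi >= 1 & gi <= 7))
  ps <- ds$psych_symptoms$values
  expect_true(all(ps[, "HAD_anxiety"] >= 0 & ps[, "HAD_anxiety"] <= 21))
  expect_true(all(ps[, "HAD_depression"] >= 0 & ps[, "HAD_depression"] <= 21))
  expect_true(all(ps[, "VSI"] >= 0 & ps[, "VSI"] <= 75))
  expect_true(all(ps[, "MFI_general_fatigue"] >= 4 &
                    ps[, "MFI_general_fatigue"] <= 20))
  expect_true(all(ds$taxa_genus$values == round(ds$taxa_genus$values)))
  expect_true(all(ds$expression$values > 0))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_cohort(preset_pilot(6))
  b <- generate_cohort(preset_pilot(6))
  expect_identical(a$dataset$expression$values, b$dataset$expression$values)
  expect_identical(a$dataset$taxa_genus$values, b$dataset$taxa_genus$values)
  expect_identical(a$dataset$gi_symptoms$values, b$dataset$gi_symptoms$values)
  expect_identical(a$truth$library_factors, b$truth$library_factors)
  # different seeds give different data
  c_ <- generate_cohort(preset_pilot(7))
  expect_false(identical(a$dataset$expression$values,
                         c_$dataset$expression$values))
})

test_that("control groups carry no planted cross-layer structure", {
  ds <- generate_cohort(preset_pilot(4))$dataset
  con <- names(ds$groups)[ds$groups == "control"]
  norm <- suppressMessages(normalize_counts(ds$taxa_genus))
  r <- cor(norm$values[con, "Chlamydiae_g1"],
           ds$expression$values[con, "PAR2"], method = "spearman")
  # n = 20 null: |rho| rarely beyond ~0.55; just assert no strong coupling
  expect_lt(abs(r), 0.55)
})

test_that("planted latent outliers are displaced in the generated tables", {
  spec <- null_spec(12)
  spec$outliers <- data.frame(sample = "P01", displacement = 6,
                              stringsAsFactors = FALSE)
  ds <- generate_cohort(spec)$dataset
  pat <- names(ds$groups)[ds$groups == "patient"]
  m <- cbind(ds$expression$values[pat, ], log1p(ds$taxa_genus$values[pat, ]))
  sc <- pca_scores(m)
  rep <- suppressMessages(flag_strong_outliers(sc))
  expect_true("P01" %in% rep$flagged$sample_id)
})
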