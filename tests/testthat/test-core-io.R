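test_that("feature tables validate ids, finiteness and count integrality", {
  m <- rand_counts(3, 2, seed = 1)
  expect_s3_class(feature_table(m, "taxon"), "feature_table")

  dup <- m; colnames(dup) <- c("t01", "t01")
  expect_error(feature_table(dup, "taxon"), "t01")
  dupr <- m; rownames(dupr) <- c("s01", "s01", "s03")
  expect_error(feature_table(dupr, "taxon"), "s01")

  bad <- m; bad[2, 1] <- NA
  expect_error(feature_table(bad, "taxon"), "non-finite")
  frac <- m; frac[1, 1] <- 1.5
  expect_error(feature_table(frac, "taxon"), "integer")
  # the same values are fine on a non-count layer or after normalization
  expect_s3_class(feature_table(frac, "host_gene"), "feature_table")
  expect_s3_class(feature_table(frac, "taxon", normalized = TRUE),
                  "feature_table")
  expect_error(feature_table(m[0, , drop = FALSE], "taxon"), "empty")
})

test_that("reading a delimited table enforces the contract with named errors", {
  d <- withr::local_tempdir()
  p <- file.path(d, "t.tsv")
  writeLines(c("sample_id\ta\tb", "s1\t1\t2", "s2\t3\t4", "s3\t5\t6"), p)
  tab <- read_feature_table(p, "taxon")
  expect_identical(dim(tab), c(3L, 2L))
  expect_identical(unname(tab$layer), rep("taxon", 2))

  writeLines(c("sample_id\ta\ta", "s1\t1\t2"), p)
  expect_error(read_feature_table(p, "taxon"), "a")
  writeLines(c("sample_id\ta\tb", "s1\t1\tx", "s2\t3\t4"), p)
  expect_error(read_feature_table(p, "taxon"), "sample 's1', feature 'b'")
  writeLines("sample_id\ta\tb", p)
  expect_error(read_feature_table(p, "taxon"), "empty")
})

test_that("write/read round-trips a pilot-scale genus table bit-identically", {
  sim <- generate_cohort(preset_pilot(11))
  tab <- sim$dataset$taxa_genus
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, p)
  back <- read_feature_table(p, "taxon")
  expect_identical(back$values, tab$values)
})

test_that("round-trip is the identity on random continuous tables", {
  for (seed in 1:5) {
    m <- rand_table(7, 5, seed)
    tab <- feature_table(m, "host_gene")
    p <- withr::local_tempfile(fileext = ".tsv")
    write_feature_table(tab, p)
    expect_identical(read_feature_table(p, "host_gene")$values, m)
  }
})

test_that("taxonomy parsing handles rank columns, QIIME strings and gaps", {
  d <- withr::local_tempdir()
  p <- file.path(d, "tax.tsv")
  writeLines(c("taxon_id\tlineage",
               "OTU1\tk__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus",
               "OTU2\tk__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Ruminococcaceae;g__",
               "OTU3\tk__Bacteria;p__Bacteroidetes"), p)
  tm <- read_taxonomy(p)
  expect_identical(tm$genus[tm$taxon_id == "OTU1"], "Lactobacillus")
  # assignment ending at family propagates down as unclassified <family>
  expect_identical(tm$genus[tm$taxon_id == "OTU2"],
                   "unclassified Ruminococcaceae")
  expect_identical(tm$class[tm$taxon_id == "OTU3"],
                   "unclassified Bacteroidetes")
  expect_identical(tm$genus[tm$taxon_id == "OTU3"],
                   "unclassified Bacteroidetes")

  expect_error(taxonomy_map(data.frame(taxon_id = "x", phylum = "",
                                       stringsAsFactors = FALSE)),
               "empty phylum")
  writeLines("taxon_id\tlineage", p)
  expect_error(read_taxonomy(p), "empty")
})

test_that("members_of partitions the genus set by phylum", {
  co <- tiny_cohort()
  a <- members_of(co$taxonomy, "PhyA")
  b <- members_of(co$taxonomy, "PhyB")
  expect_length(a, 3)
  expect_setequal(c(a, b), co$taxonomy$taxon_id)
  expect_warning(res <- members_of(co$taxonomy, "NoSuchPhylum"), "unknown")
  expect_length(res, 0)
})

test_that("align_cohort intersects samples and keeps symptom tables patient-only", {
  co <- tiny_cohort(seed = 2)
  # drop two samples from the taxon table only
  taxa <- subset_table(co$taxa_genus,
                       samples = sample_ids(co$taxa_genus)[-c(1, 2)])
  expect_message(
    ds <- align_cohort(co$expression, taxa, co$taxonomy, co$groups),
    "dropping 2")
  expect_identical(sort(sample_ids(ds$expression)),
                   sort(sample_ids(ds$taxa_genus)))
  expect_error(
    align_cohort(subset_table(co$expression, samples = sample_ids(co$expression)[1:3]),
                 subset_table(co$taxa_genus, samples = sample_ids(co$taxa_genus)[10:12]),
                 co$taxonomy, co$groups),
    "no samples")
})

test_that("synthetic pilot cohort survives alignment with 42/20 group sizes", {
  ds <- generate_cohort(preset_pilot(5))$dataset
  re <- align_cohort(ds$expression, ds$taxa_genus, ds$taxonomy, ds$groups,
                     gi_symptoms = ds$gi_symptoms,
                     psych_symptoms = ds$psych_symptoms)
  expect_identical(unname(table(re$groups)["patient"]), 42L)
  expect_identical(unname(table(re$groups)["control"]), 20L)
  expect_identical(sort(sample_ids(re$gi_symptoms)),
                   sort(names(re$groups)[re$groups == "patient"]))
})

test_that("network export round-trips and rejects unknown formats", {
  rho <- cor(rand_table(20, 6, seed = 3))
  net <- net_from_rho(rho, n = 20, mode = "overview")
  d <- withr::local_tempdir()
  expect_error(write_network(net, file.path(d, "x"), "nope"), "unknown format")

  # empty network: a valid file with zero edges
  empty <- net_from_rho(diag(3), mode = "significant")
  f <- file.path(d, "empty.tsv")
  write_network(empty, f, "edge-tsv")
  expect_identical(nrow(read_network(f, "edge-tsv")$edges), 0L)

  for (seed in 1:4) {
    rho <- cor(rand_table(15, 5, seed = seed))
    net <- net_from_rho(rho, n = 15, mode = "overview")
    fj <- file.path(d, sprintf("n%d.json", seed))
    write_network(net, fj, "json")
    back <- read_network(fj, "json")
    expect_equal(back$rho, net$rho, tolerance = 1e-12)
    expect_equal(back$p, net$p, tolerance = 1e-12)
    expect_identical(back$nodes, net$nodes)
    ft <- file.path(d, sprintf("n%d.tsv", seed))
    write_network(net, ft, "edge-tsv")
    backt <- read_network(ft, "edge-tsv")
    expect_identical(backt$edges$from, net$edges$from)
    expect_identical(backt$edges$rho, net$edges$rho)
    expect_identical(backt$edges$p, net$edges$p)
  }
})

test_that("graphml export carries the 33-node roster", {
  sim <- generate_cohort(preset_pilot(7))
  prep <- suppressMessages(run_step1_prepare(sim$dataset))
  nets <- run_step2_phylum_networks(prep)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(nets$patient$overview, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 33)
  expect_setequal(igraph::vertex_attr(g, "layer"),
                  nets$patient$overview$nodes$layer)
})
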