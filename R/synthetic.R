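#' Latent Gaussian correlation for a Spearman target
#'
#' The generator plants rank-correlation structure through a Gaussian
#' copula: for a bivariate normal with correlation \eqn{r}, the population
#' Spearman correlation is \eqn{\rho_S = (6/\pi)\arcsin(r/2)} regardless of
#' the marginal transforms applied afterwards. This function inverts that
#' map, \eqn{r = 2\sin(\pi\rho_S/6)}, so a requested Spearman target
#' survives the negative-binomial, log-normal and ordinal marginals exactly.
#'
#' @param target_spearman target Spearman correlation(s), each in (-1, 1).
#' @return latent Gaussian correlation(s).
#' @examples
#' latent_from_spearman(0.6)  # 2*sin(0.1*pi) = 0.618...
#' @export
latent_from_spearman <- function(target_spearman) {
  if (any(abs(target_spearman) >= 1))
    stop("|target Spearman| must be < 1")
  2 * sin(pi * target_spearman / 6)
}

#' Simulation specification for a synthetic cohort
#'
#' Defines a two-group cohort with planted cross-layer rank-correlation
#' structure: correlation \emph{blocks} (sets of features with a common
#' pairwise Spearman target) and \emph{cross links} (single pairs), each
#' scoped to patients, controls or both. Marginals are log-normal for
#' gene expression (2^dCt scale), negative binomial with per-sample
#' library-size factors for genus counts, and ordinal quantile-binned
#' scores for symptom instruments. The implied latent correlation matrix of
#' each group is checked for positive definiteness at construction.
#'
#' @param n_patients,n_controls group sizes.
#' @param genes character vector of host-gene ids.
#' @param genera data.frame with columns \code{taxon_id} and \code{phylum}.
#' @param gi_symptoms,psych_symptoms named lists of \code{c(min, max)}
#'   instrument ranges.
#' @param blocks list of \code{list(members=, rho=, scope=)} with scope in
#'   \code{"patients"}, \code{"controls"}, \code{"both"}.
#' @param cross_links data.frame with columns a, b, rho, scope.
#' @param marginals list with per-gene \code{meanlog}/\code{sdlog}, per-genus
#'   \code{mu}/\code{size}, and \code{lib_range} for the log-uniform
#'   library-size factors.
#' @param outliers data.frame (sample, displacement) of samples displaced in
#'   latent space (in latent standard deviations, added to every coordinate).
#' @param seed integer seed governing all randomness of the generated data.
#' @return object of class \code{sim_spec}.
#' @export
sim_spec <- function(n_patients, n_controls, genes, genera,
                     gi_symptoms = list(), psych_symptoms = list(),
                     blocks = list(), cross_links = NULL,
                     marginals = NULL, outliers = NULL, seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 0,
            all(c("taxon_id", "phylum") %in% names(genera)))
  feats <- c(genes, genera$taxon_id, names(gi_symptoms), names(psych_symptoms))
  if (anyDuplicated(feats)) stop("duplicate feature ids across layers")
  if (is.null(cross_links))
    cross_links <- data.frame(a = character(0), b = character(0),
                              rho = numeric(0), scope = character(0),
                              stringsAsFactors = FALSE)
  for (bl in blocks) {
    if (!all(bl$members %in% feats))
      stop("block member(s) not among features: ",
           paste(setdiff(bl$members, feats), collapse = ", "))
    if (abs(bl$rho) >= 1) stop("block Spearman target must be in (-1, 1)")
  }
  if (nrow(cross_links)) {
    miss <- setdiff(c(cross_links$a, cross_links$b), feats)
    if (length(miss)) stop("cross-link feature(s) unknown: ",
                           paste(miss, collapse = ", "))
    if (any(abs(cross_links$rho) >= 1))
      stop("cross-link Spearman targets must be in (-1, 1)")
  }
  if (is.null(marginals)) {
    ng <- length(genes); nt <- nrow(genera)
    marginals <- list(
      gene_meanlog = stats::setNames(rep(0, ng), genes),
      gene_sdlog = stats::setNames(rep(1, ng), genes),
      genus_mu = stats::setNames(rep(50, nt), genera$taxon_id),
      genus_size = stats::setNames(rep(5, nt), genera$taxon_id),
      lib_range = c(0.5, 2))
  }
  spec <- structure(list(n_patients = n_patients, n_controls = n_controls,
                         genes = genes, genera = genera,
                         gi_symptoms = gi_symptoms,
                         psych_symptoms = psych_symptoms,
                         blocks = blocks, cross_links = cross_links,
                         marginals = marginals, outliers = outliers,
                         seed = as.integer(seed)),
                    class = "sim_spec")
  # fail fast if either group's implied latent matrix is not PD
  for (g in c("patients", "controls")) latent_sigma(spec, g)
  spec
}

sim_features <- function(spec) {
  c(spec$genes, spec$genera$taxon_id,
    names(spec$gi_symptoms), names(spec$psych_symptoms))
}

# Latent Gaussian correlation matrix for one group ("patients"/"controls"),
# assembled from blocks and cross links in scope and checked PD.
latent_sigma <- function(spec, group) {
  feats <- sim_features(spec)
  d <- length(feats)
  S <- diag(d)
  dimnames(S) <- list(feats, feats)
  in_scope <- function(scope) scope == "both" || scope == group
  for (bl in spec$blocks) {
    if (!in_scope(bl$scope %||% "both")) next
    idx <- match(bl$members, feats)
    r <- latent_from_spearman(bl$rho)
    S[idx, idx] <- r
    diag(S)[idx] <- 1
  }
  cl <- spec$cross_links
  if (nrow(cl)) for (k in seq_len(nrow(cl))) {
    if (!in_scope(cl$scope[k])) next
    i <- match(cl$a[k], feats); j <- match(cl$b[k], feats)
    S[i, j] <- S[j, i] <- latent_from_spearman(cl$rho[k])
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8)
    stop(sprintf(
      "latent correlation matrix for %s is not positive definite (min eigenvalue %.3g); offending structure: %d block(s), %d cross link(s)",
      group, ev, length(spec$blocks), nrow(cl)))
  S
}

# U(0,1) -> ordinal instrument score on [lo, hi] via equal quantile cuts.
ordinal_bin <- function(u, lo, hi) {
  pmin(lo + floor(u * (hi - lo + 1)), hi)
}

#' Generate a synthetic cohort
#'
#' Draws a latent multivariate Gaussian per group from the spec's implied
#' correlation matrix, displaces any planted outliers in latent space, and
#' pushes the Gaussian through the copula to the stated marginals: log-normal
#' expression, negative-binomial genus counts subsequently scaled by
#' per-sample library-size factors (drawn log-uniformly, so the
#' median-of-ratios normalization has real work to do) and re-rounded to
#' integers, and quantile-binned ordinal symptom scores. Symptom tables are
#' generated for patients only, mirroring cohorts whose controls are
#' enrolled symptom-free. Deterministic for a given spec seed.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return list with \code{dataset} (a \code{\link{cohort_dataset}}) and
#'   \code{truth} (block memberships, cross links, latent matrices, library
#'   factors, planted outlier ids).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  feats <- sim_features(spec)
  d <- length(feats)
  sn_p <- sprintf("P%02d", seq_len(spec$n_patients))
  sn_c <- if (spec$n_controls > 0) sprintf("C%02d", seq_len(spec$n_controls)) else character(0)
  set.seed(spec$seed)
  draw_group <- function(n, sigma, ids) {
    Z <- matrix(stats::rnorm(n * d), n, d) %*% chol(sigma)
    dimnames(Z) <- list(ids, feats)
    Z
  }
  Sp <- latent_sigma(spec, "patients")
  Sc <- latent_sigma(spec, "controls")
  Zp <- draw_group(spec$n_patients, Sp, sn_p)
  Zc <- if (spec$n_controls > 0) draw_group(spec$n_controls, Sc, sn_c) else NULL
  Z <- rbind(Zp, Zc)
  if (!is.null(spec$outliers) && nrow(spec$outliers)) {
    for (k in seq_len(nrow(spec$outliers))) {
      s <- spec$outliers$sample[k]
      if (!s %in% rownames(Z)) stop("unknown outlier sample: ", s)
      Z[s, ] <- Z[s, ] + spec$outliers$displacement[k]
    }
  }
  # clamp away from {0,1} so extreme latent displacements (planted outliers)
  # map to large-but-finite marginal values
  U <- pmin(pmax(stats::pnorm(Z), 1e-12), 1 - 1e-12)
  mg <- spec$marginals
  sn <- rownames(Z)
  # expression: log-normal on the 2^dCt scale
  expr <- sapply(spec$genes, function(g)
    stats::qlnorm(U[, g], mg$gene_meanlog[g], mg$gene_sdlog[g]))
  dimnames(expr) <- list(sn, spec$genes)
  # genus counts: negative binomial, then library-size scaling
  lib <- exp(stats::runif(length(sn), log(mg$lib_range[1]), log(mg$lib_range[2])))
  names(lib) <- sn
  counts <- sapply(spec$genera$taxon_id, function(g)
    stats::qnbinom(U[, g], mu = mg$genus_mu[g], size = mg$genus_size[g]))
  counts <- round(counts * lib)
  dimnames(counts) <- list(sn, spec$genera$taxon_id)
  # symptoms: patients only, ordinal on instrument ranges
  bin_table <- function(defs, layer) {
    if (length(defs) == 0L) return(NULL)
    m <- sapply(names(defs), function(s)
      ordinal_bin(U[sn_p, s], defs[[s]][1], defs[[s]][2]))
    dimnames(m) <- list(sn_p, names(defs))
    feature_table(m, layer)
  }
  groups <- stats::setNames(c(rep("patient", length(sn_p)),
                              rep("control", length(sn_c))), sn)
  taxmap <- taxonomy_map(data.frame(taxon_id = spec$genera$taxon_id,
                                    phylum = spec$genera$phylum,
                                    genus = spec$genera$taxon_id,
                                    stringsAsFactors = FALSE))
  ds <- cohort_dataset(
    expression = feature_table(expr, "host_gene", group = groups),
    taxa_genus = feature_table(counts, "taxon", group = groups),
    taxonomy = taxmap, groups = groups,
    gi_symptoms = bin_table(spec$gi_symptoms, "gi_symptom"),
    psych_symptoms = bin_table(spec$psych_symptoms, "psych_symptom"))
  truth <- list(blocks = spec$blocks, cross_links = spec$cross_links,
                sigma_patients = Sp, sigma_controls = Sc,
                library_factors = lib,
                outliers = if (is.null(spec$outliers)) character(0)
                           else spec$outliers$sample)
  list(dataset = ds, truth = truth)
}

#' Pilot-scale preset specification
#'
#' A fully parameterized \code{\link{sim_spec}} emulating the structure of a
#' two-group IBS-type pilot cohort: 42 patients and 20 controls; 22 host
#' genes; 188 genera across 11 phyla; 5 GI symptom domain scores (1-7) and 4
#' psychological scores on their instrument ranges. Planted structure, at
#' fixed effect sizes:
#' \itemize{
#'   \item a patient-only "permeability"-type block of 4 genes (PAR2, OCLN,
#'     TJP1, TLR4) at pairwise Spearman 0.6, negatively coupled (-0.5) to
#'     the genera of two small phyla -- a 3-genus phylum (Chlamydiae-like)
#'     and a single-genus phylum (Lentisphaerae-like, which triggers the
#'     de-summarization skip) -- and negatively coupled (-0.4) to one GI
#'     symptom (satiety) and two psychological scores (depression, fatigue);
#'   \item an "immune-enteroendocrine"-type block of 6 genes (CHGA, CHGB,
#'     SCG3, TLR2, TLR6, TLR9) at 0.6 in both groups, coupled (-0.5) to a
#'     4-genus phylum in patients only.
#' }
#' Secondary correlations among the attached variables are set to their
#' factor-implied values so the latent matrix stays positive definite.
#' About 20\% of the unplanted genera are sparse (tiny negative-binomial
#' means), so some are absent from most samples and the zero-hit removal
#' rule has work to do.
#'
#' @param seed integer seed (drives marginal parameter draws and, via the
#'   spec, the generated data).
#' @return a \code{\link{sim_spec}}.
#' @export
preset_pilot <- function(seed = 1L) {
  genes <- c("CLD1", "DOUX2", "PAR2", "FFAR2", "FFAR3", "IL10", "IL8",
             "OCLN", "SCG2", "SLC6A4", "TJP1", "TLR4", "TNFa", "MUC",
             "NOX1", "TPH1", "CHGA", "CHGB", "SCG3", "TLR2", "TLR6", "TLR9")
  phyla <- c(Firmicutes = 95L, Bacteroidetes = 30L, Proteobacteria = 22L,
             Actinobacteria = 15L, unclassified_Bacteria = 8L,
             Verrucomicrobia = 5L, Fusobacteria = 4L, Euryarchaeota = 3L,
             Chlamydiae = 3L, Tenericutes = 2L, Lentisphaerae = 1L)
  genera <- do.call(rbind, lapply(names(phyla), function(ph) {
    ids <- switch(ph,
      Lentisphaerae = "Victivallis",
      Tenericutes = c("Anaeroplasma", "Asteroleplasma"),
      Chlamydiae = sprintf("Chlamydiae_g%d", 1:3),
      Fusobacteria = sprintf("Fusobacteria_g%d", 1:4),
      Firmicutes = c("Lactobacillus", "Lactococcus", "Finegoldia",
                     "Peptoniphilus", "Flavonifractor", "Turicibacter",
                     "Acidaminococcus", "Ruminococcus_II",
                     sprintf("Firmicutes_g%d", 9:95)),
      sprintf("%s_g%d", ph, seq_len(phyla[ph])))
    data.frame(taxon_id = ids, phylum = ph, stringsAsFactors = FALSE)
  }))
  gi <- list(abdominal_pain = c(1, 7), constipation = c(1, 7),
             diarrhea = c(1, 7), bloating = c(1, 7), satiety = c(1, 7))
  psych <- list(HAD_anxiety = c(0, 21), HAD_depression = c(0, 21),
                VSI = c(0, 75), MFI_general_fatigue = c(4, 20))

  blockA <- c("PAR2", "OCLN", "TJP1", "TLR4")
  blockB <- c("CHGA", "CHGB", "SCG3", "TLR2", "TLR6", "TLR9")
  chlam <- sprintf("Chlamydiae_g%d", 1:3)
  fuso <- sprintf("Fusobacteria_g%d", 1:4)
  taxaA <- c(chlam, "Victivallis")
  sympA <- c("satiety", "HAD_depression", "MFI_general_fatigue")
  blocks <- list(
    list(members = blockA, rho = 0.6, scope = "patients"),
    list(members = blockB, rho = 0.6, scope = "both"),
    list(members = chlam, rho = 0.6, scope = "both"),
    list(members = fuso, rho = 0.6, scope = "both"))
  link <- function(a, b, rho, scope = "patients")
    expand.grid(a = a, b = b, rho = rho, scope = scope,
                stringsAsFactors = FALSE)
  # secondary (factor-implied) correlations among attached variables keep the
  # one-factor-per-block geometry and hence positive definiteness:
  # taxon loading -0.5/sqrt(0.6), symptom loading -0.4/sqrt(0.6)
  cross_links <- rbind(
    link(taxaA, blockA, -0.5),
    link(sympA, blockA, -0.4),
    link(fuso, blockB, -0.5),
    link("Victivallis", chlam, 0.42),           # taxon-taxon, implied 0.417
    link(sympA, taxaA, 0.33),                   # symptom-taxon, implied 0.333
    data.frame(a = c("satiety", "satiety", "HAD_depression"),
               b = c("HAD_depression", "MFI_general_fatigue",
                     "MFI_general_fatigue"),
               rho = 0.27, scope = "patients",  # symptom-symptom, implied 0.267
               stringsAsFactors = FALSE))

  set.seed(child_seed(seed, 777))
  nt <- nrow(genera)
  planted <- c(taxaA, fuso)
  core <- setdiff(genera$taxon_id, planted)
  sparse <- sample(core, round(0.2 * length(core)))
  mu <- stats::setNames(exp(stats::runif(nt, log(10), log(300))), genera$taxon_id)
  size <- stats::setNames(stats::runif(nt, 2, 10), genera$taxon_id)
  mu[sparse] <- stats::runif(length(sparse), 0.02, 0.3)
  size[sparse] <- 0.5
  mu[planted] <- stats::runif(length(planted), 60, 150)
  size[planted] <- stats::runif(length(planted), 6, 12)
  marginals <- list(
    gene_meanlog = stats::setNames(stats::rnorm(length(genes), 0, 0.5), genes),
    gene_sdlog = stats::setNames(stats::runif(length(genes), 0.6, 1.1), genes),
    genus_mu = mu, genus_size = size, lib_range = c(0.5, 2))
  sim_spec(n_patients = 42L, n_controls = 20L, genes = genes, genera = genera,
           gi_symptoms = gi, psych_symptoms = psych, blocks = blocks,
           cross_links = cross_links, marginals = marginals,
           seed = child_seed(seed, 101))
}
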