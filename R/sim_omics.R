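#' Configuration for the synthetic cross-omics fixture
#'
#' Builds the ground truth for the integration pipeline: a DEG table (as an
#' external differential-expression tool would emit), validated gene-miRNA
#' edges, lncRNA-target edges, pathway membership sets and a metabolite
#' intensity matrix with an accurate-mass annotation library. One planted
#' pathway is constructed to pass both enrichment arms (its metabolite
#' members are shifted between groups, and exactly one selected miRNA — the
#' planted one — belongs to it), one planted lncRNA is chained to it through
#' a differentially expressed gene, and decoy pathways pass neither arm.
#'
#' @param n_genes Total genes (first `n_de` are differentially expressed).
#' @param n_de Number of planted DEGs.
#' @param n_mirnas miRNA universe size (all appear in the edge list; with a
#'   realistically large universe a single-miRNA pathway overlap is still
#'   statistically surprising).
#' @param n_metabolites Annotated metabolite universe (levels 1/2a); large
#'   enough, relative to the planted perturbation, that per-sample median
#'   normalization stays valid.
#' @param n_extra_metabolites Additional library metabolites at levels
#'   2b/3, excluded by the level filter.
#' @param n_samples_per_group Metabolomics samples per group.
#' @param metab_shift Group shift of planted metabolites, in SD units of
#'   the log-scale intensity noise.
#' @param planted If `FALSE`, a decoy-only fixture: no metabolite shift, no
#'   planted miRNA targeting, no planted lncRNA link (negative control).
#' @param planted_pathway Name of the planted pathway; must be one of
#'   `pathway_names`.
#' @param pathway_names Names of all pathways in the database.
#' @param seed Default seed.
#' @return An object of class `omics_sim_config`.
#' @export
omics_sim_config <- function(n_genes = 600L, n_de = 10L, n_mirnas = 1000L,
                             n_metabolites = 60L, n_extra_metabolites = 10L,
                             n_samples_per_group = 12L, metab_shift = 3,
                             planted = TRUE,
                             planted_pathway = "amino_acid_metabolism",
                             pathway_names = c("amino_acid_metabolism",
                                               "glycerophospholipid_metabolism",
                                               "tryptophan_metabolism",
                                               "nucleotide_metabolism",
                                               "tca_cycle"),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_de = as.integer(n_de),
              n_mirnas = as.integer(n_mirnas),
              n_metabolites = as.integer(n_metabolites),
              n_extra_metabolites = as.integer(n_extra_metabolites),
              n_samples_per_group = as.integer(n_samples_per_group),
              metab_shift = metab_shift, planted = isTRUE(planted),
              planted_pathway = planted_pathway,
              pathway_names = pathway_names, seed = as.integer(seed))
  check_that(cfg$n_de < cfg$n_genes, "n_de", "must be < n_genes")
  check_that(cfg$n_mirnas >= 20, "n_mirnas", "must be >= 20")
  if (!cfg$planted_pathway %in% cfg$pathway_names) {
    stop(sprintf("planted pathway '%s' absent from pathway_db",
                 cfg$planted_pathway))
  }
  structure(cfg, class = "omics_sim_config")
}

#' Simulate the cross-omics fixture
#'
#' @param cfg An [omics_sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`); identical
#'   `(cfg, seed)` give identical fixtures.
#' @return A list of class `omics_fixture` with elements `deg_table`,
#'   `mirna_edges`, `lnc_edges`, `pathway_db` (named list with `genes`,
#'   `mirnas`, `metabolites` per pathway), `metabolite_matrix`, `features`,
#'   `annotation_library`, `groups`, and the ground truth in `truth`
#'   (`planted_pathway`, `planted_mirna`, `planted_lncrna`,
#'   `planted_metabolites`).
#' @export
simulate_omics_fixture <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "omics_sim_config"))
  set.seed(as.integer(seed))
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  de_genes <- genes[seq_len(cfg$n_de)]
  null_genes <- setdiff(genes, de_genes)
  mirnas <- sprintf("miR-%04d", seq_len(cfg$n_mirnas))
  planted_mirna <- mirnas[1]
  helper_mirnas <- mirnas[2:3]        # selected alongside the planted miRNA
  decoy_mirnas <- mirnas[-(1:3)]

  # DEG table shaped like differential-expression tool output
  deg_table <- data.frame(
    gene_id = genes,
    log2fc = c(sample(c(-1, 1), cfg$n_de, replace = TRUE) *
                 runif(cfg$n_de, 1.5, 3),
               rnorm(length(null_genes), 0, 0.35)),
    p_adj = c(runif(cfg$n_de, 1e-6, 1e-3),
              runif(length(null_genes), 0, 1)),
    stringsAsFactors = FALSE)

  # Validated gene-miRNA edges: planted miRNA hits several DEGs, helpers one
  # DEG each, decoys only null genes.
  planted_targets <- if (cfg$planted) de_genes[1:4] else
    sample(null_genes, 4)
  edges <- rbind(
    data.frame(gene = planted_targets, mirna = planted_mirna,
               stringsAsFactors = FALSE),
    data.frame(gene = de_genes[4 + seq_along(helper_mirnas) %% (cfg$n_de - 4)],
               mirna = helper_mirnas, stringsAsFactors = FALSE),
    data.frame(gene = sample(null_genes, length(decoy_mirnas), replace = TRUE),
               mirna = decoy_mirnas, stringsAsFactors = FALSE))

  # lncRNA edges: planted lncRNA regulates a DEG inside the planted
  # pathway's gene set; decoy targets a gene outside the network.
  lnc_edges <- rbind(
    data.frame(lncrna = "LNC-P1",
               target = if (cfg$planted) planted_targets[1] else null_genes[1],
               mechanism = "regulates", direction = "up",
               stringsAsFactors = FALSE),
    data.frame(lncrna = "LNC-D1", target = null_genes[2],
               mechanism = "associates", direction = "down",
               stringsAsFactors = FALSE))

  # Metabolites: universe at annotation levels 1/2a plus extras filtered
  # out; planted shifts are bidirectional so per-sample median
  # normalization remains valid
  mets <- sprintf("MET%03d", seq_len(cfg$n_metabolites +
                                       cfg$n_extra_metabolites))
  core <- mets[seq_len(cfg$n_metabolites)]
  extra <- setdiff(mets, core)
  planted_mets <- core[1:10]
  shifted_mets <- planted_mets[1:8]

  # Pathway membership: planted pathway holds the planted miRNA (and only
  # that one of the selected miRNAs), genes targeted by it, and the planted
  # metabolites; decoys get disjoint members.
  pw <- cfg$pathway_names
  other_mets <- setdiff(core, planted_mets)
  pathway_db <- setNames(vector("list", length(pw)), pw)
  pathway_db[[cfg$planted_pathway]] <- list(
    genes = planted_targets[1:3],
    mirnas = planted_mirna,
    metabolites = planted_mets)
  decoy_pw <- setdiff(pw, cfg$planted_pathway)
  for (i in seq_along(decoy_pw)) {
    pathway_db[[decoy_pw[i]]] <- list(
      genes = sample(null_genes, 3),
      mirnas = sample(decoy_mirnas, 8),
      metabolites = sample(c(other_mets, extra), 6))
  }

  # Intensity matrix (feature x sample) on a log-normal scale
  n_s <- cfg$n_samples_per_group
  groups <- rep(c("case", "control"), each = n_s)
  base <- runif(length(mets), 4, 6)   # log10 baseline per metabolite
  logx <- matrix(rnorm(length(mets) * 2 * n_s, 0, 0.15),
                 length(mets), 2 * n_s) + base
  if (cfg$planted) {
    shift_rows <- match(shifted_mets, mets)
    sgn <- rep(c(1, -1), length.out = length(shift_rows))
    logx[shift_rows, groups == "case"] <-
      logx[shift_rows, groups == "case"] + sgn * cfg$metab_shift * 0.15
  }
  metabolite_matrix <- 10^logx
  rownames(metabolite_matrix) <- mets
  colnames(metabolite_matrix) <- sprintf("%s%02d", ifelse(groups == "case",
                                                          "P", "HD"),
                                         c(seq_len(n_s), seq_len(n_s)))

  # Accurate-mass library and observed m/z features ([M+H]+ with <= 1 ppm
  # error); a few decoy features sit 50 ppm off and stay unannotated.
  mass <- runif(length(mets), 100, 600)
  annotation_library <- data.frame(
    metabolite_id = mets,
    monoisotopic_mass = mass,
    annotation_level = c(sample(c("1", "2a"), cfg$n_metabolites,
                                replace = TRUE),
                         sample(c("2b", "3"), cfg$n_extra_metabolites,
                                replace = TRUE)),
    stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_along(mets)),
    mz = (mass + 1.007276) * (1 + runif(length(mets), -1, 1) * 1e-6),
    rt = runif(length(mets), 30, 600),
    metabolite_id = mets,
    stringsAsFactors = FALSE)
  decoys <- data.frame(
    feature_id = sprintf("FX%02d", 1:5),
    mz = (runif(5, 100, 600) + 1.007276) * (1 + 5e-5),
    rt = runif(5, 30, 600),
    metabolite_id = NA_character_,
    stringsAsFactors = FALSE)

  structure(list(
    deg_table = deg_table, mirna_edges = edges, lnc_edges = lnc_edges,
    pathway_db = pathway_db, metabolite_matrix = metabolite_matrix,
    features = rbind(features, decoys),
    annotation_library = annotation_library, groups = groups,
    truth = list(planted_pathway = if (cfg$planted) cfg$planted_pathway else NULL,
                 planted_mirna = if (cfg$planted) planted_mirna else NULL,
                 planted_lncrna = if (cfg$planted) "LNC-P1" else NULL,
                 planted_metabolites = if (cfg$planted) shifted_mets else NULL)),
    class = "omics_fixture")
}

#' Run the cross-omics integration pipeline on a fixture
#'
#' End-to-end: DEG filtering, miRNA/lncRNA network construction, miRNA
#' pathway over-representation, metabolomics normalization and per-
#' metabolite rank-sum testing with BH adjustment, m/z annotation,
#' metabolite-set enrichment (levels 1/2a, at least `min_sig` significant
#' members), and pathway-intersection biomarker nomination. The top-k
#' feature route (a simplified mummichog: most significant m/z features,
#' accurate-mass annotation, pathway over-representation) is also computed
#' and reported.
#'
#' @param fx An `omics_fixture` (or an equivalent list of inputs).
#' @param p_cut,fc_cut DEG cut-offs (defaults 0.05 and 2).
#' @param alpha Significance level (default 0.05).
#' @param min_sig Minimum significant metabolites per pathway (default 3).
#' @param top_k Feature count for the mummichog-style route (default 10).
#' @return List with `degs`, `network`, `mirna_enrich`, `metab_stats`,
#'   `annotated`, `metab_enrich`, `mummichog_enrich`, `candidates`.
#' @export
run_integration <- function(fx, p_cut = 0.05, fc_cut = 2, alpha = 0.05,
                            min_sig = 3, top_k = 10) {
  degs <- filter_degs(fx$deg_table, p_cut = p_cut, fc_cut = fc_cut)
  network <- map_mirnas(c(degs$up, degs$down), fx$mirna_edges)
  network <- link_lncrnas(network, fx$lnc_edges)
  vt <- if (igraph::vcount(network)) igraph::V(network)$type else character(0)
  selected_mirnas <- if (length(vt)) {
    igraph::V(network)$name[vt == "mirna"]
  } else character(0)

  mirna_sets <- lapply(fx$pathway_db, `[[`, "mirnas")
  mirna_enrich <- ora(selected_mirnas, mirna_sets,
                      universe = unique(fx$mirna_edges$mirna), alpha = alpha)

  norm <- norm_metabolites(fx$metabolite_matrix)
  case <- fx$groups == "case"
  metab_stats <- data.frame(
    metabolite_id = rownames(norm),
    p = apply(norm, 1, function(v) rank_sum_test(v[case], v[!case])$p),
    effect = rowMeans(norm[, case, drop = FALSE]) -
      rowMeans(norm[, !case, drop = FALSE]),
    stringsAsFactors = FALSE)
  metab_stats$p_adj <- adjust_p(metab_stats$p, "bh")

  annotated <- annotate_mz(fx$features, fx$annotation_library, ppm = 3)
  annotated <- merge(annotated, metab_stats, by = "metabolite_id")
  annotated$significant <- annotated$p_adj < alpha

  metab_enrich <- metabolite_ora(annotated, fx$pathway_db, min_sig = min_sig,
                                 alpha = alpha)

  # Simplified mummichog route: top-k features by significance, annotated
  # at 3 ppm, then pathway over-representation with the same >= min_sig rule
  feat_stats <- unique(annotated[, c("feature_id", "p", "effect")])
  top <- top_features(feat_stats, k = min(top_k, nrow(feat_stats)))
  top_ann <- annotated[annotated$feature_id %in% top$feature_id, , drop = FALSE]
  top_ann$significant <- TRUE
  mummichog_enrich <- metabolite_ora(
    rbind(top_ann,
          within(annotated[!annotated$feature_id %in% top$feature_id, ,
                           drop = FALSE], significant <- FALSE)),
    fx$pathway_db, min_sig = min_sig, alpha = alpha)

  candidates <- intersect_nominate(mirna_enrich, metab_enrich, network,
                                   fx$pathway_db, selected_mirnas)
  list(degs = degs, network = network, mirna_enrich = mirna_enrich,
       metab_stats = metab_stats, annotated = annotated,
       metab_enrich = metab_enrich, mummichog_enrich = mummichog_enrich,
       candidates = candidates)
}
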