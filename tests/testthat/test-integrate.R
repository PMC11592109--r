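test_that("DEG filtering applies strict printed cut-offs", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(1.5, 3, -2, 1),
    p_adj = c(0.04, 0.05, 0.01, 0.01),
    stringsAsFactors = FALSE)
  out <- filter_degs(tab)
  expect_equal(out$up, "g1")            # 1.5 > log2(2)
  expect_equal(out$down, "g3")
  expect_false("g2" %in% out$table$gene_id)   # p_adj == 0.05 is dropped
  expect_false("g4" %in% out$table$gene_id)   # |lfc| == 1 is dropped
  empty <- filter_degs(tab[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("miRNA mapping restricts to DEGs and drops isolated nodes", {
  edges <- data.frame(gene = c("g1", "g1", "g2", "g9"),
                      mirna = c("m1", "m2", "m3", "m4"),
                      stringsAsFactors = FALSE)
  g <- map_mirnas(c("g1", "g2"), edges)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 3)
  expect_false("m4" %in% igraph::V(g)$name)
  empty <- map_mirnas(c("gX"), edges)
  expect_equal(igraph::vcount(empty), 0)
})

test_that("lncRNA linking validates edge types and reachability", {
  net <- map_mirnas("g1", data.frame(gene = "g1", mirna = "m1"))
  lnc <- data.frame(lncrna = c("L1", "L2"), target = c("g1", "gZ"),
                    mechanism = c("regulates", "regulates"),
                    direction = c("up", "down"), stringsAsFactors = FALSE)
  g <- link_lncrnas(net, lnc)
  expect_true("L1" %in% igraph::V(g)$name)
  expect_false("L2" %in% igraph::V(g)$name)
  expect_equal(igraph::V(g)$type[igraph::V(g)$name == "L1"], "lncrna")
  bad <- data.frame(lncrna = "L1", target = "g1", mechanism = "teleports",
                    direction = "up")
  expect_error(link_lncrnas(net, bad), "unknown edge type")
})

test_that("hypergeometric over-representation matches enumeration", {
  uni <- paste0("i", 1:10)
  res <- ora(paste0("i", 1:4), list(pw = paste0("i", c(1:4, 10))), uni)
  expect_equal(res$p_raw, 5 / 210, tolerance = 1e-12)
  none <- ora("i9", list(pw = paste0("i", 1:4)), uni)
  expect_equal(none$p_raw, 1)
  sat <- ora(uni, list(pw = paste0("i", 1:5)), uni)
  expect_equal(sat$p_raw, 1)
  expect_error(ora("zz", list(pw = "i1"), uni), "universe")
  set.seed(11)
  for (i in 1:20) {
    N <- sample(5:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    selected <- paste0("i", sample(N, n))
    res <- ora(selected, list(pw = paste0("i", seq_len(K))), paste0("i", 1:N))
    expect_equal(res$p_raw, brute_force_hyper_p(N, K, n, res$overlap_k),
                 tolerance = 1e-10)
  }
})

test_that("p-value adjustment reproduces step-up and Bonferroni arithmetic", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(adjust_p(0.02, "bonferroni"), 0.02)
  expect_equal(adjust_p(c(0.03, 0.6), "bonferroni"), c(0.06, 1))
  set.seed(12)
  p <- runif(30)
  padj <- adjust_p(p, "bh")
  expect_true(all(padj >= p))
  expect_true(all(padj <= 1))
  # significance sets shrink monotonically as alpha decreases
  expect_true(all(which(padj < 0.01) %in% which(padj < 0.05)))
  expect_error(adjust_p(c(0.2, 1.4)), "0, 1")
})

test_that("metabolite normalization follows median / log10 / Pareto", {
  m <- matrix(c(2, 4, 8,
                2, 4, 8), nrow = 2, byrow = TRUE)
  rownames(m) <- c("f1", "f2"); colnames(m) <- c("s1", "s2", "s3")
  # after the median step each sample becomes {0.5, 1, 2} column-wise
  med <- sweep(m, 2, apply(m, 2, median), "/")
  expect_equal(unname(med[, 1]), c(1, 1))
  # full contract against an explicit composition
  set.seed(13)
  x <- matrix(10^runif(24, 3, 5), 4, 6)
  rownames(x) <- paste0("f", 1:4)
  out <- norm_metabolites(x)
  manual <- log10(sweep(x, 2, apply(x, 2, median), "/"))
  manual <- sweep(manual, 1, rowMeans(manual), "-")
  manual <- sweep(manual, 1, sqrt(apply(
    log10(sweep(x, 2, apply(x, 2, median), "/")), 1, sd)), "/")
  expect_equal(unclass(out), manual, ignore_attr = TRUE)
  # Pareto arithmetic on a {1,2,3}-like feature: (x - 2) / sqrt(1)
  v <- c(1, 2, 3)
  expect_equal((v - mean(v)) / sqrt(sd(v)), c(-1, 0, 1))
})

test_that("normalization guards zeros and constant features", {
  x <- matrix(c(0, 2, 4, 4, 4, 4), 2, 3, byrow = TRUE)
  rownames(x) <- c("f1", "f2")
  out <- norm_metabolites(x)
  expect_equal(attr(out, "n_imputed"), 1)
  # a feature proportional to every sample median is constant after
  # normalization: flagged, centred at zero, not scaled
  y <- outer(c(1, 2, 4), c(1, 2, 3))
  rownames(y) <- paste0("f", 1:3)
  outy <- norm_metabolites(y)
  expect_setequal(attr(outy, "constant_features"), rownames(y))
  expect_equal(unname(outy["f2", ]), rep(0, 3))
})

test_that("m/z annotation respects the ppm window and flags ambiguity", {
  lib <- data.frame(metabolite_id = c("glc", "near", "far"),
                    monoisotopic_mass = c(180.0634, 180.06345, 200),
                    annotation_level = c("1", "2a", "1"),
                    stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = c("f1", "f2"),
                      mz = c(180.0634 + 1.007276, (200 + 1.007276) * (1 + 1e-5)),
                      stringsAsFactors = FALSE)
  ann <- annotate_mz(feats, lib, ppm = 3)
  expect_true(all(ann$feature_id == "f1"))      # f2 is 10 ppm off
  expect_setequal(ann$metabolite_id, c("glc", "near"))
  expect_true(all(ann$ambiguous))
  exact <- annotate_mz(feats[1, ], lib[c(1, 3), ], ppm = 3)
  expect_false(exact$ambiguous)
  expect_error(annotate_mz(feats, lib[0, ]), "empty")
})

test_that("metabolite enrichment enforces level and minimum-overlap rules", {
  ann <- data.frame(
    metabolite_id = paste0("M", 1:12),
    annotation_level = c(rep("1", 6), rep("2a", 3), rep("2b", 3)),
    significant = c(rep(TRUE, 6), rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  db <- list(big = list(metabolites = paste0("M", 1:6)),
             small = list(metabolites = paste0("M", c(1, 2, 8))),
             shadow = list(metabolites = paste0("M", 10:12)))
  res <- metabolite_ora(ann, db, min_sig = 3)
  expect_true("big" %in% res$pathway_id)
  expect_false("small" %in% res$pathway_id)   # only 2 significant members
  expect_false("shadow" %in% res$pathway_id)  # level 2b excluded entirely
  expect_true(res$significant[res$pathway_id == "big"])
})

test_that("top-feature selection ranks by p, then effect, then id", {
  fs <- data.frame(feature_id = sprintf("f%02d", 1:15),
                   p = c(rep(0.001, 3), rep(0.5, 12)),
                   effect = c(1, 3, 2, seq(0.1, 1.2, length.out = 12)),
                   stringsAsFactors = FALSE)
  top <- top_features(fs, k = 10)
  expect_equal(nrow(top), 10)
  expect_equal(top$feature_id[1:3], c("f02", "f03", "f01"))
  expect_warning(all15 <- top_features(fs, k = 20), "available")
  expect_equal(nrow(all15), 15)
  expect_error(top_features(fs, k = 0), "k")
})

test_that("pathway intersection nominates along evidence chains", {
  me <- data.frame(pathway_id = c("A", "B"), significant = c(TRUE, TRUE))
  mb <- data.frame(pathway_id = c("B", "C"), significant = c(TRUE, TRUE))
  db <- list(A = list(genes = "g1", mirnas = "m1"),
             B = list(genes = "g2", mirnas = c("m2", "mX")),
             C = list(genes = "g3", mirnas = "m3"))
  net <- map_mirnas(c("g2"), data.frame(gene = "g2", mirna = "m2"))
  net <- link_lncrnas(net, data.frame(lncrna = "L1", target = "g2",
                                      mechanism = "binds", direction = "up"))
  out <- intersect_nominate(me, mb, net, db, selected_mirnas = c("m1", "m2"))
  expect_setequal(out$candidate, c("m2", "L1"))
  expect_true(all(out$pathway_id == "B"))
  none <- intersect_nominate(
    data.frame(pathway_id = "A", significant = TRUE),
    data.frame(pathway_id = "C", significant = TRUE), net, db, "m1")
  expect_equal(nrow(none), 0)
})

test_that("the planted pathway chain survives to nomination", {
  for (s in 1:10) {
    fx <- simulate_omics_fixture(omics_sim_config(), seed = s)
    res <- run_integration(fx)
    expect_setequal(res$candidates$candidate,
                    c(fx$truth$planted_mirna, fx$truth$planted_lncrna))
    expect_true(all(res$candidates$pathway_id == fx$truth$planted_pathway))
  }
  fx0 <- simulate_omics_fixture(omics_sim_config(planted = FALSE), seed = 1)
  expect_equal(nrow(run_integration(fx0)$candidates), 0)
})

test_that("network export writes GraphML and CSV sidecars", {
  tmp <- withr::local_tempdir()
  net <- map_mirnas("g1", data.frame(gene = "g1", mirna = "m1"))
  write_network(net, file.path(tmp, "net"))
  expect_true(file.exists(file.path(tmp, "net.graphml")))
  back <- igraph::read_graph(file.path(tmp, "net.graphml"),
                             format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  nodes <- read.csv(file.path(tmp, "net_nodes.csv"))
  expect_setequal(nodes$name, c("g1", "m1"))
})
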