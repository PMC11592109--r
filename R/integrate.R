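#' Filter differentially expressed genes
#'
#' Keeps genes with `p_adj < p_cut` and `|log2fc| > log2(fc_cut)` (strict
#' inequalities, matching printed cut-offs of adjusted p < 0.05 and fold
#' change > |2|), partitioned by direction.
#'
#' @param table `data.frame` with columns `gene_id`, `log2fc`, `p_adj`.
#' @param p_cut Adjusted-p cut-off (default 0.05).
#' @param fc_cut Fold-change cut-off on the linear scale (default 2).
#' @return List with `up` and `down` character vectors of gene ids, plus
#'   `table` restricted to the kept rows with a `direction` column.
#' @export
filter_degs <- function(table, p_cut = 0.05, fc_cut = 2) {
  keep <- table$p_adj < p_cut & abs(table$log2fc) > log2(fc_cut)
  kept <- table[keep, , drop = FALSE]
  kept$direction <- ifelse(kept$log2fc > 0, "up", "down")
  list(up = kept$gene_id[kept$direction == "up"],
       down = kept$gene_id[kept$direction == "down"],
       table = kept)
}

#' Build the miRNA-to-gene regulatory network
#'
#' Restricts validated gene-miRNA pairs to the filtered DEGs and returns a
#' directed graph with typed nodes (`mirna` regulates `gene`). miRNAs with
#' no retained target are excluded.
#'
#' @param degs Character vector of DEG ids (e.g. `c(up, down)` from
#'   [filter_degs()]).
#' @param edges `data.frame` with columns `gene` and `mirna`.
#' @return An `igraph` directed graph with vertex attribute `type` in
#'   `{gene, mirna}` and edge attribute `etype = "regulates"`.
#' @export
map_mirnas <- function(degs, edges) {
  keep <- edges$gene %in% degs
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) == 0) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$mirna, to = e$gene, etype = "regulates",
               stringsAsFactors = FALSE),
    directed = TRUE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% e$mirna, "mirna", "gene")
  g
}

lnc_edge_types <- c("regulates", "binds", "associates")

#' Extend the network with lncRNA (and TF) associations
#'
#' Adds lncRNA nodes whose targets are already in the network, with typed,
#' direction-labelled edges (the mechanism vocabulary of lncRNA-target
#' resources: regulation, binding/interaction, association). lncRNAs
#' touching nothing in-network are excluded.
#'
#' @param network An `igraph` graph from [map_mirnas()].
#' @param lnc_edges `data.frame` with columns `lncrna`, `target`,
#'   `mechanism` (one of `regulates`, `binds`, `associates`) and
#'   `direction` (free-text direction-of-effect label).
#' @return The extended graph; lncRNA vertices have `type = "lncrna"`.
#' @export
link_lncrnas <- function(network, lnc_edges) {
  bad <- setdiff(unique(lnc_edges$mechanism), lnc_edge_types)
  if (length(bad)) {
    stop(sprintf("unknown edge type(s): %s", paste(bad, collapse = ", ")))
  }
  present <- igraph::V(network)$name
  keep <- lnc_edges$target %in% present
  e <- lnc_edges[keep, , drop = FALSE]
  if (nrow(e) == 0) return(network)
  g <- igraph::add_vertices(network, length(setdiff(unique(e$lncrna), present)),
                            name = setdiff(unique(e$lncrna), present),
                            type = "lncrna")
  for (i in seq_len(nrow(e))) {
    g <- igraph::add_edges(g, c(e$lncrna[i], e$target[i]),
                           etype = e$mechanism[i], direction = e$direction[i])
  }
  g
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric upper-tail test per pathway: with universe size
#' `N`, pathway size `K` (after intersection with the universe), selection
#' size `n` and overlap `k`, the p-value is `P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`.
#'
#' @param selected Character ids of the selected set (must lie in
#'   `universe`).
#' @param pathway_db Named list of character member vectors.
#' @param universe Character ids of the background universe.
#' @param adjust `"bh"` (default) or `"bonferroni"` multiplicity
#'   correction, applied over the returned pathways.
#' @param alpha Significance level on the adjusted p (default 0.05, strict
#'   inequality).
#' @return `data.frame` with `pathway_id`, `overlap_k`, `set_size`,
#'   `selected_n`, `universe_n`, `p_raw`, `p_adj`, `significant`.
#' @export
ora <- function(selected, pathway_db, universe, adjust = c("bh", "bonferroni"),
                alpha = 0.05) {
  adjust <- match.arg(adjust)
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) stop("selected ids must lie in the universe")
  N <- length(universe); n <- length(selected)
  res <- lapply(names(pathway_db), function(pw) {
    members <- intersect(pathway_db[[pw]], universe)
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pw, overlap_k = k, set_size = K,
               selected_n = n, universe_n = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_p(out$p_raw, method = adjust)
  out$significant <- out$p_adj < alpha
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR (order-preserving, monotone) or
#' Bonferroni `min(m * p, 1)`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same order as input.
#' @export
adjust_p <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[[method]])
}

#' Nominate biomarkers from the miRNA/metabolite pathway intersection
#'
#' Implements the cross-omics integration step: pathways significant in both
#' the miRNA-side and the metabolite-side enrichment are intersected; for
#' each shared pathway the over-represented miRNAs belonging to it are
#' emitted as candidates, together with any lncRNA connected (within the
#' regulatory network) to one of the pathway's genes. Each candidate carries
#' its evidence chain.
#'
#' @param mirna_enrich [ora()] result for the miRNA arm (with
#'   `significant`).
#' @param metab_enrich [ora()]/[metabolite_ora()] result for the metabolite
#'   arm.
#' @param network The regulatory graph ([link_lncrnas()] output).
#' @param pathway_db Named list with per-pathway member lists: each entry a
#'   list with (any of) `genes`, `mirnas`, `metabolites` character vectors.
#' @param selected_mirnas miRNAs in the selection that drove the miRNA-side
#'   enrichment.
#' @return `data.frame` of candidates with columns `candidate`, `type`
#'   (`mirna`/`lncrna`), `pathway_id`, `evidence`.
#' @export
intersect_nominate <- function(mirna_enrich, metab_enrich, network,
                               pathway_db, selected_mirnas) {
  shared <- intersect(mirna_enrich$pathway_id[mirna_enrich$significant],
                      metab_enrich$pathway_id[metab_enrich$significant])
  if (length(shared) == 0) {
    return(data.frame(candidate = character(0), type = character(0),
                      pathway_id = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  vnames <- if (igraph::vcount(network) > 0) igraph::V(network)$name else character(0)
  vtypes <- if (igraph::vcount(network) > 0) igraph::V(network)$type else character(0)
  for (pw in shared) {
    members <- pathway_db[[pw]]
    mir <- intersect(selected_mirnas, members$mirnas)
    for (m in mir) {
      rows[[length(rows) + 1]] <- data.frame(
        candidate = m, type = "mirna", pathway_id = pw,
        evidence = sprintf("over-represented in %s; pathway metabolite-enriched", pw),
        stringsAsFactors = FALSE)
    }
    genes_in <- intersect(members$genes, vnames)
    for (g in genes_in) {
      nb <- vnames[as.integer(igraph::neighbors(network, g, mode = "all"))]
      lncs <- nb[vtypes[match(nb, vnames)] == "lncrna"]
      for (l in lncs) {
        rows[[length(rows) + 1]] <- data.frame(
          candidate = l, type = "lncrna", pathway_id = pw,
          evidence = sprintf("linked to gene %s in metabolite-enriched pathway %s",
                             g, pw),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  unique(out)
}
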