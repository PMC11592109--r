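#' Normalize a metabolite intensity matrix
#'
#' Standard untargeted-metabolomics normalization: per-sample division by
#' the sample median, log10 transformation, then Pareto scaling per feature
#' (centre, divide by the square root of the feature SD). Zero intensities
#' are imputed to half the smallest positive value before the log step
#' (reported via the `"n_imputed"` attribute). Zero-variance features are
#' centred but not scaled and flagged via `"constant_features"`.
#'
#' @param matrix Numeric feature x sample intensity matrix (non-negative).
#' @return Normalized matrix of the same shape, with attributes
#'   `"n_imputed"` and `"constant_features"`.
#' @export
norm_metabolites <- function(matrix) {
  x <- as.matrix(matrix)
  if (any(x < 0)) stop("intensities must be >= 0")
  n_imputed <- sum(x == 0)
  if (n_imputed > 0) {
    half_min <- min(x[x > 0]) / 2
    x[x == 0] <- half_min
  }
  med <- apply(x, 2, median)
  if (any(med <= 0)) stop("sample median must be positive")
  x <- sweep(x, 2, med, "/")
  x <- log10(x)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  constant <- which(s == 0)
  scale <- sqrt(s)
  scale[constant] <- 1
  out <- sweep(sweep(x, 1, mu, "-"), 1, scale, "/")
  attr(out, "n_imputed") <- n_imputed
  attr(out, "constant_features") <- rownames(x)[constant] %||% constant
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_adducts <- function() {
  # proton mass 1.007276 Da
  c("[M+H]+" = 1.007276, "[M-H]-" = -1.007276)
}

#' Annotate m/z features against a metabolite library
#'
#' Matches each observed feature m/z to library metabolites under the
#' configured adducts within a relative mass tolerance (3 ppm by default,
#' the accepted deviation for accurate-mass identification). A feature
#' matching several library entries keeps all matches and is flagged
#' ambiguous.
#'
#' @param features `data.frame` with columns `feature_id`, `mz` (and
#'   anything else, carried through).
#' @param library `data.frame` with columns `metabolite_id`,
#'   `monoisotopic_mass`, and optionally `annotation_level`.
#' @param ppm Mass tolerance in parts per million (default 3).
#' @param adducts Named numeric vector of adduct mass offsets; default
#'   `[M+H]+` and `[M-H]-` (positive/negative ionization with polarity
#'   switching).
#' @return `data.frame` with one row per (feature, match):
#'   `feature_id`, `mz`, `metabolite_id`, `adduct`, `ppm_error`,
#'   `ambiguous`, plus `annotation_level` when the library provides it.
#'   Unmatched features are absent.
#' @export
annotate_mz <- function(features, library, ppm = 3,
                        adducts = default_adducts()) {
  if (nrow(library) == 0) stop("empty annotation library")
  if (any(features$mz <= 0)) stop("m/z values must be positive")
  rows <- list()
  for (i in seq_len(nrow(features))) {
    mzobs <- features$mz[i]
    for (a in names(adducts)) {
      expected <- library$monoisotopic_mass + adducts[[a]]
      rel <- abs(mzobs - expected) / expected
      hit <- which(rel <= ppm * 1e-6)
      for (h in hit) {
        r <- data.frame(feature_id = features$feature_id[i], mz = mzobs,
                        metabolite_id = library$metabolite_id[h], adduct = a,
                        ppm_error = rel[h] * 1e6,
                        stringsAsFactors = FALSE)
        if ("annotation_level" %in% names(library)) {
          r$annotation_level <- library$annotation_level[h]
        }
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(feature_id = character(0), mz = numeric(0),
                      metabolite_id = character(0), adduct = character(0),
                      ppm_error = numeric(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  tab <- table(out$feature_id)
  out$ambiguous <- as.vector(tab[out$feature_id] > 1)
  out
}

#' Metabolite pathway over-representation
#'
#' Enrichment over annotated metabolites: only annotation levels in
#' `level_filter` (1 and 2a by default) enter the analysis; the universe is
#' all such metabolites; pathways retaining fewer than `min_sig`
#' significant metabolites are removed before multiplicity adjustment.
#'
#' @param annotated `data.frame` with columns `metabolite_id`,
#'   `annotation_level`, `significant` (logical, e.g. from a rank-sum test
#'   across groups followed by [adjust_p()]).
#' @param pathway_db Named list; each element has a `metabolites` character
#'   vector (or is itself a character vector).
#' @param min_sig Minimum significant metabolites per pathway (default 3).
#' @param level_filter Annotation levels admitted (default `c("1", "2a")`).
#' @param adjust,alpha Passed to [ora()].
#' @return [ora()]-style `data.frame` over the retained pathways.
#' @export
metabolite_ora <- function(annotated, pathway_db, min_sig = 3,
                           level_filter = c("1", "2a"),
                           adjust = "bh", alpha = 0.05) {
  keep <- as.character(annotated$annotation_level) %in% level_filter
  ann <- annotated[keep, , drop = FALSE]
  universe <- unique(ann$metabolite_id)
  selected <- unique(ann$metabolite_id[ann$significant])
  sets <- lapply(pathway_db, function(p) {
    if (is.list(p)) p$metabolites else p
  })
  sets <- lapply(sets, intersect, y = universe)
  n_sig <- vapply(sets, function(m) length(intersect(m, selected)), numeric(1))
  sets <- sets[n_sig >= min_sig]
  if (length(sets) == 0) {
    return(data.frame(pathway_id = character(0), overlap_k = integer(0),
                      set_size = integer(0), selected_n = integer(0),
                      universe_n = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  ora(selected, sets, universe, adjust = adjust, alpha = alpha)
}

#' Select the top-k most significant features
#'
#' Ranks features by raw p-value, breaking ties by larger absolute effect
#' and then by feature id, and returns the first `k` (all features with a
#' warning when fewer than `k` are available).
#'
#' @param feature_stats `data.frame` with columns `feature_id`, `p` and
#'   `effect`.
#' @param k Number of features to keep (default 10).
#' @return The selected rows, in rank order.
#' @export
top_features <- function(feature_stats, k = 10) {
  if (k < 1) stop("k must be >= 1")
  ord <- order(feature_stats$p, -abs(feature_stats$effect),
               feature_stats$feature_id)
  ranked <- feature_stats[ord, , drop = FALSE]
  if (k > nrow(ranked)) {
    warning(sprintf("only %d feature(s) available; returning all", nrow(ranked)))
    k <- nrow(ranked)
  }
  head(ranked, k)
}
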