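#' Read a fluorescence image from TIFF or PNG
#'
#' @param path File path ending in `.tif`/`.tiff` or `.png`.
#' @return Matrix or `H x W x C` array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format: .%s", ext)))
  img
}

#' Write an image as 16-bit TIFF or 8-bit PNG
#'
#' @param image Matrix/array in `[0, 1]`.
#' @param path Destination ending in `.tif`/`.tiff` (16-bit) or `.png`
#'   (8-bit).
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    png = png::writePNG(image, path),
    stop(sprintf("unsupported image format: .%s", ext)))
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG with values {0, 255}
#'
#' @param mask `mask_image` or binary matrix.
#' @param path Destination `.png`.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "mask_image")) mask <- mask$pixels
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read pathway sets from a GMT file
#'
#' Tab-delimited: set name, description, then members. Members may be
#' namespaced as `gene:`, `mirna:`, `metabolite:` prefixes, in which case
#' each pathway becomes a list split by namespace; plain members yield
#' character vectors.
#'
#' @param path GMT file path.
#' @return Named list of member vectors (or per-namespace lists).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: fewer than 3 fields")
    members <- parts[-(1:2)]
    if (any(grepl("^(gene|mirna|metabolite):", members))) {
      ns <- sub(":.*$", "", members)
      id <- sub("^[^:]*:", "", members)
      sets <- split(id, ns)
      out[[parts[1]]] <- list(genes = sets$gene %||% character(0),
                              mirnas = sets$mirna %||% character(0),
                              metabolites = sets$metabolite %||% character(0))
    } else {
      out[[parts[1]]] <- members
    }
  }
  out
}

#' Write pathway sets to a GMT file
#'
#' @param pathway_db Named list; elements either character vectors or
#'   lists with `genes`/`mirnas`/`metabolites` (written with namespace
#'   prefixes).
#' @param path Destination path.
#' @export
write_gmt <- function(pathway_db, path) {
  lines <- vapply(names(pathway_db), function(nm) {
    p <- pathway_db[[nm]]
    members <- if (is.list(p)) {
      c(if (length(p$genes)) paste0("gene:", p$genes),
        if (length(p$mirnas)) paste0("mirna:", p$mirnas),
        if (length(p$metabolites)) paste0("metabolite:", p$metabolites))
    } else p
    paste(c(nm, "na", members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a regulatory network as GraphML plus node/edge tables
#'
#' @param network igraph graph with `type` vertex attribute.
#' @param prefix Output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_nodes.csv`, `<prefix>_edges.csv`.
#' @export
write_network <- function(network, prefix) {
  igraph::write_graph(network, paste0(prefix, ".graphml"), format = "graphml")
  nodes <- data.frame(name = igraph::V(network)$name,
                      type = igraph::V(network)$type,
                      stringsAsFactors = FALSE)
  ed <- igraph::as_data_frame(network, what = "edges")
  utils::write.csv(nodes, paste0(prefix, "_nodes.csv"), row.names = FALSE)
  utils::write.csv(ed, paste0(prefix, "_edges.csv"), row.names = FALSE)
  invisible(prefix)
}
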