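# Dihedral-group transform t in 0..7: rotate by 90*(t %% 4) degrees
# clockwise, horizontal flip first when t >= 4.
d4_transform <- function(m, t) {
  if (t >= 4) m <- m[, ncol(m):1, drop = FALSE]
  for (i in seq_len(t %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

resize_plane <- function(m, px, nearest = FALSE) {
  if (nrow(m) == px && ncol(m) == px) return(m)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(m), w = px, h = px,
    filter = if (nearest) "none" else "bilinear"))
  matrix(out, px, px)
}

#' Cut an image/mask pair into training tiles
#'
#' Tiles are taken in raster order at the given stride and resized to
#' `out_px` x `out_px` (bilinear for the image, nearest-neighbour for the
#' mask so it stays binary). The per-tile count is the number of mask
#' components whose centroid falls inside the tile's half-open pixel
#' interval, so counts over a non-overlapping tiling partition the
#' whole-image count.
#'
#' @param image Matrix in `[0, 1]`.
#' @param mask Binary matrix of the same size (or a `mask_image`).
#' @param tile_px Tile side length in source pixels (`<=` image dims).
#' @param stride_px Stride between tile origins (`>= 1`).
#' @param out_px Output side length after resizing (default 128).
#' @param source_id Identifier recorded in tile provenance.
#' @return A `tile_set`: list of tiles, each with `image`, `mask`, `count`
#'   and `provenance` (`source_id`, `row_off`, `col_off`, `aug_id`);
#'   attributes `tile_px`, `stride_px`, `out_px`, `source_dim`.
#' @export
tile_image <- function(image, mask, tile_px, stride_px = tile_px,
                       out_px = 128L, source_id = "img") {
  if (inherits(mask, "mask_image")) mask <- mask$pixels
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  h <- nrow(image); w <- ncol(image)
  if (tile_px > h || tile_px > w) stop("tile larger than image")
  if (stride_px < 1) stop("stride_px must be >= 1")
  cent <- component_centroids(mask, connectivity = 8L)
  r0s <- seq(1L, h - tile_px + 1L, by = stride_px)
  c0s <- seq(1L, w - tile_px + 1L, by = stride_px)
  tiles <- list()
  for (r0 in r0s) {
    for (c0 in c0s) {
      ii <- r0:(r0 + tile_px - 1L)
      jj <- c0:(c0 + tile_px - 1L)
      # half-open [r0, r0 + tile_px) on centroid coordinates
      cnt <- if (nrow(cent) == 0) 0L else
        sum(cent[, 1] >= r0 & cent[, 1] < r0 + tile_px &
            cent[, 2] >= c0 & cent[, 2] < c0 + tile_px)
      tiles[[length(tiles) + 1]] <- list(
        image = resize_plane(image[ii, jj, drop = FALSE], out_px),
        mask = matrix(as.integer(
          resize_plane(mask[ii, jj, drop = FALSE], out_px, nearest = TRUE) > 0.5),
          out_px, out_px),
        count = as.integer(cnt),
        provenance = list(source_id = source_id, row_off = r0, col_off = c0,
                          aug_id = 0L))
    }
  }
  structure(tiles, tile_px = tile_px, stride_px = stride_px, out_px = out_px,
            source_dim = c(h, w), class = "tile_set")
}

#' Augment a tile set
#'
#' Produces exactly `n_aug` variants of every input tile by a random
#' dihedral transform (flips/right-angle rotations, applied identically to
#' image and mask) plus a multiplicative intensity jitter on the image only.
#' Geometric operations preserve the component count, so per-tile counts are
#' carried over unchanged.
#'
#' @param tileset A `tile_set`.
#' @param n_aug Variants per tile (`>= 1`, default 10).
#' @param seed Integer seed; the augmented set is a pure function of
#'   `(tileset, n_aug, seed)`.
#' @param jitter Half-width of the multiplicative intensity jitter
#'   (default 0.1, i.e. scale in `[0.9, 1.1]`, clipped back to `[0, 1]`).
#' @return A `tile_set` of `length(tileset) * n_aug` tiles with `aug_id` in
#'   provenance.
#' @export
augment_tiles <- function(tileset, n_aug = 10L, seed = 1L, jitter = 0.1) {
  stopifnot(inherits(tileset, "tile_set"))
  if (n_aug < 1) stop("n_aug must be >= 1")
  seeds <- derive_seeds(seed, length(tileset))
  out <- list()
  for (i in seq_along(tileset)) {
    set.seed(seeds[i])
    tl <- tileset[[i]]
    trans <- sample(0:7, n_aug, replace = TRUE)
    scales <- runif(n_aug, 1 - jitter, 1 + jitter)
    for (a in seq_len(n_aug)) {
      img <- pmin(pmax(d4_transform(tl$image, trans[a]) * scales[a], 0), 1)
      msk <- d4_transform(tl$mask, trans[a])
      prov <- tl$provenance
      prov$aug_id <- a
      out[[length(out) + 1]] <- list(image = img, mask = msk,
                                     count = tl$count, provenance = prov)
    }
  }
  attributes(out) <- attributes(tileset)[c("tile_px", "stride_px", "out_px",
                                           "source_dim")]
  class(out) <- "tile_set"
  out
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d tiles of %dx%d (source tile %d px, stride %d px)\n",
              length(x), attr(x, "out_px"), attr(x, "out_px"),
              attr(x, "tile_px"), attr(x, "stride_px")))
  invisible(x)
}

#' Tile a simulated dataset with its planted masks
#'
#' Convenience wrapper building one training `tile_set` from an
#' `ev_image_dataset`: each image (already single-channel in `[0, 1]`) is
#' tiled against its planted ground-truth mask.
#'
#' @param dataset An `ev_image_dataset` from [simulate_image_dataset()].
#' @param tile_px,stride_px Tiling geometry (defaults: 128, non-overlapping).
#' @return A `tile_set` spanning all images, with per-image provenance.
#' @export
tile_dataset <- function(dataset, tile_px = 128L, stride_px = tile_px) {
  sets <- lapply(seq_along(dataset), function(i) {
    tile_image(dataset[[i]]$image, dataset[[i]]$gt$true_mask,
               tile_px = tile_px, stride_px = stride_px,
               source_id = sprintf("sim%03d", i))
  })
  out <- do.call(c, lapply(sets, unclass))
  attributes(out) <- attributes(sets[[1]])[c("tile_px", "stride_px", "out_px",
                                             "source_dim")]
  class(out) <- "tile_set"
  out
}
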