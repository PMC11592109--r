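#' Configuration for the synthetic EV image generator
#'
#' Describes how fluorescence micrographs of DiO-stained extracellular
#' vesicles are emulated: EVs are sub-resolution particles, so each one is
#' rendered as an isotropic 2-D Gaussian (a PSF-limited bright spot) on a
#' noisy background. All intensities are fractions of the dynamic range
#' (`[0, 1]`).
#'
#' @param height,width Image size in pixels.
#' @param n_spots_range Integer interval `c(min, max)` for the number of
#'   planted spots per image.
#' @param spot_sigma_range Gaussian PSF width interval in pixels.
#' @param spot_amplitude_range Peak amplitude interval, as a fraction of the
#'   dynamic range; must exceed `background_level`.
#' @param background_level Constant background intensity fraction.
#' @param background_gradient If `TRUE`, a linear left-to-right gradient of
#'   the same magnitude as the background is added (stresses local-contrast
#'   enhancement).
#' @param gaussian_sd Additive Gaussian read-noise standard deviation.
#' @param poisson_scale If `> 0`, Poisson shot noise: pixel values are scaled
#'   by this factor (photons per intensity unit), Poisson-sampled and scaled
#'   back. `0` disables shot noise.
#' @param min_separation_px Minimum distance between planted spot centres.
#'   The default (12 px, about six times the widest default PSF width --
#'   the spacing below which the summed tails of two Gaussian spots bridge
#'   under a global threshold) keeps the planted count well defined; set to
#'   0 to allow overlapping, merging vesicles.
#' @param n_channels,green_index Channel layout. With `n_channels = 1` the
#'   image is a plain matrix; otherwise the spots are placed in the green
#'   channel and the remaining channels carry background noise only.
#'
#' @return An object of class `image_sim_config`.
#' @seealso [simulate_ev_image()], [simulate_image_dataset()]
#' @export
image_sim_config <- function(height = 256, width = 256,
                             n_spots_range = c(5L, 50L),
                             spot_sigma_range = c(1, 2),
                             spot_amplitude_range = c(0.3, 0.8),
                             background_level = 0.05,
                             background_gradient = FALSE,
                             gaussian_sd = 0.01,
                             poisson_scale = 0,
                             min_separation_px = 12,
                             n_channels = 1L,
                             green_index = if (n_channels == 1L) 1L else 2L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_spots_range = as.integer(round(n_spots_range)),
              spot_sigma_range = as.numeric(spot_sigma_range),
              spot_amplitude_range = as.numeric(spot_amplitude_range),
              background_level = background_level,
              background_gradient = isTRUE(background_gradient),
              gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
              min_separation_px = min_separation_px,
              n_channels = as.integer(n_channels),
              green_index = as.integer(green_index))
  validate_image_sim_config(cfg)
  structure(cfg, class = "image_sim_config")
}

validate_image_sim_config <- function(cfg) {
  check_that(cfg$height >= 8 && cfg$width >= 8, "height/width", "must be >= 8")
  check_that(cfg$n_spots_range[1] >= 0, "n_spots_range", "min must be >= 0")
  check_that(diff(cfg$n_spots_range) >= 0, "n_spots_range", "needs min <= max")
  check_that(all(cfg$spot_sigma_range > 0) && diff(cfg$spot_sigma_range) >= 0,
             "spot_sigma_range", "must be positive with min <= max")
  check_that(diff(cfg$spot_amplitude_range) >= 0, "spot_amplitude_range",
             "needs min <= max")
  check_that(cfg$spot_amplitude_range[1] > cfg$background_level,
             "spot_amplitude_range", "amplitudes must exceed background_level")
  check_that(cfg$background_level >= 0 && cfg$background_level < 1,
             "background_level", "must be in [0, 1)")
  check_that(cfg$gaussian_sd >= 0, "gaussian_sd", "must be >= 0")
  check_that(cfg$poisson_scale >= 0, "poisson_scale", "must be >= 0")
  check_that(cfg$min_separation_px >= 0, "min_separation_px", "must be >= 0")
  check_that(cfg$green_index >= 1 && cfg$green_index <= cfg$n_channels,
             "green_index", "must index an existing channel")
  invisible(cfg)
}

# Rejection-sample spot centres with a minimum pairwise separation.
# Falls back to unconstrained placement if the image is too crowded.
place_centers <- function(n, height, width, min_sep) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(NA_real_, n, 2)
  margin <- 3
  placed <- 0
  attempts <- 0
  max_attempts <- 200L * n + 200L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1
    cand <- c(runif(1, 1 + margin, height - margin),
              runif(1, 1 + margin, width - margin))
    ok <- placed == 0 || min_sep == 0 ||
      min(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          rep(cand, each = placed))^2))) >= min_sep
    if (ok) {
      placed <- placed + 1
      centers[placed, ] <- cand
    }
  }
  while (placed < n) {  # crowded image: drop the separation constraint
    placed <- placed + 1
    centers[placed, ] <- c(runif(1, 1 + margin, height - margin),
                           runif(1, 1 + margin, width - margin))
  }
  colnames(centers) <- c("row", "col")
  centers
}

#' Simulate one fluorescence image of DiO-stained EVs with ground truth
#'
#' Renders `n` isotropic Gaussian spots (diffraction-limited vesicles) on a
#' constant (optionally tilted) background, adds Gaussian read noise and
#' optional Poisson shot noise, and clips to `[0, 1]`. The ground-truth mask
#' marks, for every spot, the disk of radius `2 * sigma` around its centre;
#' the planted count is the number of spots regardless of whether nearby
#' masks merge (merging is recorded in `gt$mask_components`).
#'
#' Output is a pure function of `(cfg, seed)`.
#'
#' @param cfg An [image_sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `image` (matrix, or `height x width x
#'   n_channels` array) and `gt`, a `spot_ground_truth` list holding
#'   `centers`, `sigmas`, `amplitudes`, `true_count`, `true_mask` (0/1 integer
#'   matrix) and `mask_components` (components of `true_mask` at
#'   8-connectivity; `< true_count` when spots merge).
#' @examples
#' sim <- simulate_ev_image(image_sim_config(n_spots_range = c(5, 5)), seed = 1)
#' sim$gt$true_count
#' @export
simulate_ev_image <- function(cfg, seed) {
  validate_image_sim_config(cfg)
  set.seed(as.integer(seed))
  h <- cfg$height; w <- cfg$width
  n <- if (diff(cfg$n_spots_range) == 0) cfg$n_spots_range[1] else
    sample(cfg$n_spots_range[1]:cfg$n_spots_range[2], 1)
  centers <- place_centers(n, h, w, cfg$min_separation_px)
  sigmas <- runif(n, cfg$spot_sigma_range[1], cfg$spot_sigma_range[2])
  amps <- runif(n, cfg$spot_amplitude_range[1], cfg$spot_amplitude_range[2])

  signal <- matrix(0, h, w)
  mask <- matrix(0L, h, w)
  for (s in seq_len(n)) {
    ci <- centers[s, 1]; cj <- centers[s, 2]; sg <- sigmas[s]
    r <- ceiling(4 * sg)
    ii <- max(1, floor(ci - r)):min(h, ceiling(ci + r))
    jj <- max(1, floor(cj - r)):min(w, ceiling(cj + r))
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    signal[ii, jj] <- signal[ii, jj] + amps[s] * exp(-d2 / (2 * sg^2))
    mask[ii, jj][d2 <= (2 * sg)^2] <- 1L
  }

  bg <- matrix(cfg$background_level, h, w)
  if (cfg$background_gradient) {
    bg <- bg + cfg$background_level *
      matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  }
  clean <- signal + bg
  noisy <- clean
  if (cfg$poisson_scale > 0) {
    noisy <- rpois(h * w, lambda = pmax(clean, 0) * cfg$poisson_scale) /
      cfg$poisson_scale
    dim(noisy) <- c(h, w)
  }
  if (cfg$gaussian_sd > 0) {
    noisy <- noisy + matrix(rnorm(h * w, 0, cfg$gaussian_sd), h, w)
  }
  noisy <- pmin(pmax(noisy, 0), 1)

  if (cfg$n_channels > 1) {
    img <- array(0, dim = c(h, w, cfg$n_channels))
    for (ch in seq_len(cfg$n_channels)) {
      plane <- pmin(pmax(bg + matrix(rnorm(h * w, 0, cfg$gaussian_sd), h, w),
                         0), 1)
      img[, , ch] <- plane
    }
    img[, , cfg$green_index] <- noisy
  } else {
    img <- noisy
  }

  gt <- structure(
    list(centers = centers, sigmas = sigmas, amplitudes = amps,
         true_count = n, true_mask = mask,
         mask_components = count_objects(mask, connectivity = 8L)),
    class = "spot_ground_truth")
  list(image = img, gt = gt)
}

#' Simulate a seeded dataset of EV images with ground truth
#'
#' Per-image seeds are derived deterministically from `seed`, so the dataset
#' is reproducible and any single image can be regenerated in isolation.
#'
#' @param cfg An [image_sim_config()].
#' @param n_images Number of images (`>= 1`).
#' @param seed Master integer seed.
#' @return An object of class `ev_image_dataset`: a list of
#'   [simulate_ev_image()] results, with the per-image seeds in
#'   `attr(, "seeds")`.
#' @export
simulate_image_dataset <- function(cfg, n_images, seed) {
  check_that(n_images >= 1, "n_images", "must be >= 1")
  seeds <- derive_seeds(seed, n_images)
  out <- lapply(seeds, function(s) simulate_ev_image(cfg, s))
  structure(out, seeds = seeds, class = "ev_image_dataset")
}

#' @export
print.ev_image_dataset <- function(x, ...) {
  counts <- vapply(x, function(p) p$gt$true_count, integer(1))
  d <- dim(as.array(x[[1]]$image))
  cat(sprintf("<ev_image_dataset> %d images (%s), planted counts %d-%d (mean %.1f)\n",
              length(x), paste(d, collapse = "x"),
              min(counts), max(counts), mean(counts)))
  invisible(x)
}
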