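# Small shared fixtures, generated in code.

# A tiny tile set built from simulated 128x128 images.
make_tiles <- function(n_images = 4, seed = 7, n_spots = c(3, 10)) {
  cfg <- image_sim_config(height = 128, width = 128, n_spots_range = n_spots)
  ds <- simulate_image_dataset(cfg, n_images, seed = seed)
  tile_dataset(ds, tile_px = 128)
}

# Independent brute-force rank-sum p-value: enumerate every assignment of
# the pooled data into groups of the observed sizes and compare rank sums.
brute_force_ranksum_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  n <- length(pool)
  r <- rank(pool)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- combn(n, nx)
  stats <- apply(sets, 2, function(ix) {
    rr <- rank(pool)
    sum(rr[ix]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(stats <= obs), mean(stats >= obs)))
}

# Exhaustive hypergeometric upper tail by enumerating subsets.
brute_force_hyper_p <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  sets <- combn(N, n)
  overlaps <- apply(sets, 2, function(s) length(intersect(s, inset)))
  mean(overlaps >= k)
}

random_mask <- function(px = 16, p = 0.3) {
  matrix(rbinom(px * px, 1, p), px, px)
}
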