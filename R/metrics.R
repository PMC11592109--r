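as_binary_pixels <- function(m) {
  if (inherits(m, "mask_image")) m <- m$pixels
  if (!all(m %in% c(0, 1))) stop("mask must be binary (0/1)")
  m
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks agree perfectly and score 1.
#'
#' @param a,b Binary matrices (or `mask_image`s) of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_binary_pixels(a); b <- as_binary_pixels(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch between masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Intersection over union between two binary masks
#'
#' `|A n B| / |A u B|`; two empty masks score 1.
#'
#' @inheritParams dice
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_binary_pixels(a); b <- as_binary_pixels(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch between masks")
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Counting error summary
#'
#' Mean absolute error, mean absolute percentage error (entries with zero
#' truth are excluded from MAPE and reported) and mean signed bias
#' (prediction minus truth).
#'
#' @param pred Numeric predictions.
#' @param truth Numeric/integer ground-truth counts, same length.
#' @return List with `mae`, `mape` (percent; `NA` if no nonzero truths),
#'   `bias`, `n_zero_truth`.
#' @export
count_errors <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 1) stop("need at least one observation")
  err <- pred - truth
  nz <- truth != 0
  list(mae = mean(abs(err)),
       mape = if (any(nz)) 100 * mean(abs(err[nz]) / truth[nz]) else NA_real_,
       bias = mean(err),
       n_zero_truth = sum(!nz))
}

# Mann-Whitney U statistic of x relative to y, with 0.5 credit for ties.
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test for independent groups, as used to compare EV
#' counts or relative expression between patient groups. For small samples
#' (combined `n <= exact_limit`) without ties the p-value is exact, from
#' full enumeration of all group labelings; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric observations for the two groups.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (alternative: `x` tends larger than `y`).
#' @param exact_limit Combined-size limit for the exact path (default 12).
#' @return List with `u` (Mann-Whitney U of `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) stop("both groups need >= 1 observation")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u <- mw_u(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (n <= exact_limit && !ties) {
    pool <- c(x, y)
    idx <- combn(n, nx)
    us <- apply(idx, 2, function(ix) mw_u(pool[ix], pool[-ix]))
    p <- switch(alternative,
      two.sided = min(1, 2 * min(mean(us <= u), mean(us >= u))),
      greater = mean(us >= u),
      less = mean(us <= u))
    return(list(u = u, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  r <- rank(c(x, y))
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  sigma <- sqrt(sigma2)
  if (sigma == 0) return(list(u = u, p = 1, method = "normal"))
  z <- switch(alternative,
    two.sided = max(0, abs(u - mu) - 0.5) / sigma,
    greater = (u - mu - 0.5) / sigma,
    less = (mu - u - 0.5) / sigma)
  p <- switch(alternative,
    two.sided = min(1, 2 * pnorm(-z)),
    greater = pnorm(-z),
    less = pnorm(-z))
  list(u = u, p = p, method = "normal")
}
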