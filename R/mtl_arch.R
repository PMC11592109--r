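#' Architecture configuration for the multitask EV network
#'
#' A U-Net-style encoder/decoder for 128 x 128 single-channel tiles with
#' two outputs: a per-pixel foreground probability map (segmentation
#' decoder with skip connections) and a non-negative scalar EV count (a
#' regression head on the bottleneck features, global average pooling
#' followed by a small dense stack with softplus output). A 1x1
#' convolutional connection block adapts the encoder output to the decoder.
#'
#' The only encoder family provided is `"tiny"`, a from-scratch encoder
#' small enough to train on a single CPU; `pretrained = TRUE` is an error
#' because no pretrained weights are defined for it.
#'
#' @param encoder Encoder family; only `"tiny"`.
#' @param pretrained Must be `FALSE` for the tiny encoder.
#' @param depth Number of encoder stages (`>= 2`; each halves resolution).
#' @param base_filters Filters in the first stage (`>= 4`); doubled per
#'   stage.
#' @param residual Add residual shortcuts (1x1 projection where channel
#'   counts differ) around each conv block.
#' @param count_hidden Hidden units of the count-regression head.
#' @return An `arch_config`.
#' @export
arch_config <- function(encoder = "tiny", pretrained = FALSE, depth = 2L,
                        base_filters = 8L, residual = TRUE,
                        count_hidden = 16L) {
  if (!identical(encoder, "tiny")) {
    stop("unknown encoder family: only 'tiny' is available")
  }
  if (isTRUE(pretrained)) {
    stop("no pretrained weights are defined for the tiny encoder")
  }
  check_that(depth >= 2, "depth", "must be >= 2")
  check_that(base_filters >= 4, "base_filters", "must be >= 4")
  structure(list(encoder = encoder, pretrained = FALSE,
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 residual = isTRUE(residual),
                 count_hidden = as.integer(count_hidden)),
            class = "arch_config")
}

#' Training configuration
#'
#' @param lambda_seg,lambda_count Non-negative loss weights for the
#'   segmentation loss (Dice + binary cross-entropy, equal weights) and the
#'   counting loss (MSE on `log1p(count)`); their sum must be positive.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without improvement of
#'   the validation composite score); must be `<= max_epochs`.
#' @param score_alpha Weight of the normalized count MAE in the composite
#'   validation score `dice - alpha * mae / mean(true count)`.
#' @param seed Seed controlling shuffling (parameter init is seeded in
#'   [build_mtl()]).
#' @return A `train_config`.
#' @export
train_config <- function(lambda_seg = 1, lambda_count = 0.5, lr = 3e-3,
                         batch_size = 16L, max_epochs = 12L, patience = 4L,
                         score_alpha = 0.5, seed = 1L) {
  check_that(lambda_seg >= 0 && lambda_count >= 0 &&
               lambda_seg + lambda_count > 0,
             "lambda_seg/lambda_count", "must be >= 0 with positive sum")
  check_that(patience <= max_epochs, "patience", "must be <= max_epochs")
  structure(list(lambda_seg = lambda_seg, lambda_count = lambda_count,
                 lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 score_alpha = score_alpha, seed = as.integer(seed)),
            class = "train_config")
}

new_conv <- function(cin, cout, k) {
  w <- matrix(rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))),
              cout, cin * k * k)
  list(w = w, b = numeric(cout), k = as.integer(k),
       pad = as.integer((k - 1) / 2), cin = cin, cout = cout)
}

new_block <- function(cin, cout, residual) {
  bl <- list(conv1 = new_conv(cin, cout, 3), conv2 = new_conv(cout, cout, 3),
             residual = residual, proj = NULL)
  if (residual && cin != cout) bl$proj <- new_conv(cin, cout, 1)
  bl
}

#' Build a multitask model with seeded initialization
#'
#' He-normal parameter initialization as a pure function of
#' `(arch, seed)`.
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed.
#' @return An `mtl_model` holding `arch`, `params` and `seed`.
#' @export
build_mtl <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  set.seed(as.integer(seed))
  d <- arch$depth; F0 <- arch$base_filters
  filt <- F0 * 2^(seq_len(d) - 1)
  enc <- vector("list", d)
  cin <- 1L
  for (s in seq_len(d)) {
    enc[[s]] <- new_block(cin, filt[s], arch$residual)
    cin <- filt[s]
  }
  conn <- new_conv(filt[d], filt[d], 1)
  dec <- vector("list", d)
  cprev <- filt[d]
  for (s in rev(seq_len(d))) {
    dec[[s]] <- new_block(cprev + filt[s], filt[s], arch$residual)
    cprev <- filt[s]
  }
  # small-scale head init with a background-prior bias keeps the
  # segmentation logits unsaturated at the start of training
  seg_head <- new_conv(filt[1], 1L, 1)
  seg_head$w <- seg_head$w * 0.1
  seg_head$b <- -2
  h <- arch$count_hidden
  count_head <- list(
    w1 = matrix(rnorm(h * filt[d], 0, sqrt(2 / filt[d])), h, filt[d]),
    b1 = numeric(h),
    w2 = matrix(rnorm(h, 0, sqrt(2 / h)), 1, h),
    b2 = numeric(1))
  structure(list(arch = arch, seed = as.integer(seed),
                 params = list(enc = enc, conn = conn, dec = dec,
                               seg_head = seg_head,
                               count_head = count_head)),
            class = "mtl_model")
}

#' Number of trainable parameters
#' @param model An `mtl_model` or `mtl_fit`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  cnt <- 0L
  walk <- function(x) {
    if (!is.list(x)) return(invisible())
    for (nm in names(x)) {
      if (nm %in% c("w", "b", "w1", "b1", "w2", "b2") &&
          is.numeric(x[[nm]])) {
        cnt <<- cnt + length(x[[nm]])
      } else if (is.list(x[[nm]])) {
        walk(x[[nm]])
      }
    }
    if (is.null(names(x))) for (e in x) walk(e)
  }
  walk(model$params)
  cnt
}

#' @export
print.mtl_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<mtl_model> tiny encoder, depth %d, base filters %d%s; %d parameters (seed %d)\n",
              a$depth, a$base_filters,
              if (a$residual) ", residual" else "", n_params(x), x$seed))
  invisible(x)
}

## ---- forward / backward -------------------------------------------------

conv_fw <- function(layer, x) {
  .conv2d_forward(x, dim(x), layer$w, layer$b, layer$k, layer$pad)
}

conv_bw <- function(layer, x, gy) {
  .conv2d_backward(x, dim(x), layer$w, gy, layer$k, layer$pad)
}

relu <- function(x) {
  y <- pmax(x, 0); dim(y) <- dim(x); y
}

block_fw <- function(bl, x) {
  z1 <- conv_fw(bl$conv1, x)
  a1 <- relu(z1)
  z2 <- conv_fw(bl$conv2, a1)
  if (bl$residual) {
    s <- if (!is.null(bl$proj)) conv_fw(bl$proj, x) else x
    zs <- z2 + s
    dim(zs) <- dim(z2)
  } else {
    zs <- z2
  }
  list(out = relu(zs), cache = list(x = x, z1 = z1, zs = zs))
}

block_bw <- function(bl, cache, gout) {
  gz <- gout * (cache$zs > 0); dim(gz) <- dim(gout)
  a1 <- relu(cache$z1)
  b2 <- conv_bw(bl$conv2, a1, gz)
  gz1 <- b2$gx * (cache$z1 > 0); dim(gz1) <- dim(b2$gx)
  b1 <- conv_bw(bl$conv1, cache$x, gz1)
  gx <- b1$gx
  grads <- list(conv1 = list(w = b1$gw, b = b1$gb),
                conv2 = list(w = b2$gw, b = b2$gb))
  if (bl$residual) {
    if (!is.null(bl$proj)) {
      bp <- conv_bw(bl$proj, cache$x, gz)
      gx <- gx + bp$gx
      grads$proj <- list(w = bp$gw, b = bp$gb)
    } else {
      gx <- gx + gz
    }
    dim(gx) <- dim(b1$gx)
  }
  list(gx = gx, grads = grads)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Full forward pass on a batch array (128, 128, 1, B).
mtl_forward <- function(params, x, keep = FALSE) {
  d <- length(params$enc)
  caches <- list(enc = vector("list", d), pool = vector("list", d),
                 dec = vector("list", d))
  skips <- vector("list", d)
  h <- x
  for (s in seq_len(d)) {
    bf <- block_fw(params$enc[[s]], h)
    skips[[s]] <- bf$out
    if (keep) caches$enc[[s]] <- bf$cache
    mp <- .maxpool2_forward(bf$out, dim(bf$out))
    if (keep) caches$pool[[s]] <- list(arg = mp$arg, dims_in = dim(bf$out))
    h <- mp$y
  }
  conn_in <- h
  zc <- conv_fw(params$conn, h)
  hc <- relu(zc)
  if (keep) caches$conn <- list(x = conn_in, z = zc)

  # count head on bottleneck features; sum pooling scaled by 1/sqrt(HW)
  # keeps the count signal extensive (counts grow with occupied area)
  # while leaving features O(1) for the dense stack
  dm <- dim(hc)
  gap <- matrix(colSums(matrix(hc, dm[1] * dm[2], dm[3] * dm[4])) /
                  sqrt(dm[1] * dm[2]),
                dm[3], dm[4])
  ch <- params$count_head
  z1 <- ch$w1 %*% gap + ch$b1
  a1 <- pmax(z1, 0)
  u <- as.numeric(ch$w2 %*% a1 + ch$b2)
  counts <- softplus(u)
  if (keep) caches$count <- list(gap = gap, z1 = z1, a1 = a1, u = u,
                                 hc_dim = dm)

  h <- hc
  for (s in rev(seq_len(d))) {
    up <- .upsample2_forward(h, dim(h))
    cc <- concat_c(up, skips[[s]])
    bf <- block_fw(params$dec[[s]], cc)
    if (keep) {
      caches$dec[[s]] <- list(cache = bf$cache, up_dims_in = dim(h),
                              nc_up = dim(up)[3])
    }
    h <- bf$out
  }
  logits <- conv_fw(params$seg_head, h)
  if (keep) caches$seg_in <- h
  list(prob = sigmoid(logits), logits = logits, counts = counts, u = u,
       caches = if (keep) caches else NULL)
}

# Backward pass: g_logits (128,128,1,B), g_u (length B).
mtl_backward <- function(params, fw, g_logits, g_u) {
  caches <- fw$caches
  d <- length(params$enc)
  grads <- list(enc = vector("list", d), dec = vector("list", d))

  sh <- conv_bw(params$seg_head, caches$seg_in, g_logits)
  grads$seg_head <- list(w = sh$gw, b = sh$gb)
  gh <- sh$gx
  for (s in seq_len(d)) {
    bb <- block_bw(params$dec[[s]], caches$dec[[s]]$cache, gh)
    grads$dec[[s]] <- bb$grads
    nc_up <- caches$dec[[s]]$nc_up
    gcc <- bb$gx
    gup <- gcc[, , seq_len(nc_up), , drop = FALSE]
    # gradient into the skip connection
    gskip <- gcc[, , nc_up + seq_len(dim(gcc)[3] - nc_up), , drop = FALSE]
    caches$enc[[s]]$gskip <- gskip
    gh <- .upsample2_backward(gup, caches$dec[[s]]$up_dims_in)
  }

  # count-head gradient into bottleneck features
  ch <- params$count_head
  cc <- caches$count
  gu <- matrix(g_u, 1, length(g_u))
  grads$count_head <- list(
    w2 = gu %*% t(cc$a1), b2 = sum(gu),
    w1 = NULL, b1 = NULL)
  ga1 <- t(ch$w2) %*% gu
  gz1 <- ga1 * (cc$z1 > 0)
  grads$count_head$w1 <- gz1 %*% t(cc$gap)
  grads$count_head$b1 <- rowSums(gz1)
  ggap <- t(ch$w1) %*% gz1                       # (C, B)
  dm <- cc$hc_dim
  gap_g <- array(rep(as.numeric(ggap), each = dm[1] * dm[2]) /
                   sqrt(dm[1] * dm[2]), dm)
  ghc <- gh + gap_g
  dim(ghc) <- dm

  gzc <- ghc * (caches$conn$z > 0); dim(gzc) <- dm
  cb <- conv_bw(params$conn, caches$conn$x, gzc)
  grads$conn <- list(w = cb$gw, b = cb$gb)
  gh <- cb$gx

  for (s in rev(seq_len(d))) {
    gpool <- .maxpool2_backward(gh, caches$pool[[s]]$arg,
                                caches$pool[[s]]$dims_in)
    gout <- gpool + caches$enc[[s]]$gskip
    dim(gout) <- caches$pool[[s]]$dims_in
    bb <- block_bw(params$enc[[s]], caches$enc[[s]], gout)
    grads$enc[[s]] <- bb$grads
    gh <- bb$gx
  }
  grads
}
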