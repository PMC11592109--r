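# Stack a list of tiles into batch arrays.
batch_arrays <- function(tiles, idx) {
  B <- length(idx)
  px <- nrow(tiles[[idx[1]]]$image)
  x <- array(0, c(px, px, 1, B))
  m <- array(0, c(px, px, 1, B))
  y <- numeric(B)
  for (q in seq_len(B)) {
    tl <- tiles[[idx[q]]]
    x[, , 1, q] <- tl$image
    m[, , 1, q] <- tl$mask
    y[q] <- tl$count
  }
  list(x = x, m = m, y = y)
}

# Segmentation (Dice + BCE) and counting (MSE on log1p) losses with
# gradients w.r.t. the segmentation logits and the count pre-activation.
mtl_loss <- function(fw, m, y, lambda_seg, lambda_count) {
  p <- fw$prob
  z <- fw$logits
  dm <- dim(p); B <- dm[4]; npx <- prod(dm[1:3])
  # numerically stable BCE computed in logit space
  bce <- mean(pmax(z, 0) - z * m + log1p(exp(-abs(z))))
  g_bce <- (p - m) / (npx * B)

  pe <- 1e-6
  g_dice <- array(0, dm)
  dice_loss <- 0
  for (b in seq_len(B)) {
    pb <- p[, , , b]; mb <- m[, , , b]
    S <- sum(pb * mb); U <- sum(pb) + sum(mb)
    dice_loss <- dice_loss + 1 - (2 * S + pe) / (U + pe)
    g_dice[, , , b] <- (-(2 * mb * (U + pe)) + (2 * S + pe)) / (U + pe)^2 / B
  }
  dice_loss <- dice_loss / B
  seg <- bce + dice_loss
  g_logits <- lambda_seg * (g_bce + g_dice * p * (1 - p))
  dim(g_logits) <- dm

  cp <- fw$counts
  resid <- log1p(cp) - log1p(y)
  count <- mean(resid^2)
  g_u <- lambda_count * 2 * resid / (1 + cp) * sigmoid(fw$u) / B

  list(seg = seg, count = count,
       total = lambda_seg * seg + lambda_count * count,
       g_logits = g_logits, g_u = g_u)
}

# Adam over the parameter tree; 'state' mirrors the gradient tree.
adam_init <- function() list(t = 0, m = NULL, v = NULL)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  # recursion over names where present, indices otherwise (stage lists)
  walk2 <- function(p, g, m, v) {
    if (is.numeric(g)) return(upd(p, g, m, v))
    keys <- if (!is.null(names(g))) names(g) else seq_along(g)
    out_p <- p
    out_m <- if (is.null(m)) vector("list", length(g)) else m
    out_v <- if (is.null(v)) vector("list", length(g)) else v
    for (ki in seq_along(keys)) {
      kk <- keys[[ki]]
      if (is.null(g[[kk]])) next
      r <- walk2(p[[kk]], g[[kk]],
                 if (is.null(m)) NULL else m[[kk]],
                 if (is.null(v)) NULL else v[[kk]])
      out_p[[kk]] <- r$p
      out_m[[kk]] <- r$m
      out_v[[kk]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  }
  r <- walk2(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = t, m = r$m, v = r$v))
}

# Validation metrics over a tile list.
evaluate_tiles <- function(params, tiles, batch_size = 16L, threshold = 0.5) {
  dices <- numeric(length(tiles))
  preds <- numeric(length(tiles))
  truths <- vapply(tiles, function(t) as.numeric(t$count), numeric(1))
  i <- 1
  while (i <= length(tiles)) {
    idx <- i:min(i + batch_size - 1, length(tiles))
    ba <- batch_arrays(tiles, idx)
    fw <- mtl_forward(params, ba$x, keep = FALSE)
    for (q in seq_along(idx)) {
      pm <- matrix(as.integer(fw$prob[, , 1, q] > threshold),
                   dim(ba$x)[1], dim(ba$x)[2])
      dices[idx[q]] <- dice(pm, tiles[[idx[q]]]$mask)
      preds[idx[q]] <- fw$counts[q]
    }
    i <- i + batch_size
  }
  list(dice = mean(dices), count_mae = mean(abs(preds - truths)),
       mean_true = mean(truths), pred = preds, truth = truths)
}

#' Train the multitask model
#'
#' Joint minimization of the weighted segmentation (Dice + binary
#' cross-entropy) and counting (MSE on `log1p` counts) losses with Adam.
#' After each epoch the validation composite score
#' `dice - alpha * MAE / mean(count)` is evaluated; the parameters at the
#' best epoch are returned, with early stopping after `patience`
#' non-improving epochs. With fixed seeds the whole history is
#' reproducible.
#'
#' @param model An `mtl_model` from [build_mtl()].
#' @param train_set,val_set `tile_set`s (binary masks, counts `>= 0`).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An `mtl_fit`: the trained model (`params` at the best epoch)
#'   plus `history` (per-epoch losses and validation Dice / count MAE) and
#'   `best_epoch`. Has `print`, `summary`, `predict`, `plot` methods.
#' @export
train_mtl <- function(model, train_set, val_set, cfg = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "mtl_model"), inherits(cfg, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0) {
    stop("training and validation sets must be non-empty")
  }
  for (tl in train_set) {
    if (!all(tl$mask %in% c(0, 1))) stop("masks must be binary")
    if (tl$count < 0) stop("counts must be >= 0")
  }
  params <- model$params
  state <- adam_init()
  n <- length(train_set)
  hist <- data.frame(epoch = integer(0), total = numeric(0),
                     seg = numeric(0), count = numeric(0),
                     val_dice = numeric(0), val_count_mae = numeric(0),
                     val_score = numeric(0))
  best <- list(score = -Inf, params = params, epoch = 0L)
  bad <- 0L
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tot <- sg <- ct <- 0
    nb <- 0
    i <- 1
    while (i <= n) {
      idx <- ord[i:min(i + cfg$batch_size - 1, n)]
      ba <- batch_arrays(train_set, idx)
      fw <- mtl_forward(params, ba$x, keep = TRUE)
      ls <- mtl_loss(fw, ba$m, ba$y, cfg$lambda_seg, cfg$lambda_count)
      if (!is.finite(ls$total)) {
        stop(sprintf("NaN/Inf loss at epoch %d (batch starting %d): try a lower learning rate",
                     epoch, i))
      }
      grads <- mtl_backward(params, fw, ls$g_logits, ls$g_u)
      st <- adam_step(params, grads, state, cfg$lr)
      params <- st$params
      state <- st$state
      tot <- tot + ls$total; sg <- sg + ls$seg; ct <- ct + ls$count
      nb <- nb + 1
      i <- i + cfg$batch_size
    }
    ev <- evaluate_tiles(params, val_set, cfg$batch_size)
    score <- ev$dice - cfg$score_alpha * ev$count_mae / max(1, ev$mean_true)
    hist <- rbind(hist, data.frame(
      epoch = epoch, total = tot / nb, seg = sg / nb, count = ct / nb,
      val_dice = ev$dice, val_count_mae = ev$count_mae, val_score = score))
    if (verbose) {
      message(sprintf("epoch %2d: loss %.4f, val dice %.3f, val MAE %.2f",
                      epoch, tot / nb, ev$dice, ev$count_mae))
    }
    if (score > best$score) {
      best <- list(score = score, params = params, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  structure(list(arch = model$arch, seed = model$seed, params = best$params,
                 cfg = cfg, history = hist, best_epoch = best$epoch),
            class = c("mtl_fit", "mtl_model"))
}

#' @export
print.mtl_fit <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  cat(sprintf("<mtl_fit> %d epochs (best %d): val Dice %.3f, val count MAE %.2f\n",
              nrow(x$history), x$best_epoch, h$val_dice, h$val_count_mae))
  invisible(x)
}

#' @export
summary.mtl_fit <- function(object, ...) {
  cat(sprintf("Multitask EV model: depth %d, base filters %d, %d parameters\n",
              object$arch$depth, object$arch$base_filters, n_params(object)))
  cat(sprintf("Loss weights: seg %.2f, count %.2f; lr %g; batch %d\n",
              object$cfg$lambda_seg, object$cfg$lambda_count, object$cfg$lr,
              object$cfg$batch_size))
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.mtl_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$total, type = "b", xlab = "epoch", ylab = "training loss",
       ...)
  abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Predict masks and counts for preprocessed tiles
#'
#' Probability maps are thresholded at strictly greater than 0.5 (a pixel
#' at exactly 0.5 is background). Counts come from the regression head and
#' are non-negative by construction.
#'
#' @param object An `mtl_fit` (or untrained `mtl_model`).
#' @param tiles A `tile_set`, a list of 128 x 128 matrices in `[0, 1]`, or
#'   a single matrix.
#' @param batch_size Inference batch size.
#' @param threshold Probability threshold (default 0.5).
#' @param ... Unused.
#' @return List with `masks` (list of `mask_image`), `counts` (numeric) and
#'   `prob` (list of probability maps).
#' @export
predict.mtl_model <- function(object, tiles, batch_size = 16L,
                              threshold = 0.5, ...) {
  if (is.matrix(tiles)) tiles <- list(tiles)
  imgs <- lapply(tiles, function(t) if (is.list(t)) t$image else t)
  px <- nrow(imgs[[1]])
  for (im in imgs) {
    if (!is.matrix(im) || nrow(im) != px || ncol(im) != px) {
      stop("shape mismatch: tiles must all be square matrices of equal size")
    }
  }
  masks <- vector("list", length(imgs))
  probs <- vector("list", length(imgs))
  counts <- numeric(length(imgs))
  i <- 1
  while (i <= length(imgs)) {
    idx <- i:min(i + batch_size - 1, length(imgs))
    x <- array(0, c(px, px, 1, length(idx)))
    for (q in seq_along(idx)) x[, , 1, q] <- imgs[[idx[q]]]
    fw <- mtl_forward(object$params, x, keep = FALSE)
    for (q in seq_along(idx)) {
      pr <- matrix(fw$prob[, , 1, q], px, px)
      probs[[idx[q]]] <- pr
      masks[[idx[q]]] <- mask_image(matrix(as.integer(pr > threshold), px, px))
      counts[idx[q]] <- fw$counts[q]
    }
    i <- i + batch_size
  }
  list(masks = masks, counts = counts, prob = probs)
}

#' Whole-image EV count from tiled predictions
#'
#' Tiles the image, predicts per-tile counts, and aggregates them to a
#' whole-image count. With overlapping tiles each tile's contribution is
#' weighted by the mean reciprocal coverage of its pixels, so area counted
#' twice is averaged rather than double-counted.
#'
#' @param fit An `mtl_fit`.
#' @param image Preprocessed matrix in `[0, 1]`.
#' @param tile_px,stride_px Tiling geometry (defaults 128 / non-overlapping).
#' @return List with `count` (aggregated), `tile_counts`, `n_tiles`.
#' @export
predict_image_count <- function(fit, image, tile_px = 128L,
                                stride_px = tile_px) {
  ts <- tile_image(image, matrix(0L, nrow(image), ncol(image)),
                   tile_px = tile_px, stride_px = stride_px)
  pr <- predict(fit, ts)
  cov <- matrix(0, nrow(image), ncol(image))
  wts <- numeric(length(ts))
  for (t in seq_along(ts)) {
    p <- ts[[t]]$provenance
    cov[p$row_off:(p$row_off + tile_px - 1),
        p$col_off:(p$col_off + tile_px - 1)] <-
      cov[p$row_off:(p$row_off + tile_px - 1),
          p$col_off:(p$col_off + tile_px - 1)] + 1
  }
  for (t in seq_along(ts)) {
    p <- ts[[t]]$provenance
    wts[t] <- mean(1 / cov[p$row_off:(p$row_off + tile_px - 1),
                           p$col_off:(p$col_off + tile_px - 1)])
  }
  list(count = sum(pr$counts * wts), tile_counts = pr$counts,
       n_tiles = length(ts))
}

#' Random hyperparameter search
#'
#' Draws `budget` configurations from a discrete search space, trains each
#' with a per-trial derived seed, and selects the best composite validation
#' score (`dice - alpha * normalized count MAE`). Failed trials (e.g.
#' divergent learning rates) score `-Inf` and stay on the leaderboard.
#'
#' @param train_set,val_set `tile_set`s.
#' @param search_space Named list of candidate-value vectors; recognized
#'   names: `base_filters`, `depth`, `residual`, `lr`, `lambda_count`,
#'   `batch_size`, `max_epochs`.
#' @param budget Number of trials (`>= 1`).
#' @param seed Master seed.
#' @return List with `best_arch`, `best_cfg`, `leaderboard`
#'   (`data.frame`, one row per trial, sorted by score), `best_fit`.
#' @export
tune_mtl <- function(train_set, val_set, search_space, budget = 4L,
                     seed = 1L) {
  if (budget < 1) stop("budget must be >= 1")
  if (length(search_space) == 0) stop("empty search space")
  seeds <- derive_seeds(seed, budget)
  rows <- list()
  best <- list(score = -Inf)
  for (tr in seq_len(budget)) {
    set.seed(seeds[tr])
    pick <- lapply(search_space, function(v) v[[sample.int(length(v), 1)]])
    arch <- arch_config(
      depth = pick$depth %||% 2L,
      base_filters = pick$base_filters %||% 8L,
      residual = pick$residual %||% TRUE)
    cfg <- train_config(
      lr = pick$lr %||% 1e-3,
      lambda_count = pick$lambda_count %||% 0.5,
      batch_size = pick$batch_size %||% 16L,
      max_epochs = pick$max_epochs %||% 6L,
      patience = pick$max_epochs %||% 6L,
      seed = seeds[tr])
    fit <- tryCatch(
      train_mtl(build_mtl(arch, seed = seeds[tr]), train_set, val_set, cfg),
      error = function(e) e)
    if (inherits(fit, "error")) {
      score <- -Inf; dice_v <- NA_real_; mae_v <- NA_real_
    } else {
      h <- fit$history[fit$best_epoch, ]
      score <- h$val_score; dice_v <- h$val_dice; mae_v <- h$val_count_mae
    }
    rows[[tr]] <- data.frame(
      trial = tr, seed = seeds[tr],
      depth = arch$depth, base_filters = arch$base_filters,
      residual = arch$residual, lr = cfg$lr,
      lambda_count = cfg$lambda_count, batch_size = cfg$batch_size,
      max_epochs = cfg$max_epochs,
      val_dice = dice_v, val_count_mae = mae_v, score = score)
    if (score > best$score) {
      best <- list(score = score, arch = arch, cfg = cfg, fit = fit)
    }
  }
  lb <- do.call(rbind, rows)
  lb <- lb[order(-lb$score), ]
  list(best_arch = best$arch, best_cfg = best$cfg, leaderboard = lb,
       best_fit = best$fit)
}
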