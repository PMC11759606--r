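#' Patch-model training configuration
#'
#' @param backbone `"tiny"` (the built-in small network: per-tile block
#'   statistics of the Z-scored image feeding one hidden ReLU layer and a
#'   softmax head). The large ImageNet backbones (`"densenet121"`,
#'   `"resnet50"`, `"inception_v3"`) are recognised names but require an
#'   external deep-learning runtime and raise an error here.
#' @param epochs number of training epochs `T_i` of the cosine schedule
#'   (default 50).
#' @param eta_max,eta_min maximum / minimum learning rate of the cosine
#'   decay schedule (defaults 0.01 and 0).
#' @param batch_size SGD minibatch size.
#' @param seed seed controlling initialisation, shuffling and augmentation.
#' @param augment apply random crop + flips during training (test-time
#'   inference always uses normalization only).
#' @param crop_fraction linear size of the random crop relative to the tile.
#' @param input_grid block-statistics grid resolution `g`: the network input
#'   is `g^2` block means per channel plus `g^2` block standard deviations
#'   of luminance plus 9 global luminance summaries (`4 g^2 + 9` inputs).
#' @param hidden_units width of the hidden layer.
#' @return object of class `train_config`.
#' @export
train_config <- function(backbone = "tiny", epochs = 50, eta_max = 0.01,
                         eta_min = 0, batch_size = 32, seed = 1L,
                         augment = TRUE, crop_fraction = 0.875,
                         input_grid = 8, hidden_units = 16) {
  backbone <- match.arg(backbone,
                        c("tiny", "densenet121", "resnet50", "inception_v3"))
  assert_that(is_count(epochs), "epochs must be a positive integer")
  assert_that(is.numeric(eta_max) && is.numeric(eta_min) && eta_min <= eta_max,
              "need eta_min <= eta_max")
  assert_that(is_count(batch_size), "batch_size must be a positive integer")
  assert_that(is.numeric(crop_fraction) && crop_fraction > 0 && crop_fraction <= 1,
              "crop_fraction must be in (0, 1]")
  cfg <- list(backbone = backbone, epochs = as.integer(epochs),
              eta_max = eta_max, eta_min = eta_min,
              batch_size = as.integer(batch_size), seed = as.integer(seed),
              augment = isTRUE(augment), crop_fraction = crop_fraction,
              input_grid = as.integer(input_grid),
              hidden_units = as.integer(hidden_units))
  class(cfg) <- "train_config"
  cfg
}

#' Cosine-decay learning rate
#'
#' `eta(t) = eta_min + (eta_max - eta_min) / 2 * (1 + cos(pi * t / T_i))`
#' for epoch counter `t` in `[0, T_i]`.
#'
#' @param t_cur current epoch counter (0-based).
#' @param cfg a [train_config()].
#' @return the learning rate at `t_cur`.
#' @export
cosine_lr <- function(t_cur, cfg = train_config()) {
  assert_that(is.numeric(t_cur) && length(t_cur) == 1 && t_cur >= 0 &&
                t_cur <= cfg$epochs,
              "t_cur must lie in [0, T_i]")
  cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) *
    (1 + cos(pi * t_cur / cfg$epochs))
}

#' Per-tile Z-score normalization of the RGB channels
#'
#' Each channel is centred and scaled to unit (population) standard
#' deviation within the tile. A constant channel maps to zeros through an
#' epsilon-guarded divisor.
#'
#' @param tile a tile list or pixel array in `[0, 255]`.
#' @return numeric array of the same shape.
#' @export
zscore_input <- function(tile) {
  px <- if (is.list(tile)) tile$pixels else tile
  out <- px
  for (ch in 1:3) {
    x <- px[, , ch]
    s <- sd_pop(x)
    out[, , ch] <- if (s < 1e-8) 0 * x else (x - mean(x)) / s
  }
  out
}

# nearest-neighbour square resize
resize_nn <- function(px, size) {
  d <- dim(px)
  ri <- pmin(d[1], pmax(1, round((seq_len(size) - 0.5) * d[1] / size + 0.5)))
  ci <- pmin(d[2], pmax(1, round((seq_len(size) - 0.5) * d[2] / size + 0.5)))
  px[ri, ci, , drop = FALSE]
}

#' Random crop-and-flip augmentation
#'
#' Takes a random crop of `crop_fraction` linear size (resized back to the
#' tile size by nearest neighbour) and applies independent random horizontal
#' and vertical flips. With `crop_fraction = 1` and `flip = FALSE` this is
#' the identity. Uses the current RNG stream; seed at the caller.
#'
#' @param tile tile list or pixel array.
#' @param crop_fraction linear crop size relative to the tile (default 0.875).
#' @param flip enable the random flips.
#' @return augmented object of the same kind.
#' @export
augment_tile <- function(tile, crop_fraction = 0.875, flip = TRUE) {
  px <- if (is.list(tile)) tile$pixels else tile
  d <- dim(px)
  if (crop_fraction < 1) {
    cs <- max(1, round(crop_fraction * d[1]))
    r0 <- sample.int(d[1] - cs + 1, 1) - 1
    c0 <- sample.int(d[2] - cs + 1, 1) - 1
    px <- resize_nn(px[r0 + 1:cs, c0 + 1:cs, , drop = FALSE], d[1])
  }
  if (flip) {
    if (runif(1) < 0.5) px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    if (runif(1) < 0.5) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  }
  if (is.list(tile)) {
    tile$pixels <- px
    tile
  } else {
    px
  }
}

# Input representation of the tiny backbone: Z-score the tile, then take
# g x g block means per channel, g x g block standard deviations of the
# luminance (mean of the three z-scored channels), and global luminance
# summaries (lower-tail fractions and quantiles). The tail fractions carry
# the nucleus-blob density, which per-tile Z-scoring cannot remove.
tile_input_features <- function(px, grid = 8) {
  z <- zscore_input(px)
  d <- dim(z)
  g <- grid
  br <- d[1] %/% g
  bc <- d[2] %/% g
  z <- z[seq_len(br * g), seq_len(bc * g), , drop = FALSE]
  block_mean <- function(m) {
    a <- array(m, dim = c(br, g, bc, g))
    apply(a, c(2, 4), mean)
  }
  block_sd <- function(m) {
    a <- array(m, dim = c(br, g, bc, g))
    mu <- apply(a, c(2, 4), mean)
    sqrt(pmax(apply(a^2, c(2, 4), mean) - mu^2, 0))
  }
  lum <- (z[, , 1] + z[, , 2] + z[, , 3]) / 3
  tails <- vapply(c(-2, -1.5, -1, -0.5), function(th) mean(lum < th), numeric(1))
  qs <- as.numeric(quantile(lum, c(0.01, 0.05, 0.1, 0.25, 0.5)))
  c(block_mean(z[, , 1]), block_mean(z[, , 2]), block_mean(z[, , 3]),
    block_sd(lum), tails, qs)
}

n_input_features <- function(grid) 4 * grid^2 + 9

softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the patch-level classifier on weakly labelled tiles
#'
#' Every tile inherits its slide's ER status as its (weak) label. The tiny
#' backbone is a single-hidden-layer ReLU network over per-tile block
#' statistics of the Z-scored image, trained by minibatch SGD on the softmax
#' cross-entropy loss under the cosine-decay learning-rate schedule.
#'
#' @param tiles list of tiles (lists with `pixels`, optionally `slide_id`,
#'   `row`, `col`) or bare pixel arrays.
#' @param labels integer vector of weak labels in `{0, 1}`, one per tile.
#' @param cfg a [train_config()].
#' @return object of class `patch_model` with the fitted weights and a
#'   per-epoch `history` data frame (`epoch`, `lr`, `loss`, `accuracy`).
#' @export
train_patch_model <- function(tiles, labels, cfg = train_config()) {
  assert_that(length(tiles) == length(labels), "one label per tile required")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stop("training tiles contain a single class; need both labels", call. = FALSE)
  }
  if (cfg$backbone != "tiny") {
    stop("backbone '", cfg$backbone, "' requires an external deep-learning ",
         "runtime; this package trains the 'tiny' backbone", call. = FALSE)
  }
  pixels <- lapply(tiles, function(t) if (is.list(t)) t$pixels else t)
  n <- length(pixels)
  p <- n_input_features(cfg$input_grid)
  h <- cfg$hidden_units

  base_feats <- NULL
  if (!cfg$augment) {
    base_feats <- t(vapply(pixels, tile_input_features, numeric(p),
                           grid = cfg$input_grid))
  }

  withr::with_seed(cfg$seed, {
    W1 <- matrix(rnorm(p * h, sd = sqrt(2 / p)), p, h)
    b1 <- rep(0, h)
    W2 <- matrix(rnorm(h * 2, sd = sqrt(2 / h)), h, 2)
    b2 <- rep(0, 2)
    y <- cbind(1 - labels, labels)  # one-hot: column 2 = positive class

    history <- data.frame(epoch = integer(), lr = numeric(),
                          loss = numeric(), accuracy = numeric())
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cosine_lr(epoch - 1, cfg)
      feats <- if (cfg$augment) {
        t(vapply(pixels, function(px) {
          tile_input_features(
            augment_tile(px, crop_fraction = cfg$crop_fraction, flip = TRUE),
            grid = cfg$input_grid
          )
        }, numeric(p)))
      } else {
        base_feats
      }
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        X <- feats[idx, , drop = FALSE]
        Yb <- y[idx, , drop = FALSE]
        m <- length(idx)
        Z1 <- sweep(X %*% W1, 2, b1, "+")
        A1 <- pmax(Z1, 0)
        Z2 <- sweep(A1 %*% W2, 2, b2, "+")
        P <- softmax2(Z2)
        loss <- -mean(rowSums(Yb * log(pmax(P, 1e-12))))
        if (!is.finite(loss)) {
          stop("NaN/Inf loss at epoch ", epoch,
               " (lr = ", signif(lr, 4), "); training aborted", call. = FALSE)
        }
        ep_loss <- ep_loss + loss * m
        ep_correct <- ep_correct + sum((P[, 2] >= 0.5) == (Yb[, 2] == 1))
        dZ2 <- (P - Yb) / m
        dW2 <- t(A1) %*% dZ2
        db2 <- colSums(dZ2)
        dA1 <- dZ2 %*% t(W2)
        dZ1 <- dA1 * (Z1 > 0)
        dW1 <- t(X) %*% dZ1
        db1 <- colSums(dZ1)
        W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
        W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / n, accuracy = ep_correct / n
      ))
    }
    model <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, cfg = cfg,
                  history = history)
    class(model) <- "patch_model"
    model
  })
}

#' @export
print.patch_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("patch_model (", x$cfg$backbone, "): ", nrow(x$history),
      " epochs, final loss ", signif(last$loss, 4),
      ", train accuracy ", signif(last$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Predict class likelihoods for tiles
#'
#' Evaluation-mode forward pass (normalization only, no augmentation); the
#' softmax outputs of each tile sum to one and `likelihood` is the positive
#' (ER+) class probability.
#'
#' @param model a fitted [train_patch_model()] model.
#' @param tiles list of tiles or pixel arrays.
#' @return data frame with `slide_id`, `row`, `col` (where available),
#'   `likelihood` and `pred_label` (`1` iff `likelihood >= 0.5`).
#' @export
predict_patches <- function(model, tiles) {
  assert_that(inherits(model, "patch_model"), "model must be a patch_model")
  pixels <- lapply(tiles, function(t) if (is.list(t)) t$pixels else t)
  p <- n_input_features(model$cfg$input_grid)
  X <- t(vapply(pixels, tile_input_features, numeric(p),
                grid = model$cfg$input_grid))
  A1 <- pmax(sweep(X %*% model$W1, 2, model$b1, "+"), 0)
  P <- softmax2(sweep(A1 %*% model$W2, 2, model$b2, "+"))
  meta <- function(field, default) {
    sapply(tiles, function(t) {
      if (is.list(t) && !is.null(t[[field]])) t[[field]] else default
    })
  }
  data.frame(
    slide_id = as.character(meta("slide_id", NA_character_)),
    row = as.integer(meta("row", NA_integer_)),
    col = as.integer(meta("col", NA_integer_)),
    likelihood = P[, 2],
    pred_label = as.integer(P[, 2] >= 0.5),
    stringsAsFactors = FALSE
  )
}

#' Per-slide probability map
#'
#' Arranges the patch likelihoods of one slide on its tile grid.
#'
#' @param preds a `predict_patches()` data frame.
#' @param slide_id the slide to map.
#' @return numeric matrix of shape `(max_row + 1) x (max_col + 1)`;
#'   grid cells with no prediction are `NA` (no-data).
#' @export
probability_map <- function(preds, slide_id) {
  sub <- preds[!is.na(preds$slide_id) & preds$slide_id == slide_id, ]
  if (nrow(sub) == 0) {
    stop("no predictions for slide ", slide_id, call. = FALSE)
  }
  grid <- matrix(NA_real_, nrow = max(sub$row) + 1, ncol = max(sub$col) + 1)
  grid[cbind(sub$row + 1, sub$col + 1)] <- sub$likelihood
  grid
}
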