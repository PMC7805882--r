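# Supervised marker decoder: a residual network predicting the 12 code
# bits, trained with binary crossentropy and evaluated on the mean Hamming
# distance (MHD) -- the expected number of wrongly decoded bits per tag.
# Chance level for independent bits is n_bits / 2.

#' Build the decoder network
#'
#' A 34-layer residual network (initial convolution, four stages of basic
#' residual blocks in the 3-4-6-3 layout, global average pooling, one dense
#' output layer), starting at `base_width` feature maps (16 by default,
#' a quarter of the common width) and doubling per stage.  One sigmoid
#' output per bit; the binary-crossentropy loss acts on the logits.
#'
#' @param resolution Input image size (divisible by 8).
#' @param n_bits Number of code bits.
#' @param base_width Feature maps of the first stage.
#' @return An object of class `decoder`.
#' @export
build_decoder <- function(resolution, n_bits = 12L, base_width = 16) {
  if (resolution %% 8 != 0) stop("resolution must be divisible by 8")
  w <- base_width
  blocks <- function(n, cin, cout, stride) {
    ls <- list(nn_resblock(cin, cout, stride))
    for (i in seq_len(n - 1)) ls <- c(ls, list(nn_resblock(cout, cout)))
    ls
  }
  net <- nn_sequential(c(
    list(nn_conv(1, w), nn_bn(w), nn_act("relu")),
    blocks(3, w, w, 1),
    blocks(4, w, 2 * w, 2),
    blocks(6, 2 * w, 4 * w, 2),
    blocks(3, 4 * w, 8 * w, 2),
    list(nn_gap(), nn_dense(8 * w, n_bits))))
  structure(list(net = net, resolution = resolution, n_bits = n_bits,
                 base_width = base_width),
            class = "decoder")
}

#' Number of trainable parameters of a decoder
#' @param decoder A [build_decoder()] result.
#' @export
decoder_n_params <- function(decoder) n_parameters(decoder$net)

#' Decoder training protocol
#'
#' @param epochs Maximum number of epochs.
#' @param batches_per_epoch Batches per epoch (1,000 at full scale).
#' @param batch_size Samples per batch (128 at full scale).
#' @param patience Early stopping: stop after this many epochs without a
#'   validation-loss improvement; the best epoch's weights are returned.
#' @param mix_ratio Fraction of each batch drawn from the generated source
#'   when a real dataset is supplied alongside it.
#' @param learning_rate Adam learning rate.
#' @param augment_real Apply on-the-fly augmentation (translation,
#'   rotation, shear, histogram scaling, noise) to real-source samples.
#' @param max_translate,max_rotate,max_shear,hist_scale,noise_sd
#'   Real-data augmentation bounds (pixels, radians, radians, relative
#'   scale, intensity).
#' @param seed Integer seed.
#' @return An object of class `decoder_train_config`.
#' @export
decoder_train_config <- function(epochs = 20, batches_per_epoch = 1000,
                                 batch_size = 128, patience = 3,
                                 mix_ratio = 0.5, learning_rate = 1e-3,
                                 augment_real = TRUE, max_translate = 4,
                                 max_rotate = 10 * pi / 180,
                                 max_shear = 5 * pi / 180,
                                 hist_scale = 0.2, noise_sd = 0.08,
                                 seed = 1) {
  stopifnot(epochs >= 1, batches_per_epoch >= 1, batch_size >= 1,
            patience >= 0, mix_ratio >= 0, mix_ratio <= 1)
  structure(as.list(environment()), class = "decoder_train_config")
}

#' Train the decoder
#'
#' Trains with the configured epoch structure on one or two sources:
#' generated data is used as-is (it needs no further augmentation), real
#' data is augmented on the fly; with both, each batch interleaves the
#' sources at `mix_ratio`.  After each epoch the validation loss is
#' computed; the weights of the best epoch are kept (early stopping).
#'
#' @param config A [decoder_train_config()].
#' @param train A [labeled_dataset()], or a list of two
#'   (`list(generated = , real = )`) for the mixed regime.
#' @param val A [labeled_dataset()] used for validation.
#' @return List with `decoder` (best weights), `history` (per-epoch train
#'   and validation loss) and `best_epoch`.
#' @export
train_decoder <- function(config, train, val) {
  stopifnot(inherits(config, "decoder_train_config"))
  sources <- if (inherits(train, "labeled_dataset")) list(train) else train
  if (length(sources) == 0 || any(!vapply(sources, inherits, logical(1),
                                          "labeled_dataset"))) {
    stop("train: expected labeled_dataset(s)")
  }
  if (any(vapply(sources, dataset_size, numeric(1)) == 0) ||
      dataset_size(val) == 0) {
    stop("empty dataset")
  }
  res <- dim(sources[[1]]$images)[1]
  n_bits <- ncol(sources[[1]]$bits)
  with_seed(config$seed, {
    dec <- build_decoder(res, n_bits)
    opt <- adam_new(nn_parameters(dec$net), lr = config$learning_rate)
    is_real <- vapply(sources, function(s) s$provenance$source == "real",
                      logical(1))
    counts <- batch_source_counts(config, length(sources), is_real)
    history <- data.frame()
    best <- list(loss = Inf, state = NULL, epoch = 0)
    for (epoch in seq_len(config$epochs)) {
      tr_loss <- 0
      for (b in seq_len(config$batches_per_epoch)) {
        xb <- array(0, c(res, res, config$batch_size, 1))
        yb <- matrix(0, config$batch_size, n_bits)
        at <- 0
        for (s in seq_along(sources)) {
          ns <- counts[s]
          if (ns == 0) next
          idx <- sample.int(dataset_size(sources[[s]]), ns, replace = TRUE)
          for (j in seq_len(ns)) {
            img <- sources[[s]]$images[, , idx[j]]
            if (is_real[s] && config$augment_real) img <- augment_real_image(img, config)
            xb[, , at + j, 1] <- img
          }
          yb[at + seq_len(ns), ] <- sources[[s]]$bits[idx, ]
          at <- at + ns
        }
        zl <- nn_forward(dec$net, xb, train = TRUE)
        lo <- bce_with_logits(zl, yb)
        nn_backward(dec$net, matrix(lo$grad, nrow(zl), ncol(zl)))
        adam_step(opt)
        if (!is.finite(lo$loss)) stop("training diverged: non-finite loss")
        tr_loss <- tr_loss + lo$loss
      }
      tr_loss <- tr_loss / config$batches_per_epoch
      val_loss <- decoder_loss(dec, val)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                           val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, state = nn_state(dec$net), epoch = epoch)
      } else if (epoch - best$epoch > config$patience) {
        break
      }
    }
    nn_load_state(dec$net, best$state)
    nn_clear_cache(dec$net)
    list(decoder = dec, history = history, best_epoch = best$epoch)
  })
}

batch_source_counts <- function(config, n_sources, is_real) {
  if (n_sources == 1) return(config$batch_size)
  if (n_sources != 2) stop("train: at most two sources (generated + real)")
  n1 <- round(config$batch_size * config$mix_ratio)
  c(n1, config$batch_size - n1)
}

# translation / rotation / shear / histogram scaling / noise, the on-the-fly
# augmentation applied to real training samples
augment_real_image <- function(img, config) {
  rot <- stats::runif(1, -config$max_rotate, config$max_rotate)
  shear <- stats::runif(1, -config$max_shear, config$max_shear)
  tx <- stats::runif(1, -config$max_translate, config$max_translate)
  ty <- stats::runif(1, -config$max_translate, config$max_translate)
  img <- warp_image(img, rot, shear, ty, tx)
  img <- img * stats::runif(1, 1 - config$hist_scale, 1 + config$hist_scale)
  img <- img + matrix(stats::rnorm(length(img),
                                   sd = stats::runif(1, 0, config$noise_sd)),
                      nrow(img))
  pmin(pmax(img, -1), 1)
}

# inverse-mapped affine warp with bilinear sampling, edge-clamped
warp_image <- function(img, rot = 0, shear = 0, drow = 0, dcol = 0) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  rows <- matrix(0:(h - 1) - cy, h, w)
  cols <- matrix(0:(w - 1) - cx, h, w, byrow = TRUE)
  cr <- cos(-rot); sr <- sin(-rot)
  x1 <- cols * cr - rows * sr
  y1 <- cols * sr + rows * cr
  x1 <- x1 + shear * y1
  sy <- y1 + cy - drow
  sx <- x1 + cx - dcol
  sy <- pmin(pmax(sy, 0), h - 1)
  sx <- pmin(pmax(sx, 0), w - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  y1i <- pmin(y0 + 1, h - 1); x1i <- pmin(x0 + 1, w - 1)
  fy <- sy - y0; fx <- sx - x0
  idx <- function(r, c) img[cbind(as.vector(r) + 1, as.vector(c) + 1)]
  v <- (1 - fy) * (1 - fx) * idx(y0, x0) + (1 - fy) * fx * idx(y0, x1i) +
    fy * (1 - fx) * idx(y1i, x0) + fy * fx * idx(y1i, x1i)
  matrix(v, h, w)
}

decoder_loss <- function(dec, ds, batch = 64) {
  n <- dataset_size(ds)
  total <- 0
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    x <- ds$images[, , idx, drop = FALSE]
    dim(x) <- c(dim(x), 1)
    zl <- nn_forward(dec$net, x, train = FALSE)
    y <- ds$bits[idx, , drop = FALSE]
    total <- total + sum(pmax(zl, 0) - zl * y + log1p(exp(-abs(zl))))
  }
  nn_clear_cache(dec$net)
  total / (n * ncol(ds$bits))
}

#' Predicted bit probabilities
#'
#' @param decoder A [build_decoder()] result (typically trained).
#' @param images Array `(H, W, n)` or `(H, W, n, 1)`.
#' @param batch Evaluation batch size.
#' @return Matrix `n x n_bits` of probabilities in (0, 1).
#' @export
predict_bits <- function(decoder, images, batch = 64) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  d <- dim(images)
  if (d[1] != decoder$resolution) {
    stop("resolution mismatch: decoder expects ", decoder$resolution,
         ", images are ", d[1])
  }
  out <- matrix(0, d[3], decoder$n_bits)
  for (start in seq(1, d[3], by = batch)) {
    idx <- start:min(start + batch - 1, d[3])
    zl <- nn_forward(decoder$net, images[, , idx, , drop = FALSE], train = FALSE)
    # keep probabilities in the open interval even for saturated logits
    out[idx, ] <- pmin(pmax(sigmoid(zl), 1e-12), 1 - 1e-12)
  }
  nn_clear_cache(decoder$net)
  out
}

#' Mean Hamming distance
#'
#' The expected number of wrongly decoded bits per tag: predictions are
#' thresholded at 0.5 (a prediction of exactly 0.5 counts as 1) and
#' compared to the true bits.  Ranges over \[0, n_bits\].
#'
#' @param predictions Matrix `n x n_bits` of probabilities (or hard bits).
#' @param truth Matrix `n x n_bits` of true bits.
#' @return Scalar MHD.
#' @export
mhd <- function(predictions, truth) {
  if (!all(dim(predictions) == dim(truth))) {
    stop("shape mismatch between predictions and truth")
  }
  mean(rowSums((predictions >= 0.5) != (truth == 1)))
}

#' Evaluate a decoder on a labeled dataset
#'
#' @param decoder A trained [build_decoder()] result.
#' @param ds A [labeled_dataset()].
#' @return List with `mhd` and `per_bit` error rates.
#' @export
evaluate_decoder <- function(decoder, ds) {
  p <- predict_bits(decoder, ds$images)
  err <- (p >= 0.5) != (ds$bits == 1)
  list(mhd = mean(rowSums(err)), per_bit = colMeans(err))
}
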