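# Adversarial training of the augmentation chain.
#
# The generator maps a latent vector (plus uniformly sampled code bits) to
# the pose of the marker and to the parameter fields of the augmentation
# stages; the composed augmentations turn the idealistic render into a
# realistic image.  Because every stage is label-preserving by
# construction, whatever the generator learns, the bits fed to the
# renderer remain the ground truth of the generated image.
#
# The rasterizer is piecewise constant in the pose, so during adversarial
# training its image output is replaced by a frozen emulator network that
# reproduces the renders while letting gradients flow back into the pose
# head ("emulator" mode).  In "direct" mode the rasterizer itself is used
# and the pose head receives gradients only from the clip penalties.

#' Adversarial training configuration
#'
#' Defaults follow the published training protocol: Adam with a starting
#' learning rate of 0.0002, reduced by a factor of 0.25 in epochs 200, 250
#' and 300.  Batch size, epoch size and latent dimension are configurable;
#' desk-scale runs shrink `epochs`/`batches_per_epoch` and the resolution.
#'
#' @param resolution Image size (divisible by 8; the generator upsampling
#'   chain starts at 4x4).
#' @param z_dim Latent dimension.
#' @param batch_size Samples per training batch.
#' @param epochs,batches_per_epoch Training length.
#' @param learning_rate,lr_decay_epochs,lr_decay_factor Adam schedule.
#' @param seed Integer seed controlling all training randomness.
#' @param renderer_mode `"emulator"` (default) or `"direct"`, see above.
#' @param pose_source `"generator"` (default): the pose head predicts the
#'   marker pose; `"sampled"`: the pose is drawn uniformly from `ranges`
#'   instead and the pose head is unused.
#' @param clip_gamma Penalty weight of the clip layers.
#' @param t_clip Interval for the lighting shift field `t` (length-2
#'   numeric), or `NULL` to leave the shift unrestricted.  A bounded shift
#'   keeps weakly supervised desk-scale runs label-preserving; realistic
#'   lighting shifts are well inside the default bound.
#' @param ranges [pose_ranges()] of the marker population.
#' @param blur Optional [blur_spec()]; default scaled to `resolution`.
#' @param render_supersample Supersampling of the in-loop rasterizer.
#' @param emulator_steps,emulator_pool,emulator_batch Emulator pretraining
#'   budget (gradient steps, render pool size, batch size).
#' @param emulator_mae_target Pixelwise mean-absolute-error target at which
#'   emulator pretraining may stop early.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(resolution = 32, z_dim = 64, batch_size = 64,
                       epochs = 350, batches_per_epoch = 1000,
                       learning_rate = 2e-4,
                       lr_decay_epochs = c(200, 250, 300),
                       lr_decay_factor = 0.25, seed = 1,
                       renderer_mode = c("emulator", "direct"),
                       pose_source = c("generator", "sampled"),
                       clip_gamma = 15, t_clip = c(-0.5, 0.5),
                       ranges = pose_ranges(),
                       blur = NULL, render_supersample = 2,
                       emulator_steps = 1500, emulator_pool = 1500,
                       emulator_batch = 32, emulator_mae_target = 0.05) {
  renderer_mode <- match.arg(renderer_mode)
  pose_source <- match.arg(pose_source)
  if (resolution %% 8 != 0 || resolution < 16) {
    stop("resolution must be >= 16 and divisible by 8")
  }
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1) {
    stop("lr_decay_factor must be in (0, 1)")
  }
  if (batch_size < 2) stop("batch_size must be >= 2")
  if (is.null(blur)) blur <- blur_spec_for(resolution)
  structure(list(resolution = resolution, z_dim = z_dim,
                 batch_size = batch_size, epochs = epochs,
                 batches_per_epoch = batches_per_epoch,
                 learning_rate = learning_rate,
                 lr_decay_epochs = lr_decay_epochs,
                 lr_decay_factor = lr_decay_factor, seed = seed,
                 renderer_mode = renderer_mode, pose_source = pose_source,
                 clip_gamma = clip_gamma,
                 t_clip = t_clip, ranges = ranges, blur = blur,
                 render_supersample = render_supersample,
                 emulator_steps = emulator_steps,
                 emulator_pool = emulator_pool,
                 emulator_batch = emulator_batch,
                 emulator_mae_target = emulator_mae_target),
            class = "gan_config")
}

#' Learning rate implied by the decay schedule
#'
#' @param epoch Epoch number (1-based).
#' @param config A [gan_config()].
#' @return `learning_rate * lr_decay_factor^k` with `k` the number of decay
#'   epochs already reached.
#' @export
scheduled_lr <- function(epoch, config) {
  k <- sum(epoch >= config$lr_decay_epochs)
  config$learning_rate * config$lr_decay_factor^k
}

# ---- pose parameterization --------------------------------------------------

# The generator predicts raw pose values; additive offsets put the network's
# zero-initialization mid-range, and clip layers enforce the pose ranges.
pose_clip_specs <- function(cfg) {
  r <- cfg$ranges
  res <- cfg$resolution
  jit <- max(r$center_jitter_frac * res, 1e-6)
  list(pitch = clip_spec(r$pitch[1], r$pitch[2], cfg$clip_gamma),
       roll = clip_spec(r$roll[1], r$roll[2], cfg$clip_gamma),
       drow = clip_spec(-jit, jit, cfg$clip_gamma),
       dcol = clip_spec(-jit, jit, cfg$clip_gamma),
       radius = clip_spec(r$radius_frac[1] * res, r$radius_frac[2] * res,
                          cfg$clip_gamma))
}

# raw (N x 6) -> pose matrix (N x 6: yaw pitch roll row col radius) + penalty
pose_from_raw <- function(raw, cfg) {
  cs <- pose_clip_specs(cfg)
  res <- cfg$resolution
  mid <- (res - 1) / 2
  pen <- 0
  cl <- function(v, spec) {
    out <- clip_with_penalty(v, spec)
    pen <<- pen + out$penalty
    out$value
  }
  pose <- cbind(yaw = raw[, 1],
                pitch = cl(raw[, 2], cs$pitch),
                roll = cl(raw[, 3], cs$roll),
                center_row = mid + cl(raw[, 4], cs$drow),
                center_col = mid + cl(raw[, 5], cs$dcol),
                radius = cl(raw[, 6] + (cs$radius$a + cs$radius$b) / 2,
                            cs$radius))
  list(pose = pose, penalty = pen)
}

pose_from_raw_vjp <- function(raw, cfg, dpose, pw = 1) {
  cs <- pose_clip_specs(cfg)
  cbind(dpose[, 1],
        clip_with_penalty_vjp(raw[, 2], cs$pitch, dpose[, 2], pw),
        clip_with_penalty_vjp(raw[, 3], cs$roll, dpose[, 3], pw),
        clip_with_penalty_vjp(raw[, 4], cs$drow, dpose[, 4], pw),
        clip_with_penalty_vjp(raw[, 5], cs$dcol, dpose[, 5], pw),
        clip_with_penalty_vjp(raw[, 6] + (cs$radius$a + cs$radius$b) / 2,
                              cs$radius, dpose[, 6], pw))
}

# Normalized pose features fed to the emulator (and their pullback).
pose_features <- function(pose, resolution) {
  mid <- (resolution - 1) / 2
  cbind(sin(pose[, 1]), cos(pose[, 1]), pose[, 2], pose[, 3],
        (pose[, 4] - mid) / (resolution / 8),
        (pose[, 5] - mid) / (resolution / 8),
        (pose[, 6] - 0.36 * resolution) / (0.06 * resolution))
}

pose_features_vjp <- function(pose, resolution, dfeat) {
  cbind(cos(pose[, 1]) * dfeat[, 1] - sin(pose[, 1]) * dfeat[, 2],
        dfeat[, 3], dfeat[, 4],
        dfeat[, 5] / (resolution / 8),
        dfeat[, 6] / (resolution / 8),
        dfeat[, 7] / (0.06 * resolution))
}

# Exact renders for a pose/bits batch; returns (H,W,N,1) arrays.
render_batch <- function(pose, bits, cfg) {
  n <- nrow(pose)
  res <- cfg$resolution
  img <- array(0, c(res, res, n, 1))
  bg <- array(0, c(res, res, n, 1))
  dep <- array(0, c(res, res, n, 1))
  renders <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tag_params(bits[i, ], yaw = pose[i, 1], pitch = pose[i, 2],
                    roll = pose[i, 3], center_row = pose[i, 4],
                    center_col = pose[i, 5], radius = pose[i, 6],
                    n_bits = ncol(bits))
    r <- render_tag(p, res, supersample = cfg$render_supersample)
    renders[[i]] <- r
    img[, , i, 1] <- r$image
    bg[, , i, 1] <- r$bg_mask
    dep[, , i, 1] <- r$depth_map
  }
  list(image = img, bg = bg, depth = dep, renders = renders)
}

# ---- renderer emulator ------------------------------------------------------

build_emulator_net <- function(resolution, n_bits = 12L) {
  n_up <- as.integer(log2(resolution / 4))
  if (2^n_up * 4 != resolution) stop("resolution must be 4 * 2^k for the emulator")
  ch <- pmax(12, c(32, 16, 12, 12)[seq_len(n_up)])
  layers <- list(nn_dense(7 + n_bits, 256), nn_act("relu"),
                 nn_dense(256, 4 * 4 * 48), nn_act("relu"),
                 nn_reshape(4, 4, 48))
  prev <- 48
  for (k in seq_len(n_up)) {
    layers <- c(layers, list(nn_upsample2(), nn_conv(prev, ch[k]),
                             nn_bn(ch[k]), nn_act("relu")))
    prev <- ch[k]
  }
  layers <- c(layers, list(nn_conv(prev, 1), nn_act("tanh")))
  nn_sequential(layers)
}

#' Pretrain the renderer emulator
#'
#' Trains a small upsampling network to reproduce the rasterizer's image
#' from the pose and bits, on a pool of exact renders.  Training stops
#' after `config$emulator_steps` Adam steps or once the held-out pixelwise
#' mean absolute error drops below `config$emulator_mae_target`.  The
#' emulator's weights are frozen afterwards; its only role is to let
#' discriminator gradients reach the pose head.
#'
#' @param config A [gan_config()].
#' @param seed Integer seed.
#' @return List with `net`, final held-out `mae`, and `history` of the
#'   training MAE.
#' @export
train_emulator <- function(config, seed = config$seed) {
  with_seed(seed, {
    res <- config$resolution
    net <- build_emulator_net(res)
    pool_p <- sample_tag_params(config$emulator_pool, res, config$ranges)
    feats <- pose_features(do.call(rbind, lapply(pool_p, function(p) {
      c(p$yaw, p$pitch, p$roll, p$center_row, p$center_col, p$radius)
    })), res)
    feats <- cbind(feats, do.call(rbind, lapply(pool_p, `[[`, "bits")))
    imgs <- array(0, c(res, res, config$emulator_pool, 1))
    for (i in seq_along(pool_p)) {
      imgs[, , i, 1] <- render_tag(pool_p[[i]], res,
                                   supersample = config$render_supersample)$image
    }
    opt <- adam_new(nn_parameters(net), lr = 1e-3)
    history <- numeric(0)
    mae <- Inf
    for (step in seq_len(config$emulator_steps)) {
      idx <- sample.int(config$emulator_pool, config$emulator_batch)
      x <- feats[idx, , drop = FALSE]
      y <- imgs[, , idx, , drop = FALSE]
      out <- nn_forward(net, x, train = TRUE)
      diff <- out - y
      nn_backward(net, 2 * diff / length(diff))
      adam_step(opt)
      if (step %% 50 == 0) {
        history <- c(history, mean(abs(diff)))
        if (step %% 250 == 0) {
          hold <- sample.int(config$emulator_pool, min(128, config$emulator_pool))
          pred <- nn_forward(net, feats[hold, , drop = FALSE], train = FALSE)
          mae <- mean(abs(pred - imgs[, , hold, , drop = FALSE]))
          if (mae <= config$emulator_mae_target) break
        }
      }
    }
    hold <- sample.int(config$emulator_pool, min(256, config$emulator_pool))
    pred <- nn_forward(net, feats[hold, , drop = FALSE], train = FALSE)
    mae <- mean(abs(pred - imgs[, , hold, , drop = FALSE]))
    if (mae > config$emulator_mae_target) {
      warning(sprintf("emulator MAE %.3f above target %.3f after %d steps",
                      mae, config$emulator_mae_target, config$emulator_steps))
    }
    list(net = net, mae = mae, history = history)
  })
}

# ---- generator --------------------------------------------------------------

#' Build the generator
#'
#' A dense pose head predicts the marker pose (constrained by clip layers);
#' a dense-reshape-upsample trunk produces spatial features into which the
#' renderer's depth map is merged; from the fused features, heads predict
#' the blur amount (a feature map reduced to one scalar), the three
#' lighting fields, the background image (with the lighting output and the
#' model image merged back in) and the detail field.  Every range-bound
#' output passes through a clip-with-penalty layer.
#'
#' @param config A [gan_config()].
#' @param emulator Optional pretrained emulator (from [train_emulator()]);
#'   required later for `renderer_mode = "emulator"` training.
#' @return An object of class `generator`.
#' @export
build_generator <- function(config, emulator = NULL) {
  res <- config$resolution
  n_up <- as.integer(log2(res / 4))
  g <- new.env(parent = emptyenv())
  g$config <- config
  g$emulator <- emulator
  g$pose_head <- nn_sequential(nn_dense(config$z_dim, 64), nn_act("relu"),
                               nn_dense(64, 64), nn_act("relu"),
                               nn_dense(64, 6, init_sd = 0.05))
  trunk <- list(nn_dense(config$z_dim, 4 * 4 * 24), nn_act("relu"),
                nn_reshape(4, 4, 24))
  ch <- c(24, 16, rep(12, max(0, n_up - 2)))
  prev <- 24
  for (k in seq_len(n_up)) {
    trunk <- c(trunk, list(nn_upsample2(), nn_conv(prev, ch[k]),
                           nn_bn(ch[k]), nn_act("relu")))
    prev <- ch[k]
  }
  g$trunk <- nn_sequential(trunk)
  g$trunk_ch <- prev
  g$f_ch <- 12
  g$fuse <- nn_sequential(nn_conv(prev + 1, g$f_ch), nn_act("relu"))
  g$alpha_head <- nn_sequential(nn_conv(g$f_ch, 6), nn_act("relu"),
                                nn_conv(6, 1, init_sd = 0.02), nn_gap())
  # lighting fields are predicted at quarter resolution and upsampled:
  # coarse prediction (plus the smoothing blur inside the stage) keeps the
  # fields from painting cell-sized structure that could redraw the code
  g$light_head <- nn_sequential(nn_conv(g$f_ch, 10, stride = 2),
                                nn_act("relu"),
                                nn_conv(10, 8, stride = 2), nn_act("relu"),
                                nn_conv(8, 3, init_sd = 0.02),
                                nn_upsample2(), nn_upsample2())
  g$bg_head <- nn_sequential(nn_conv(g$f_ch + 2, 6), nn_act("relu"),
                             nn_conv(6, 1, init_sd = 0.05))
  g$detail_head <- nn_sequential(nn_conv(g$f_ch + 1, 6), nn_act("relu"),
                                 nn_conv(6, 1, init_sd = 0.05))
  g$clip <- list(alpha = clip_spec(0, 1, config$clip_gamma),
                 s = clip_spec(0.10, 1, config$clip_gamma),
                 bg = clip_spec(-1, 1, config$clip_gamma),
                 detail = clip_spec(-2, 2, config$clip_gamma),
                 t = if (!is.null(config$t_clip)) {
                   clip_spec(config$t_clip[1], config$t_clip[2],
                             config$clip_gamma)
                 })
  class(g) <- "generator"
  g
}

generator_parameters <- function(g) {
  c(nn_parameters(g$pose_head), nn_parameters(g$trunk), nn_parameters(g$fuse),
    nn_parameters(g$alpha_head), nn_parameters(g$light_head),
    nn_parameters(g$bg_head), nn_parameters(g$detail_head))
}

# per-sample broadcast helpers for (H, W, N, 1) arrays
bc <- function(v, d) array(rep(v, each = d[1] * d[2]), d)

#' Run the generator
#'
#' Maps a latent batch and uniformly sampled bits to pose, augmentation
#' parameters and the final composed images.  With `train = TRUE` (and
#' `renderer_mode = "emulator"`) the augmentation chain starts from the
#' emulator's differentiable image; otherwise from the exact render, in
#' which case `final_image` equals the composed augmentations of the
#' idealistic render exactly.
#'
#' @param g A [build_generator()] result.
#' @param z Latent matrix (n x z_dim).
#' @param bits Bit matrix (n x n_bits).
#' @param train Logical; training mode (emulator image, caches kept).
#' @return List with `pose`, `aug_params` (per-sample
#'   [augmentation_params()]), `renders`, `final_image` (H, W, n, 1 array),
#'   `taps` (per-stage batch arrays) and `penalty`.
#' @export
generator_forward <- function(g, z, bits, train = FALSE) {
  cfg <- g$config
  n <- nrow(z)
  cache <- list(z = z, bits = bits, n = n)
  pose_sampled <- identical(cfg$pose_source, "sampled")
  if (pose_sampled) {
    ps <- sample_tag_params(n, cfg$resolution, cfg$ranges)
    pose <- do.call(rbind, lapply(ps, function(p) {
      c(p$yaw, p$pitch, p$roll, p$center_row, p$center_col, p$radius)
    }))
    pose_raw <- NULL
    penalty <- 0
  } else {
    pose_raw <- nn_forward(g$pose_head, z, train)
    pr <- pose_from_raw(pose_raw, cfg)
    pose <- pr$pose
    penalty <- pr$penalty
  }
  rb <- render_batch(pose, bits, cfg)
  use_emu <- train && identical(cfg$renderer_mode, "emulator")
  x0 <- rb$image
  if (use_emu) {
    # straight-through renderer: the chain composes on the exact render,
    # while the frozen emulator (run forward here to populate its caches)
    # supplies the pose-gradient path in the backward pass
    if (is.null(g$emulator)) stop("generator has no emulator attached")
    feats <- cbind(pose_features(pose, cfg$resolution), bits)
    invisible(nn_forward(g$emulator, feats, train = FALSE))
    cache$feats <- feats
  }
  tf <- nn_forward(g$trunk, z, train)
  fused_in <- abind4(tf, rb$depth)
  f0 <- nn_forward(g$fuse, fused_in, train)
  d4 <- dim(x0)

  araw <- nn_forward(g$alpha_head, f0, train)  # n x 1
  a_in <- araw[, 1] + 0.5
  ac <- clip_with_penalty(a_in, g$clip$alpha)
  alpha <- ac$value
  penalty <- penalty + ac$penalty

  lraw <- nn_forward(g$light_head, f0, train)  # (H,W,N,3)
  swc <- clip_with_penalty(lraw[, , , 1, drop = FALSE] + 0.55, g$clip$s)
  sbc <- clip_with_penalty(lraw[, , , 2, drop = FALSE] + 0.55, g$clip$s)
  traw <- lraw[, , , 3, drop = FALSE]
  if (!is.null(g$clip$t)) {
    tc <- clip_with_penalty(traw, g$clip$t)
    tfield <- tc$value
    penalty <- penalty + tc$penalty
  } else {
    tfield <- traw
  }
  penalty <- penalty + swc$penalty + sbc$penalty

  sb <- cfg$blur$sigma_blur
  bx0 <- gaussian_blur(x0, sb)
  x1 <- (1 - bc(alpha, d4)) * x0 + bc(alpha, d4) * bx0
  W <- (x1 > 0) * 1
  bw <- gaussian_blur(swc$value, sb)
  bb <- gaussian_blur(sbc$value, sb)
  x2 <- x1 * bw * W + x1 * bb * (1 - W) + gaussian_blur(tfield, sb)

  braw <- nn_forward(g$bg_head, abind4(f0, x2, x0), train)
  bgc <- clip_with_penalty(braw, g$clip$bg)
  penalty <- penalty + bgc$penalty
  B <- rb$bg
  x3 <- x2 * (1 - B) + bgc$value * B

  draw <- nn_forward(g$detail_head, abind4(f0, x3), train)
  dc <- clip_with_penalty(draw, g$clip$detail)
  penalty <- penalty + dc$penalty
  x4 <- x3 + highpass(dc$value, cfg$blur)

  if (train) {
    g$cache <- c(cache, list(pose_raw = pose_raw, pose = pose, use_emu = use_emu,
                             x0 = x0, bx0 = bx0, alpha = alpha, a_in = a_in,
                             x1 = x1, W = W, bw = bw, bb = bb,
                             sw_in = lraw[, , , 1, drop = FALSE] + 0.55,
                             sb_in = lraw[, , , 2, drop = FALSE] + 0.55,
                             traw = traw,
                             pose_sampled = pose_sampled,
                             braw = braw, draw = draw, B = B,
                             x2 = x2, x3 = x3, d4 = d4))
  }
  aug_params <- lapply(seq_len(n), function(i) {
    augmentation_params(alpha = alpha[i],
                        s_w = swc$value[, , i, 1], s_b = sbc$value[, , i, 1],
                        t = tfield[, , i, 1], d_bg = bgc$value[, , i, 1],
                        d_detail = dc$value[, , i, 1])
  })
  list(pose = pose, aug_params = aug_params, renders = rb$renders,
       final_image = x4,
       taps = list(render = rb$image, blur = x1, lighting = x2, bg = x3),
       penalty = penalty)
}

# concatenate (H, W, N, C) arrays along channels
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  chs <- vapply(xs, function(x) dim(x)[4], numeric(1))
  out <- array(0, c(d[1], d[2], d[3], sum(chs)))
  at <- 0
  for (x in xs) {
    c_x <- dim(x)[4]
    out[, , , at + seq_len(c_x)] <- x
    at <- at + c_x
  }
  out
}

# Backpropagate d(loss)/d(final_image) plus the penalty term (weight pw)
# through the augmentation chain and all generator heads.
generator_backward <- function(g, dimg, pw = 1) {
  cfg <- g$config
  ca <- g$cache
  sb <- cfg$blur$sigma_blur
  d4 <- ca$d4

  # detail stage
  dd_detail <- highpass_adj(dimg, cfg$blur)
  ddraw <- clip_with_penalty_vjp(ca$draw, g$clip$detail, dd_detail, pw)
  fc <- g$f_ch
  ddet_in <- nn_backward(g$detail_head, ddraw)
  df0 <- ddet_in[, , , seq_len(fc), drop = FALSE]
  g3 <- dimg + ddet_in[, , , fc + 1, drop = FALSE]

  # background stage
  dd_bg <- g3 * ca$B
  dbraw <- clip_with_penalty_vjp(ca$braw, g$clip$bg, dd_bg, pw)
  dbg_in <- nn_backward(g$bg_head, dbraw)
  df0 <- df0 + dbg_in[, , , seq_len(fc), drop = FALSE]
  g2 <- g3 * (1 - ca$B) + dbg_in[, , , fc + 1, drop = FALSE]
  dx0_extra <- dbg_in[, , , fc + 2, drop = FALSE]

  # lighting stage
  ds_w <- gaussian_blur_adj(g2 * ca$x1 * ca$W, sb)
  ds_b <- gaussian_blur_adj(g2 * ca$x1 * (1 - ca$W), sb)
  dt <- gaussian_blur_adj(g2, sb)
  dsw_raw <- clip_with_penalty_vjp(ca$sw_in, g$clip$s, ds_w, pw)
  dsb_raw <- clip_with_penalty_vjp(ca$sb_in, g$clip$s, ds_b, pw)
  if (!is.null(g$clip$t)) dt <- clip_with_penalty_vjp(ca$traw, g$clip$t, dt, pw)
  dlraw <- abind4(dsw_raw, dsb_raw, dt)
  df0 <- df0 + nn_backward(g$light_head, dlraw)
  g1 <- g2 * (ca$bw * ca$W + ca$bb * (1 - ca$W))

  # blur stage
  diffs <- ca$bx0 - ca$x0
  dalpha <- vapply(seq_len(ca$n), function(i) sum(g1[, , i, 1] * diffs[, , i, 1]),
                   numeric(1))
  daraw <- clip_with_penalty_vjp(ca$a_in, g$clip$alpha, dalpha, pw)
  df0 <- df0 + nn_backward(g$alpha_head, matrix(daraw, ncol = 1))
  g0 <- (1 - bc(ca$alpha, d4)) * g1 + gaussian_blur_adj(bc(ca$alpha, d4) * g1, sb) +
    dx0_extra

  # fused features -> trunk (depth-map channel gradient is discarded)
  dfuse_in <- nn_backward(g$fuse, df0)
  nn_backward(g$trunk, dfuse_in[, , , seq_len(g$trunk_ch), drop = FALSE])

  # pose head: gradients through the emulator image (emulator mode only)
  if (!isTRUE(ca$pose_sampled)) {
    dpose <- matrix(0, ca$n, 6)
    if (ca$use_emu) {
      dfeat <- nn_backward(g$emulator, g0)
      dpose <- pose_features_vjp(ca$pose, cfg$resolution,
                                 dfeat[, 1:7, drop = FALSE])
    }
    dpose_raw <- pose_from_raw_vjp(ca$pose_raw, cfg, dpose, pw)
    nn_backward(g$pose_head, dpose_raw)
  }
  invisible(g)
}

# ---- discriminator ----------------------------------------------------------

#' Build the discriminator
#'
#' Convolutional classifier in the DCGAN family with the convolutional
#' depth doubled (a stride-1 layer before every stride-2 layer) and an
#' additional dense layer before the scalar output.  `disc_score()` maps
#' the logit through a sigmoid, so scores live in (0, 1).
#'
#' @param resolution Input image size (divisible by 8).
#' @return An `nn_layer` network returning one logit per image.
#' @export
build_discriminator <- function(resolution) {
  if (resolution %% 8 != 0) stop("resolution must be divisible by 8")
  # no batch normalization: with small mixed real/fake batches, train-mode
  # batch statistics let the discriminator separate the sources trivially
  # and its gradients stop reflecting per-image realism
  nn_sequential(
    nn_conv(1, 6), nn_act("lrelu"),
    nn_conv(6, 12, stride = 2), nn_act("lrelu"),
    nn_conv(12, 12), nn_act("lrelu"),
    nn_conv(12, 24, stride = 2), nn_act("lrelu"),
    nn_conv(24, 24), nn_act("lrelu"),
    nn_conv(24, 48, stride = 2), nn_act("lrelu"),
    nn_flatten(),
    nn_dense((resolution / 8)^2 * 48, 48), nn_act("lrelu"),
    nn_dense(48, 1))
}

#' Discriminator scores for a batch of images
#'
#' @param disc A [build_discriminator()] network.
#' @param images Array `(H, W, n)` or `(H, W, n, 1)`.
#' @return Numeric vector of scores in (0, 1), one per image.
#' @export
disc_score <- function(disc, images) {
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1)
  sigmoid(nn_forward(disc, images, train = FALSE)[, 1])
}

# ---- training loop ----------------------------------------------------------

#' Train the adversarial augmentation model
#'
#' Alternating discriminator/generator updates with the standard
#' binary-crossentropy objective; the generator loss additionally carries
#' the summed clip penalties.  The emulator is pretrained first (emulator
#' mode) and frozen.  Training aborts with a diagnostic if either loss
#' becomes non-finite.
#'
#' @param config A [gan_config()].
#' @param real_images A [labeled_dataset()] (its images are the unlabeled
#'   "real" corpus; labels are ignored) or a plain `(H, W, n)` array.
#' @return An object of class `gan_checkpoint`: networks, config and
#'   per-epoch history (`d_loss`, `g_loss`, `penalty`, `lr`,
#'   `d_acc` on balanced batches).
#' @export
train_rendergan <- function(config, real_images) {
  imgs <- if (inherits(real_images, "labeled_dataset")) real_images$images else real_images
  if (is.null(dim(imgs)) || dim(imgs)[3] < config$batch_size) {
    stop("real_images: need a nonempty image corpus of at least one batch")
  }
  n_real <- dim(imgs)[3]
  emu <- NULL
  if (identical(config$renderer_mode, "emulator")) {
    emu <- train_emulator(config)$net
  }
  with_seed(config$seed + 1L, {
    gen <- build_generator(config, emulator = emu)
    disc <- build_discriminator(config$resolution)
    g_opt <- adam_new(generator_parameters(gen), lr = config$learning_rate,
                      beta1 = 0.5)
    d_opt <- adam_new(nn_parameters(disc), lr = config$learning_rate,
                      beta1 = 0.5)
    nb <- config$batch_size
    history <- data.frame()
    for (epoch in seq_len(config$epochs)) {
      lr <- scheduled_lr(epoch, config)
      g_opt$lr <- lr
      d_opt$lr <- lr
      ep <- c(d_loss = 0, g_loss = 0, penalty = 0, d_acc = 0)
      for (b in seq_len(config$batches_per_epoch)) {
        # one generator forward serves both updates: its caches stay valid
        # until the generator's own weights change
        z <- matrix(stats::rnorm(nb * config$z_dim), nb)
        bits <- matrix(stats::rbinom(nb * 12L, 1, 0.5), nb)
        fake <- generator_forward(gen, z, bits, train = TRUE)

        # generator update against the current discriminator
        zl <- nn_forward(disc, fake$final_image, train = TRUE)
        lo_g <- bce_with_logits(zl[, 1], rep(1, nb))
        dimg <- nn_backward(disc, matrix(lo_g$grad, ncol = 1))
        generator_backward(gen, dimg, pw = 1 / nb)
        adam_step(g_opt)

        # discriminator update on a balanced real/fake batch
        ridx <- sample.int(n_real, nb)
        xr <- imgs[, , ridx, drop = FALSE]
        dim(xr) <- c(dim(xr), 1)
        xb <- abind_n(xr, fake$final_image)
        zl <- nn_forward(disc, xb, train = TRUE)
        lab <- c(rep(1, nb), rep(0, nb))
        lo_d <- bce_with_logits(zl[, 1], lab)
        nn_backward(disc, matrix(lo_d$grad, ncol = 1))
        adam_step(d_opt)
        d_acc <- mean((zl[, 1] > 0) == (lab == 1))

        g_loss <- lo_g$loss + fake$penalty / nb
        if (!is.finite(lo_d$loss) || !is.finite(g_loss)) {
          stop(sprintf("training diverged at epoch %d batch %d (d %.3f g %.3f)",
                       epoch, b, lo_d$loss, g_loss))
        }
        ep <- ep + c(lo_d$loss, g_loss, fake$penalty / nb, d_acc)
      }
      ep <- ep / config$batches_per_epoch
      history <- rbind(history,
                       data.frame(epoch = epoch, d_loss = ep[1], g_loss = ep[2],
                                  penalty = ep[3], d_acc = ep[4], lr = lr))
    }
    rownames(history) <- NULL
    gen$cache <- NULL
    for (m in list(gen$pose_head, gen$trunk, gen$fuse, gen$alpha_head,
                   gen$light_head, gen$bg_head, gen$detail_head, disc)) {
      nn_clear_cache(m)
    }
    if (!is.null(emu)) nn_clear_cache(emu)
    structure(list(config = config, history = history,
                   gen_state = generator_state(gen),
                   disc_state = nn_state(disc),
                   emulator_state = if (!is.null(emu)) nn_state(emu)),
              class = "gan_checkpoint")
  })
}

abind_n <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

generator_state <- function(g) {
  list(pose_head = nn_state(g$pose_head), trunk = nn_state(g$trunk),
       fuse = nn_state(g$fuse), alpha_head = nn_state(g$alpha_head),
       light_head = nn_state(g$light_head), bg_head = nn_state(g$bg_head),
       detail_head = nn_state(g$detail_head))
}

generator_load_state <- function(g, st) {
  nn_load_state(g$pose_head, st$pose_head)
  nn_load_state(g$trunk, st$trunk)
  nn_load_state(g$fuse, st$fuse)
  nn_load_state(g$alpha_head, st$alpha_head)
  nn_load_state(g$light_head, st$light_head)
  nn_load_state(g$bg_head, st$bg_head)
  nn_load_state(g$detail_head, st$detail_head)
  invisible(g)
}

#' Rebuild the networks stored in a checkpoint
#'
#' @param ckpt A `gan_checkpoint` (from [train_rendergan()] or
#'   [gan_load()]).
#' @return List with `gen`, `disc` and the checkpoint `config`.
#' @export
gan_restore <- function(ckpt) {
  stopifnot(inherits(ckpt, "gan_checkpoint"))
  emu <- NULL
  if (!is.null(ckpt$emulator_state)) {
    emu <- build_emulator_net(ckpt$config$resolution)
    nn_load_state(emu, ckpt$emulator_state)
  }
  gen <- with_seed(1L, build_generator(ckpt$config, emulator = emu))
  generator_load_state(gen, ckpt$gen_state)
  disc <- with_seed(1L, build_discriminator(ckpt$config$resolution))
  nn_load_state(disc, ckpt$disc_state)
  list(gen = gen, disc = disc, config = ckpt$config)
}

#' Save / load a checkpoint
#'
#' @param ckpt A `gan_checkpoint`.
#' @param path File path.
#' @return `gan_save` returns `path` invisibly; `gan_load` the checkpoint.
#' @export
gan_save <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "gan_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname gan_save
#' @export
gan_load <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "gan_checkpoint"))
  ckpt
}

# ---- discriminator-score filtering ------------------------------------------

#' Drop the least realistic generated samples
#'
#' The discriminator reliably assigns low scores to the generator's failure
#' modes (e.g. high-frequency artifacts), so the lowest-scoring fraction of
#' generated samples is discarded before supervised training.  Exactly
#' `ceiling(n * (1 - discard_fraction))` samples are retained; ties at the
#' cutoff are broken by stable input order and the original order of the
#' retained samples is preserved.
#'
#' @param samples A [labeled_dataset()] or any list of samples.
#' @param scores Numeric vector, one score per sample.
#' @param discard_fraction Fraction in \[0, 1) to drop.
#' @return The retained samples, same type as `samples`.
#' @export
filter_by_discriminator <- function(samples, scores, discard_fraction = 0.05) {
  n <- if (inherits(samples, "labeled_dataset")) dataset_size(samples) else length(samples)
  if (length(scores) != n) {
    stop("length mismatch: ", n, " samples but ", length(scores), " scores")
  }
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must be in [0, 1)")
  }
  keep_n <- ceiling(n * (1 - discard_fraction))
  ord <- order(scores, seq_len(n))    # stable: ties broken by input order
  keep <- sort(ord[seq(n - keep_n + 1, n)])
  if (inherits(samples, "labeled_dataset")) return(dataset_subset(samples, keep))
  samples[keep]
}
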