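# Labeled-dataset generation from a trained checkpoint: draw latents and
# uniform bits, run the generator on the exact renders, score the composed
# images with the discriminator and discard the least realistic fraction.
# The generated data is not augmented any further downstream.

#' Generate a labeled dataset from a trained model
#'
#' @param ckpt A `gan_checkpoint`.
#' @param n Number of retained samples to produce.
#' @param discard_fraction Fraction of lowest-discriminator-score samples
#'   to drop (must be < 0.5; larger values starve generation).
#' @param seed Integer seed; same checkpoint and seed give an identical
#'   dataset.
#' @param taps If `TRUE`, also return the per-sample stage taps needed by
#'   the hand-made baseline combos.
#' @param batch_size Generation batch size.
#' @return A [labeled_dataset()] (source `"rendergan"`), or, with
#'   `taps = TRUE`, a list with `dataset` and `taps` (lists `renders`,
#'   `lighting`, `bg`).
#' @export
generate_labeled_dataset <- function(ckpt, n, discard_fraction = 0.05,
                                     seed = 1, taps = FALSE, batch_size = 64) {
  stopifnot(inherits(ckpt, "gan_checkpoint"), n > 0)
  if (discard_fraction >= 0.5) {
    stop("filter starvation: discard_fraction >= 0.5 retains less than half ",
         "of each batch")
  }
  nets <- gan_restore(ckpt)
  cfg <- nets$config
  res <- cfg$resolution
  with_seed(seed, {
    got <- 0
    images <- array(0, c(res, res, n))
    bits_out <- matrix(0L, n, 12)
    pose_out <- matrix(0, n, 6)
    tap_renders <- vector("list", if (taps) n else 0)
    tap_light <- vector("list", if (taps) n else 0)
    tap_bg <- vector("list", if (taps) n else 0)
    while (got < n) {
      nb <- batch_size
      z <- matrix(stats::rnorm(nb * cfg$z_dim), nb)
      bits <- matrix(stats::rbinom(nb * 12L, 1, 0.5), nb)
      out <- generator_forward(nets$gen, z, bits, train = FALSE)
      scores <- disc_score(nets$disc, out$final_image)
      keep <- filter_by_discriminator(seq_len(nb), scores, discard_fraction)
      for (i in keep) {
        if (got >= n) break
        got <- got + 1
        images[, , got] <- pmin(pmax(out$final_image[, , i, 1], -1), 1)
        bits_out[got, ] <- bits[i, ]
        pose_out[got, ] <- out$pose[i, ]
        if (taps) {
          tap_renders[[got]] <- out$renders[[i]]
          tap_light[[got]] <- out$taps$lighting[, , i, 1]
          tap_bg[[got]] <- out$taps$bg[, , i, 1]
        }
      }
    }
    ds <- labeled_dataset(images, bits_out, pose_out,
                          list(source = "rendergan",
                               config_hash = config_hash(cfg), seed = seed))
    if (!taps) return(ds)
    list(dataset = ds, taps = list(renders = tap_renders, lighting = tap_light,
                                   bg = tap_bg))
  })
}

#' Dataset of idealistic (unaugmented) renders
#'
#' Baseline training data straight from the parametric model: binary
#' images, no blur, lighting, background or noise.
#'
#' @param n Number of samples.
#' @param resolution Image size.
#' @param ranges [pose_ranges()].
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with source `"idealistic"`.
#' @export
idealistic_dataset <- function(n, resolution = 64, ranges = pose_ranges(),
                               seed = 1) {
  with_seed(seed, {
    params <- sample_tag_params(n, resolution, ranges)
    images <- array(0, c(resolution, resolution, n))
    bits <- matrix(0L, n, params[[1]]$n_bits)
    pose <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      images[, , i] <- render_tag(params[[i]], resolution)$image
      bits[i, ] <- params[[i]]$bits
      pose[i, ] <- unlist(params[[i]][c("yaw", "pitch", "roll", "center_row",
                                        "center_col", "radius")])
    }
    labeled_dataset(images, bits, pose,
                    list(source = "idealistic", config_hash = "", seed = seed))
  })
}
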