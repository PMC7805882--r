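# Hand-designed augmentation samplers: blur, lighting, pyramid background,
# spotlights and sensor noise with randomly drawn (not learned) parameters.
# They serve two purposes: baseline datasets that isolate the value of each
# learned stage, and a stand-in "real image" distribution for adversarial
# training at desk scale.

#' Hand-made augmentation configuration
#'
#' Distribution parameters for each hand-designed effect.  The defaults are
#' sized for `resolution`-pixel crops and were chosen so that the reference
#' decoder still recovers the code on augmented images; that invariant
#' (recovery rate >= `min_recovery` on a Monte-Carlo sample) is verified at
#' construction time and the result cached per configuration.
#'
#' @param resolution Working image size in pixels.
#' @param alpha_range Range of the blur amount.
#' @param field_sd,smooth_frac,t_max Lighting-field parameters, see
#'   [sample_augmentation_params()].
#' @param pyramid_scales Per-level intensity scales of the background image
#'   pyramid, coarsest first; the number of levels is their length and
#'   `resolution` must be divisible by `2^(levels - 1)`.
#' @param noise_range Range of the additive Gaussian noise sigma.
#' @param max_spots Maximum number of spotlights per image.
#' @param spot_radius_frac Spotlight radius range as a fraction of the tag
#'   radius (a spotlight is a little smaller than a code cell).
#' @param spot_amp Spotlight amplitude range.
#' @param blur Optional [blur_spec()]; defaults to
#'   [blur_spec_for()]`(resolution)`.
#' @param min_recovery Required reference-decoder recovery rate.
#' @param n_check Monte-Carlo sample size for the construction-time check.
#' @return An object of class `handmade_config`.
#' @export
handmade_config <- function(resolution = 64,
                            alpha_range = c(0, 1),
                            field_sd = 0.35, smooth_frac = 0.25, t_max = 0.3,
                            pyramid_scales = c(0.6, 0.3, 0.15, 0.1),
                            noise_range = c(0.02, 0.08),
                            max_spots = 2,
                            spot_radius_frac = c(0.12, 0.25),
                            spot_amp = c(0.2, 0.5),
                            blur = NULL,
                            min_recovery = 0.9, n_check = 80) {
  for (nm in c("alpha_range", "noise_range", "spot_radius_frac", "spot_amp")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] > r[2] || any(r < 0)) {
      stop(nm, ": invalid range")
    }
  }
  if (any(pyramid_scales < 0)) stop("pyramid_scales: must be non-negative")
  levels <- length(pyramid_scales)
  if (resolution %% 2^(levels - 1) != 0) {
    stop("resolution must be a multiple of 2^(levels - 1)")
  }
  if (is.null(blur)) blur <- blur_spec_for(resolution)
  cfg <- structure(list(resolution = resolution, alpha_range = alpha_range,
                        field_sd = field_sd, smooth_frac = smooth_frac,
                        t_max = t_max, pyramid_scales = pyramid_scales,
                        noise_range = noise_range, max_spots = max_spots,
                        spot_radius_frac = spot_radius_frac,
                        spot_amp = spot_amp, blur = blur,
                        min_recovery = min_recovery),
                   class = "handmade_config")
  check_handmade_recovery(cfg, n_check)
  cfg
}

.hm_recovery_cache <- new.env(parent = emptyenv())

check_handmade_recovery <- function(cfg, n_check) {
  key <- paste(deparse(unclass(cfg)), collapse = "")
  hit <- .hm_recovery_cache[[key]]
  if (!is.null(hit)) return(invisible(hit))
  rate <- with_seed(990017, {
    mean(vapply(seq_len(n_check), function(i) {
      p <- sample_tag_params(1, cfg$resolution)[[1]]
      r <- render_tag(p, cfg$resolution)
      x <- hm_augment(r, cfg, .check = FALSE)
      all(reference_decode(x, p) == p$bits)
    }, logical(1)))
  })
  if (rate < cfg$min_recovery) {
    stop(sprintf(paste0("hand-made augmentation config is not label-",
                        "preserving: recovery %.2f < %.2f"),
                 rate, cfg$min_recovery))
  }
  .hm_recovery_cache[[key]] <- rate
  invisible(rate)
}

#' Random background from an image pyramid
#'
#' Sums nearest-neighbour-upsampled grids of independently drawn uniform
#' intensities, one grid per pyramid level (coarsest level first, each
#' scaled by its configured intensity), and clips to \[-1, 1\].
#'
#' @param resolution Output size; must be divisible by `2^(levels - 1)`.
#' @param config A [handmade_config()].
#' @param seed Optional integer seed.
#' @return Background image matrix in \[-1, 1\].
#' @export
pyramid_background <- function(resolution, config = handmade_config(resolution),
                               seed = NULL) {
  scales <- config$pyramid_scales
  levels <- length(scales)
  if (resolution %% 2^(levels - 1) != 0) {
    stop("resolution must be a multiple of 2^(levels - 1)")
  }
  with_seed(seed, {
    bg <- matrix(0, resolution, resolution)
    for (l in seq_len(levels)) {
      g <- resolution / 2^(levels - l)
      grid <- matrix(stats::runif(g * g, -1, 1) * scales[l], g, g)
      f <- resolution / g
      if (f > 1) grid <- grid[rep(seq_len(g), each = f), rep(seq_len(g), each = f)]
      bg <- bg + grid
    }
    pmin(pmax(bg, -1), 1)
  })
}

hm_spotlights <- function(x, params, config) {
  if (config$max_spots == 0 || config$spot_amp[2] == 0) return(x)
  n_spots <- sample.int(config$max_spots + 1, 1) - 1
  if (n_spots == 0) return(x)
  h <- nrow(x); w <- ncol(x)
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (i in seq_len(n_spots)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- params$radius * sqrt(stats::runif(1)) * 0.85
    cr <- params$center_row + rad * sin(ang)
    cc <- params$center_col + rad * cos(ang)
    sr <- params$radius * stats::runif(1, config$spot_radius_frac[1],
                                       config$spot_radius_frac[2])
    amp <- stats::runif(1, config$spot_amp[1], config$spot_amp[2])
    x <- x + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sr^2))
  }
  x
}

#' Apply all hand-made augmentations to a render
#'
#' Sampled blur, lighting, pyramid background, spotlights and additive
#' Gaussian noise, in that order, reusing the differentiable stage
#' operators with randomly drawn parameters.  The result is clipped to
#' \[-1, 1\] (sensor saturation).
#'
#' @param render A [render_tag()] result.
#' @param config A [handmade_config()].
#' @param seed Optional integer seed; same seed, same output.
#' @param .check Internal; disables the construction-time recovery check
#'   when the config is being validated.
#' @return Augmented image matrix.
#' @export
hm_augment <- function(render, config = handmade_config(nrow(render$image)),
                       seed = NULL, .check = TRUE) {
  stopifnot(inherits(render, "tag_render"))
  with_seed(seed, {
    res <- nrow(render$image)
    # every effect whose scales are all zero is an exact identity
    alpha <- stats::runif(1, config$alpha_range[1], config$alpha_range[2])
    x <- phi_blur(render$image, alpha, config$blur)
    if (config$field_sd > 0 || config$t_max > 0) {
      ap <- sample_augmentation_params(res, smooth_frac = config$smooth_frac,
                                       field_sd = config$field_sd,
                                       t_max = config$t_max)
      x <- phi_lighting(x, ap$s_w, ap$s_b, ap$t, config$blur)
    }
    if (any(config$pyramid_scales > 0)) {
      x <- phi_bg(x, pyramid_background(res, config), render$bg_mask)
    }
    x <- hm_spotlights(x, render$params, config)
    if (config$noise_range[2] > 0) {
      sigma <- stats::runif(1, config$noise_range[1], config$noise_range[2])
      x <- x + matrix(stats::rnorm(res * res, sd = sigma), res, res)
    }
    pmin(pmax(x, -1), 1)
  })
}

#' Sample a corpus of hand-made-augmented marker images
#'
#' Convenience wrapper used as the desk-scale "real image" corpus for
#' adversarial training: random tags, rendered and hand-augmented.
#'
#' @param n Number of images.
#' @param resolution Image size.
#' @param config A [handmade_config()].
#' @param ranges [pose_ranges()] for the tag population.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with source `"real"`.
#' @export
hm_corpus <- function(n, resolution = 64,
                      config = handmade_config(resolution),
                      ranges = pose_ranges(), seed = 1) {
  with_seed(seed, {
    params <- sample_tag_params(n, resolution, ranges)
    images <- array(0, c(resolution, resolution, n))
    bits <- matrix(0L, n, params[[1]]$n_bits)
    pose <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      r <- render_tag(params[[i]], resolution)
      images[, , i] <- hm_augment(r, config)
      bits[i, ] <- params[[i]]$bits
      pose[i, ] <- unlist(params[[i]][c("yaw", "pitch", "roll", "center_row",
                                        "center_col", "radius")])
    }
    labeled_dataset(images, bits, pose,
                    list(source = "real", config_hash = config_hash(config),
                         seed = seed))
  })
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  # small stable checksum; enough to detect config changes in provenance
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %% .Machine$integer.max)
}

#' Baseline datasets mixing learned and hand-made stages
#'
#' Builds the three stage-combination baselines: `hm3d` applies all
#' hand-made effects to the idealistic render; `hmli` starts from the
#' learned blur+lighting output and adds hand-made background, spotlights
#' and noise; `hmbg` starts from the learned background output and adds
#' hand-made spotlights and noise.  Together with the fully learned
#' pipeline, the set of effects applied is always
#' \{blur, lighting, background, noise, spotlights\}.
#'
#' @param combo One of `"hm3d"`, `"hmli"`, `"hmbg"`.
#' @param stage_taps List with per-sample stage outputs: `renders` (list of
#'   [render_tag()] objects; always required), `lighting` (list of learned
#'   blur+lighting images; required for `hmli`), `bg` (list of learned
#'   background-stage images; required for `hmbg`).
#' @param n Number of samples (at most the number of taps).
#' @param config A [handmade_config()].
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with the combo as source.
#' @export
make_baseline_dataset <- function(combo = c("hm3d", "hmli", "hmbg"),
                                  stage_taps, n = length(stage_taps$renders),
                                  config = NULL, seed = 1) {
  combo <- match.arg(combo)
  renders <- stage_taps$renders
  if (is.null(renders) || length(renders) < n) {
    stop("stage_taps$renders: need ", n, " idealistic renders")
  }
  need <- switch(combo, hm3d = NULL, hmli = "lighting", hmbg = "bg")
  if (!is.null(need) && (is.null(stage_taps[[need]]) ||
                         length(stage_taps[[need]]) < n)) {
    stop("stage_taps$", need, ": missing taps required for combo ", combo)
  }
  resolution <- nrow(renders[[1]]$image)
  if (is.null(config)) config <- handmade_config(resolution)
  with_seed(seed, {
    images <- array(0, c(resolution, resolution, n))
    nb <- renders[[1]]$params$n_bits
    bits <- matrix(0L, n, nb)
    pose <- matrix(0, n, 6)
    for (i in seq_len(n)) {
      r <- renders[[i]]
      p <- r$params
      x <- switch(combo,
        hm3d = {
          alpha <- stats::runif(1, config$alpha_range[1], config$alpha_range[2])
          x <- phi_blur(r$image, alpha, config$blur)
          if (config$field_sd > 0 || config$t_max > 0) {
            ap <- sample_augmentation_params(resolution,
                                             smooth_frac = config$smooth_frac,
                                             field_sd = config$field_sd,
                                             t_max = config$t_max)
            x <- phi_lighting(x, ap$s_w, ap$s_b, ap$t, config$blur)
          }
          if (any(config$pyramid_scales > 0)) {
            x <- phi_bg(x, pyramid_background(resolution, config), r$bg_mask)
          }
          x
        },
        hmli = phi_bg(stage_taps$lighting[[i]],
                      pyramid_background(resolution, config), r$bg_mask),
        hmbg = stage_taps$bg[[i]])
      x <- hm_spotlights(x, p, config)
      if (config$noise_range[2] > 0) {
        sigma <- stats::runif(1, config$noise_range[1], config$noise_range[2])
        x <- x + matrix(stats::rnorm(resolution^2, sd = sigma),
                        resolution, resolution)
      }
      images[, , i] <- pmin(pmax(x, -1), 1)
      bits[i, ] <- p$bits
      pose[i, ] <- unlist(p[c("yaw", "pitch", "roll", "center_row",
                              "center_col", "radius")])
    }
    labeled_dataset(images, bits, pose,
                    list(source = combo, config_hash = config_hash(config),
                         seed = seed))
  })
}
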