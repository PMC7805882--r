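# The four differentiable, label-preserving augmentation stages and the
# clip-with-penalty layer.
#
# All stages operate on single images (numeric matrices) in the [-1, 1]
# intensity convention.  Each stage has an explicit backward companion
# (suffix _vjp) returning vector-Jacobian products with respect to every
# input, so the stages can sit inside an adversarially trained generator.
# The white/black segmentation W(x) is a hard threshold and is treated as
# locally constant by the backward passes.

#' Augmentation parameters for one image
#'
#' The parameter ranges are exactly the label-preserving ranges: the blur
#' amount cannot exceed the fixed kernel scale, the lighting scalings keep
#' black parts darker than white parts, the background image can only touch
#' background pixels, and the detail field is bounded and high-pass
#' filtered.  Out-of-range values are a constructor error; during
#' adversarial training the clip layer is what enforces the ranges.
#'
#' @param alpha Scalar blur amount in \[0, 1\].
#' @param s_w,s_b Matrices of white/black intensity scalings in \[0.10, 1\].
#' @param t Matrix of additive intensity shifts (unrestricted).
#' @param d_bg Matrix of background intensities in \[-1, 1\].
#' @param d_detail Matrix of detail intensities in \[-2, 2\].
#' @return An object of class `augmentation_params`.
#' @export
augmentation_params <- function(alpha, s_w, s_b, t, d_bg, d_detail) {
  if (length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha: must be a scalar in [0, 1]")
  }
  if (any(s_w < 0.10 - 1e-12) || any(s_w > 1 + 1e-12)) {
    stop("s_w: values must lie in [0.10, 1]")
  }
  if (any(s_b < 0.10 - 1e-12) || any(s_b > 1 + 1e-12)) {
    stop("s_b: values must lie in [0.10, 1]")
  }
  if (any(abs(d_bg) > 1 + 1e-12)) stop("d_bg: values must lie in [-1, 1]")
  if (any(abs(d_detail) > 2 + 1e-12)) stop("d_detail: values must lie in [-2, 2]")
  structure(list(alpha = alpha, s_w = s_w, s_b = s_b, t = t,
                 d_bg = d_bg, d_detail = d_detail),
            class = "augmentation_params")
}

#' Blur stage
#'
#' `phi_blur(x, alpha) = (1 - alpha) (x - b(x)) + b(x)` with `b` the
#' Gaussian blur at `spec$sigma_blur`: a convex interpolation between the
#' sharp image and its blurred copy, in the spirit of a Laplacian pyramid
#' level.  The bounded kernel scale is what preserves the labels.
#'
#' @param x Image matrix.
#' @param alpha Blur amount in \[0, 1\]; 0 = identity, 1 = full blur.
#' @param spec A [blur_spec()].
#' @return Blurred image, same shape.
#' @export
phi_blur <- function(x, alpha, spec = blur_spec()) {
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha: must be a scalar in [0, 1]")
  }
  b <- gaussian_blur(x, spec$sigma_blur)
  (1 - alpha) * x + alpha * b
}

phi_blur_vjp <- function(x, alpha, g, spec = blur_spec()) {
  b <- gaussian_blur(x, spec$sigma_blur)
  list(dx = (1 - alpha) * g + alpha * gaussian_blur_adj(g, spec$sigma_blur),
       dalpha = sum(g * (b - x)))
}

#' White/black segmentation mask
#'
#' Thresholds at 0, the midpoint of the -1/+1 intensity convention:
#' 1 where `x > 0` (white parts), 0 elsewhere.
#'
#' @param x Image matrix.
#' @return Binary matrix, same shape.
#' @export
white_mask <- function(x) (x > 0) * 1

#' Lighting stage
#'
#' Smooth multiplicative scaling of the white and black parts plus a smooth
#' additive shift:
#' `x b(s_w) W(x) + x b(s_b) (1 - W(x)) + b(t)`.
#' Because `s_w` and `s_b` are restricted to \[0.10, 1\], black marker
#' cells always stay darker than white ones, so no bit can flip.
#'
#' @param x Image matrix.
#' @param s_w,s_b,t Parameter fields, same shape as `x`.
#' @param spec A [blur_spec()]; its `sigma_blur` smooths the fields.
#' @return Lit image, same shape.
#' @export
phi_lighting <- function(x, s_w, s_b, t, spec = blur_spec()) {
  if (any(s_w < 0.10 - 1e-9) || any(s_w > 1 + 1e-9)) {
    stop("s_w: values must lie in [0.10, 1]")
  }
  if (any(s_b < 0.10 - 1e-9) || any(s_b > 1 + 1e-9)) {
    stop("s_b: values must lie in [0.10, 1]")
  }
  W <- white_mask(x)
  s <- spec$sigma_blur
  x * gaussian_blur(s_w, s) * W + x * gaussian_blur(s_b, s) * (1 - W) +
    gaussian_blur(t, s)
}

phi_lighting_vjp <- function(x, s_w, s_b, t, g, spec = blur_spec()) {
  W <- white_mask(x)
  s <- spec$sigma_blur
  bw <- gaussian_blur(s_w, s)
  bb <- gaussian_blur(s_b, s)
  list(dx = g * (bw * W + bb * (1 - W)),
       ds_w = gaussian_blur_adj(g * x * W, s),
       ds_b = gaussian_blur_adj(g * x * (1 - W), s),
       dt = gaussian_blur_adj(g, s))
}

#' Background stage
#'
#' Pixelwise selection `x (1 - B) + d (B)`: background pixels (B = 1) are
#' replaced by the generated background image, foreground pixels are passed
#' through bit-identically, so the marker itself cannot be touched.
#'
#' @param x Image matrix.
#' @param d_bg Background image, same shape.
#' @param B Binary background mask (1 = background), same shape.
#' @return Composited image.
#' @export
phi_bg <- function(x, d_bg, B) {
  if (!all(dim(x) == dim(d_bg)) || !all(dim(x) == dim(B))) {
    stop("shape mismatch between image, background and mask")
  }
  x * (1 - B) + d_bg * B
}

phi_bg_vjp <- function(g, B) list(dx = g * (1 - B), dd_bg = g * B)

#' Detail stage
#'
#' Adds a high-pass-filtered detail field: `x + highpass(d)`.  The iterated
#' high-pass filter removes everything at the spatial scale of a code cell
#' and above, so the added detail cannot flip a bit; the \[-2, 2\] bound on
#' `d` keeps the generator from overwhelming the filter.
#'
#' @param x Image matrix.
#' @param d_detail Detail field in \[-2, 2\], same shape as `x`.
#' @param spec A [blur_spec()].
#' @return Detailed image.
#' @export
phi_detail <- function(x, d_detail, spec = blur_spec()) {
  if (any(abs(d_detail) > 2 + 1e-9)) stop("d_detail: values must lie in [-2, 2]")
  x + highpass(d_detail, spec)
}

phi_detail_vjp <- function(g, spec = blur_spec()) {
  list(dx = g, dd_detail = highpass_adj(g, spec))
}

#' Compose all augmentation stages
#'
#' Applies blur, lighting, background and detail in that order to the
#' idealistic render.  The white mask inside the lighting stage is computed
#' on the blur-stage output (the stage's own input); the background mask is
#' the render's.
#'
#' @param render A [render_tag()] result.
#' @param params An [augmentation_params()].
#' @param spec A [blur_spec()].
#' @param taps If `TRUE`, return the per-stage outputs as a list
#'   (`blur`, `lighting`, `bg`, `detail`, `image`) instead of just the
#'   final image.
#' @return The augmented image matrix, or the stage-tap list.
#' @export
compose_augmentations <- function(render, params, spec = blur_spec(),
                                  taps = FALSE) {
  stopifnot(inherits(render, "tag_render"),
            inherits(params, "augmentation_params"))
  x1 <- phi_blur(render$image, params$alpha, spec)
  x2 <- phi_lighting(x1, params$s_w, params$s_b, params$t, spec)
  x3 <- phi_bg(x2, params$d_bg, render$bg_mask)
  x4 <- phi_detail(x3, params$d_detail, spec)
  if (taps) return(list(blur = x1, lighting = x2, bg = x3, detail = x4,
                        image = x4))
  x4
}

#' Interval specification for the clip layer
#'
#' @param a,b Interval bounds, `a < b`.
#' @param gamma Non-negative penalty weight; 15 by default.
#' @return An object of class `clip_spec`.
#' @export
clip_spec <- function(a, b, gamma = 15) {
  if (!(a < b)) stop("clip interval requires a < b")
  if (gamma < 0) stop("gamma: must be >= 0")
  structure(list(a = a, b = b, gamma = gamma), class = "clip_spec")
}

#' Clip to an interval with an out-of-bounds penalty
#'
#' Hard clipping `min(max(a, x), b)` combined with an L1 activity penalty
#' `gamma * |x - a|` below the interval and `gamma * |x - b|` above it,
#' summed over elements.  Saturating activations starve the upstream
#' network of gradients; the hard clip passes gradients unchanged inside
#' the interval and the penalty supplies a corrective gradient outside it.
#' The penalty is continuous (zero) at both boundaries.
#'
#' @param x Numeric vector, matrix or array.
#' @param spec A [clip_spec()].
#' @return List with `value` (clipped, same shape as `x`) and `penalty`
#'   (scalar).
#' @export
clip_with_penalty <- function(x, spec) {
  stopifnot(inherits(spec, "clip_spec"))
  v <- pmin(pmax(x, spec$a), spec$b)
  if (is.array(x)) dim(v) <- dim(x)
  pen <- spec$gamma * (sum((spec$a - x)[x < spec$a]) + sum((x - spec$b)[x > spec$b]))
  list(value = v, penalty = pen)
}

# VJP of the clip layer: the clip passes gradients unchanged inside [a, b]
# and zero outside; the penalty contributes gamma * sign outside.  g is the
# gradient on the clipped value; pw the weight on the penalty term.
clip_with_penalty_vjp <- function(x, spec, g, pw = 1) {
  inside <- x >= spec$a & x <= spec$b
  dx <- g * inside + pw * spec$gamma * ((x > spec$b) - (x < spec$a))
  if (is.array(x)) dim(dx) <- dim(x)
  dx
}

#' Sample random in-range augmentation parameters
#'
#' Draws spatially smooth random parameter fields inside the
#' label-preserving ranges: the lighting and background fields are blurred
#' white noise squashed into their intervals, the detail field mixes a
#' smooth component with pixel noise.  Used by the hand-made augmentation
#' baselines and by the label-preservation checks.
#'
#' @param resolution Image size the fields are drawn at.
#' @param seed Optional integer seed.
#' @param smooth_frac Correlation length of the smooth fields as a fraction
#'   of the image size.
#' @param field_sd Standard deviation of the normalized smooth field before
#'   squashing (controls how much the lighting varies across the tag).
#' @param t_max Maximum amplitude of the additive lighting shift.
#' @param detail_noise_max Maximum standard deviation of the pixel-noise
#'   component of the detail field.
#' @return An [augmentation_params()].
#' @export
sample_augmentation_params <- function(resolution, seed = NULL,
                                       smooth_frac = 0.25, field_sd = 0.35,
                                       t_max = 0.3, detail_noise_max = 0.3) {
  with_seed(seed, {
    r <- resolution
    sf <- function() {
      f <- gaussian_blur(matrix(stats::rnorm(r * r), r, r), smooth_frac * r)
      f <- f / max(stats::sd(f), 1e-8) * field_sd
      f
    }
    squash01 <- function(f) (tanh(f) + 1) / 2
    s_w <- 0.10 + 0.90 * squash01(sf())
    s_b <- 0.10 + 0.90 * squash01(sf())
    t <- stats::runif(1, 0, t_max) * tanh(sf())
    d_bg <- tanh(sf() * 2)
    noise <- matrix(stats::rnorm(r * r, sd = stats::runif(1, 0, detail_noise_max)), r, r)
    d_detail <- pmin(pmax(1.5 * tanh(sf()) + noise, -2), 2)
    augmentation_params(alpha = stats::runif(1), s_w = s_w, s_b = s_b, t = t,
                        d_bg = d_bg, d_detail = d_detail)
  })
}
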