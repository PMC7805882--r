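# Separable Gaussian blur and the derived high-pass filter.
#
# The blur is a linear operator: blurring an H x W image is
# B_H %*% X %*% t(B_W) with B_n the 1-D blur matrix at scale sigma
# (kernel truncated at 3 sigma, reflect-padded borders, rows sum to one).
# Linearity gives the exact adjoint (transpose matrices), which is what the
# augmentation backward passes use.

#' Blur and high-pass filter settings
#'
#' Bundles the Gaussian scales used by the augmentation stages: `sigma_blur`
#' is the scale of the blur stage and of the smoothing applied to the
#' lighting fields; `sigma_highpass` and `highpass_repeats` define the
#' high-pass filter of the detail stage (difference from a blurred copy,
#' iterated to sharpen the frequency cutoff).
#'
#' @param sigma_blur Gaussian scale (pixels) for the blur stage; default 2.
#' @param sigma_highpass Gaussian scale (pixels) inside the high-pass
#'   filter; default 3.5.
#' @param highpass_repeats How often the high-pass filter is applied;
#'   default 3.
#' @return An object of class `blur_spec`.
#' @export
blur_spec <- function(sigma_blur = 2, sigma_highpass = 3.5, highpass_repeats = 3) {
  stopifnot(sigma_blur > 0, sigma_highpass > 0, highpass_repeats >= 1)
  structure(list(sigma_blur = sigma_blur, sigma_highpass = sigma_highpass,
                 highpass_repeats = as.integer(highpass_repeats)),
            class = "blur_spec")
}

#' Blur settings scaled to a working resolution
#'
#' The default kernel scales (blur sigma 2, high-pass sigma 3.5) are sized
#' for 64-pixel marker crops, where a code cell is about 6 pixels wide.  At
#' other resolutions the kernels must shrink or grow with the image so that
#' the blur stays label-preserving relative to the cell size.
#'
#' @param resolution Working image size in pixels.
#' @param base_resolution Resolution the default scales refer to.
#' @return A [blur_spec()] with proportionally scaled sigmas.
#' @export
blur_spec_for <- function(resolution, base_resolution = 64) {
  f <- resolution / base_resolution
  blur_spec(sigma_blur = 2 * f, sigma_highpass = 3.5 * f, highpass_repeats = 3)
}

.blur_cache <- new.env(parent = emptyenv())

# 1-D Gaussian blur matrix with reflect (edge-duplicated) padding.
blur_matrix <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in -r:r) {
      j <- i + k
      if (j < 1) j <- 1 - j
      if (j > n) j <- 2 * n + 1 - j
      j <- max(1, min(n, j))
      B[i, j] <- B[i, j] + w[k + r + 1]
    }
  }
  .blur_cache[[key]] <- B
  B
}

# Gaussian blur of a matrix (H x W) or batch array (H, W, N, C).
gaussian_blur <- function(x, sigma, transpose = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) {
    Bh <- blur_matrix(nrow(x), sigma)
    Bw <- blur_matrix(ncol(x), sigma)
    if (transpose) return(crossprod(Bh, x %*% Bw))
    return(Bh %*% tcrossprod(x, Bw))
  }
  stopifnot(length(d) == 4)
  Bh <- blur_matrix(d[1], sigma)
  Bw <- blur_matrix(d[2], sigma)
  if (transpose) { Bh <- t(Bh); Bw <- t(Bw) }
  m <- x
  dim(m) <- c(d[1], d[2] * d[3] * d[4])
  m <- Bh %*% m
  dim(m) <- d
  m <- aperm(m, c(2, 1, 3, 4))
  dim(m) <- c(d[2], d[1] * d[3] * d[4])
  m <- Bw %*% m
  dim(m) <- c(d[2], d[1], d[3], d[4])
  aperm(m, c(2, 1, 3, 4))
}

# Adjoint of gaussian_blur, used by backward passes.
gaussian_blur_adj <- function(g, sigma) gaussian_blur(g, sigma, transpose = TRUE)

#' High-pass filter an image
#'
#' Subtracts a Gaussian-blurred copy from the image and repeats the
#' operation `spec$highpass_repeats` times.  The iterated filter attenuates
#' low frequencies strongly enough that the detail stage cannot move the
#' mean intensity of a code cell.  Linear in its input.
#'
#' @param d Image matrix (H x W) or batch array (H, W, N, C).
#' @param spec A [blur_spec()].
#' @return Filtered image, same shape as `d`.
#' @export
highpass <- function(d, spec = blur_spec()) {
  for (i in seq_len(spec$highpass_repeats)) {
    d <- d - gaussian_blur(d, spec$sigma_highpass)
  }
  d
}

highpass_adj <- function(g, spec = blur_spec()) {
  for (i in seq_len(spec$highpass_repeats)) {
    g <- g - gaussian_blur_adj(g, spec$sigma_highpass)
  }
  g
}
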