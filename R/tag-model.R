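# Parametric model of the circular bee marker.
#
# The marker is modelled as a flat disc: the outer annulus is divided into
# 12 equal 30-degree sectors carrying the binary code, and the inner disc is
# split into two semicircles (one white, one black) that encode the
# orientation.  The disc is rotated in 3D (yaw about the view axis, then
# pitch, then roll), projected orthographically, and rasterized with 4x
# supersampling followed by thresholding so the idealistic image stays
# binary.  Intensities: white = +1, black = -1, background = -1.
#
# Conventions: 0-based pixel coordinates, origin top-left, row-major;
# angles in radians; yaw 0 points the tag's "north" toward image row 0;
# code cell 0 starts at north and the cells proceed clockwise; the white
# orientation semicircle is the clockwise (east) half of the inner disc.

TAG_WHITE <- 1
TAG_BLACK <- -1
TAG_BG <- -1
INNER_FRAC <- 0.5

#' Marker parameters (the label)
#'
#' @param bits Integer vector of code bits (0/1), one per code cell.
#' @param yaw,pitch,roll Orientation in radians.  Yaw is the in-plane
#'   rotation (unrestricted); pitch and roll tilt the disc out of plane and
#'   are limited to `pose_limit` so the code stays visible.
#' @param center_row,center_col Marker center in pixels (0-based,
#'   origin top-left).
#' @param radius Marker radius in pixels, > 0.
#' @param n_bits Number of code cells (default 12).
#' @param pose_limit Maximum |pitch| and |roll| in radians (default 60 deg).
#' @return An object of class `tag_params`.
#' @export
tag_params <- function(bits, yaw = 0, pitch = 0, roll = 0,
                       center_row = 31.5, center_col = 31.5, radius = 24,
                       n_bits = 12L, pose_limit = pi / 3) {
  bits <- as.integer(bits)
  if (length(bits) != n_bits || anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("bits: must be ", n_bits, " values in {0, 1}")
  }
  for (nm in c("yaw", "pitch", "roll", "center_row", "center_col", "radius")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(nm, ": must be a single finite number")
    }
  }
  if (abs(pitch) > pose_limit) stop("pitch: outside the visibility range")
  if (abs(roll) > pose_limit) stop("roll: outside the visibility range")
  if (radius <= 0) stop("radius: must be positive")
  structure(list(bits = bits, yaw = yaw, pitch = pitch, roll = roll,
                 center_row = center_row, center_col = center_col,
                 radius = radius, n_bits = as.integer(n_bits),
                 pose_limit = pose_limit),
            class = "tag_params")
}

#' @export
print.tag_params <- function(x, ...) {
  cat("<tag_params> id", paste(x$bits, collapse = ""),
      sprintf("| yaw %.2f pitch %.2f roll %.2f | center (%.1f, %.1f) r %.1f\n",
              x$yaw, x$pitch, x$roll, x$center_row, x$center_col, x$radius))
  invisible(x)
}

#' Pose and code sampling ranges
#'
#' Defaults describe the marker population seen by an overhead hive camera:
#' uniform yaw, tilts up to 60 degrees, the marker roughly centered and
#' filling most of the crop.
#'
#' @param yaw Range of yaw in radians.
#' @param pitch,roll Ranges in radians (within the visibility limit).
#' @param radius_frac Range of radius as a fraction of the image size.
#' @param center_jitter_frac Maximum offset of the center from the image
#'   center, as a fraction of the image size.
#' @return An object of class `pose_ranges`.
#' @export
pose_ranges <- function(yaw = c(0, 2 * pi),
                        pitch = c(-pi / 3, pi / 3),
                        roll = c(-pi / 3, pi / 3),
                        radius_frac = c(0.30, 0.42),
                        center_jitter_frac = 0.04) {
  rs <- list(yaw = yaw, pitch = pitch, roll = roll, radius_frac = radius_frac)
  for (nm in names(rs)) {
    r <- rs[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop(nm, ": degenerate range (min > max)")
  }
  if (center_jitter_frac < 0) stop("center_jitter_frac: must be >= 0")
  structure(c(rs, list(center_jitter_frac = center_jitter_frac)),
            class = "pose_ranges")
}

#' Sample random marker parameters
#'
#' Bits are i.i.d. uniform over \{0, 1\} (every one of the 2^n_bits ids is
#' equally likely); pose components are uniform over the configured ranges.
#'
#' @param n Number of draws.
#' @param resolution Image size in pixels the pose is scaled to.
#' @param ranges A [pose_ranges()].
#' @param n_bits Number of code cells.
#' @param seed Optional integer seed; when given the draw is a deterministic
#'   function of it and the global RNG state is left untouched.
#' @return A list of `n` [tag_params()] objects.
#' @export
sample_tag_params <- function(n = 1, resolution = 64, ranges = pose_ranges(),
                              n_bits = 12L, seed = NULL) {
  with_seed(seed, {
    mid <- (resolution - 1) / 2
    jit <- ranges$center_jitter_frac * resolution
    lapply(seq_len(n), function(i) {
      tag_params(
        bits = stats::rbinom(n_bits, 1, 0.5),
        yaw = stats::runif(1, ranges$yaw[1], ranges$yaw[2]),
        pitch = stats::runif(1, ranges$pitch[1], ranges$pitch[2]),
        roll = stats::runif(1, ranges$roll[1], ranges$roll[2]),
        center_row = mid + stats::runif(1, -jit, jit),
        center_col = mid + stats::runif(1, -jit, jit),
        radius = resolution * stats::runif(1, ranges$radius_frac[1],
                                           ranges$radius_frac[2]),
        n_bits = n_bits)
    })
  })
}

# Run code with a temporary RNG state when seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Rotation matrix: yaw about the view axis, then pitch, then roll.
tag_rotation <- function(yaw, pitch, roll) {
  cz <- cos(yaw); sz <- sin(yaw)
  cy <- cos(pitch); sy <- sin(pitch)
  cx <- cos(roll); sx <- sin(roll)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Tag-plane coordinates of every pixel of an h x w grid (optionally
# supersampled).  Returns list(p, q, z): p = component along tag north,
# q = along tag east, both in units of the radius; z = unnormalized depth.
tag_plane_coords <- function(params, h, w, ss = 1) {
  R <- tag_rotation(params$yaw, params$pitch, params$roll)
  # image-plane offsets of the tag basis vectors (x = col, y = row)
  e_east <- R %*% c(1, 0, 0)    # local east
  e_north <- R %*% c(0, -1, 0)  # local north (row 0 is "up")
  A <- params$radius * rbind(c(e_east[1], e_north[1]),
                             c(e_east[2], e_north[2]))
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-9) stop("degenerate pose: tag viewed edge-on")
  Ai <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / det
  rows <- ((seq_len(h * ss) - 0.5) / ss - 0.5) - params$center_row
  cols <- ((seq_len(w * ss) - 0.5) / ss - 0.5) - params$center_col
  DX <- matrix(cols, h * ss, w * ss, byrow = TRUE)
  DY <- matrix(rows, h * ss, w * ss)
  q <- Ai[1, 1] * DX + Ai[1, 2] * DY
  p <- Ai[2, 1] * DX + Ai[2, 2] * DY
  z <- params$radius * (e_east[3] * q - (-e_north[3]) * p)
  list(p = p, q = q, z = z)
}

# Integer region map: 0 background, 1..n_bits code cells (1 = cell 0),
# n_bits+1 white semicircle, n_bits+2 black semicircle.
tag_region_map <- function(params, h, w, ss = 1) {
  pc <- tag_plane_coords(params, h, w, ss)
  r2 <- pc$p^2 + pc$q^2
  theta <- atan2(pc$q, pc$p) %% (2 * pi)
  nb <- params$n_bits
  cell <- pmin(floor(theta / (2 * pi / nb)), nb - 1) + 1L
  map <- matrix(0L, h * ss, w * ss)
  ring <- r2 <= 1 & r2 > INNER_FRAC^2
  inner <- r2 <= INNER_FRAC^2
  map[ring] <- cell[ring]
  map[inner] <- ifelse(pc$q[inner] >= 0, nb + 1L, nb + 2L)
  map
}

#' Render the idealistic marker image
#'
#' Produces the binary marker image together with a background segmentation
#' mask and a depth map, all deterministic functions of the parameters.
#' The image is supersampled and thresholded, so values are exactly -1 or
#' +1; anti-aliasing is left to the blur augmentation stage.
#'
#' @param params A [tag_params()].
#' @param resolution Output size in pixels (square), >= 16.
#' @param supersample Supersampling factor for rasterization.
#' @return An object of class `tag_render`: list with `image` (values in
#'   \{-1, 1\}), `bg_mask` (1 = background), `depth_map` (0 on background,
#'   in (0, 1] on the marker surface), and `params`.
#' @export
render_tag <- function(params, resolution = 64, supersample = 4) {
  stopifnot(inherits(params, "tag_params"))
  if (resolution < 16) stop("resolution: must be >= 16")
  if (params$center_row - params$radius < -0.5 ||
      params$center_row + params$radius > resolution - 0.5 ||
      params$center_col - params$radius < -0.5 ||
      params$center_col + params$radius > resolution - 0.5) {
    stop("radius: projected tag does not fit inside the image")
  }
  ss <- supersample
  map <- tag_region_map(params, resolution, resolution, ss)
  nb <- params$n_bits
  lut <- c(TAG_BG, ifelse(params$bits == 1L, TAG_WHITE, TAG_BLACK),
           TAG_WHITE, TAG_BLACK)
  img_ss <- matrix(lut[map + 1L], nrow(map), ncol(map))
  pc <- tag_plane_coords(params, resolution, resolution, ss)
  z <- pc$z
  z[map == 0L] <- NA
  zr <- range(z, na.rm = TRUE)
  depth_ss <- if (diff(zr) < 1e-9) {
    ifelse(is.na(z), 0, 0.55)
  } else {
    ifelse(is.na(z), 0, 0.1 + 0.9 * (z - zr[1]) / diff(zr))
  }
  img <- block_mean(img_ss, ss)
  depth <- block_mean(depth_ss, ss)
  bg <- block_mean((map == 0L) * 1, ss)
  bg_mask <- (bg > 0.5) * 1
  image <- ifelse(img > 0, TAG_WHITE, TAG_BLACK)
  image[bg_mask == 1] <- TAG_BG
  depth[bg_mask == 1] <- 0
  depth[bg_mask == 0] <- pmax(depth[bg_mask == 0], 0.05)
  structure(list(image = image, bg_mask = bg_mask, depth_map = pmin(depth, 1),
                 params = params),
            class = "tag_render")
}

block_mean <- function(m, ss) {
  if (ss == 1) return(m)
  h <- nrow(m) / ss; w <- ncol(m) / ss
  dim(m) <- c(ss, h, ss, w)
  out <- colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
  dim(out) <- c(h, w)
  out
}

#' Decode the code bits from an image with known pose
#'
#' Reference decoder used as the label-preservation oracle: it projects the
#' known pose onto the image, averages the intensity over each code cell and
#' over the two orientation semicircles, and calls a bit white when its cell
#' mean is closer to the white-semicircle mean than to the black-semicircle
#' mean.  Comparing against local references makes the decision invariant to
#' smooth intensity shifts and positive scalings.
#'
#' @param image Numeric matrix depicting a marker.
#' @param pose A [tag_params()] describing the depicted pose (its bits are
#'   ignored).
#' @return Integer vector of decoded bits.
#' @export
reference_decode <- function(image, pose) {
  stopifnot(is.matrix(image), inherits(pose, "tag_params"))
  map <- tag_region_map(pose, nrow(image), ncol(image))
  nb <- pose$n_bits
  means <- vapply(seq_len(nb + 2L), function(k) {
    v <- image[map == k]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }, numeric(1))
  if (anyNA(means)) stop("projected reference regions are empty (tag outside frame?)")
  m_w <- means[nb + 1L]
  m_b <- means[nb + 2L]
  as.integer(abs(means[1:nb] - m_w) <= abs(means[1:nb] - m_b))
}

#' Write a rendered or augmented marker image to PNG
#'
#' Maps the \[-1, 1\] intensity convention linearly to 8-bit grayscale.
#'
#' @param image Numeric matrix in \[-1, 1\] (values outside are clipped).
#' @param path Output file path.
#' @export
write_tag_png <- function(image, path) {
  g <- pmin(pmax((image + 1) / 2, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}
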