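# Parametric marker model: rendering, pose sampling, reference decoding.

test_that("the worked example id decodes from its frontal render", {
  bits <- as.integer(strsplit("100110100010", "")[[1]])
  p <- frontal_params(bits)
  r <- render_tag(p, 64)
  expect_identical(reference_decode(r$image, p), bits)
})

test_that("render obeys the binary-image and mask/depth invariants", {
  for (seed in 1:5) {
    p <- sample_tag_params(1, 48, seed = seed)[[1]]
    r <- render_tag(p, 48)
    expect_true(all(r$image %in% c(-1, 1)))
    expect_true(all(r$bg_mask %in% c(0, 1)))
    expect_true(all(r$depth_map >= 0 & r$depth_map <= 1))
    # background <=> zero depth, and background pixels carry the constant
    expect_identical(r$bg_mask == 1, r$depth_map == 0)
    expect_true(all(r$image[r$bg_mask == 1] == -1))
  }
})

test_that("rendering is deterministic and validates its inputs", {
  p <- frontal_params()
  expect_identical(render_tag(p, 64), render_tag(p, 64))
  expect_error(tag_params(c(1, 0, 1)), "bits")
  expect_error(tag_params(rep(2, 12)), "bits")
  expect_error(tag_params(rep(1, 12), pitch = 1.5), "pitch")
  expect_error(tag_params(rep(1, 12), roll = -1.5), "roll")
  expect_error(tag_params(rep(1, 12), radius = 0), "radius")
  expect_error(render_tag(frontal_params(resolution = 64), 8), "resolution")
  big <- tag_params(rep(1, 12), center_row = 30, center_col = 30, radius = 40)
  expect_error(render_tag(big, 64), "fit")
})

test_that("all-white and all-black renders differ exactly on the code cells", {
  p0 <- frontal_params(rep(0, 12))
  p1 <- frontal_params(rep(1, 12))
  r0 <- render_tag(p0, 64)
  r1 <- render_tag(p1, 64)
  diff <- r0$image != r1$image
  # supersampled code-cell coverage per output pixel
  map <- beetag:::tag_region_map(p0, 64, 64, ss = 4)
  cov <- beetag:::block_mean((map >= 1 & map <= 12) * 1, 4)
  expect_true(all(cov[diff] > 0))          # differences only touch cells
  expect_true(all(diff[cov == 1]))         # fully covered pixels all flip
})

test_that("decode-render round trip is exact across poses and codes", {
  set.seed(11)
  for (i in 1:50) {
    pose <- sample_tag_params(1, 64)[[1]]
    for (j in 1:20) {
      bits <- as.integer(stats::rbinom(12, 1, 0.5))
      p <- tag_params(bits, pose$yaw, pose$pitch, pose$roll,
                      pose$center_row, pose$center_col, pose$radius)
      expect_identical(reference_decode(render_tag(p, 64)$image, p), bits)
    }
  }
})

test_that("rotating a yawed render back matches the unyawed render", {
  for (theta in c(0.4, 1.2, 2.9)) {
    p0 <- frontal_params()
    p1 <- tag_params(p0$bits, yaw = theta, center_row = p0$center_row,
                     center_col = p0$center_col, radius = p0$radius)
    img1 <- render_tag(p1, 64)$image
    back <- beetag:::warp_image(img1, rot = -theta)
    back <- ifelse(back > 0, 1, -1)
    mismatch <- mean(back != render_tag(p0, 64)$image)
    expect_lt(mismatch, 0.02)
  }
})

test_that("sampled bits are uniform and codes cover the id space", {
  n <- 10000
  ps <- sample_tag_params(n, 64, seed = 7)
  bits <- do.call(rbind, lapply(ps, `[[`, "bits"))
  freq <- colMeans(bits)
  expect_true(all(abs(freq - 0.5) < 0.02))  # 3 sigma ~ 0.015
  codes <- apply(bits, 1, paste, collapse = "")
  m <- 2^12
  expected_distinct <- m * (1 - (1 - 1 / m)^n)
  expect_lt(abs(length(unique(codes)) - expected_distinct), 60)
})

test_that("pose sampling is seed-deterministic and validates ranges", {
  a <- sample_tag_params(5, 64, seed = 123)
  b <- sample_tag_params(5, 64, seed = 123)
  expect_identical(a, b)
  expect_error(pose_ranges(pitch = c(1, -1)), "degenerate")
})

test_that("decoding is invariant to intensity maps and flags empty regions", {
  p <- sample_tag_params(1, 64, seed = 3)[[1]]
  r <- render_tag(p, 64)
  b <- reference_decode(r$image, p)
  # local semicircle references move with the image: any affine intensity
  # map (including negation) leaves the decision unchanged
  expect_identical(reference_decode(-r$image, p), b)
  expect_identical(reference_decode(0.3 * r$image + 0.2, p), b)
  off <- tag_params(p$bits, center_row = 200, center_col = 200, radius = 10)
  expect_error(reference_decode(r$image, off), "empty")
})

test_that("renders can be written as 8-bit grayscale PNG", {
  f <- tempfile(fileext = ".png")
  write_tag_png(render_tag(frontal_params(), 64)$image, f)
  g <- png::readPNG(f)
  expect_equal(dim(g), c(64, 64))
  expect_true(all(g %in% c(0, 1)))  # binary render maps to full black/white
})
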