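# Differentiable augmentation stages and the clip-with-penalty layer.

test_that("blur stage interpolates between identity and the full blur", {
  set.seed(1)
  x <- matrix(rnorm(32 * 32), 32)
  sp <- blur_spec()
  expect_identical(phi_blur(x, 0, sp), x)
  expect_equal(phi_blur(x, 1, sp), beetag:::gaussian_blur(x, sp$sigma_blur))
  expect_equal(phi_blur(x, 0.5, sp),
               0.5 * x + 0.5 * beetag:::gaussian_blur(x, sp$sigma_blur))
  expect_error(phi_blur(x, 1.2, sp), "alpha")
})

test_that("blur does not increase total variation as alpha grows", {
  r <- render_tag(frontal_params(resolution = 48), 48)
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  tvs <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                function(a) tv(phi_blur(r$image, a)), numeric(1))
  expect_true(all(diff(tvs) <= 1e-9))
})

test_that("white mask thresholds at the midpoint of the intensity convention", {
  r <- render_tag(frontal_params(), 64)
  m <- white_mask(r$image)
  expect_identical(m, (r$image == 1) * 1)
  expect_identical(white_mask(matrix(-1, 4, 4)), matrix(0, 4, 4))
  x <- matrix(rnorm(100), 10)
  expect_identical(white_mask(x) + white_mask(-x), (x != 0) * 1)
})

test_that("lighting with unit scalings and zero shift is the identity", {
  r <- render_tag(frontal_params(), 64)
  one <- matrix(1, 64, 64)
  zero <- matrix(0, 64, 64)
  expect_equal(phi_lighting(r$image, one, one, zero), r$image)
  expect_equal(phi_lighting(r$image, one * 0.1, one * 0.1, zero),
               0.1 * r$image)
  expect_error(phi_lighting(r$image, one * 1.5, one, zero), "s_w")
  expect_error(phi_lighting(r$image, one, one * 0.01, zero), "s_b")
})

test_that("lighting preserves the code for random in-range smooth fields", {
  set.seed(21)
  ok <- vapply(1:500, function(i) {
    p <- sample_tag_params(1, 64)[[1]]
    r <- render_tag(p, 64)
    a <- sample_augmentation_params(64)
    x <- phi_lighting(r$image, a$s_w, a$s_b, a$t)
    all(reference_decode(x, p) == p$bits)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("background stage only ever touches background pixels", {
  set.seed(2)
  x <- matrix(rnorm(64), 8)
  d <- matrix(rnorm(64), 8)
  B <- matrix(rbinom(64, 1, 0.4), 8)
  expect_identical(phi_bg(x, d, matrix(0, 8, 8)), x)
  expect_identical(phi_bg(x, d, matrix(1, 8, 8)), d)
  out <- phi_bg(x, d, B)
  expect_identical(out[B == 0], x[B == 0])
  expect_identical(out[B == 1], d[B == 1])
  expect_error(phi_bg(x, d[1:4, 1:4], B), "shape")
})

test_that("the iterated high-pass filter kills constants and low frequencies", {
  sp <- blur_spec()
  expect_equal(highpass(matrix(5, 24, 24), sp), matrix(0, 24, 24),
               tolerance = 1e-12)
  set.seed(3)
  a <- matrix(rnorm(24 * 24), 24)
  b <- matrix(rnorm(24 * 24), 24)
  expect_equal(highpass(a + b, sp), highpass(a, sp) + highpass(b, sp))
  # low-frequency sinusoid (period 48 px >> sigma 3.5) is attenuated hard
  g <- outer(1:48, 1:48, function(i, j) sin(2 * pi * i / 48))
  interior <- highpass(g, sp)[7:42, 7:42]
  expect_lt(max(abs(interior)) / max(abs(g)), 0.05)
})

test_that("detail stage with constant fields is the identity", {
  r <- render_tag(frontal_params(), 64)
  expect_equal(phi_detail(r$image, matrix(1.7, 64, 64)), r$image,
               tolerance = 1e-12)
  expect_identical(phi_detail(r$image, matrix(0, 64, 64)), r$image)
  expect_error(phi_detail(r$image, matrix(3, 64, 64)), "d_detail")
})

test_that("detail stage preserves the code for random in-range fields", {
  set.seed(22)
  ok <- vapply(1:500, function(i) {
    p <- sample_tag_params(1, 64)[[1]]
    r <- render_tag(p, 64)
    a <- sample_augmentation_params(64)
    all(reference_decode(phi_detail(r$image, a$d_detail), p) == p$bits)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("neutral parameters compose to the identity; taps chain in order", {
  r <- render_tag(frontal_params(), 64)
  one <- matrix(1, 64, 64)
  zero <- matrix(0, 64, 64)
  neutral <- augmentation_params(alpha = 0, s_w = one, s_b = one, t = zero,
                                 d_bg = zero - 1, d_detail = zero)
  expect_equal(compose_augmentations(r, neutral), r$image, tolerance = 1e-12)
  a <- sample_augmentation_params(64, seed = 5)
  sp <- blur_spec()
  taps <- compose_augmentations(r, a, sp, taps = TRUE)
  expect_identical(dim(taps$image), dim(r$image))
  # each stage output reproduces the chain applied one step further
  x1 <- phi_blur(r$image, a$alpha, sp)
  expect_equal(taps$blur, x1)
  x2 <- phi_lighting(x1, a$s_w, a$s_b, a$t, sp)
  expect_equal(taps$lighting, x2)
  x3 <- phi_bg(x2, a$d_bg, r$bg_mask)
  expect_equal(taps$bg, x3)
  expect_equal(taps$detail, phi_detail(x3, a$d_detail, sp))
})

test_that("augmentation parameter ranges are enforced at construction", {
  one <- matrix(1, 8, 8)
  expect_error(augmentation_params(2, one, one, one * 0, one * 0, one * 0),
               "alpha")
  expect_error(augmentation_params(0.5, one * 0.05, one, one * 0, one * 0,
                                   one * 0), "s_w")
  expect_error(augmentation_params(0.5, one, one, one * 0, one * 2, one * 0),
               "d_bg")
  expect_error(augmentation_params(0.5, one, one, one * 0, one * 0, one * 3),
               "d_detail")
})

test_that("clip layer matches its closed form and is continuous at bounds", {
  sp <- clip_spec(0.10, 1, gamma = 15)
  x <- c(0.05, 0.10, 0.5, 1, 1.2)
  out <- clip_with_penalty(x, sp)
  expect_equal(out$value, c(0.10, 0.10, 0.5, 1, 1))
  expect_equal(out$penalty, 15 * (0.05 + 0.2))
  expect_equal(clip_with_penalty(c(0.10, 1), sp)$penalty, 0)
  # boundary continuity: penalty tends to zero from outside
  eps <- 1e-9
  expect_lt(clip_with_penalty(0.10 - eps, sp)$penalty, 1e-6)
  expect_lt(clip_with_penalty(1 + eps, sp)$penalty, 1e-6)
  # scalar overshoot: penalty = gamma * delta
  expect_equal(clip_with_penalty(1 + 0.3, sp)$penalty, 15 * 0.3)
  expect_error(clip_spec(1, 0), "a < b")
  expect_error(clip_spec(0, 1, gamma = -1), "gamma")
})

test_that("stage backward passes agree with finite differences", {
  set.seed(9)
  sp <- blur_spec(sigma_blur = 1.5, sigma_highpass = 2, highpass_repeats = 2)
  n <- 12
  x <- matrix(rnorm(n * n), n) + 0.3   # keep clear of the W(x) threshold
  g <- matrix(rnorm(n * n), n)
  rel <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-6)

  # blur: d/dx and d/dalpha
  vj <- beetag:::phi_blur_vjp(x, 0.4, g, sp)
  for (k in sample(n * n, 5)) {
    fd <- num_grad(function(v) sum(g * phi_blur(v, 0.4, sp)), x, k)
    expect_lt(rel(fd, vj$dx[k]), 1e-5)
  }
  fd_a <- (sum(g * phi_blur(x, 0.4 + 1e-6, sp)) -
           sum(g * phi_blur(x, 0.4 - 1e-6, sp))) / 2e-6
  expect_lt(rel(fd_a, vj$dalpha), 1e-5)

  # lighting: all four inputs
  sw <- matrix(runif(n * n, 0.3, 0.9), n)
  sb <- matrix(runif(n * n, 0.3, 0.9), n)
  tt <- matrix(rnorm(n * n, sd = 0.2), n)
  vj <- beetag:::phi_lighting_vjp(x, sw, sb, tt, g, sp)
  for (k in sample(n * n, 4)) {
    expect_lt(rel(num_grad(function(v) sum(g * phi_lighting(x, v, sb, tt, sp)), sw, k),
                  vj$ds_w[k]), 1e-5)
    expect_lt(rel(num_grad(function(v) sum(g * phi_lighting(x, sw, v, tt, sp)), sb, k),
                  vj$ds_b[k]), 1e-5)
    expect_lt(rel(num_grad(function(v) sum(g * phi_lighting(x, sw, sb, v, sp)), tt, k),
                  vj$dt[k]), 1e-5)
    expect_lt(rel(num_grad(function(v) sum(g * phi_lighting(v, sw, sb, tt, sp)), x, k),
                  vj$dx[k]), 1e-5)
  }

  # detail: d/dd is the adjoint high-pass
  vj <- beetag:::phi_detail_vjp(g, sp)
  dd <- matrix(rnorm(n * n, sd = 0.3), n)
  for (k in sample(n * n, 4)) {
    expect_lt(rel(num_grad(function(v) sum(g * phi_detail(x, v, sp)), dd, k),
                  vj$dd_detail[k]), 1e-5)
  }
})
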