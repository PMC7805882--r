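# Hand-designed augmentation samplers and the stage-combination baselines.

test_that("pyramid background: degenerate, reproducible, centered", {
  cfg <- test_hm16()
  zero <- handmade_config(16, pyramid_scales = 0, field_sd = 0.25,
                          t_max = 0.2, spot_amp = c(0.1, 0.3),
                          noise_range = c(0, 0.05))
  expect_identical(pyramid_background(16, zero, seed = 1), matrix(0, 16, 16))
  expect_identical(pyramid_background(16, cfg, seed = 9),
                   pyramid_background(16, cfg, seed = 9))
  expect_error(pyramid_background(22, cfg), "multiple")
  # symmetric construction: per-pixel mean near zero over many draws
  acc <- matrix(0, 16, 16)
  sq <- matrix(0, 16, 16)
  for (i in 1:1000) {
    b <- pyramid_background(16, cfg, seed = 10000 + i)
    acc <- acc + b
    sq <- sq + b^2
  }
  m <- acc / 1000
  s <- sqrt(pmax(sq / 1000 - m^2, 1e-12))
  # per-pixel CLT bound at 4.5 sigma (256 simultaneous, correlated tests)
  expect_true(all(abs(m) <= 4.5 * s / sqrt(1000) + 1e-8))
})

test_that("hand-made augmentation with all scales zero is the identity", {
  r <- render_tag(frontal_params(resolution = 32), 32)
  expect_equal(hm_augment(r, identity_hm_config(32), seed = 1), r$image)
})

test_that("hand-made augmentation is seeded and label-preserving", {
  cfg <- handmade_config(32)
  r <- render_tag(sample_tag_params(1, 32, seed = 2)[[1]], 32)
  expect_identical(hm_augment(r, cfg, seed = 7), hm_augment(r, cfg, seed = 7))
  set.seed(31)
  ok <- vapply(1:200, function(i) {
    p <- sample_tag_params(1, 32)[[1]]
    rr <- render_tag(p, 32)
    all(reference_decode(hm_augment(rr, cfg), p) == p$bits)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("a config that cannot preserve labels is rejected at construction", {
  expect_error(handmade_config(32, spot_amp = c(2.5, 3), max_spots = 4,
                               spot_radius_frac = c(0.4, 0.6)),
               "not label-preserving")
})

test_that("baseline combos partition effects exactly as configured", {
  cfg <- handmade_config(32)
  set.seed(4)
  params <- sample_tag_params(6, 32)
  renders <- lapply(params, render_tag, resolution = 32)
  # fabricate learned-stage taps from the stage operators themselves
  lighting <- lapply(renders, function(r) {
    a <- sample_augmentation_params(32)
    phi_lighting(phi_blur(r$image, a$alpha, cfg$blur), a$s_w, a$s_b, a$t,
                 cfg$blur)
  })
  bg <- lapply(seq_along(renders), function(i) {
    phi_bg(lighting[[i]], pyramid_background(32, cfg), renders[[i]]$bg_mask)
  })
  stage_taps <- list(renders = renders, lighting = lighting, bg = bg)

  for (combo in c("hm3d", "hmli", "hmbg")) {
    ds <- make_baseline_dataset(combo, stage_taps, n = 6, config = cfg, seed = 1)
    expect_equal(dataset_size(ds), 6)
    expect_identical(ds$provenance$source, combo)
    # labels pass through untouched
    expect_identical(ds$bits, do.call(rbind, lapply(params, `[[`, "bits")))
  }
  expect_error(make_baseline_dataset("hmbg", list(renders = renders), 6),
               "missing taps")

  # with noise and spotlights disabled, hmbg reduces to the clipped bg tap
  quiet <- handmade_config(32, noise_range = c(0, 0), max_spots = 0,
                           spot_amp = c(0, 0))
  ds_q <- make_baseline_dataset("hmbg", stage_taps, n = 3, config = quiet,
                                seed = 2)
  for (i in 1:3) {
    expect_equal(ds_q$images[, , i], pmin(pmax(bg[[i]], -1), 1))
  }
})

test_that("hm3d with zero scales yields the idealistic renders", {
  params <- sample_tag_params(3, 32, seed = 6)
  renders <- lapply(params, render_tag, resolution = 32)
  ds <- make_baseline_dataset("hm3d", list(renders = renders), n = 3,
                              config = identity_hm_config(32), seed = 1)
  for (i in 1:3) expect_equal(ds$images[, , i], renders[[i]]$image)
})

test_that("the hand-made corpus audits above the recovery floor", {
  ds <- hm_corpus(120, 32, handmade_config(32), seed = 11)
  expect_gte(audit_labels(ds, 120), 0.9)
  expect_identical(ds$provenance$source, "real")
})
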