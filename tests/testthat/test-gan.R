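# Generator/discriminator construction, training mechanics, filtering.

test_that("learning-rate schedule decays by 0.25 at the configured epochs", {
  cfg <- gan_config(resolution = 16)
  expect_identical(scheduled_lr(1, cfg), 2e-4)
  expect_identical(scheduled_lr(199, cfg), 2e-4)
  expect_identical(scheduled_lr(200, cfg), 2e-4 * 0.25)
  expect_identical(scheduled_lr(250, cfg), 2e-4 * 0.25^2)
  expect_identical(scheduled_lr(300, cfg), 2e-4 * 0.25^3)
  expect_identical(scheduled_lr(1000, cfg), 2e-4 * 0.25^3)
})

test_that("generator outputs respect every declared parameter range", {
  set.seed(12)
  cfg <- gan_config(resolution = 16, renderer_mode = "direct")
  gen <- build_generator(cfg)
  z <- matrix(rnorm(6 * cfg$z_dim), 6)
  bits <- matrix(rbinom(72, 1, 0.5), 6)
  out <- generator_forward(gen, z, bits)
  expect_gte(out$penalty, 0)
  for (a in out$aug_params) {
    expect_true(a$alpha >= 0 && a$alpha <= 1)
    expect_true(all(a$s_w >= 0.10 & a$s_w <= 1))
    expect_true(all(a$s_b >= 0.10 & a$s_b <= 1))
    expect_true(all(abs(a$d_bg) <= 1))
    expect_true(all(abs(a$d_detail) <= 2))
  }
  r <- cfg$ranges
  expect_true(all(abs(out$pose[, 2]) <= r$pitch[2]))
  expect_true(all(out$pose[, 6] >= r$radius_frac[1] * 16 &
                  out$pose[, 6] <= r$radius_frac[2] * 16))
  # determinism given weights and z
  out2 <- generator_forward(gen, z, bits)
  expect_identical(out$final_image, out2$final_image)
})

test_that("generated images equal the composed augmentations of their render", {
  set.seed(13)
  cfg <- gan_config(resolution = 16, renderer_mode = "direct")
  gen <- build_generator(cfg)
  z <- matrix(rnorm(3 * cfg$z_dim), 3)
  bits <- matrix(rbinom(36, 1, 0.5), 3)
  out <- generator_forward(gen, z, bits)
  for (i in 1:3) {
    recomposed <- compose_augmentations(out$renders[[i]], out$aug_params[[i]],
                                        cfg$blur)
    expect_equal(out$final_image[, , i, 1], recomposed, tolerance = 1e-10)
  }
})

test_that("untrained generator decode rate is reported as a proportion", {
  set.seed(14)
  cfg <- gan_config(resolution = 16, renderer_mode = "direct")
  gen <- build_generator(cfg)
  z <- matrix(rnorm(20 * cfg$z_dim), 20)
  bits <- matrix(rbinom(240, 1, 0.5), 20)
  out <- generator_forward(gen, z, bits)
  rate <- mean(vapply(1:20, function(i) {
    p <- beetag:::pose_to_params(out$pose[i, ], 12L)
    all(reference_decode(out$final_image[, , i, 1], p) == bits[i, ])
  }, logical(1)))
  expect_true(rate >= 0 && rate <= 1)
})

test_that("discriminator returns one finite score in (0,1) per image", {
  set.seed(15)
  disc <- build_discriminator(16)
  imgs <- array(0, c(16, 16, 5))
  s <- disc_score(disc, imgs)
  expect_length(s, 5)
  expect_true(all(is.finite(s) & s > 0 & s < 1))
  expect_error(build_discriminator(20), "divisible")
})

test_that("zero-epoch training returns a reproducible initialization", {
  ck1 <- init_checkpoint(seed = 42)
  ck2 <- init_checkpoint(seed = 42)
  expect_equal(nrow(ck1$history), 0)
  expect_identical(ck1$gen_state, ck2$gen_state)
  expect_identical(ck1$disc_state, ck2$disc_state)
})

test_that("checkpoints reload and reproduce generation bit-exactly", {
  ck <- init_checkpoint(seed = 43)
  f <- tempfile(fileext = ".rds")
  gan_save(ck, f)
  ck2 <- gan_load(f)
  d1 <- generate_labeled_dataset(ck, 8, discard_fraction = 0, seed = 77,
                                 batch_size = 8)
  d2 <- generate_labeled_dataset(ck2, 8, discard_fraction = 0, seed = 77,
                                 batch_size = 8)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$bits, d2$bits)
})

test_that("a short adversarial run updates both players with finite losses", {
  real <- hm_corpus(64, 16, test_hm16(), seed = 21)
  cfg <- gan_config(resolution = 16, batch_size = 4, epochs = 2,
                    batches_per_epoch = 10, seed = 22,
                    renderer_mode = "direct")
  ck <- train_rendergan(cfg, real)
  expect_equal(nrow(ck$history), 2)
  expect_true(all(is.finite(ck$history$d_loss)))
  expect_true(all(is.finite(ck$history$g_loss)))
  expect_true(all(ck$history$d_acc >= 0 & ck$history$d_acc <= 1))
  expect_identical(ck$history$lr, rep(2e-4, 2))
  # training moved the generator away from its initialization
  ck0 <- train_rendergan(gan_config(resolution = 16, batch_size = 4,
                                    epochs = 0, batches_per_epoch = 1,
                                    seed = 22, renderer_mode = "direct"), real)
  expect_false(identical(ck$gen_state, ck0$gen_state))
})

test_that("discriminator filtering keeps the highest-scoring samples stably", {
  expect_identical(filter_by_discriminator(1:10, 10:1, 0), 1:10)
  set.seed(30)
  scores <- runif(100)
  kept <- filter_by_discriminator(seq_len(100), scores, 0.05)
  expect_length(kept, 95)
  expect_gte(min(scores[kept]), max(scores[setdiff(1:100, kept)]))
  # ties at the cutoff: retained count is exactly ceiling(n (1 - f))
  kept_tie <- filter_by_discriminator(seq_len(100), rep(0.5, 100), 0.33)
  expect_length(kept_tie, ceiling(100 * 0.67))
  expect_identical(kept_tie, sort(kept_tie))
  expect_error(filter_by_discriminator(1:5, 1:4, 0.1), "length mismatch")
  expect_error(filter_by_discriminator(1:5, 1:5, 1), "discard_fraction")
})

test_that("the pose can alternatively be sampled instead of predicted", {
  set.seed(16)
  cfg <- gan_config(resolution = 16, renderer_mode = "direct",
                    pose_source = "sampled")
  gen <- build_generator(cfg)
  z <- matrix(rnorm(5 * cfg$z_dim), 5)
  bits <- matrix(rbinom(60, 1, 0.5), 5)
  out <- generator_forward(gen, z, bits)
  r <- cfg$ranges
  expect_true(all(out$pose[, 2] >= r$pitch[1] & out$pose[, 2] <= r$pitch[2]))
  expect_true(all(out$pose[, 6] >= r$radius_frac[1] * 16 &
                  out$pose[, 6] <= r$radius_frac[2] * 16))
  expect_identical(dim(out$final_image), c(16L, 16L, 5L, 1L))
})
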