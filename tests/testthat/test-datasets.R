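# Labeled-dataset container, on-disk format, generation from a checkpoint.

test_that("binary format round-trips bit-exactly, including empty datasets", {
  ds <- hm_corpus(20, 16, test_hm16(), seed = 41)
  f <- tempfile()
  write_dataset(ds, f)
  ds2 <- read_dataset(f)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$bits, ds2$bits)
  expect_identical(ds$pose, ds2$pose)
  expect_identical(ds$provenance$source, ds2$provenance$source)

  empty <- dataset_subset(ds, integer(0))
  f0 <- tempfile()
  write_dataset(empty, f0)
  expect_equal(dataset_size(read_dataset(f0)), 0)
})

test_that("plain-text JSON format is equally lossless", {
  ds <- dataset_subset(hm_corpus(4, 16, test_hm16(), seed = 42), 1:4)
  f <- tempfile(fileext = ".json")
  write_dataset(ds, f, format = "json")
  ds2 <- read_dataset(f)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$bits, ds2$bits)
  expect_identical(ds$pose, ds2$pose)
})

test_that("corrupt or inconsistent files are rejected with format errors", {
  f <- tempfile()
  writeLines("not a dataset", f)
  expect_error(read_dataset(f), "format error")
  expect_error(read_dataset(tempfile()), "no such file")
  # count mismatch between images and labels in the header
  bad <- list(magic = "BTLD1", version = 1L, images_dim = c(4L, 4L, 3L),
              bits_dim = c(2L, 12L), pose_dim = c(3L, 6L),
              provenance = list(source = "real"),
              images = rep(0, 48), bits = rep(0L, 24), pose = rep(0, 18))
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, fj, auto_unbox = TRUE)
  expect_error(read_dataset(fj), "count mismatch")
})

test_that("container validates alignment and ranges", {
  imgs <- array(0, c(8, 8, 3))
  bits <- matrix(0L, 3, 12)
  pose <- matrix(1, 3, 6)
  expect_error(labeled_dataset(imgs, bits[1:2, ], pose,
                               list(source = "real")), "count mismatch")
  expect_error(labeled_dataset(imgs, bits, pose[1:2, ],
                               list(source = "real")), "count mismatch")
  expect_error(labeled_dataset(imgs + 3, bits, pose, list(source = "real")),
               "\\[-1, 1\\]")
  expect_error(labeled_dataset(imgs, bits, pose, list(source = "nope")),
               "provenance")
})

test_that("generation returns exactly n samples whose labels are the bits", {
  ck <- init_checkpoint(seed = 51)
  out <- generate_labeled_dataset(ck, 10, discard_fraction = 0, seed = 52,
                                  batch_size = 8, taps = TRUE)
  ds <- out$dataset
  expect_equal(dataset_size(ds), 10)
  expect_identical(ds$provenance$source, "rendergan")
  for (i in 1:10) {
    expect_identical(as.integer(ds$bits[i, ]), out$taps$renders[[i]]$params$bits)
  }
  expect_error(generate_labeled_dataset(ck, 10, discard_fraction = 0.6),
               "starvation")
})

test_that("generated bit marginals are uniform within binomial bounds", {
  ck <- init_checkpoint(seed = 53)
  ds <- generate_labeled_dataset(ck, 600, discard_fraction = 0.05, seed = 54,
                                 batch_size = 64)
  freq <- colMeans(ds$bits)
  expect_true(all(abs(freq - 0.5) <= 3 * sqrt(0.25 / 600)))
})

test_that("generation is a deterministic function of checkpoint and seed", {
  ck <- init_checkpoint(seed = 55)
  d1 <- generate_labeled_dataset(ck, 12, seed = 9, batch_size = 8)
  d2 <- generate_labeled_dataset(ck, 12, seed = 9, batch_size = 8)
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(d1, f1)
  write_dataset(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generated datasets pass the label audit", {
  ck <- init_checkpoint(seed = 57, resolution = 32)
  ds <- generate_labeled_dataset(ck, 150, discard_fraction = 0.05, seed = 58,
                                 batch_size = 64)
  expect_gte(audit_labels(ds, 150), 0.95)
})
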