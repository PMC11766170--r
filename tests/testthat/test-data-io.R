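# Readers, preprocessing, label mapping and the phantom generator.

test_that("DICOM fixtures round-trip with identity and affine rescale", {
  set.seed(70)
  px <- matrix(sample(0:4095, 12 * 10, TRUE), 12, 10)
  f <- tempfile(fileext = ".dcm")
  write_test_dicom(f, px, slope = 1, intercept = 0)
  d <- load_dicom_slice(f)
  expect_equal(d$pixels, px, ignore_attr = TRUE)
  # slope 2, intercept -1024: stored v maps to 2 v - 1024
  write_test_dicom(f, px, slope = 2, intercept = -1024)
  d2 <- load_dicom_slice(f)
  expect_equal(d2$pixels, 2 * px - 1024, ignore_attr = TRUE)
  # implicit VR little endian
  write_test_dicom(f, px, slope = 1, intercept = 0, explicit = FALSE)
  expect_equal(load_dicom_slice(f)$pixels, px, ignore_attr = TRUE)
})

test_that("non-DICOM files are rejected with the path in the message", {
  f <- tempfile(fileext = ".dcm")
  writeBin(as.raw(sample(0:255, 400, TRUE)), f)
  expect_error(load_dicom_slice(f), "DICM")
  expect_error(load_dicom_slice(f), basename(f), fixed = TRUE)
})

test_that("preprocess resizes, normalises to [0,1] and is idempotent", {
  set.seed(71)
  img <- matrix(runif(64 * 64, 10, 500), 64)
  out <- preprocess(img, 32L)
  expect_equal(dim(out), c(32L, 32L))
  expect_equal(range(out), c(0, 1))
  expect_equal(preprocess(out, 32L), out, tolerance = 1e-12)
  expect_equal(max(abs(preprocess(matrix(7, 16, 16), 16L))), 0)
  big <- matrix(runif(512 * 512), 512)
  expect_equal(dim(preprocess(big, 256L)), c(256L, 256L))
})

test_that("CHAOS label mapping bins raw intensities onto 0..4", {
  expect_equal(max(abs(map_chaos_labels(matrix(0L, 8, 8)))), 0)
  raw <- matrix(c(0L, 63L, 126L, 189L, 252L), 5, 5)
  mapped <- map_chaos_labels(raw)
  expect_identical(sort(unique(as.vector(mapped))), 0:4)
  # ascending intensities map to ascending classes, bijectively
  expect_identical(as.vector(mapped[, 1]), c(0L, 1L, 2L, 3L, 4L))
  # nearest-neighbour resize never invents labels
  rs <- map_chaos_labels(raw, target_size = 16L)
  expect_true(all(rs %in% 0:4))
  expect_identical(sort(unique(as.vector(rs))), sort(unique(as.vector(mapped))))
})

test_that("phantoms are seeded-deterministic with valid masks and pairing", {
  cfg <- phantom_config(n_samples = 5, image_size = 48, seed = 72)
  a <- generate_phantoms(cfg)
  b <- generate_phantoms(cfg)
  expect_identical(a, b)
  for (s in a) {
    expect_true(all(s$mask %in% 0:4))
    expect_equal(dim(s$image)[1:2], dim(s$mask))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
  c2 <- generate_phantoms(phantom_config(n_samples = 5, image_size = 48, seed = 73))
  expect_false(identical(a, c2))
})

test_that("noise-free single-ellipse phantom matches a point-in-ellipse scan", {
  cfg <- phantom_config(n_samples = 1, image_size = 64, noise_sd = 0,
                        force_classes = 1L, seed = 74)
  s <- generate_phantoms(cfg)[[1]]
  # independent rasterisation: recover the ellipse by scanning every pixel
  # against the analytic inequality with the same draws
  set.seed(74)
  ax <- runif(1, cfg$axis_frac[1, 1], cfg$axis_frac[1, 2]) * 64
  bx <- runif(1, cfg$axis_frac[1, 1], cfg$axis_frac[1, 2]) * 64
  cy <- (cfg$centre_frac[1, 1] + runif(1, -0.05, 0.05)) * 64
  cx <- (cfg$centre_frac[1, 2] + runif(1, -0.05, 0.05)) * 64
  th <- runif(1, 0, pi)
  inside <- matrix(FALSE, 64, 64)
  for (h in 1:64) for (w in 1:64) {
    u <- cos(th) * (h - cy) + sin(th) * (w - cx)
    v <- -sin(th) * (h - cy) + cos(th) * (w - cx)
    inside[h, w] <- (u / ax)^2 + (v / bx)^2 <= 1
  }
  expect_identical(s$mask == 1L, inside)
  expect_equal(sum(s$mask == 1L), sum(inside))
})

test_that("phantom class fractions stay inside analytic area bounds", {
  n <- 200
  cfg <- phantom_config(n_samples = n, image_size = 64, seed = 75)
  ph <- generate_phantoms(cfg)
  S2 <- 64^2
  for (k in 1:4) {
    amax <- cfg$axis_frac[k, 2] * 64
    frac <- vapply(ph, function(s) sum(s$mask == k) / S2, 0)
    # upper bound: maximal ellipse dilated one pixel for rasterisation
    expect_true(all(frac <= pi * (amax + 1)^2 / S2))
  }
  # the spleen is drawn last, never overwritten: when present its area is
  # at least the minimal ellipse eroded one pixel
  amin <- cfg$axis_frac[4, 1] * 64
  fr4 <- vapply(ph, function(s) sum(s$mask == 4) / S2, 0)
  present <- fr4 > 0
  expect_gt(mean(present), 0.3)   # drawn often under organs_range 2..4
  expect_true(all(fr4[present] >= pi * (amin - 1)^2 / S2))
})

test_that("datasets round-trip through PGM files and manifests", {
  ph <- generate_phantoms(phantom_config(n_samples = 3, image_size = 32, seed = 76))
  d <- file.path(tempdir(), "ds_test")
  mp <- write_dataset(ph, d)
  ld <- load_manifest(mp)
  expect_length(ld, 3L)
  expect_identical(ld[[1]]$mask, ph[[1]]$mask)
  # image round-trips up to 16-bit quantisation and re-normalisation
  orig <- ph[[2]]$image[, , 1]
  orig <- (orig - min(orig)) / (max(orig) - min(orig))
  expect_lt(max(abs(ld[[2]]$image[, , 1] - orig)), 1e-3)
  expect_error(load_manifest(tempfile()), "not found")
  empty <- tempfile(fileext = ".csv")
  write.csv(data.frame(image = character(), mask = character(),
                       split = character()), empty, row.names = FALSE)
  expect_error(load_manifest(empty), "empty")
})
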