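# Enhancement chain and patch machinery.

test_that("channel fusion is a unit-sum weighted projection", {
  expect_equal(as.numeric(fuse_channels(array(100, c(1, 1, 3)))), 100)
  expect_equal(as.numeric(fuse_channels(array(c(0, 255, 0), c(1, 1, 3)))),
               149.685)
  img <- array(runif(48, 0, 255), c(4, 4, 3))
  expect_equal(fuse_channels(img, c(1, 0, 0)), img[, , 1])
  expect_error(fuse_channels(img, c(0.5, 0.2, 0.2)), "sum to 1")
  # the default mapping weights green most; the literal config flips R/G
  expect_equal(preprocess_config()$fusion_weights[2], 0.587)
  expect_equal(preprocess_config(literal_grb = TRUE)$fusion_weights[1], 0.587)
})

test_that("normalization rescales to [0,1] and is affine-invariant", {
  expect_equal(as.numeric(normalize(matrix(c(10, 20), 1))), c(0, 1))
  x <- matrix(runif(64), 8)
  n1 <- normalize(x)
  expect_equal(range(n1), c(0, 1))
  expect_equal(normalize(3.2 * x + 11), n1, tolerance = 1e-12)
  expect_warning(z <- normalize(matrix(5, 4, 4)), "constant")
  expect_true(all(z == 0))
})

test_that("CLAHE raises local contrast and stays in range", {
  s <- fixture_sample(seed = 3)
  g0 <- normalize(fuse_channels(s$image, c(0.299, 0.587, 0.114)))
  g1 <- clahe(g0, clip = 2, tiles = 8)
  expect_true(min(g1) >= 0 && max(g1) <= 1)
  local_sd <- function(m) {
    v <- c()
    for (i in seq(4, nrow(m) - 3, by = 4)) for (j in seq(4, ncol(m) - 3, by = 4))
      if (s$fov_mask[i, j] == 1) v <- c(v, stats::sd(m[(i - 3):(i + 3),
                                                       (j - 3):(j + 3)]))
    mean(v)
  }
  expect_gt(local_sd(g1), local_sd(g0))          # strict contrast increase
  # (near-)constant input stays (near-)constant
  flat <- clahe(matrix(0.5, 64, 64), 2, 8)
  expect_lt(diff(range(flat)), 0.02)
  expect_error(clahe(g0, clip = 0), "positive")
})

test_that("gamma correction is a monotone power transform with identity at 1", {
  x <- matrix(runif(64), 8)
  expect_equal(gamma_correct(x, 1), x)
  expect_equal(gamma_correct(matrix(0.25), 2), matrix(0.0625))
  a <- sort(runif(10))
  expect_true(all(diff(gamma_correct(matrix(a, 1), 1.7)) >= 0))
  expect_error(gamma_correct(x, 0), "positive")
  expect_error(gamma_correct(x + 1, 2), "\\[0, 1\\]")
})

test_that("preprocess composes the four stages in order and helps contrast", {
  s <- fixture_sample(seed = 3)
  cfg <- preprocess_config()
  got <- preprocess(s, cfg)
  manual <- gamma_correct(clahe(normalize(fuse_channels(s$image,
                                                        cfg$fusion_weights)),
                                cfg$clahe_clip, cfg$clahe_tiles), cfg$gamma)
  expect_identical(got, manual)
  expect_identical(preprocess(s, cfg), got)      # deterministic and pure
  contrast <- function(m) mean(m[s$fov_mask == 1 & s$vessel_mask == 0]) -
    mean(m[s$vessel_mask == 1])
  raw <- normalize(fuse_channels(s$image, cfg$fusion_weights))
  expect_gt(contrast(got), contrast(raw))
})

test_that("patch extraction covers the grid, is seeded, and pools correctly", {
  s <- fixture_sample(seed = 3)
  g <- preprocess(s)
  ex <- extract_patches(g, s$vessel_mask, s$fov_mask, mode = "grid",
                        stride = 64)
  expect_equal(nrow(ex$origins), 4)
  expect_setequal(ex$origins[, 1], c(0, 64))
  expect_setequal(ex$origins[, 2], c(0, 64))
  r1 <- extract_patches(g, s$vessel_mask, s$fov_mask, n = 12,
                        mode = "random", seed = 4)
  r2 <- extract_patches(g, s$vessel_mask, s$fov_mask, n = 12,
                        mode = "random", seed = 4)
  expect_identical(r1$origins, r2$origins)
  # every pyramid level halves the side via 2x2 mean pooling
  p <- r1$pyramids[[1]]
  pool2 <- mtpaunet:::pool2
  expect_equal(p$level32, pool2(p$level64))
  expect_equal(p$level16, pool2(p$level32))
  expect_equal(p$level8, pool2(p$level16))
  # labels are cropped at the same origin
  o <- r1$origins[1, ]
  expect_identical(r1$labels[[1]], s$vessel_mask[o[1] + 1:64, o[2] + 1:64])
  expect_error(extract_patches(matrix(0, 32, 32)), "at least 64x64")
})

test_that("stitching averages overlaps and inverts grid extraction", {
  s <- fixture_sample(seed = 3)
  g <- preprocess(s)
  for (stride in c(64, 32)) {
    ex <- extract_patches(g, NULL, NULL, mode = "grid", stride = stride)
    st <- stitch(lapply(ex$pyramids, `[[`, "level64"), ex$origins, dim(g))
    expect_equal(st, g, tolerance = 1e-12)       # identity on full coverage
  }
  # explicit overlap average: 0.2 and 0.6 -> 0.4
  p1 <- matrix(0.2, 64, 64); p2 <- matrix(0.6, 64, 64)
  st <- stitch(list(p1, p2), rbind(c(0, 0), c(0, 32)), c(64, 96))
  expect_true(all(abs(st[, 33:64] - 0.4) < 1e-12))
  expect_error(stitch(list(p1), rbind(c(0, 0)), c(64, 96)), "cover")
})
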