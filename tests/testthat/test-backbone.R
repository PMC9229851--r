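# Encoder/decoder blocks and the assembled network.

test_that("FE block preserves space, retargets channels, and its parameters
           match an independent per-layer tally", {
  ns <- asNamespace("mtpaunet")
  set.seed(1)
  x <- array(rnorm(6 * 12 * 10), c(6, 12, 10))
  y <- fe_block(x, out_channels = 9)
  expect_identical(dim(y), c(9L, 12L, 10L))
  # hand tally at (in=32, out=32, reduce=16): five convolutions + one norm
  fe <- ns$fe_new(32, 32, reduce = 16)
  tally <- (32 * 16 + 16) +          # 1x1 reduction
    (9 * 16 * 16 + 16) +             # 3x3 convolution
    (9 * 16 * 16 + 16) +             # 3x3 transposed convolution
    (32 * 32 + 32) +                 # 1x1 bottleneck (2*reduce -> out)
    (2 * 32) +                       # batch norm
    (32 * 32 + 32)                   # 1x1 residual projection
  expect_equal(mtpaunet:::n_params(fe), tally)
})

test_that("DS block halves the side and reduces to 2x2 mean pooling when
           its convolution is frozen to identity", {
  ns <- asNamespace("mtpaunet")
  set.seed(2)
  x <- array(abs(rnorm(3 * 32 * 32)) + 0.1, c(3, 32, 32))   # positive input
  expect_identical(dim(ds_block(x)), c(3L, 16L, 16L))
  y <- array(abs(rnorm(2 * 64 * 64)) + 0.1, c(2, 64, 64))
  for (k in 1:4) y <- ds_block(y)
  expect_identical(dim(y), c(2L, 4L, 4L))
  expect_error(ds_block(array(0, c(2, 7, 8))), "even")
  # identity freeze: delta conv kernel, eval-mode norm with unit stats
  ds <- ns$ds_new(3)
  wid <- array(0, c(3, 3, 3, 3))
  for (c in 1:3) wid[c, c, 2, 2] <- 1
  ds$sub$conv$params$w$v <- wid
  ds$sub$conv$params$b$v <- numeric(3)
  got <- ds_block(x, ds)
  pooled <- val(mtpaunet:::op_avgpool2(tsr(array(x, c(3, 32, 32, 1)))))
  expect_lt(max(abs(got - pooled[, , , 1] / sqrt(1 + 1e-5))), 1e-4)
})

test_that("multilayer pooling preserves shape and its branches equal
           brute-force block means", {
  ns <- asNamespace("mtpaunet")
  set.seed(3)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  y <- multilayer_pool(x, pool_scales = c(1, 2, 4))
  expect_identical(dim(y)[2:3], dim(x)[2:3])
  # constant input stays constant per channel
  xc <- array(rep(1:4, 8 * 8), c(4, 8, 8))
  yc <- multilayer_pool(xc, pool_scales = c(1, 2))
  expect_lt(max(apply(yc, 1, function(ch) diff(range(ch)))), 1e-10)
  expect_error(multilayer_pool(x, pool_scales = c(1, 16)), "scale")
  # pooled branch values on a 4x4 map
  x4 <- array(rnorm(2 * 4 * 4), c(2, 4, 4, 1))
  m <- ns$mlp_new(2, c(1, 2))
  br <- ns$fwd_mlp(m, tsr(x4), return_branches = TRUE)
  expect_equal(as.numeric(val(br$pooled[[1]])),
               as.numeric(apply(x4[, , , 1], 1, mean)), tolerance = 1e-12)
  want22 <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2)
    want22[, a, b] <- apply(x4[, (2 * a - 1):(2 * a), (2 * b - 1):(2 * b), 1],
                            1, mean)
  expect_equal(array(val(br$pooled[[2]]), c(2, 2, 2)), want22,
               tolerance = 1e-12)
})

test_that("SCI fusion lands on the deepest grid and shallow layers reach it", {
  set.seed(4)
  encs <- list(array(rnorm(4 * 32 * 32), c(4, 32, 32)),
               array(rnorm(8 * 16 * 16), c(8, 16, 16)),
               array(rnorm(16 * 8 * 8), c(16, 8, 8)),
               array(rnorm(32 * 4 * 4), c(32, 4, 4)))
  ns <- asNamespace("mtpaunet")
  mod <- ns$sci_new(c(4, 8, 16, 32))
  y <- sci_fuse(encs, mod)
  expect_identical(dim(y), c(32L, 4L, 4L))
  encs0 <- encs
  for (k in 1:3) encs0[[k]] <- encs[[k]] * 0
  y0 <- sci_fuse(encs0, mod)
  expect_gt(max(abs(y - y0)), 1e-6)   # shallow information reaches the bottom
  expect_error(sci_fuse(encs[1:3]), "4 encoder outputs")
})

test_that("decoder blocks upsample to the skip grid and chain back to 64x64", {
  ns <- asNamespace("mtpaunet")
  set.seed(5)
  x <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  skip <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
  mod <- ns$dec_new(8, 6, 6)
  y <- decoder_block(x, skip, module = mod)
  expect_identical(dim(y)[2:3], dim(skip)[2:3])
  # additive merge: zero skip leaves the refined upsampled path alone
  y0 <- decoder_block(x, skip * 0, module = mod)
  up <- ns$op_resize_bilinear(tsr(array(x, c(8, 4, 4, 1))), 8, 8)
  alone <- val(ns$fwd_fe(mod$sub$fe, ns$fwd_conv2d(mod$sub$align, up)))
  expect_equal(array(y0, dim(alone)), alone, tolerance = 1e-10)
  expect_error(decoder_block(x, array(0, c(6, 16, 16)), module = mod), "twice")
  # four doublings recover 64x64 from the 4x4 bottom
  z <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  for (side in c(8, 16, 32, 64)) {
    sk <- array(rnorm(4 * side * side), c(4, side, side))
    z <- decoder_block(z, sk, out_channels = 8)
  }
  expect_identical(dim(z)[2:3], c(64L, 64L))
})

test_that("the assembled network maps a 64x64 pyramid to a [0,1] probability
           map, deterministically in evaluation mode", {
  set.seed(6)
  cfg <- tiny_model_cfg()
  model <- mtpa_model(cfg, seed = 2)
  p64 <- matrix(runif(64 * 64), 64)
  pyr <- patch_pyramid(p64)
  out1 <- mtpa_unet_forward(pyr, model)
  out2 <- mtpa_unet_forward(pyr, model)
  expect_identical(dim(out1), c(64L, 64L))
  expect_true(all(out1 >= 0 & out1 <= 1))
  expect_identical(out1, out2)
  expect_error(mtpa_unet_forward(list(level64 = p64), model), "levels")
})

test_that("every parameter of the assembled network learns from the Dice loss", {
  ops <- asNamespace("mtpaunet")
  set.seed(7)
  cfg <- tiny_model_cfg()
  model <- mtpa_model(cfg, seed = 3)
  ps <- collect_params(model)
  zero_grads(ps)
  old <- training_mode(TRUE)
  on.exit(training_mode(old))
  p64 <- array(runif(64 * 64 * 2), c(1, 64, 64, 2))
  pyr <- mtpaunet:::stack_batch(list(patch_pyramid(matrix(p64[1, , , 1], 64)),
                                     patch_pyramid(matrix(p64[1, , , 2], 64))))
  out <- mtpaunet:::fwd_mtpa(model, pyr)
  G <- array(rbinom(64 * 64 * 2, 1, 0.12), c(1, 64, 64, 2))
  backward(ops$op_dice_loss(out, G))
  dead <- names(ps)[vapply(ps, function(p)
    is.null(p$grad) || all(p$grad == 0), logical(1))]
  expect_length(dead, 0)
})

test_that("parameter counting enumerates learnable scalars exactly", {
  ns <- asNamespace("mtpaunet")
  conv <- ns$mod_conv2d(2, 3, k = 1, pad = 0)
  expect_equal(mtpaunet:::n_params(conv), 2 * 3 + 3)
  cfg <- tiny_model_cfg()
  m <- mtpa_model(cfg, seed = 1)
  expect_equal(count_parameters(m),
               sum(vapply(collect_params(m), function(p) length(p$v),
                          numeric(1))))
  # the count is a function of the configuration, not of any input size
  expect_equal(count_parameters(mtpa_model(cfg, seed = 9)),
               count_parameters(m))
  # stacking a second TPA block per stage adds exactly one block's worth
  cfg2 <- mtpa_config("desk", channels = cfg$channels, depth = 2)
  ns <- asNamespace("mtpaunet")
  per_stage <- vapply(1:4, function(i) {
    ac <- attention_config(cfg$channels[i], cfg$heads[i], cfg$sr_ratios[i],
                           cfg$ffn_expansion, 1)
    mtpaunet:::n_params(ns$tpa_new(ac))
  }, numeric(1))
  expect_equal(count_parameters(mtpa_config("desk", channels = cfg$channels,
                                            depth = 2)),
               count_parameters(m) + sum(per_stage))
})
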