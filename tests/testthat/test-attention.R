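# Transformer-side blocks against independent oracles.

test_that("patch embedding halves the side, doubles channels, gates boundedly", {
  set.seed(1)
  x <- array(rnorm(64 * 16 * 16), c(64, 16, 16))
  expect_identical(dim(patch_embed(x)), c(128L, 8L, 8L))
  x2 <- array(rnorm(32 * 64 * 64), c(32, 64, 64))
  expect_identical(dim(patch_embed(x2)), c(64L, 32L, 32L))
  expect_error(patch_embed(array(rnorm(4 * 5 * 6), c(4, 5, 6))), "even")
})

test_that("positional encoding preserves shape with a (0,1) gate", {
  ns <- asNamespace("mtpaunet")
  set.seed(2)
  x <- array(rnorm(6 * 10 * 8), c(6, 10, 8))
  mod <- ns$pos_enc_new(6)
  y <- positional_encode(x, mod)
  expect_identical(dim(y), dim(x))
  expect_true(all(positional_encode(array(0, c(3, 4, 4))) == 0))
  # the per-element gate factor lies strictly inside (0,1)
  gate <- y / x
  expect_true(all(gate[is.finite(gate)] > 0 & gate[is.finite(gate)] < 1))
})

test_that("TMSA reduces to vanilla self-attention under the identity freeze", {
  ns <- asNamespace("mtpaunet")
  set.seed(3)
  d <- 3; H <- 4; W <- 5
  cfg <- attention_config(d, heads = 1, sr_ratio = 1, ffn_expansion = 1,
                          use_norm = FALSE)
  tm <- ns$tmsa_new(cfg)
  eye <- function(k) array(diag(k), c(k, k, 1, 1))
  for (nm in c("wq", "wk", "wv", "wo")) {
    tm$sub[[nm]]$params$w$v <- eye(d)
    tm$sub[[nm]]$params$b$v <- numeric(d)
  }
  tm$sub$mix$params$w$v <- matrix(1, 1, 1)
  tm$sub$mix$params$b$v <- numeric(1)
  tm$sub$ffn2$params$w$v <- array(0, dim(tm$sub$ffn2$params$w$v))
  tm$sub$ffn2$params$b$v <- numeric(d)
  x <- array(rnorm(d * H * W), c(d, H, W, 1))
  got <- val(ns$fwd_tmsa(tm, tsr(x)))
  # brute-force n x n self-attention oracle on the token matrix
  Xt <- t(matrix(x, d))
  S <- Xt %*% t(Xt) / sqrt(d)
  A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  expect_true(all(abs(rowSums(A) - 1) < 1e-12))
  want <- x + array(t(A %*% Xt), c(d, H, W, 1))
  expect_lt(max(abs(got - want)), 1e-4)
})

test_that("TMSA is shape-preserving for arbitrary head/reduction settings", {
  set.seed(4)
  for (cfg in list(attention_config(8, heads = 2, sr_ratio = 2),
                   attention_config(12, heads = 3, sr_ratio = 1,
                                    ffn_expansion = 2),
                   attention_config(8, heads = 1, sr_ratio = 4))) {
    x <- array(rnorm(cfg$d_m * 8 * 8 * 2), c(cfg$d_m, 8, 8, 2))
    expect_identical(dim(tmsa(x, cfg)), dim(x))
  }
  expect_error(attention_config(6, heads = 4), "d_m")
})

test_that("position attention matches the double-loop criss-cross oracle", {
  ns <- asNamespace("mtpaunet")
  set.seed(5)
  for (dims in list(c(3, 4, 5), c(2, 8, 8), c(4, 6, 3))) {
    C <- dims[1]; H <- dims[2]; W <- dims[3]
    Fx <- array(rnorm(C * H * W), c(C, H, W, 1))
    mod <- ns$pos_attn_new(C)
    got <- position_attention(Fx[, , , 1], mod)
    X3 <- Fx[, , , 1]
    M <- conv1x1_oracle(val(mod$sub$m$params$w), val(mod$sub$m$params$b), X3)
    Nn <- conv1x1_oracle(val(mod$sub$n$params$w), val(mod$sub$n$params$b), X3)
    V <- conv1x1_oracle(val(mod$sub$v$params$w), val(mod$sub$v$params$b), X3)
    want <- array(0, c(C, H, W))
    for (i in seq_len(H)) for (j in seq_len(W)) {
      pos <- list()
      for (ii in seq_len(H)) if (ii != i) pos[[length(pos) + 1]] <- c(ii, j)
      for (jj in seq_len(W)) pos[[length(pos) + 1]] <- c(i, jj)
      expect_length(pos, H + W - 1)
      lg <- vapply(pos, function(p) sum(M[, i, j] * Nn[, p[1], p[2]]),
                   numeric(1))
      a <- exp(lg - max(lg)); a <- a / sum(a)
      agg <- numeric(C)
      for (k in seq_along(pos))
        agg <- agg + a[k] * V[, pos[[k]][1], pos[[k]][2]]
      want[, i, j] <- agg + X3[, i, j]
    }
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("a 1x1 map degenerates to V(F) + F with unit attention weight", {
  ns <- asNamespace("mtpaunet")
  set.seed(6)
  F1 <- array(rnorm(4), c(4, 1, 1, 1))
  mod <- ns$pos_attn_new(4)
  got <- val(ns$fwd_pos_attn(mod, tsr(F1)))
  v <- matrix(val(mod$sub$v$params$w), 4) %*% F1[, 1, 1, 1] +
    val(mod$sub$v$params$b)
  expect_equal(got[, 1, 1, 1], as.numeric(v + F1[, 1, 1, 1]), tolerance = 1e-12)
})

test_that("criss-cross attention weights are nonnegative and sum to one", {
  set.seed(7)
  x <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
  A <- position_attention_weights(x)
  expect_true(all(A >= 0))
  sums <- apply(A, c(2, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # the masked column self-slot carries exactly zero weight
  for (i in 1:6) expect_true(all(A[i, i, , ] == 0))
})

test_that("two criss-cross passes give full pairwise influence on a 6x6 map", {
  ns <- asNamespace("mtpaunet")
  set.seed(8)
  C <- 2; H <- 6; W <- 6
  pa <- ns$pos_attn_new(C)
  x <- array(rnorm(C * H * W), c(C, H, W, 1))
  ops <- asNamespace("mtpaunet")
  for (p in seq_len(H * W)) {
    xt <- tsr(x, TRUE)
    y <- ns$fwd_pos_attn(pa, ns$fwd_pos_attn(pa, xt))
    pi <- ((p - 1) %% H) + 1; pj <- ((p - 1) %/% H) + 1
    sel <- array(0, dim(x)); sel[, pi, pj, ] <- 1
    backward(ops$op_sum(ops$op_mul(y, tsr(sel))))
    influence <- apply(abs(xt$grad), c(2, 3), max)
    expect_true(all(influence > 1e-12))
  }
})

test_that("the TPA block preserves shape, is deterministic, and trains fully", {
  ns <- asNamespace("mtpaunet")
  ops <- asNamespace("mtpaunet")
  set.seed(9)
  cfg <- attention_config(4, heads = 2, sr_ratio = 2, ffn_expansion = 2)
  tp <- ns$tpa_new(cfg)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  y1 <- tpa_block(x, cfg, tp)
  y2 <- tpa_block(x, cfg, tp)
  expect_identical(dim(y1), dim(x))
  expect_identical(y1, y2)
  # every learnable parameter receives a nonzero gradient from a Dice loss
  ps <- collect_params(tp)
  zero_grads(ps)
  old <- training_mode(TRUE)
  on.exit(training_mode(old))
  out <- ns$fwd_tpa(tp, tsr(array(x, c(4, 8, 8, 1))))
  G <- array(rbinom(64, 1, 0.3), c(4, 8, 8, 1))
  backward(ops$op_dice_loss(ops$op_sigmoid(out), G))
  dead <- names(ps)[vapply(ps, function(p)
    is.null(p$grad) || all(p$grad == 0), logical(1))]
  expect_length(dead, 0)
})
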