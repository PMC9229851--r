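# Numerical gradient checks of the differentiable primitives: every analytic
# backward must agree with central finite differences on small tensors.

expect_gradmatch <- function(got, want, tol = 1e-5) {
  expect_lt(max(abs(got - want)), tol)
}

test_that("convolution backwards match finite differences", {
  ops <- asNamespace("mtpaunet")
  set.seed(42)
  cases <- list(
    list(stride = 2, pad = 1, k = 3),   # im2col path (patch embedding)
    list(stride = 1, pad = 1, k = 3),   # direct shift-and-GEMM path
    list(stride = 1, pad = 0, k = 1)    # pointwise path
  )
  for (cs in cases) {
    x <- array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2))
    w <- array(rnorm(3 * 2 * cs$k^2), c(3, 2, cs$k, cs$k))
    b <- rnorm(3)
    f <- function(xv, wv, bv) {
      sum(val(ops$op_conv2d(tsr(xv), tsr(wv), tsr(bv),
                            stride = cs$stride, pad = cs$pad))^2) / 2
    }
    xt <- tsr(x, TRUE); wt <- tsr(w, TRUE); bt <- tsr(b, TRUE)
    out <- ops$op_conv2d(xt, wt, bt, stride = cs$stride, pad = cs$pad)
    backward(ops$op_scale(ops$op_sum(ops$op_mul(out, out)), 0.5))
    expect_gradmatch(xt$grad, num_grad(function(v) f(v, w, b), x))
    expect_gradmatch(wt$grad, num_grad(function(v) f(x, v, b), w))
    expect_gradmatch(bt$grad, num_grad(function(v) f(x, w, v), array(b)))
  }
})

test_that("attention primitives (bmm, softmax, criss-cross) backprop correctly", {
  ops <- asNamespace("mtpaunet")
  set.seed(7)
  # batched matmul with both transpose flags
  a <- array(rnorm(24), c(3, 4, 2)); b <- array(rnorm(16), c(4, 2, 2))
  rv <- array(rnorm(12), c(3, 2, 2))
  f <- function(av, bv) sum(val(ops$op_bmm(tsr(av), tsr(bv))) * rv)
  at <- tsr(a, TRUE); bt <- tsr(b, TRUE)
  backward(ops$op_sum(ops$op_mul(ops$op_bmm(at, bt), tsr(rv))))
  expect_gradmatch(at$grad, num_grad(function(v) f(v, b), a))
  expect_gradmatch(bt$grad, num_grad(function(v) f(a, v), b))
  # softmax with -Inf masking
  x <- array(rnorm(24), c(4, 3, 2))
  mask <- array(0, dim(x)); mask[2, , ] <- -Inf
  rv <- array(rnorm(24), dim(x))
  f <- function(v) sum(val(ops$op_softmax(ops$op_addc(tsr(v, TRUE), mask), 1)) * rv)
  xt <- tsr(x, TRUE)
  backward(ops$op_sum(ops$op_mul(ops$op_softmax(ops$op_addc(xt, mask), 1), tsr(rv))))
  expect_gradmatch(xt$grad, num_grad(f, x))
  # fused criss-cross op
  C <- 2; H <- 3; W <- 4
  Mv <- array(rnorm(C * H * W * 2), c(C, H, W, 2))
  Nv <- array(rnorm(C * H * W * 2), c(C, H, W, 2))
  Vv <- array(rnorm(C * H * W * 2), c(C, H, W, 2))
  rv <- array(rnorm(C * H * W * 2), c(C, H, W, 2))
  f <- function(mv, nv, vv)
    sum(val(ops$op_crisscross(tsr(mv), tsr(nv), tsr(vv))) * rv)
  Mt <- tsr(Mv, TRUE); Nt <- tsr(Nv, TRUE); Vt <- tsr(Vv, TRUE)
  backward(ops$op_sum(ops$op_mul(ops$op_crisscross(Mt, Nt, Vt), tsr(rv))))
  expect_gradmatch(Mt$grad, num_grad(function(v) f(v, Nv, Vv), Mv), 1e-4)
  expect_gradmatch(Nt$grad, num_grad(function(v) f(Mv, v, Vv), Nv), 1e-4)
  expect_gradmatch(Vt$grad, num_grad(function(v) f(Mv, Nv, v), Vv), 1e-4)
})

test_that("normalization, pooling and resize backwards match finite differences", {
  ops <- asNamespace("mtpaunet")
  set.seed(11)
  x <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2))
  ga <- runif(3, 0.5, 1.5); be <- rnorm(3)
  rv <- array(rnorm(length(x)), dim(x))
  mkstate <- function() {
    e <- new.env(); e$running_mean <- rep(0, 3); e$running_var <- rep(1, 3); e
  }
  old <- training_mode(TRUE)
  on.exit(training_mode(old))
  f <- function(xv, gv, bv)
    sum(val(ops$op_batchnorm2d(tsr(xv), tsr(gv), tsr(bv), mkstate())) * rv)
  xt <- tsr(x, TRUE); gt <- tsr(ga, TRUE); bt <- tsr(be, TRUE)
  backward(ops$op_sum(ops$op_mul(
    ops$op_batchnorm2d(xt, gt, bt, mkstate()), tsr(rv))))
  expect_gradmatch(xt$grad, num_grad(function(v) f(v, ga, be), x), 1e-4)
  expect_gradmatch(gt$grad, num_grad(function(v) f(x, v, be), array(ga)), 1e-4)
  f2 <- function(xv, gv, bv)
    sum(val(ops$op_layernorm_c(tsr(xv), tsr(gv), tsr(bv))) * rv)
  xt <- tsr(x, TRUE); gt <- tsr(ga, TRUE); bt <- tsr(be, TRUE)
  backward(ops$op_sum(ops$op_mul(ops$op_layernorm_c(xt, gt, bt), tsr(rv))))
  expect_gradmatch(xt$grad, num_grad(function(v) f2(v, ga, be), x), 1e-4)
  # pooling / resize are linear; check their adjoints numerically too
  for (op in list(function(t) ops$op_adaptive_avgpool(t, 3, 3),
                  function(t) ops$op_avgpool2(t),
                  function(t) ops$op_resize_bilinear(t, 8, 8))) {
    x <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
    xt <- tsr(x, TRUE)
    y <- op(xt)
    rv <- array(rnorm(length(val(y))), dim(val(y)))
    backward(ops$op_sum(ops$op_mul(y, tsr(rv))))
    f3 <- function(v) sum(val(op(tsr(v))) * rv)
    expect_gradmatch(xt$grad, num_grad(f3, x))
  }
})

test_that("dice loss gradient and smooth activations backprop correctly", {
  ops <- asNamespace("mtpaunet")
  set.seed(5)
  p <- array(runif(24), c(1, 4, 6, 1))
  G <- array(rbinom(24, 1, 0.4), dim(p))
  pt <- tsr(p, TRUE)
  backward(ops$op_dice_loss(pt, G, 1e-5))
  expect_gradmatch(pt$grad,
                   num_grad(function(v) val(ops$op_dice_loss(tsr(v), G, 1e-5)), p))
  for (nm in c("op_gelu", "op_sigmoid", "op_relu")) {
    x <- array(rnorm(24) + 0.05, c(2, 3, 2, 2))   # keep away from ReLU kink
    rv <- array(rnorm(24), dim(x))
    xt <- tsr(x, TRUE)
    backward(ops$op_sum(ops$op_mul(ops[[nm]](xt), tsr(rv))))
    expect_gradmatch(xt$grad,
                     num_grad(function(v) sum(val(ops[[nm]](tsr(v))) * rv), x),
                     1e-4)
  }
})
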