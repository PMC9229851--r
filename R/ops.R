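# Differentiable primitive operations. Feature maps are arrays with dims
# (C, H, W, N): channels, height, width, batch. Column-major layout makes
# the channel axis fastest, so length-C vectors broadcast along channels by
# plain recycling.

dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  d
}

# ---- elementwise -----------------------------------------------------------

op_add <- function(a, b) {
  stopifnot(identical(dim(a$v), dim(b$v)))
  tn_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

op_mul <- function(a, b) {
  stopifnot(identical(dim(a$v), dim(b$v)))
  av <- a$v; bv <- b$v
  tn_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# add a constant (no-grad) array or scalar
op_addc <- function(x, k) tn_node(x$v + k, list(x), function(g) list(g))

op_scale <- function(x, k) tn_node(x$v * k, list(x), function(g) list(g * k))

# per-channel bias along dim 1
op_bias <- function(x, b) {
  C <- dim(x$v)[1]
  stopifnot(length(b$v) == C)
  tn_node(x$v + as.vector(b$v), list(x, b), function(g)
    list(g, rowSums(matrix(g, nrow = C))))
}

# per-channel scale along dim 1 (used by norm layers)
op_cscale <- function(x, s) {
  C <- dim(x$v)[1]
  sv <- as.vector(s$v); xv <- x$v
  tn_node(xv * sv, list(x, s), function(g)
    list(g * sv, rowSums(matrix(g * xv, nrow = C))))
}

op_relu <- function(x) {
  m <- x$v > 0
  tn_node(x$v * m, list(x), function(g) list(g * m))
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  tn_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_gelu <- function(x) {
  # tanh approximation of the Gaussian error linear unit
  v <- x$v
  tn_node(cpp_gelu_fwd(v), list(x), function(g) list(cpp_gelu_bwd(v, g)))
}

# ---- shape -----------------------------------------------------------------

op_reshape <- function(x, dims) {
  old <- dim(x$v)
  tn_node(array(x$v, dim = dims), list(x), function(g) list(array(g, dim = old)))
}

op_aperm <- function(x, perm) {
  inv <- order(perm)
  tn_node(aperm(x$v, perm), list(x), function(g) list(aperm(g, inv)))
}

op_concat_c <- function(xs) {
  dms <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(dms, `[`, numeric(1), 1)
  rest <- dms[[1]][-1]
  for (d in dms) stopifnot(identical(d[-1], rest))
  C <- sum(cs)
  out <- array(0, dim = c(C, rest))
  at <- 0
  for (i in seq_along(xs)) {
    out[at + seq_len(cs[i]), , , ] <- xs[[i]]$v
    at <- at + cs[i]
  }
  offs <- c(0, cumsum(cs))
  tn_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i)
      g[offs[i] + seq_len(cs[i]), , , , drop = FALSE])
  })
}

# take a contiguous index set along dim 1 of a 4-D array
op_slice1 <- function(x, idx) {
  d <- dim(x$v)
  tn_node(x$v[idx, , , , drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = d)
    dx[idx, , , ] <- g
    list(dx)
  })
}

# ---- reductions ------------------------------------------------------------

op_sum <- function(x) {
  d <- dim(x$v)
  tn_node(sum(x$v), list(x), function(g) list(array(as.numeric(g), dim = d)))
}

op_mean <- function(x) {
  n <- length(x$v); d <- dim(x$v)
  tn_node(mean(x$v), list(x), function(g)
    list(array(as.numeric(g) / n, dim = d)))
}

# ---- linear algebra --------------------------------------------------------

op_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  tn_node(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

# batched matmul on 3-D arrays; `ta`/`tb` transpose each slice logically,
# so A is (p,q,B) after transposition and B is (q,r,B); result (p,r,B)
op_bmm <- function(a, b, ta = FALSE, tb = FALSE, out_dim = NULL) {
  av <- a$v; bv <- b$v
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3, length(db) == 3, da[3] == db[3])
  p <- if (ta) da[2] else da[1]
  q <- if (ta) da[1] else da[2]
  r <- if (tb) db[1] else db[2]
  stopifnot((if (tb) db[2] else db[1]) == q)
  B <- da[3]
  out <- cpp_bmm(av, bv, p, q, B, r, ta, tb)
  if (!is.null(out_dim)) dim(out) <- out_dim
  tn_node(out, list(a, b), function(g) {
    ga <- if (!ta) cpp_bmm(g, bv, p, r, B, q, FALSE, !tb)
          else     cpp_bmm(bv, g, q, r, B, p, tb, TRUE)
    gb <- if (!tb) cpp_bmm(av, g, q, p, B, r, !ta, FALSE)
          else     cpp_bmm(g, av, r, p, B, q, TRUE, ta)
    list(ga, gb)
  })
}

# ---- softmax ---------------------------------------------------------------

# softmax along dimension `dm` of an arbitrary array; -Inf entries get
# exactly zero weight (used for criss-cross self-slot masking)
op_softmax <- function(x, dm) {
  d <- dim(x$v)
  nd <- length(d)
  K <- d[dm]
  if (dm == 1) {
    out <- cpp_softmax_cols(x$v, K)
    dim(out) <- d
    return(tn_node(out, list(x), function(g) {
      dx <- cpp_softmax_cols_bw(out, g, K)
      dim(dx) <- d
      list(dx)
    }))
  }
  perm <- c(dm, setdiff(seq_len(nd), dm))
  inv <- order(perm)
  a <- cpp_softmax_cols(aperm(x$v, perm), K)
  dim(a) <- d[perm]
  out <- aperm(a, inv)
  tn_node(out, list(x), function(g) {
    dx <- cpp_softmax_cols_bw(a, aperm(g, perm), K)
    dim(dx) <- d[perm]
    list(aperm(dx, inv))
  })
}

# fused transpose + reshape: aperm then set target dims without extra copy
op_permdim <- function(x, perm, newdim) {
  d <- dim(x$v)
  out <- aperm(x$v, perm)
  dim(out) <- newdim
  inv <- order(perm)
  tn_node(out, list(x), function(g) {
    dim(g) <- d[perm]
    list(aperm(g, inv))
  })
}

# set the column-direction self slot (Z[i,i,,]) to -Inf before a softmax
# over dim 1 of a (H+W, H, W, N) logit stack
op_neginf_colself <- function(x) {
  d <- dim(x$v)
  H <- d[2]
  v <- x$v
  for (i in seq_len(H)) v[i, i, , ] <- -Inf
  tn_node(v, list(x), function(g) {
    for (i in seq_len(H)) g[i, i, , ] <- 0
    list(g)
  })
}

# fused criss-cross attention core: softmax-normalized affinities of each
# pixel's query (from M) against keys (from N) over its row and column,
# aggregating V over that set; residual NOT included
op_crisscross <- function(M, N, V) {
  d <- dims4(M$v)
  r <- cpp_cc_fwd(M$v, N$v, V$v, d[1], d[2], d[3], d[4])
  A <- r$A
  Mv <- M$v; Nv <- N$v; Vv <- V$v
  tn_node(r$Y, list(M, N, V), function(g) {
    gr <- cpp_cc_bwd(Mv, Nv, Vv, A, g, d[1], d[2], d[3], d[4])
    list(gr$dM, gr$dN, gr$dV)
  })
}

# ---- convolution -----------------------------------------------------------

# x (Ci,H,W,N), w (Co,Ci,k,k), b length Co or NULL. The im2col matrix is
# recomputed during backward instead of being retained, which keeps the
# graph's peak memory proportional to the activations alone.
op_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0) {
  d <- dims4(x$v)
  wd <- dim(w$v)
  stopifnot(length(wd) == 4, wd[2] == d[1])
  k <- wd[3]
  oh <- (d[2] + 2 * pad - k) %/% stride + 1
  ow <- (d[3] + 2 * pad - k) %/% stride + 1
  xv <- x$v
  # stride-1 'same' convolutions go through a direct shift-and-GEMM kernel
  if (k > 1 && stride == 1 && pad == (k - 1) %/% 2) {
    wv <- w$v
    out <- cpp_conv_same_fwd(xv, wv, d[1], d[2], d[3], d[4], wd[1], k)
    if (!is.null(b)) out <- out + as.vector(b$v)
    parents <- if (is.null(b)) list(x, w) else list(x, w, b)
    return(tn_node(out, parents, function(g) {
      gr <- cpp_conv_same_bwd(xv, wv, g, d[1], d[2], d[3], d[4], wd[1], k)
      if (is.null(b)) list(gr$dx, gr$dw)
      else list(gr$dx, gr$dw, rowSums(matrix(g, nrow = wd[1])))
    }))
  }
  wm <- matrix(w$v, nrow = wd[1])
  pointwise <- (k == 1 && stride == 1 && pad == 0)
  colm <- if (pointwise) {
    xm <- xv; dim(xm) <- c(d[1], d[2] * d[3] * d[4]); xm
  } else cpp_im2col(xv, d[1], d[2], d[3], d[4], k, stride, pad, oh, ow)
  y <- wm %*% colm
  if (!is.null(b)) y <- y + as.vector(b$v)
  dim(y) <- c(wd[1], oh, ow, d[4])
  out <- y
  colm <- NULL; y <- NULL   # not needed by backward; free before graph retention
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tn_node(out, parents, function(g) {
    dim(g) <- c(wd[1], oh * ow * d[4])
    if (pointwise) {
      xm <- xv; dim(xm) <- c(d[1], d[2] * d[3] * d[4])
      dw <- tcrossprod(g, xm)
      dim(dw) <- wd
      dx <- crossprod(wm, g)
      dim(dx) <- d
    } else {
      colm <- cpp_im2col(xv, d[1], d[2], d[3], d[4], k, stride, pad, oh, ow)
      dw <- tcrossprod(g, colm)
      dim(dw) <- wd
      dcolm <- crossprod(wm, g)
      dx <- cpp_col2im(dcolm, d[1], d[2], d[3], d[4], k, stride, pad, oh, ow)
    }
    if (is.null(b)) list(dx, dw) else list(dx, dw, rowSums(g))
  })
}

# depthwise 3x3, stride 1, pad 1; w (C,3,3), b length C or NULL
op_dwconv2d <- function(x, w, b = NULL) {
  d <- dims4(x$v)
  C <- d[1]
  stopifnot(all(dim(w$v) == c(C, 3, 3)))
  xv <- x$v; wv <- w$v
  out <- cpp_dwconv_fwd(xv, wv, d[1], d[2], d[3], d[4])
  if (!is.null(b)) out <- out + as.vector(b$v)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tn_node(out, parents, function(g) {
    gr <- cpp_dwconv_bwd(xv, wv, g, d[1], d[2], d[3], d[4])
    if (is.null(b)) list(gr$dx, gr$dw)
    else list(gr$dx, gr$dw, rowSums(matrix(g, nrow = C)))
  })
}

# ---- pooling and resizing --------------------------------------------------

op_avgpool2 <- function(x) {
  d <- dims4(x$v)
  stopifnot(d[2] %% 2 == 0, d[3] %% 2 == 0)
  hi <- seq(1, d[2], by = 2); wi <- seq(1, d[3], by = 2)
  v <- x$v
  out <- (v[, hi, wi, , drop = FALSE] + v[, hi + 1, wi, , drop = FALSE] +
          v[, hi, wi + 1, , drop = FALSE] + v[, hi + 1, wi + 1, , drop = FALSE]) / 4
  tn_node(out, list(x), function(g) {
    dx <- array(0, dim = d)
    g4 <- g / 4
    dx[, hi, wi, ] <- g4
    dx[, hi + 1, wi, ] <- g4
    dx[, hi, wi + 1, ] <- g4
    dx[, hi + 1, wi + 1, ] <- g4
    list(dx)
  })
}

adaptive_bounds <- function(n, g) {
  lo <- floor((seq_len(g) - 1) * n / g) + 1
  hi <- ceiling(seq_len(g) * n / g)
  cbind(lo, hi)
}

op_adaptive_avgpool <- function(x, gh, gw = gh) {
  d <- dims4(x$v)
  stopifnot(gh <= d[2], gw <= d[3])
  bh <- adaptive_bounds(d[2], gh); bw <- adaptive_bounds(d[3], gw)
  out <- array(0, dim = c(d[1], gh, gw, d[4]))
  for (a in seq_len(gh)) for (b in seq_len(gw)) {
    s <- x$v[, bh[a, 1]:bh[a, 2], bw[b, 1]:bw[b, 2], , drop = FALSE]
    K <- dim(s)[2] * dim(s)[3]
    sm <- array(s, dim = c(d[1], K, d[4]))
    acc <- array(0, dim = c(d[1], d[4]))
    for (q in seq_len(K)) acc <- acc + sm[, q, ]
    out[, a, b, ] <- acc / K
  }
  tn_node(out, list(x), function(g) {
    dx <- array(0, dim = d)
    for (a in seq_len(gh)) for (b in seq_len(gw)) {
      hs <- bh[a, 1]:bh[a, 2]; ws <- bw[b, 1]:bw[b, 2]
      K <- length(hs) * length(ws)
      gi <- matrix(g[, a, b, ], nrow = d[1])              # (C,N)
      rep4 <- array(gi / K, dim = c(d[1], d[4], length(hs), length(ws)))
      dx[, hs, ws, ] <- dx[, hs, ws, , drop = FALSE] + aperm(rep4, c(1, 3, 4, 2))
    }
    list(dx)
  })
}

# bilinear interpolation matrix (half-pixel centers), rows sum to 1
bilinear_matrix <- function(n_in, n_out) {
  U <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    lo <- floor(src)
    wq <- src - lo
    i0 <- min(max(lo, 0), n_in - 1)
    i1 <- min(max(lo + 1, 0), n_in - 1)
    U[i, i0 + 1] <- U[i, i0 + 1] + (1 - wq)
    U[i, i1 + 1] <- U[i, i1 + 1] + wq
  }
  U
}

# apply separable linear resize given row/col operators
resize_core <- function(v, Uh, Uw) {
  d <- dims4(v)
  oh <- nrow(Uh); ow <- nrow(Uw)
  xp <- aperm(v, c(2, 3, 1, 4))                         # (H,W,C,N)
  m1 <- Uh %*% matrix(xp, nrow = d[2])                  # (oh, W*C*N)
  a1 <- array(m1, dim = c(oh, d[3], d[1], d[4]))
  a1 <- aperm(a1, c(2, 1, 3, 4))                        # (W,oh,C,N)
  m2 <- Uw %*% matrix(a1, nrow = d[3])                  # (ow, oh*C*N)
  a2 <- array(m2, dim = c(ow, oh, d[1], d[4]))
  aperm(a2, c(3, 2, 1, 4))                              # (C,oh,ow,N)
}

op_resize_bilinear <- function(x, oh, ow) {
  d <- dims4(x$v)
  Uh <- bilinear_matrix(d[2], oh)
  Uw <- bilinear_matrix(d[3], ow)
  out <- resize_core(x$v, Uh, Uw)
  tn_node(out, list(x), function(g) list(resize_core(g, t(Uh), t(Uw))))
}

# ---- normalization ---------------------------------------------------------

# batch norm over (H,W,N) per channel; state: env with running_mean/var
op_batchnorm2d <- function(x, gamma, beta, state, eps = 1e-5, momentum = 0.1) {
  d <- dims4(x$v)
  C <- d[1]; M <- prod(d[-1])
  xv <- x$v
  train <- is_training()
  if (train) {
    st <- cpp_channel_stats(xv, C)
    mu <- st$mean; va <- st$var
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * M / max(M - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  gv <- as.vector(gamma$v)
  out <- cpp_bn_apply(xv, mu, invstd, gv, as.vector(beta$v), C)
  tn_node(out, list(x, gamma, beta), function(g) {
    r <- cpp_bn_bwd(xv, gv, g, mu, invstd, C, train)
    list(r$dx, r$dgamma, r$dbeta)
  })
}

# layer norm over the channel axis per spatial position / sample
op_layernorm_c <- function(x, gamma, beta, eps = 1e-5) {
  d <- dims4(x$v)
  C <- d[1]
  xv <- x$v
  gv <- as.vector(gamma$v)
  r <- cpp_ln_fwd(xv, gv, as.vector(beta$v), C, eps)
  mu <- r$mu; invstd <- r$invstd
  tn_node(r$y, list(x, gamma, beta), function(g) {
    b <- cpp_ln_bwd(xv, gv, g, mu, invstd, C)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

# ---- loss ------------------------------------------------------------------

# soft Dice loss 1 - (2*sum(p*g)+w)/(sum(p)+sum(g)+w); G is a constant array
op_dice_loss <- function(p, G, w = 1e-5) {
  pv <- p$v
  G <- array(G, dim = dim(pv) %||% length(pv))
  I <- sum(pv * G)
  S <- 2 * I + w
  T_ <- sum(pv) + sum(G) + w
  tn_node(1 - S / T_, list(p), function(g) {
    list(array(as.numeric(g) * (-(2 * G * T_ - S) / T_^2), dim = dim(pv)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
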