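# Transformer-side blocks of MTPA_Unet.
#
# A TPA block replaces standard multi-head self-attention by
#   positional encoding -> TMSA (+FFN) -> criss-cross position attention x2.
# TMSA queries at full resolution, keys/values on a spatially reduced map
# (strided convolution + layer norm), with head interactions mixed by a 1x1
# convolution applied across the head axis of the logit stack.

#' Attention configuration for one Transformer stage
#'
#' @param d_m embedding channels of the stage; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param sr_ratio spatial-reduction factor for the key/value map; keys and
#'   values are computed on a map whose side is divided by this factor.
#' @param ffn_expansion hidden-width multiplier of the feed-forward network.
#' @param depth number of TPA blocks in the stage.
#' @param use_norm logical; disable the internal layer norms (used by
#'   equivalence tests against plain self-attention).
#' @return a list of class `attention_config`.
#' @export
attention_config <- function(d_m, heads = 1, sr_ratio = 1, ffn_expansion = 4,
                             depth = 1, use_norm = TRUE) {
  stopifnot(d_m %% heads == 0, sr_ratio >= 1, ffn_expansion >= 1, depth >= 1)
  structure(list(d_m = d_m, heads = heads, sr_ratio = sr_ratio,
                 ffn_expansion = ffn_expansion, depth = depth,
                 use_norm = use_norm),
            class = "attention_config")
}

# ---- patch embedding -------------------------------------------------------

patch_embed_new <- function(ci) {
  co <- 2L * ci
  new_module("patch_embed", sub = list(
    bn = mod_bn(ci),
    proj = mod_conv2d(ci, ci, k = 1, pad = 0),
    conv = mod_conv2d(ci, co, k = 3, stride = 2, pad = 1)
  ), cfg = list(ci = ci, co = co))
}

fwd_patch_embed <- function(m, x) {
  d <- dims4(x$v)
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0)
    stop("patch_embed requires even spatial dimensions, got ",
         d[2], "x", d[3])
  xp <- op_mul(fwd_bn(m$sub$bn, x), fwd_conv2d(m$sub$proj, x))
  y <- fwd_conv2d(m$sub$conv, xp)
  op_mul(op_sigmoid(y), y)
}

#' Patch embedding: halve the spatial side, double the channels
#'
#' Gated tokenization used between Transformer stages: the input is
#' batch-normalized and multiplied with a pointwise projection of itself,
#' then passed through a 3x3 stride-2 convolution whose output self-gates
#' through a sigmoid. Spatial area is divided by 4 and channels double.
#'
#' @param x numeric array `(C, H, W)` or `(C, H, W, N)` with even `H`, `W`.
#' @param module optional prebuilt module (weights are drawn from the current
#'   RNG state otherwise).
#' @return array `(2C, H/2, W/2[, N])`.
#' @export
patch_embed <- function(x, module = NULL) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- patch_embed_new(dim(x4)[1])
  out <- val(fwd_patch_embed(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- positional encoding ---------------------------------------------------

pos_enc_new <- function(C) {
  new_module("pos_enc", sub = list(dw = mod_dwconv(C)))
}

fwd_pos_enc <- function(m, x) op_mul(op_sigmoid(fwd_dwconv(m$sub$dw, x)), x)

#' Convolutional positional encoding
#'
#' A 3x3 depthwise convolution produces per-pixel weights that are squashed
#' through a sigmoid and multiply the input; shape is preserved and the gate
#' factor lies in (0, 1).
#'
#' @inheritParams patch_embed
#' @return array with the shape of `x`.
#' @export
positional_encode <- function(x, module = NULL) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- pos_enc_new(dim(x4)[1])
  out <- val(fwd_pos_enc(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- TMSA ------------------------------------------------------------------

tmsa_new <- function(cfg) {
  d <- cfg$d_m; sr <- cfg$sr_ratio; E <- cfg$ffn_expansion
  sub <- list(
    wq = mod_conv2d(d, d, k = 1, pad = 0),
    wk = mod_conv2d(d, d, k = 1, pad = 0),
    wv = mod_conv2d(d, d, k = 1, pad = 0),
    mix = mod_dense(cfg$heads, cfg$heads),
    ln_attn = mod_ln(d),
    wo = mod_conv2d(d, d, k = 1, pad = 0),
    ln_ffn = mod_ln(d),
    ffn1 = mod_conv2d(d, E * d, k = 1, pad = 0),
    ffn2 = mod_conv2d(E * d, d, k = 1, pad = 0)
  )
  if (sr > 1) {
    sub$red <- mod_conv2d(d, d, k = sr, stride = sr, pad = 0)
    sub$ln_red <- mod_ln(d)
  }
  new_module("tmsa", sub = sub, cfg = cfg)
}

# (C,H,W,N) feature map -> (tokens, d_k, heads*N) batch of per-head tokens
tokens_split_heads <- function(x, dk, heads) {
  d <- dim(x$v)
  n <- d[2] * d[3]; N <- d[4]
  t1 <- op_reshape(x, c(dk, heads, n, N))
  op_permdim(t1, c(3, 1, 2, 4), c(n, dk, heads * N))
}

fwd_tmsa <- function(m, x) {
  cfg <- m$cfg
  d <- dims4(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  heads <- cfg$heads; dk <- C %/% heads
  n <- H * W
  q <- fwd_conv2d(m$sub$wq, x)
  xr <- x
  if (cfg$sr_ratio > 1) {
    xr <- fwd_conv2d(m$sub$red, x)
    if (cfg$use_norm) xr <- fwd_ln(m$sub$ln_red, xr)
  }
  kk <- fwd_conv2d(m$sub$wk, xr)
  vv <- fwd_conv2d(m$sub$wv, xr)
  mtok <- dim(kk$v)[2] * dim(kk$v)[3]
  Qb <- tokens_split_heads(q, dk, heads)                      # (n,dk,heads*N)
  Kb <- tokens_split_heads(kk, dk, heads)                     # (m,dk,heads*N)
  Vb <- tokens_split_heads(vv, dk, heads)                     # (m,dk,heads*N)
  # keys-first logit layout so the key-axis softmax runs along dim 1
  logits <- op_scale(op_bmm(Kb, Qb, tb = TRUE), 1 / sqrt(dk)) # (m,n,heads*N)
  # 1x1 convolution across the head axis of the logit stack
  if (heads == 1) {
    lh <- fwd_dense(m$sub$mix, op_reshape(logits, c(1, mtok * n * N)))
    l4 <- op_reshape(lh, c(mtok, n, 1, N))
  } else {
    l4 <- op_reshape(logits, c(mtok, n, heads, N))
    lh <- fwd_dense(m$sub$mix, op_permdim(l4, c(3, 1, 2, 4),
                                          c(heads, mtok * n * N)))
    l4 <- op_permdim(op_reshape(lh, c(heads, mtok, n, N)), c(2, 3, 1, 4),
                     c(mtok, n, heads, N))
  }
  A <- op_softmax(l4, 1)                                      # keys axis
  Ab <- op_reshape(A, c(mtok, n, heads * N))
  ctx <- op_bmm(Ab, Vb, ta = TRUE)                            # (n,dk,heads*N)
  c4 <- op_reshape(ctx, c(n, dk, heads, N))
  cmap <- op_permdim(c4, c(2, 3, 1, 4), c(C, H, W, N))
  if (cfg$use_norm) cmap <- fwd_ln(m$sub$ln_attn, cmap)
  cmap <- fwd_conv2d(m$sub$wo, cmap)
  y <- op_add(x, cmap)                                        # residual
  z <- if (cfg$use_norm) fwd_ln(m$sub$ln_ffn, y) else y
  f <- fwd_conv2d(m$sub$ffn2, op_gelu(fwd_conv2d(m$sub$ffn1, z)))
  op_add(y, f)                                                # residual FFN
}

#' TMSA: spatially-reduced multi-head self-attention with head mixing
#'
#' Queries are taken at full resolution; keys and values come from a map
#' spatially reduced by a strided convolution (factor `cfg$sr_ratio`) with
#' layer normalization. Per-head scaled dot-product logits are mixed across
#' the head axis by a learned 1x1 convolution before the softmax over keys.
#' A residual connection and a feed-forward network complete the block;
#' the output has the shape of the input.
#'
#' @param x numeric array `(d_m, H, W)` or `(d_m, H, W, N)`.
#' @param cfg an [attention_config()].
#' @param module optional prebuilt module with matching configuration.
#' @return array with the shape of `x`.
#' @export
tmsa <- function(x, cfg, module = NULL) {
  x4 <- as_map4(x)
  stopifnot(dim(x4)[1] == cfg$d_m)
  if (is.null(module)) module <- tmsa_new(cfg)
  out <- val(fwd_tmsa(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- criss-cross position attention ----------------------------------------

pos_attn_new <- function(C) {
  new_module("pos_attn", sub = list(
    m = mod_conv2d(C, C, k = 1, pad = 0),
    n = mod_conv2d(C, C, k = 1, pad = 0),
    v = mod_conv2d(C, C, k = 1, pad = 0)
  ), cfg = list(C = C))
}

fwd_pos_attn <- function(m, Fx) {
  M <- fwd_conv2d(m$sub$m, Fx)
  Nn <- fwd_conv2d(m$sub$n, Fx)
  V <- fwd_conv2d(m$sub$v, Fx)
  op_add(op_crisscross(M, Nn, V), Fx)
}

#' Criss-cross attention weights of one position-attention pass
#'
#' Returns the softmax-normalized attention stack: for each pixel, H+W
#' slots (column neighbours first, then row neighbours; the duplicate
#' self-slot in the column direction carries weight 0), summing to 1.
#'
#' @inheritParams position_attention
#' @return array `(H+W, H, W, N)` of nonnegative weights.
#' @export
position_attention_weights <- function(x, module = NULL) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- pos_attn_new(dim(x4)[1])
  Fx <- tsr(x4)
  M <- fwd_conv2d(module$sub$m, Fx)
  Nn <- fwd_conv2d(module$sub$n, Fx)
  V <- fwd_conv2d(module$sub$v, Fx)
  d <- dim(x4)
  cpp_cc_fwd(val(M), val(Nn), val(V), d[1], d[2], d[3], d[4])$A
}

#' Criss-cross position attention (one pass)
#'
#' For every pixel, affinities of its query vector against the H+W-1
#' positions sharing its row or column are softmax-normalized and used to
#' aggregate value vectors over that criss-cross set; the result is added to
#' the input. Queries, keys and values come from 1x1 convolutions of the
#' input. Two passes propagate information between every pair of pixels.
#'
#' @param x numeric array `(C, H, W)` or `(C, H, W, N)`.
#' @param module optional prebuilt module.
#' @return array with the shape of `x`.
#' @export
position_attention <- function(x, module = NULL) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- pos_attn_new(dim(x4)[1])
  out <- val(fwd_pos_attn(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- TPA block -------------------------------------------------------------

tpa_new <- function(cfg) {
  new_module("tpa", sub = list(
    pe = pos_enc_new(cfg$d_m),
    tmsa = tmsa_new(cfg),
    pa = pos_attn_new(cfg$d_m)     # shared weights for both criss-cross passes
  ), cfg = cfg)
}

fwd_tpa <- function(m, x) {
  x <- fwd_pos_enc(m$sub$pe, x)
  x <- fwd_tmsa(m$sub$tmsa, x)
  x <- fwd_pos_attn(m$sub$pa, x)
  fwd_pos_attn(m$sub$pa, x)
}

#' TPA block: positional encoding, TMSA, double criss-cross attention
#'
#' The block that replaces standard multi-head self-attention: convolutional
#' positional encoding, TMSA with its feed-forward network, then position
#' attention applied twice with shared projection weights so each pixel
#' reaches every other pixel. Shape preserving.
#'
#' @inheritParams tmsa
#' @return array with the shape of `x`.
#' @export
tpa_block <- function(x, cfg, module = NULL) {
  x4 <- as_map4(x)
  stopifnot(dim(x4)[1] == cfg$d_m)
  if (is.null(module)) module <- tpa_new(cfg)
  out <- val(fwd_tpa(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# coerce (C,H,W) to (C,H,W,1)
as_map4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3, 4)))
    stop("expected a (C,H,W) or (C,H,W,N) array")
  if (length(d) == 3) dim(x) <- c(d, 1)
  if (any(!is.finite(x))) stop("feature map contains non-finite entries")
  x
}
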