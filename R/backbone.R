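# MTPA_Unet assembly: four Transformer stages with multi-scale image
# injection, FE/DS encoder blocks, shallow-information fusion (SCI) into a
# pyramid-pooling bottom, and a decoder with additive residual skips.

#' Model configuration
#'
#' Builds the hyperparameter ledger for MTPA_Unet. The `"paper"` profile is
#' the reference configuration (channel schedule 32/64/128/256, one TPA
#' block per stage, heads 1/2/4/8, key/value spatial reduction 8/4/2/1,
#' shared-weight double criss-cross attention, additive encoder-decoder
#' skips); its free widths are frozen so the assembled model totals the
#' 11.8 M trainable parameters published for MTPA_Unet. The `"desk"`
#' profile is a narrow variant of the same architecture for CPU-scale
#' training and testing.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param channels per-stage channel schedule (must double stage to stage).
#' @param input_sizes per-stage patch sides (must halve stage to stage).
#' @param heads attention heads per stage.
#' @param sr_ratios key/value spatial-reduction factor per stage.
#' @param ffn_expansion feed-forward hidden-width multiplier.
#' @param depth TPA blocks per stage.
#' @param pool_scales pyramid-pooling grid sides of the bottom module; each
#'   must not exceed the bottom map side (`input_sizes[4]/2`).
#' @param decoder_widths output channels of the four decoder blocks.
#' @param decoder_expand internal refinement width of each decoder block,
#'   as a multiple of its output width.
#' @param threshold probability threshold for binarization.
#' @return a list of class `mtpa_config`.
#' @export
mtpa_config <- function(profile = c("desk", "paper"),
                        channels = NULL,
                        input_sizes = c(64, 32, 16, 8),
                        heads = c(1, 2, 4, 8),
                        sr_ratios = c(8, 4, 2, 1),
                        ffn_expansion = NULL,
                        depth = 1,
                        pool_scales = c(1, 2, 4),
                        decoder_widths = NULL,
                        decoder_expand = NULL,
                        threshold = 0.5) {
  profile <- match.arg(profile)
  if (is.null(channels))
    channels <- if (profile == "paper") c(32, 64, 128, 256) else c(8, 16, 32, 64)
  if (is.null(ffn_expansion))
    ffn_expansion <- if (profile == "paper") 4 else 2
  if (is.null(decoder_widths))
    decoder_widths <- if (profile == "paper") c(278, 128, 64, 32)
                      else c(32, 16, 8, 8)
  if (is.null(decoder_expand))
    decoder_expand <- if (profile == "paper") 2 else 1
  stopifnot(length(channels) == 4, length(input_sizes) == 4,
            all(channels[-1] == 2 * channels[-4]),
            all(input_sizes[-4] == 2 * input_sizes[-1]),
            all(channels %% heads == 0),
            all(pool_scales <= input_sizes[4] / 2))
  structure(list(
    profile = profile, stages = 4L, channels = channels,
    input_sizes = input_sizes, heads = heads, sr_ratios = sr_ratios,
    ffn_expansion = ffn_expansion, depth = depth, pool_scales = pool_scales,
    decoder_widths = decoder_widths, decoder_expand = decoder_expand,
    threshold = threshold
  ), class = "mtpa_config")
}

# ---- FE block --------------------------------------------------------------

fe_new <- function(ci, co, reduce = NULL) {
  if (is.null(reduce)) reduce <- max(1L, co %/% 2L)
  new_module("fe", sub = list(
    red = mod_conv2d(ci, reduce, k = 1, pad = 0),
    conv3 = mod_conv2d(reduce, reduce, k = 3, pad = 1),
    deconv3 = mod_deconv2d(reduce, reduce),
    btl = mod_conv2d(2 * reduce, co, k = 1, pad = 0),
    bn = mod_bn(co),
    proj = mod_conv2d(ci, co, k = 1, pad = 0)
  ), cfg = list(ci = ci, co = co, reduce = reduce))
}

fwd_fe <- function(m, x) {
  r <- fwd_conv2d(m$sub$red, x)
  a <- fwd_conv2d(m$sub$conv3, r)
  b <- fwd_deconv2d(m$sub$deconv3, r)
  y <- fwd_conv2d(m$sub$btl, op_concat_c(list(a, b)))
  y <- op_relu(fwd_bn(m$sub$bn, y))
  op_add(y, fwd_conv2d(m$sub$proj, x))
}

#' Feature-extraction (FE) block
#'
#' 1x1 reduction, parallel 3x3 convolution and 3x3 transposed convolution
#' (both shape preserving), concatenation, 1x1 bottleneck to `out_channels`,
#' batch norm, ReLU, and a projected residual connection to the input.
#'
#' @param x numeric array `(C, H, W)` or `(C, H, W, N)`.
#' @param out_channels output channel count.
#' @param module optional prebuilt module.
#' @return array `(out_channels, H, W[, N])`.
#' @export
fe_block <- function(x, out_channels, module = NULL) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- fe_new(dim(x4)[1], out_channels)
  out <- val(fwd_fe(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- DS block --------------------------------------------------------------

ds_new <- function(C, literal_three_norms = FALSE) {
  sub <- list(bn1 = mod_bn(C))
  if (literal_three_norms) {
    sub$bn2 <- mod_bn(C)
    sub$bn3 <- mod_bn(C)
  }
  sub$conv <- mod_conv2d(C, C, k = 3, pad = 1)
  new_module("ds", sub = sub, cfg = list(literal = literal_three_norms))
}

fwd_ds <- function(m, x) {
  d <- dims4(x$v)
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0)
    stop("ds_block requires even spatial dimensions")
  y <- op_avgpool2(x)       # adaptive average pooling to half the side
  y <- fwd_bn(m$sub$bn1, y)
  if (isTRUE(m$cfg$literal)) {
    y <- fwd_bn(m$sub$bn2, y)
    y <- fwd_bn(m$sub$bn3, y)
  }
  fwd_conv2d(m$sub$conv, op_relu(y))
}

#' Downsampling (DS) block
#'
#' Adaptive average pooling to half the spatial side, batch normalization,
#' ReLU and a 3x3 convolution; channels are preserved. The literal stack of
#' three consecutive normalization layers collapses to one affine map, so a
#' single norm is used by default (`literal_three_norms = TRUE` restores the
#' stack).
#'
#' @inheritParams fe_block
#' @param literal_three_norms use three stacked batch norms.
#' @return array `(C, H/2, W/2[, N])`.
#' @export
ds_block <- function(x, module = NULL, literal_three_norms = FALSE) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- ds_new(dim(x4)[1], literal_three_norms)
  out <- val(fwd_ds(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- bottom: multilayer pooling -------------------------------------------

mlp_new <- function(C, scales, co = C) {
  cb <- max(1L, C %/% length(scales))
  branches <- lapply(scales, function(g) mod_conv2d(C, cb, k = 1, pad = 0))
  names(branches) <- paste0("b", scales)
  branches$fuse <- mod_conv2d(C + length(scales) * cb, co, k = 1, pad = 0)
  new_module("mlp", sub = branches, cfg = list(scales = scales, cb = cb, co = co))
}

fwd_mlp <- function(m, x, return_branches = FALSE) {
  d <- dims4(x$v)
  scales <- m$cfg$scales
  if (any(scales > min(d[2], d[3])))
    stop("pool scale exceeds the spatial side of the input")
  pooled <- list()
  outs <- list(x)
  for (i in seq_along(scales)) {
    g <- scales[i]
    p <- op_adaptive_avgpool(x, g, g)
    pooled[[i]] <- p
    b <- op_relu(fwd_conv2d(m$sub[[paste0("b", g)]], p))
    outs[[i + 1]] <- op_resize_bilinear(b, d[2], d[3])
  }
  y <- fwd_conv2d(m$sub$fuse, op_concat_c(outs))
  if (return_branches) list(out = y, pooled = pooled) else y
}

#' Multilayer (pyramid) pooling bottom module
#'
#' Parallel adaptive average poolings at the configured grid scales, each
#' followed by a 1x1 convolution and bilinear upsampling back to the input
#' size, concatenated with the input and fused by a 1x1 convolution.
#' Expands the receptive field at the deepest point of the network.
#'
#' @inheritParams fe_block
#' @param pool_scales integer grid sides; each must not exceed the map side.
#' @return array of the input spatial size.
#' @export
multilayer_pool <- function(x, pool_scales = c(1, 2, 4), module = NULL) {
  x4 <- as_map4(x)
  if (is.null(module)) module <- mlp_new(dim(x4)[1], pool_scales)
  out <- val(fwd_mlp(module, tsr(x4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- SCI fusion ------------------------------------------------------------

sci_new <- function(channels) {
  new_module("sci",
             sub = list(fuse = mod_conv2d(sum(channels), channels[length(channels)],
                                          k = 1, pad = 0)),
             cfg = list(channels = channels))
}

fwd_sci <- function(m, encs) {
  stopifnot(length(encs) == length(m$cfg$channels))
  dd <- dims4(encs[[length(encs)]]$v)
  th <- dd[2]; tw <- dd[3]
  shrunk <- lapply(encs, function(e) {
    de <- dims4(e$v)
    if (de[2] == th && de[3] == tw) e else op_adaptive_avgpool(e, th, tw)
  })
  fwd_conv2d(m$sub$fuse, op_concat_c(shrunk))
}

#' Shallow-information (SCI) fusion
#'
#' Average-pools every encoder output to the deepest spatial size,
#' concatenates them and fuses by a 1x1 convolution to the deepest channel
#' width, so shallow detail reaches the bottom of the network.
#'
#' @param encoder_outputs list of 4 arrays `(C_i, H_i, W_i[, N])` at
#'   descending resolutions.
#' @param module optional prebuilt module.
#' @return array at the deepest spatial size with `channels[4]` channels.
#' @export
sci_fuse <- function(encoder_outputs, module = NULL) {
  if (length(encoder_outputs) != 4)
    stop("sci_fuse expects exactly 4 encoder outputs")
  xs <- lapply(encoder_outputs, as_map4)
  chans <- vapply(xs, function(x) dim(x)[1], numeric(1))
  if (is.null(module)) module <- sci_new(chans)
  out <- val(fwd_sci(module, lapply(xs, tsr)))
  if (length(dim(encoder_outputs[[1]])) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- decoder ---------------------------------------------------------------

dec_new <- function(ci, skip_c, co, expand = 1) {
  new_module("dec", sub = list(
    align = mod_conv2d(ci, skip_c, k = 1, pad = 0),
    fe = fe_new(skip_c, co, reduce = max(1L, round(expand * co)))
  ), cfg = list(ci = ci, skip_c = skip_c, co = co))
}

fwd_dec <- function(m, x, skip) {
  dx <- dims4(x$v); dsk <- dims4(skip$v)
  if (dsk[2] != 2 * dx[2] || dsk[3] != 2 * dx[3])
    stop("decoder skip must be twice the spatial size of the input")
  if (dsk[1] != m$cfg$skip_c) stop("decoder skip channel mismatch")
  up <- op_resize_bilinear(x, dsk[2], dsk[3])
  merged <- op_add(fwd_conv2d(m$sub$align, up), skip)   # additive residual
  fwd_fe(m$sub$fe, merged)
}

#' Decoder block: upsample, align, additive skip merge, FE refinement
#'
#' @param x array `(C, H, W[, N])`.
#' @param skip encoder skip array at twice the spatial size of `x`.
#' @param out_channels output width of the refinement block.
#' @param module optional prebuilt module.
#' @return array at the skip's spatial size with `out_channels` channels.
#' @export
decoder_block <- function(x, skip, out_channels = NULL, module = NULL) {
  x4 <- as_map4(x); s4 <- as_map4(skip)
  if (is.null(out_channels)) out_channels <- dim(s4)[1]
  if (is.null(module)) module <- dec_new(dim(x4)[1], dim(s4)[1], out_channels)
  out <- val(fwd_dec(module, tsr(x4), tsr(s4)))
  if (length(dim(x)) == 3) out <- array(out, dim = dim(out)[1:3])
  out
}

# ---- full model ------------------------------------------------------------

#' Build an MTPA_Unet model
#'
#' Instantiates all weights of the network described by `cfg`. Weight draws
#' are seeded so models are reproducible.
#'
#' @param cfg an [mtpa_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `mtpa_model`.
#' @export
mtpa_model <- function(cfg = mtpa_config(), seed = 1L) {
  ch <- cfg$channels
  with_seed(seed, {
    sub <- list(stem = mod_conv2d(1, ch[1], k = 3, pad = 1))
    for (i in 1:4) {
      acfg <- attention_config(ch[i], cfg$heads[i], cfg$sr_ratios[i],
                               cfg$ffn_expansion, cfg$depth)
      blocks <- lapply(seq_len(cfg$depth), function(j) tpa_new(acfg))
      names(blocks) <- paste0("b", seq_len(cfg$depth))
      sub[[paste0("tpa", i)]] <- new_module("stage", sub = blocks)
      if (i > 1) {
        sub[[paste0("pe", i)]] <- patch_embed_new(ch[i - 1])
        sub[[paste0("inj", i)]] <- mod_conv2d(1, ch[i], k = 1, pad = 0)
        sub[[paste0("injfuse", i)]] <- mod_conv2d(2 * ch[i], ch[i], k = 1, pad = 0)
      }
      fe_ci <- if (i == 1) ch[1] else ch[i - 1] + ch[i]
      sub[[paste0("fe", i)]] <- fe_new(fe_ci, ch[i])
      sub[[paste0("ds", i)]] <- ds_new(ch[i])
    }
    sub$sci <- sci_new(ch)
    sub$bottom <- mlp_new(ch[4], cfg$pool_scales)
    dw <- cfg$decoder_widths
    skips <- rev(ch)                       # fe4, fe3, fe2, fe1 outputs
    cin <- ch[4]
    for (k in 1:4) {
      sub[[paste0("dec", k)]] <- dec_new(cin, skips[k], dw[k],
                                         expand = cfg$decoder_expand)
      cin <- dw[k]
    }
    sub$head <- mod_conv2d(dw[4], 1, k = 1, pad = 0)
    model <- new_module("mtpa_unet", sub = sub, cfg = cfg)
    class(model) <- c("mtpa_model", class(model))
    model
  })
}

fwd_stage <- function(stage, x) {
  for (b in stage$sub) x <- fwd_tpa(b, x)
  x
}

# pyramid: list with levels level64, level32, level16, level8 as arrays
# (1, s, s, N); returns the probability tensor (1, 64, 64, N)
fwd_mtpa <- function(model, pyr) {
  cfg <- model$cfg
  sz <- cfg$input_sizes
  levels <- lapply(1:4, function(i) {
    li <- pyr[[paste0("level", sz[i])]]
    if (is.null(li)) stop("pyramid is missing level", sz[i])
    t <- tsr(as_map4(li))
    if (dim(t$v)[2] != sz[i] || dim(t$v)[3] != sz[i])
      stop("pyramid level", sz[i], " has the wrong size")
    t
  })
  s <- model$sub
  x <- fwd_conv2d(s$stem, levels[[1]])
  tpa_out <- vector("list", 4)
  tpa_out[[1]] <- fwd_stage(s$tpa1, x)
  for (i in 2:4) {
    emb <- fwd_patch_embed(s[[paste0("pe", i)]], tpa_out[[i - 1]])
    inj <- fwd_conv2d(s[[paste0("inj", i)]], levels[[i]])
    xi <- fwd_conv2d(s[[paste0("injfuse", i)]], op_concat_c(list(emb, inj)))
    tpa_out[[i]] <- fwd_stage(s[[paste0("tpa", i)]], xi)
  }
  fe_out <- vector("list", 4)
  ds_out <- vector("list", 4)
  fe_out[[1]] <- fwd_fe(s$fe1, tpa_out[[1]])
  ds_out[[1]] <- fwd_ds(s$ds1, fe_out[[1]])
  for (i in 2:4) {
    fe_in <- op_concat_c(list(ds_out[[i - 1]], tpa_out[[i]]))
    fe_out[[i]] <- fwd_fe(s[[paste0("fe", i)]], fe_in)
    ds_out[[i]] <- fwd_ds(s[[paste0("ds", i)]], fe_out[[i]])
  }
  bottom <- fwd_mlp(s$bottom, fwd_sci(s$sci, ds_out))
  x <- bottom
  for (k in 1:4) x <- fwd_dec(s[[paste0("dec", k)]], x, fe_out[[5 - k]])
  op_sigmoid(fwd_conv2d(s$head, x))
}

#' Forward pass of MTPA_Unet on a patch pyramid
#'
#' @param pyramid a `patch_pyramid` (see [extract_patches()]) or a list with
#'   elements `level64`, `level32`, `level16`, `level8` holding single-channel
#'   arrays; a batch dimension is allowed.
#' @param model an [mtpa_model()]; built fresh from `cfg` when `NULL`.
#' @param cfg an [mtpa_config()] used when `model` is `NULL`.
#' @return vessel probability array `(64, 64)` (or `(64, 64, N)`) in \[0,1\].
#' @export
mtpa_unet_forward <- function(pyramid, model = NULL, cfg = mtpa_config()) {
  if (is.null(model)) model <- mtpa_model(cfg)
  pyr <- normalize_pyramid(pyramid)
  out <- val(fwd_mtpa(model, pyr))
  N <- dim(out)[4]
  if (N == 1) matrix(out[1, , , 1], dim(out)[2]) else out[1, , , ]
}

normalize_pyramid <- function(p) {
  lv <- c("level64", "level32", "level16", "level8")
  if (!all(lv %in% names(p))) stop("pyramid must have levels 64/32/16/8")
  out <- list()
  for (l in lv) {
    x <- p[[l]]
    d <- dim(x)
    if (is.null(d) || length(d) == 2) x <- array(x, c(1, dim(as.matrix(x)), 1))
    else if (length(d) == 3) x <- array(x, c(1, d))    # (H,W,N)
    else if (length(d) != 4) stop("bad pyramid level")
    out[[l]] <- x
  }
  out
}

#' Count trainable parameters
#'
#' Enumerates every learnable scalar of the assembled model.
#'
#' @param x an [mtpa_model()] or an [mtpa_config()] (a model is then built).
#' @return integer count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "mtpa_config")) x <- mtpa_model(x)
  stopifnot(inherits(x, "mtpa_model"))
  n_params(x)
}
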