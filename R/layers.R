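# Lightweight module system: a module is a list with `params` (named tensors),
# optional `state` (environment, e.g. batch-norm running statistics), optional
# `sub` (named child modules) and a `type` dispatched by its forward function.

new_module <- function(type, params = list(), sub = list(), state = NULL,
                       cfg = list()) {
  m <- list(type = type, params = params, sub = sub, state = state, cfg = cfg)
  class(m) <- "mt_module"
  m
}

# fan-in scaled uniform init (the convention of the reference deep-learning
# stacks); variance 1/(3*fan_in) keeps residual towers from amplifying
he_init <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

mod_conv2d <- function(ci, co, k = 3, stride = 1, pad = NULL, bias = TRUE) {
  if (is.null(pad)) pad <- (k - 1) %/% 2
  params <- list(w = tsr(he_init(c(co, ci, k, k), ci * k * k), TRUE))
  if (bias) params$b <- tsr(numeric(co), TRUE)
  new_module("conv2d", params, cfg = list(stride = stride, pad = pad))
}

fwd_conv2d <- function(m, x) {
  op_conv2d(x, m$params$w, m$params$b, stride = m$cfg$stride, pad = m$cfg$pad)
}

# transposed 3x3 convolution, stride 1, padding 1 (shape preserving):
# realized as correlation with the spatially flipped kernel
mod_deconv2d <- function(ci, co) {
  params <- list(w = tsr(he_init(c(co, ci, 3, 3), ci * 9), TRUE),
                 b = tsr(numeric(co), TRUE))
  new_module("deconv2d", params)
}

op_flipk <- function(w) {
  d <- dim(w$v)
  ih <- rev(seq_len(d[3])); iw <- rev(seq_len(d[4]))
  tn_node(w$v[, , ih, iw, drop = FALSE], list(w), function(g)
    list(g[, , ih, iw, drop = FALSE]))
}

fwd_deconv2d <- function(m, x) {
  op_conv2d(x, op_flipk(m$params$w), m$params$b, stride = 1, pad = 1)
}

mod_dwconv <- function(C) {
  new_module("dwconv", list(w = tsr(he_init(c(C, 3, 3), 9), TRUE),
                            b = tsr(numeric(C), TRUE)))
}

fwd_dwconv <- function(m, x) op_dwconv2d(x, m$params$w, m$params$b)

mod_bn <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  new_module("bn", list(gamma = tsr(rep(1, C), TRUE),
                        beta = tsr(numeric(C), TRUE)), state = st)
}

fwd_bn <- function(m, x) op_batchnorm2d(x, m$params$gamma, m$params$beta, m$state)

mod_ln <- function(C) {
  new_module("ln", list(gamma = tsr(rep(1, C), TRUE),
                        beta = tsr(numeric(C), TRUE)))
}

fwd_ln <- function(m, x) op_layernorm_c(x, m$params$gamma, m$params$beta)

# dense map used for head mixing: y = W x + b on a (k, M) matrix
mod_dense <- function(ci, co) {
  new_module("dense", list(w = tsr(he_init(c(co, ci), ci), TRUE),
                           b = tsr(numeric(co), TRUE)))
}

fwd_dense <- function(m, x) op_bias_mat(op_matmul(m$params$w, x), m$params$b)

# bias broadcast along rows of a matrix
op_bias_mat <- function(x, b) {
  k <- nrow(x$v)
  stopifnot(length(b$v) == k)
  tn_node(x$v + as.vector(b$v), list(x, b), function(g)
    list(g, rowSums(g)))
}

#' Collect learnable parameters of a module tree
#'
#' @param m an internal network module.
#' @param prefix name prefix used for diagnostics.
#' @return named list of parameter tensors.
#' @keywords internal
#' @export
collect_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params)) {
    nm <- paste0(prefix, names(m$params))
    out <- m$params
    names(out) <- nm
  }
  for (s in names(m$sub)) {
    out <- c(out, collect_params(m$sub[[s]], paste0(prefix, s, ".")))
  }
  out
}

# number of learnable scalars in a module tree
n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$v), numeric(1)))
}
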