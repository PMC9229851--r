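# Shared fixtures: tiny configurations and cached synthetic samples so the
# suite builds its data in code and reuses expensive objects.

.fixtures <- new.env(parent = emptyenv())

# narrowest architecture that still satisfies every config invariant
tiny_model_cfg <- function() {
  mtpa_config("desk", channels = c(4, 8, 16, 32))
}

fixture_sample <- function(seed = 3, size = 128) {
  key <- paste0("s", seed, "_", size)
  if (is.null(.fixtures[[key]])) {
    cfg <- synth_config(size = size, seed = seed)
    .fixtures[[key]] <- render_sample(generate_vessel_mask(cfg), cfg,
                                      sample_id = paste0("fix", seed))
  }
  .fixtures[[key]]
}

# central-difference gradient of a scalar function of an array
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# 1x1-convolve a (C,H,W) array with explicit loops (oracle helper)
conv1x1_oracle <- function(W4, b, X) {
  Co <- dim(W4)[1]
  Wm <- matrix(W4, Co)
  Y <- array(0, c(Co, dim(X)[2], dim(X)[3]))
  for (i in seq_len(dim(X)[2])) for (j in seq_len(dim(X)[3]))
    Y[, i, j] <- Wm %*% X[, i, j] + b
  Y
}
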