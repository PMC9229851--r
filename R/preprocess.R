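# Fundus enhancement chain (weighted channel fusion -> per-image
# standardization -> CLAHE -> gamma correction) and the patch machinery
# producing the multi-scale network inputs.

#' Preprocessing configuration
#'
#' @param fusion_weights weights for the R, G and B channels; must sum to 1.
#'   The default weights green most heavily (0.587), where fundus vessel
#'   contrast lives; `literal_grb = TRUE` instead assigns 0.587 to red,
#'   matching a literal reading of the published G/R/B ratio order.
#' @param clahe_clip CLAHE clip limit (> 0).
#' @param clahe_tiles CLAHE tile grid side.
#' @param gamma exponent of the gamma correction (> 0).
#' @param literal_grb use the literal published channel-order mapping.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(fusion_weights = NULL, clahe_clip = 2,
                              clahe_tiles = 8, gamma = 1.2,
                              literal_grb = FALSE) {
  if (is.null(fusion_weights))
    fusion_weights <- if (literal_grb) c(0.587, 0.299, 0.114)
                      else c(0.299, 0.587, 0.114)
  if (abs(sum(fusion_weights) - 1) > 1e-9)
    stop("fusion weights must sum to 1")
  if (clahe_clip <= 0) stop("clahe_clip must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(fusion_weights = fusion_weights, clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles), gamma = gamma),
            class = "preprocess_config")
}

#' Weighted RGB channel fusion
#'
#' Per-pixel weighted sum of the three channels; the output range is that
#' of the input (weights sum to 1, so a constant gray image is unchanged).
#'
#' @param image H x W x 3 numeric array.
#' @param weights three reals summing to 1 (R, G, B order).
#' @return H x W matrix.
#' @export
fuse_channels <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (abs(sum(weights) - 1) > 1e-9) stop("fusion weights must sum to 1")
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  image[, , 1] * weights[1] + image[, , 2] * weights[2] +
    image[, , 3] * weights[3]
}

#' Per-image standardization and min-max rescale
#'
#' Subtracts the mean, divides by the standard deviation, then rescales to
#' \[0, 1\]. Invariant under positive affine transforms of the input. A
#' constant image yields all zeros with a warning.
#'
#' @param gray numeric matrix.
#' @return matrix with values in \[0, 1\].
#' @export
normalize <- function(gray) {
  s <- stats::sd(gray)
  if (s == 0 || !is.finite(s)) {
    warning("constant image: normalize() returns all zeros")
    return(matrix(0, nrow(gray), ncol(gray)))
  }
  z <- (gray - mean(gray)) / s
  (z - min(z)) / (max(z) - min(z))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper around the CLAHE implementation in EBImage, operating on
#' \[0, 1\] intensities with the given clip limit and tile grid.
#'
#' @param gray numeric matrix with values in \[0, 1\].
#' @param clip clip limit (> 0).
#' @param tiles tile grid side.
#' @return matrix with values in \[0, 1\].
#' @export
clahe <- function(gray, clip = 2, tiles = 8) {
  if (clip <= 0) stop("clip limit must be positive")
  if (min(gray) < 0 || max(gray) > 1) stop("clahe expects intensities in [0, 1]")
  if (diff(range(gray)) == 0) return(gray)   # no contrast to redistribute
  # EBImage images are (x, y); transpose in and out
  out <- t(EBImage::imageData(EBImage::clahe(EBImage::Image(t(gray)),
                                             nx = tiles, ny = tiles,
                                             limit = clip, keep.range = TRUE)))
  pmin(pmax(out, 0), 1)
}

#' Gamma correction
#'
#' Elementwise power transform `out = in^gamma` on \[0, 1\] intensities.
#'
#' @param gray numeric matrix in \[0, 1\].
#' @param gamma exponent (> 0).
#' @return matrix in \[0, 1\].
#' @export
gamma_correct <- function(gray, gamma = 1.2) {
  if (gamma <= 0) stop("gamma must be positive")
  if (min(gray) < 0 || max(gray) > 1)
    stop("gamma correction expects intensities in [0, 1]")
  gray^gamma
}

#' Full preprocessing chain for one fundus sample
#'
#' Channel fusion, standardization with min-max rescale, CLAHE and gamma
#' correction, in that order.
#'
#' @param sample a `fundus_sample`.
#' @param cfg a [preprocess_config()].
#' @return H x W matrix in \[0, 1\].
#' @export
preprocess <- function(sample, cfg = preprocess_config()) {
  stopifnot(inherits(sample, "fundus_sample"))
  g <- fuse_channels(sample$image, cfg$fusion_weights)
  g <- normalize(g)
  g <- clahe(g, cfg$clahe_clip, cfg$clahe_tiles)
  gamma_correct(g, cfg$gamma)
}

# ---- patches ---------------------------------------------------------------

# 2x2 mean pooling of a matrix with even sides
pool2 <- function(m) {
  hi <- seq(1, nrow(m), by = 2); wi <- seq(1, ncol(m), by = 2)
  (m[hi, wi] + m[hi + 1, wi] + m[hi, wi + 1] + m[hi + 1, wi + 1]) / 4
}

#' Build the multi-scale pyramid of one 64x64 patch
#'
#' Successive 2x2 average poolings produce the 32/16/8 companions used by
#' the four Transformer stages.
#'
#' @param patch64 64x64 numeric matrix.
#' @param origin integer `(row, col)` of the patch in its source image
#'   (0-based, top-left, half-open extents).
#' @return a list of class `patch_pyramid` with elements `level64`,
#'   `level32`, `level16`, `level8` and `origin`.
#' @export
patch_pyramid <- function(patch64, origin = c(0L, 0L)) {
  stopifnot(identical(dim(patch64), c(64L, 64L)))
  l32 <- pool2(patch64)
  l16 <- pool2(l32)
  l8 <- pool2(l16)
  structure(list(level64 = patch64, level32 = l32, level16 = l16,
                 level8 = l8, origin = as.integer(origin)),
            class = "patch_pyramid")
}

#' Extract training/inference patches with their pyramids
#'
#' Random mode samples `n` origins uniformly among positions whose patch
#' centre lies inside the field of view; grid mode tiles the image with the
#' given stride, always covering every pixel (a final row/column of patches
#' is clamped to the image border).
#'
#' @param gray preprocessed image matrix (at least 64x64).
#' @param vessel_mask binary label matrix of the same size (or `NULL`).
#' @param fov_mask binary field-of-view matrix of the same size (or `NULL`,
#'   meaning everything is inside).
#' @param n number of patches (random mode).
#' @param mode `"random"` or `"grid"`.
#' @param seed integer seed for random mode.
#' @param stride grid stride in pixels.
#' @return list with `pyramids` (list of `patch_pyramid`), `labels` (list of
#'   64x64 binary matrices or `NULL`s) and `origins` (n x 2 integer matrix,
#'   0-based).
#' @export
extract_patches <- function(gray, vessel_mask = NULL, fov_mask = NULL,
                            n = 200, mode = c("random", "grid"), seed = 1L,
                            stride = 32L) {
  mode <- match.arg(mode)
  H <- nrow(gray); W <- ncol(gray)
  if (H < 64 || W < 64) stop("image must be at least 64x64 for patching")
  if (is.null(fov_mask)) fov_mask <- matrix(1L, H, W)
  origins <- if (mode == "grid") {
    rs <- unique(c(seq(0L, H - 64L, by = stride), H - 64L))
    cs <- unique(c(seq(0L, W - 64L, by = stride), W - 64L))
    as.matrix(expand.grid(row = rs, col = cs))
  } else {
    with_seed(seed, {
      ok <- which(fov_mask[33:(H - 31), 33:(W - 31), drop = FALSE] == 1,
                  arr.ind = TRUE)
      if (!nrow(ok)) stop("no valid patch centres inside the field of view")
      pick <- ok[sample.int(nrow(ok), n, replace = TRUE), , drop = FALSE]
      cbind(row = pick[, 1] - 1L, col = pick[, 2] - 1L)  # centre-32 = origin
    })
  }
  pyr <- vector("list", nrow(origins))
  lab <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    r <- origins[i, 1]; cc <- origins[i, 2]
    p <- gray[r + 1:64, cc + 1:64]
    pyr[[i]] <- patch_pyramid(p, c(r, cc))
    if (!is.null(vessel_mask)) lab[[i]] <- vessel_mask[r + 1:64, cc + 1:64]
  }
  list(pyramids = pyr, labels = if (is.null(vessel_mask)) NULL else lab,
       origins = origins)
}

#' Stitch overlapping patch predictions back into an image
#'
#' Per-pixel average of all patch predictions covering the pixel.
#'
#' @param patch_probs list of 64x64 probability matrices.
#' @param origins n x 2 matrix of 0-based patch origins.
#' @param size `(H, W)` of the output image.
#' @return H x W matrix in \[0, 1\].
#' @export
stitch <- function(patch_probs, origins, size) {
  H <- size[1]; W <- size[2]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_along(patch_probs)) {
    r <- origins[i, 1]; cc <- origins[i, 2]
    acc[r + 1:64, cc + 1:64] <- acc[r + 1:64, cc + 1:64] + patch_probs[[i]]
    cnt[r + 1:64, cc + 1:64] <- cnt[r + 1:64, cc + 1:64] + 1
  }
  if (any(cnt == 0)) stop("patches do not cover the whole image")
  acc / cnt
}
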