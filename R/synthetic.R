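# Seeded synthetic fundus generator: branching curvilinear vessel trees on a
# noisy, low-contrast background with a smooth radial illumination gradient
# and a circular field of view, so the whole pipeline is testable without
# external datasets.

#' Synthetic fundus configuration
#'
#' @param size image side in pixels (square images).
#' @param n_trees number of vessel tree roots placed on the disc margin.
#' @param width_range minimum and maximum vessel width in pixels.
#' @param target_density desired vessel fraction of the field of view,
#'   in (0, 1); fundus vasculature typically occupies 8-13%.
#' @param noise_sd standard deviation of the additive background noise on
#'   the 0-255 intensity scale.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(size = 128, n_trees = 6, width_range = c(1, 5),
                         target_density = 0.10, noise_sd = 8, seed = 1L) {
  stopifnot(size >= 32, width_range[1] >= 1, width_range[2] >= width_range[1],
            target_density > 0, target_density < 1, noise_sd >= 0)
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 width_range = width_range, target_density = target_density,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# circular field of view, radius 0.48 * size, centered
fov_disc <- function(size) {
  r <- 0.48 * size
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
  (d2 <= r^2) * 1L
}

#' Generate a binary vessel mask
#'
#' Draws `n_trees` random-walk vessel trees with stochastic branching and
#' tapering widths on a 2x supersampled canvas (anti-aliased discs,
#' thresholded back at full resolution), clipped to a centered circular
#' field of view of radius 0.48 x size. The per-tree step budget is scaled
#' so the foreground fraction lands near `target_density`.
#'
#' @param cfg a [synth_config()].
#' @return binary matrix `(size, size)`; 1 = vessel.
#' @export
generate_vessel_mask <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  size <- cfg$size
  if (cfg$n_trees > 0 && size < 48)
    stop("image side ", size, " is too small to place a vessel tree; use >= 48")
  fov <- fov_disc(size)
  if (cfg$n_trees == 0) return(matrix(0L, size, size))
  with_seed(cfg$seed, {
    ss <- 2L                                 # supersampling factor
    canvas <- matrix(0, ss * size, ss * size)
    r_fov <- 0.48 * size
    ctr <- (size + 1) / 2
    mean_w <- mean(cfg$width_range)
    # total path length needed for the target density, split across trees;
    # the 0.63 factor discounts the extra coverage contributed by branches
    total_len <- 0.63 * cfg$target_density * pi * r_fov^2 / mean_w
    budget_per_tree <- total_len / cfg$n_trees
    branch_p <- 0.03                         # branching probability per step
    stamp <- function(y, x, w) {
      # draw a disc of diameter w (vessel width) at (y, x), supersampled
      rad <- max(ss * w / 2, 1)
      cy <- ss * y; cx <- ss * x
      lo_y <- max(1, floor(cy - rad)); hi_y <- min(ss * size, ceiling(cy + rad))
      lo_x <- max(1, floor(cx - rad)); hi_x <- min(ss * size, ceiling(cx + rad))
      if (lo_y > hi_y || lo_x > hi_x) return()
      ys <- lo_y:hi_y; xs <- lo_x:hi_x
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      canvas[ys, xs] <<- pmax(canvas[ys, xs], (d2 <= rad^2) * 1)
    }
    walk <- function(y, x, ang, w, steps, depth) {
      while (steps > 0) {
        stamp(y, x, w)
        ang <- ang + stats::rnorm(1, 0, 0.18)
        y <- y + sin(ang); x <- x + cos(ang)
        if ((y - ctr)^2 + (x - ctr)^2 > r_fov^2) break
        w <- max(cfg$width_range[1], w * 0.998)       # taper towards the tip
        steps <- steps - 1
        if (depth < 3 && stats::runif(1) < branch_p) {
          bw <- max(cfg$width_range[1], w * stats::runif(1, 0.5, 0.8))
          walk(y, x, ang + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9),
               bw, round(steps * stats::runif(1, 0.4, 0.8)), depth + 1)
        }
      }
    }
    for (tree in seq_len(cfg$n_trees)) {
      # roots on the disc margin, heading inward
      phi <- stats::runif(1, 0, 2 * pi)
      y0 <- ctr + 0.9 * r_fov * sin(phi)
      x0 <- ctr + 0.9 * r_fov * cos(phi)
      w0 <- stats::runif(1, 0.6 * cfg$width_range[2], cfg$width_range[2])
      walk(y0, x0, phi + pi + stats::rnorm(1, 0, 0.3), w0,
           round(budget_per_tree), 1)
    }
    # downsample the supersampled canvas by 2x2 mean, threshold at 0.5
    hi <- seq(1, ss * size, by = ss)
    m <- (canvas[hi, hi] + canvas[hi + 1, hi] +
          canvas[hi, hi + 1] + canvas[hi + 1, hi + 1]) / 4
    mask <- (m >= 0.5) * 1L
    mask * fov
  })
}

#' Render a fundus-like RGB image from a vessel mask
#'
#' Produces an 8-bit RGB image in which vessels are darker than the
#' background in the green channel, the background carries a smooth radial
#' illumination gradient plus zero-mean Gaussian noise of sd `noise_sd`,
#' and everything outside the circular field of view is near-black.
#'
#' @param mask binary matrix, 1 = vessel.
#' @param cfg a [synth_config()] (its `seed` drives the noise draw).
#' @param sample_id identifier stored in the returned sample.
#' @return a `fundus_sample`: list with `image` (H x W x 3 integer array,
#'   0-255), `fov_mask`, `vessel_mask` and `sample_id`.
#' @export
render_sample <- function(mask, cfg, sample_id = "synthetic") {
  stopifnot(all(mask %in% c(0, 1)))
  size <- nrow(mask)
  fov <- fov_disc(size)
  mask <- mask * fov                         # vessels only inside the FOV
  with_seed(cfg$seed + 101L, {
    ctr <- (size + 1) / 2
    r_fov <- 0.48 * size
    d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
    # brighter center, mild vignetting toward the rim
    illum <- 150 + 40 * (1 - d2 / r_fov^2)
    green <- illum - 55 * mask + matrix(stats::rnorm(size^2, 0, cfg$noise_sd),
                                        size, size)
    red <- pmin(255, green * 1.35 + 10)
    blue <- green * 0.45
    img <- array(0, dim = c(size, size, 3))
    img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
    for (k in 1:3) img[, , k] <- img[, , k] * fov + 4 * (1 - fov)
    img <- array(as.integer(pmin(255, pmax(0, round(img)))),
                 dim = dim(img))
    new_fundus_sample(img, fov, mask, sample_id)
  })
}

#' Construct and validate a fundus sample
#'
#' @param image H x W x 3 integer array with intensities 0-255.
#' @param fov_mask binary matrix, 1 = inside the field of view.
#' @param vessel_mask binary matrix, 1 = vessel pixel; must be a subset of
#'   the field of view.
#' @param sample_id character identifier.
#' @return a list of class `fundus_sample`.
#' @export
new_fundus_sample <- function(image, fov_mask, vessel_mask, sample_id) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            identical(dim(image)[1:2], dim(fov_mask)),
            identical(dim(fov_mask), dim(vessel_mask)))
  if (!all(fov_mask %in% c(0, 1)) || !all(vessel_mask %in% c(0, 1)))
    stop("masks must be binary")
  if (any(vessel_mask == 1 & fov_mask == 0))
    stop("vessel mask extends outside the field of view")
  if (min(image) < 0 || max(image) > 255)
    stop("image intensities must lie in [0, 255]")
  structure(list(image = image, fov_mask = fov_mask,
                 vessel_mask = vessel_mask, sample_id = as.character(sample_id)),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  d <- dim(x$image)
  dens <- sum(x$vessel_mask) / max(1, sum(x$fov_mask))
  cat(sprintf("<fundus_sample %s: %dx%d, vessel density %.1f%% of FOV>\n",
              x$sample_id, d[1], d[2], 100 * dens))
  invisible(x)
}

#' Generate a dataset of synthetic fundus samples
#'
#' Seeds are offset per sample so the dataset is reproducible as a whole
#' while samples stay independent.
#'
#' @param n number of samples (>= 1).
#' @param cfg a [synth_config()].
#' @return list of `fundus_sample` objects.
#' @export
make_dataset <- function(n, cfg = synth_config()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$seed <- cfg$seed + 1000L * (i - 1L)
    mask <- generate_vessel_mask(ci)
    render_sample(mask, ci, sample_id = sprintf("synth_%02d", i))
  })
}

#' Write samples in a DRIVE-style directory layout
#'
#' Creates `images/`, `mask/` and `1st_manual/` subdirectories holding the
#' RGB image, the field-of-view mask and the vessel ground truth as PNG, so
#' the same loaders serve real and synthetic data.
#'
#' @param samples list of `fundus_sample` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  for (sub in c("images", "mask", "1st_manual"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(s$image / 255, file.path(dir, "images",
                                           paste0(s$sample_id, ".png")))
    png::writePNG(s$fov_mask + 0.0, file.path(dir, "mask",
                                              paste0(s$sample_id, "_mask.png")))
    png::writePNG(s$vessel_mask + 0.0,
                  file.path(dir, "1st_manual",
                            paste0(s$sample_id, "_manual1.png")))
  }
  invisible(dir)
}

#' Read a DRIVE-style directory layout
#'
#' @param dir dataset root containing `images/`, `mask/`, `1st_manual/`.
#' @return list of `fundus_sample` objects, ordered by file name.
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (!length(imgs)) stop("no images found under ", dir)
  lapply(imgs, function(f) {
    id <- sub("\\.[^.]+$", "", basename(f))
    img <- read_raster(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- array(as.integer(round(img[, , 1:3] * 255)), dim = c(dim(img)[1:2], 3))
    fovf <- list.files(file.path(dir, "mask"), paste0("^", id, "_mask\\."),
                       full.names = TRUE)
    gtf <- list.files(file.path(dir, "1st_manual"), paste0("^", id, "_manual1\\."),
                      full.names = TRUE)
    fov <- if (length(fovf)) round(as_gray(read_raster(fovf[1])))
           else matrix(1L, dim(img)[1], dim(img)[2])
    gt <- if (length(gtf)) round(as_gray(read_raster(gtf[1])))
          else matrix(0L, dim(img)[1], dim(img)[2])
    storage.mode(fov) <- "integer"
    storage.mode(gt) <- "integer"
    new_fundus_sample(img, fov, gt * fov, id)
  })
}

# read PNG/TIFF/JPEG into a [0,1] array
read_raster <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         png = png::readPNG(path),
         tif = , tiff = tiff::readTIFF(path),
         jpg = , jpeg = {
           a <- EBImage::imageData(EBImage::readImage(path))
           if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
         },
         stop("unsupported raster format: ", ext))
}

as_gray <- function(x) if (length(dim(x)) == 3) x[, , 1] else x
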