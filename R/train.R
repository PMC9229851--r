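# Training and evaluation orchestration: Adam on the Dice loss over seeded
# random patches, best-validation checkpointing, grid-stitched whole-image
# evaluation, and the leave-one-out protocol.

#' Training control parameters
#'
#' The `"desk"` profile holds CPU-scale defaults (few patches, few epochs,
#' narrow model); the `"paper"` profile keeps the published protocol:
#' initial learning rate 0.001, 100 epochs, batch 32 (64 and threshold 0.48
#' for single-image leave-one-out folds).
#'
#' @param lr initial learning rate (> 0); Adam is used throughout.
#' @param epochs passes over the training patches.
#' @param batch_size patches per optimizer step.
#' @param threshold binarization threshold in (0, 1).
#' @param seed integer seed controlling patching, splits and shuffling.
#' @param patches_per_image random training patches drawn per image.
#' @param val_fraction fraction of patches held out to select the best
#'   checkpoint.
#' @param protocol `"holdout"` or `"leave_one_out"`.
#' @param loo_conventional leave-one-out orientation: `FALSE` (default)
#'   trains each fold on a single image and tests on all others;
#'   `TRUE` uses the conventional train-on-rest / test-on-one orientation.
#' @param stride grid stride for whole-image inference.
#' @param max_steps optional cap on total optimizer steps.
#' @param profile `"desk"` or `"paper"`.
#' @return a list of class `train_control`.
#' @export
train_control <- function(lr = 0.001, epochs = NULL, batch_size = NULL,
                          threshold = 0.5, seed = 1L,
                          patches_per_image = NULL, val_fraction = 0.1,
                          protocol = c("holdout", "leave_one_out"),
                          loo_conventional = FALSE, stride = 32L,
                          max_steps = Inf, profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  protocol <- match.arg(protocol)
  if (is.null(epochs)) epochs <- if (profile == "paper") 100L else 20L
  if (is.null(batch_size)) batch_size <- if (profile == "paper") 32L else 8L
  if (is.null(patches_per_image))
    patches_per_image <- if (profile == "paper") 200L else 20L
  stopifnot(lr > 0, threshold > 0, threshold < 1, batch_size >= 1,
            epochs >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), threshold = threshold,
                 seed = as.integer(seed),
                 patches_per_image = as.integer(patches_per_image),
                 val_fraction = val_fraction, protocol = protocol,
                 loo_conventional = loo_conventional,
                 stride = as.integer(stride), max_steps = max_steps,
                 profile = profile),
            class = "train_control")
}

# ---- parameter state / checkpointing ---------------------------------------

params_state <- function(model) {
  ps <- collect_params(model)
  st <- lapply(ps, function(p) p$v)
  # batch-norm running statistics
  bn <- list()
  walk <- function(m, prefix) {
    if (!is.null(m$state))
      bn[[prefix]] <<- list(mean = m$state$running_mean,
                            var = m$state$running_var)
    for (s in names(m$sub)) walk(m$sub[[s]], paste0(prefix, s, "."))
  }
  walk(model, "")
  list(params = st, bn = bn)
}

set_params_state <- function(model, state) {
  ps <- collect_params(model)
  stopifnot(identical(names(ps), names(state$params)))
  for (nm in names(ps)) ps[[nm]]$v <- state$params[[nm]]
  walk <- function(m, prefix) {
    if (!is.null(m$state) && !is.null(state$bn[[prefix]])) {
      m$state$running_mean <- state$bn[[prefix]]$mean
      m$state$running_var <- state$bn[[prefix]]$var
    }
    for (s in names(m$sub)) walk(m$sub[[s]], paste0(prefix, s, "."))
  }
  walk(model, "")
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing archive embedding the model
#' configuration and every weight and running statistic.
#'
#' @param fit an `mtpa_fit` or `mtpa_model`-bearing list with `$model`.
#' @param path file path.
#' @return `path` invisibly; `load_checkpoint` returns an `mtpa_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mtpa_fit"))
  saveRDS(list(cfg = fit$model$cfg, state = params_state(fit$model),
               control = fit$control, pre_cfg = fit$pre_cfg,
               loss_trace = fit$loss_trace,
               val_trace = fit$val_trace, best_epoch = fit$best_epoch),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- mtpa_model(ck$cfg, seed = 0L)
  set_params_state(model, ck$state)
  structure(list(model = model, control = ck$control,
                 pre_cfg = ck$pre_cfg %||% preprocess_config(),
                 loss_trace = ck$loss_trace, val_trace = ck$val_trace,
                 best_epoch = ck$best_epoch),
            class = "mtpa_fit")
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps; e$t <- 0
  e$m <- lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v)))
  e$v <- lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v)))
  e
}

adam_step <- function(opt, params) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * p$grad
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * p$grad^2
    p$v <- p$v - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  invisible(NULL)
}

# ---- batching --------------------------------------------------------------

# stack a list of patch pyramids (+labels) into batched (1,s,s,B) arrays
stack_batch <- function(pyramids, labels = NULL, idx = seq_along(pyramids)) {
  B <- length(idx)
  lv <- c(64, 32, 16, 8)
  out <- list()
  for (l in lv) {
    a <- array(0, dim = c(1, l, l, B))
    for (b in seq_len(B)) a[1, , , b] <- pyramids[[idx[b]]][[paste0("level", l)]]
    out[[paste0("level", l)]] <- a
  }
  if (!is.null(labels)) {
    y <- array(0, dim = c(1, 64, 64, B))
    for (b in seq_len(B)) y[1, , , b] <- labels[[idx[b]]]
    out$labels <- y
  }
  out
}

# dice of thresholded predictions against labels for a set of patches
patch_dice <- function(model, pyramids, labels, idx, threshold, batch = 8) {
  mode <- training_mode(FALSE)
  on.exit(training_mode(mode))
  num <- 0; den <- 0
  for (start in seq(1, length(idx), by = batch)) {
    sub <- idx[start:min(start + batch - 1, length(idx))]
    bt <- stack_batch(pyramids, labels, sub)
    pr <- val(fwd_mtpa(model, bt))
    pd <- (pr >= threshold) * 1
    num <- num + 2 * sum(pd * bt$labels)
    den <- den + sum(pd) + sum(bt$labels)
  }
  if (den == 0) 1 else num / den
}

# ---- training --------------------------------------------------------------

#' Train MTPA_Unet on fundus samples
#'
#' Preprocesses each sample, draws seeded random patch pyramids, and runs
#' Adam on the soft Dice loss. A seeded fraction of patches is held out and
#' the parameters with the best validation Dice are retained.
#'
#' @param model_cfg an [mtpa_config()].
#' @param train_cfg a [train_control()].
#' @param data list of `fundus_sample` objects (>= 1).
#' @param pre_cfg a [preprocess_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `mtpa_fit`.
#' @export
train <- function(model_cfg, train_cfg, data,
                  pre_cfg = preprocess_config(), verbose = FALSE) {
  if (!length(data)) stop("training requires at least one sample")
  stopifnot(inherits(model_cfg, "mtpa_config"), inherits(train_cfg, "train_control"))
  # patch extraction
  pyramids <- list(); labels <- list()
  for (i in seq_along(data)) {
    s <- data[[i]]
    g <- preprocess(s, pre_cfg)
    ex <- extract_patches(g, s$vessel_mask, s$fov_mask,
                          n = train_cfg$patches_per_image, mode = "random",
                          seed = train_cfg$seed + i)
    pyramids <- c(pyramids, ex$pyramids)
    labels <- c(labels, ex$labels)
  }
  n <- length(pyramids)
  idx_all <- with_seed(train_cfg$seed, sample.int(n))
  n_val <- floor(train_cfg$val_fraction * n)
  val_idx <- if (n_val > 0) idx_all[seq_len(n_val)] else integer(0)
  tr_idx <- if (n_val > 0) idx_all[-seq_len(n_val)] else idx_all
  model <- mtpa_model(model_cfg, seed = train_cfg$seed)
  ps <- collect_params(model)
  opt <- adam_new(ps, train_cfg$lr)
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best <- list(dice = -Inf, state = NULL, epoch = 0L)
  steps <- 0
  for (epoch in seq_len(train_cfg$epochs)) {
    order_ep <- with_seed(train_cfg$seed + 7919L * epoch,
                          sample(tr_idx, length(tr_idx)))
    ep_losses <- c()
    training_mode(TRUE)
    for (start in seq(1, length(order_ep), by = train_cfg$batch_size)) {
      if (steps >= train_cfg$max_steps) break
      sub <- order_ep[start:min(start + train_cfg$batch_size - 1,
                                length(order_ep))]
      bt <- stack_batch(pyramids, labels, sub)
      zero_grads(ps)
      out <- fwd_mtpa(model, bt)
      loss <- op_dice_loss(out, bt$labels)
      if (!is.finite(val(loss)))
        stop("non-finite Dice loss at step ", steps + 1,
             "; check inputs and learning rate")
      backward(loss)
      adam_step(opt, ps)
      ep_losses <- c(ep_losses, val(loss))
      steps <- steps + 1
    }
    training_mode(FALSE)
    loss_trace <- c(loss_trace, mean(ep_losses))
    vd <- if (length(val_idx))
      patch_dice(model, pyramids, labels, val_idx, train_cfg$threshold)
    else patch_dice(model, pyramids, labels, tr_idx, train_cfg$threshold)
    val_trace <- c(val_trace, vd)
    if (vd >= best$dice) {
      best$dice <- vd
      best$state <- params_state(model)
      best$epoch <- epoch
    }
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  val Dice %.4f",
                      epoch, train_cfg$epochs, mean(ep_losses), vd))
    if (steps >= train_cfg$max_steps) break
  }
  if (!is.null(best$state)) set_params_state(model, best$state)
  structure(list(model = model, control = train_cfg, pre_cfg = pre_cfg,
                 loss_trace = loss_trace, val_trace = val_trace,
                 best_epoch = best$epoch, steps = steps,
                 n_train = length(tr_idx), n_val = length(val_idx)),
            class = "mtpa_fit")
}

# ---- inference / evaluation ------------------------------------------------

#' Segment one fundus sample with a trained model
#'
#' Preprocesses the image, runs the network over a stride-`stride` grid of
#' patch pyramids and averages overlapping predictions.
#'
#' @param fit an `mtpa_fit`.
#' @param sample a `fundus_sample`.
#' @param threshold binarization threshold; defaults to the training one.
#' @param batch forward batch size.
#' @return a `segmentation_result`: list with `prob_map`, `bin_mask` (of
#'   `prob_map >= threshold`) and `threshold`.
#' @export
segment_sample <- function(fit, sample, threshold = NULL, batch = 8) {
  if (is.null(threshold)) threshold <- fit$control$threshold
  g <- preprocess(sample, fit$pre_cfg)
  ex <- extract_patches(g, NULL, NULL, mode = "grid",
                        stride = fit$control$stride)
  mode <- training_mode(FALSE)
  on.exit(training_mode(mode))
  probs <- vector("list", length(ex$pyramids))
  for (start in seq(1, length(ex$pyramids), by = batch)) {
    sub <- start:min(start + batch - 1, length(ex$pyramids))
    bt <- stack_batch(ex$pyramids, NULL, sub)
    pr <- val(fwd_mtpa(fit$model, bt))
    for (k in seq_along(sub)) probs[[sub[k]]] <- matrix(pr[1, , , k], 64, 64)
  }
  pm <- stitch(probs, ex$origins, dim(g))
  pm <- pmin(pmax(pm, 0), 1)
  structure(list(prob_map = pm, bin_mask = (pm >= threshold) * 1L,
                 threshold = threshold),
            class = "segmentation_result")
}

#' Evaluate a trained model on fundus samples
#'
#' Segments each sample and scores it against its vessel ground truth
#' inside the field of view; the aggregate is the arithmetic mean of the
#' per-image metrics.
#'
#' @param fit an `mtpa_fit`.
#' @param samples list of `fundus_sample` objects.
#' @param threshold binarization threshold; defaults to the training one.
#' @param fov_restrict evaluate inside the FOV mask only (default) or over
#'   the whole image.
#' @return list with `per_image` (list of `metric_report`) and `aggregate`
#'   (named list of mean metrics).
#' @export
evaluate <- function(fit, samples, threshold = NULL, fov_restrict = TRUE) {
  stopifnot(inherits(fit, "mtpa_fit"))
  reports <- lapply(samples, function(s) {
    sr <- segment_sample(fit, s, threshold)
    report(sr$prob_map, s$vessel_mask,
           fov = if (fov_restrict) s$fov_mask else NULL,
           threshold = sr$threshold)
  })
  list(per_image = reports, aggregate = aggregate_reports(reports))
}

#' Leave-one-out protocol over a sample set
#'
#' In the default orientation each fold trains on a single image and tests
#' on the remaining `n - 1` (the protocol used for the 20-image STARE set);
#' `loo_conventional = TRUE` in the control flips the orientation.
#'
#' @param model_cfg an [mtpa_config()].
#' @param train_cfg a [train_control()].
#' @param samples list of at least 2 `fundus_sample` objects.
#' @param pre_cfg a [preprocess_config()].
#' @param verbose print fold progress.
#' @return list with `folds` (per-fold aggregates) and `average` (mean over
#'   folds).
#' @export
leave_one_out <- function(model_cfg, train_cfg, samples,
                          pre_cfg = preprocess_config(), verbose = FALSE) {
  n <- length(samples)
  if (n < 2) stop("leave-one-out requires at least 2 samples")
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tc <- train_cfg
    tc$seed <- train_cfg$seed + i
    if (train_cfg$loo_conventional) {
      tr <- samples[-i]; te <- samples[i]
    } else {
      tr <- samples[i]; te <- samples[-i]
    }
    fit <- train(model_cfg, tc, tr, pre_cfg)
    ev <- evaluate(fit, te)
    folds[[i]] <- ev$aggregate
    if (verbose)
      message(sprintf("fold %d/%d  Dice %.4f", i, n, ev$aggregate$dice))
  }
  keys <- names(folds[[1]])
  avg <- lapply(keys, function(k)
    mean(vapply(folds, function(f) as.numeric(f[[k]]), numeric(1)), na.rm = TRUE))
  names(avg) <- keys
  list(folds = folds, average = avg)
}
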