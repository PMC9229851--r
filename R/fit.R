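# User-facing model interface in the classic R idiom: one fitting function
# returning a classed object with print / summary / predict / plot / coef
# methods.

#' Fit MTPA_Unet to fundus samples
#'
#' The main entry point: trains the multi-scale Transformer-position
#' attention U-Net on a list of fundus samples and returns a fitted model
#' object. `predict()` segments new samples; `plot()` shows the training
#' trace; `coef()` returns the learned weights.
#'
#' @param data list of `fundus_sample` objects (see [make_dataset()],
#'   [read_dataset()]).
#' @param model an [mtpa_config()] describing the architecture.
#' @param control a [train_control()] describing the optimization protocol.
#' @param preprocess a [preprocess_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `mtpa_fit`.
#' @examples
#' \donttest{
#' samples <- make_dataset(2, synth_config(size = 128, seed = 1))
#' ctl <- train_control(epochs = 2, patches_per_image = 8, seed = 1)
#' fit <- mtpa_fit(samples, model = mtpa_config("desk"), control = ctl)
#' pred <- predict(fit, samples[[1]])
#' }
#' @export
mtpa_fit <- function(data, model = mtpa_config("desk"),
                     control = train_control(), preprocess = preprocess_config(),
                     verbose = FALSE) {
  train(model, control, data, pre_cfg = preprocess, verbose = verbose)
}

#' @export
print.mtpa_fit <- function(x, ...) {
  cat(sprintf("MTPA_Unet fit (%s profile): %s parameters\n",
              x$model$cfg$profile,
              format(n_params(x$model), big.mark = ",")))
  cat(sprintf("  trained %d steps (%d epochs); best validation Dice %.4f at epoch %d\n",
              x$steps, length(x$loss_trace),
              if (length(x$val_trace)) max(x$val_trace) else NA, x$best_epoch))
  invisible(x)
}

#' @export
summary.mtpa_fit <- function(object, ...) {
  cfg <- object$model$cfg
  cat("MTPA_Unet: serial Transformer + CNN encoder-decoder\n")
  cat(sprintf("  channels %s | inputs %s | heads %s | K/V reduction %s\n",
              paste(cfg$channels, collapse = "/"),
              paste(cfg$input_sizes, collapse = "/"),
              paste(cfg$heads, collapse = "/"),
              paste(cfg$sr_ratios, collapse = "/")))
  cat(sprintf("  FFN expansion %d | pyramid scales %s | decoder widths %s\n",
              cfg$ffn_expansion, paste(cfg$pool_scales, collapse = "/"),
              paste(cfg$decoder_widths, collapse = "/")))
  cat(sprintf("  trainable parameters: %s\n",
              format(n_params(object$model), big.mark = ",")))
  cat(sprintf("  optimizer: Adam, lr %g, batch %d, %d epochs (%d steps)\n",
              object$control$lr, object$control$batch_size,
              length(object$loss_trace), object$steps))
  cat(sprintf("  final loss %.4f | best val Dice %.4f (epoch %d)\n",
              utils::tail(object$loss_trace, 1),
              if (length(object$val_trace)) max(object$val_trace) else NA,
              object$best_epoch))
  invisible(object)
}

#' Segment fundus samples with a fitted model
#'
#' @param object an `mtpa_fit`.
#' @param newdata a `fundus_sample` or a list of them.
#' @param type `"prob"` for probability maps, `"mask"` for binary masks;
#'   both are always present in the returned `segmentation_result`.
#' @param threshold binarization threshold; defaults to the training one.
#' @param ... unused.
#' @return a `segmentation_result` (or a list of them).
#' @export
predict.mtpa_fit <- function(object, newdata, type = c("prob", "mask"),
                             threshold = NULL, ...) {
  type <- match.arg(type)
  one <- function(s) segment_sample(object, s, threshold)
  if (inherits(newdata, "fundus_sample")) one(newdata) else lapply(newdata, one)
}

#' Plot the training trace of a fitted model
#'
#' @param x an `mtpa_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mtpa_fit <- function(x, ...) {
  ep <- seq_along(x$loss_trace)
  graphics::plot(ep, x$loss_trace, type = "l", col = "steelblue", lwd = 2,
                 xlab = "epoch", ylab = "Dice loss",
                 main = "MTPA_Unet training", ...)
  if (length(x$val_trace)) {
    graphics::par(new = TRUE)
    graphics::plot(ep, x$val_trace, type = "l", col = "darkorange", lwd = 2,
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation Dice", side = 4, line = 2)
    graphics::legend("right", c("loss", "val Dice"), lwd = 2,
                     col = c("steelblue", "darkorange"), bty = "n")
  }
  invisible(x)
}

#' Extract learned weights
#'
#' @param object an `mtpa_fit`.
#' @param ... unused.
#' @return named list of weight arrays (one entry per parameter tensor).
#' @export
coef.mtpa_fit <- function(object, ...) {
  params_state(object$model)$params
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result %dx%d, threshold %.2f, vessel fraction %.1f%%>\n",
              nrow(x$prob_map), ncol(x$prob_map), x$threshold,
              100 * mean(x$bin_mask)))
  invisible(x)
}
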