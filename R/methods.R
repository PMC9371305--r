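#' @export
print.tfnn_model <- function(x, ...) {
  cat(sprintf("Tensor-factorized MIL model (%s)\n", x$config$architecture))
  cat(sprintf("  input %d x %d, bag size %d, %d training bags\n",
              x$config$input_freq, x$config$input_time, x$bag_size,
              x$n_train_bags))
  cat(sprintf("  learnable parameters: %s\n",
              format(count_parameters(x$params), big.mark = ",")))
  cat(sprintf("  best epoch %d: dev UA %.3f at threshold %.3f\n",
              x$best_epoch, x$dev_ua, x$threshold))
  invisible(x)
}

#' @export
summary.tfnn_model <- function(object, ...) {
  cat(sprintf("Architecture: %s\n", object$config$architecture))
  if (!is.null(object$config$ff_dims)) {
    dims <- vapply(object$config$ff_dims, paste, character(1), collapse = "x")
    cat("Tensor FF layer outputs:", paste(dims, collapse = " -> "), "\n")
  }
  cat(sprintf("Aggregation: %s | class weights: %s\n",
              object$config$aggregation,
              paste(sprintf("%.3f", object$class_weights), collapse = "/")))
  cat(sprintf("Learnable parameters: %s\n",
              format(count_parameters(object$params), big.mark = ",")))
  cat(sprintf("Epochs run: %d (best %d), dev UA %.3f, threshold %.3f\n",
              nrow(object$history), object$best_epoch, object$dev_ua,
              object$threshold))
  print(utils::tail(object$history, 3))
  invisible(object)
}

#' Model parameters
#'
#' @param object a fitted `tfnn_model`.
#' @param ... unused.
#' @return named list of parameter arrays (flattened path names).
#' @export
coef.tfnn_model <- function(object, ...) .walk_params(object$params)

#' Predict bag or speaker probabilities
#'
#' @param object a fitted `tfnn_model`.
#' @param newdata either a list of [speaker_record()]s, a single bag
#'   (`U x F x T` array), or a list of bags from [make_bags()].
#' @param type `"prob"` or `"class"` (thresholded at the model's dev
#'   threshold).
#' @param level `"speaker"` (default; mean over each speaker's bags) or
#'   `"bag"`.
#' @param seed seed for the evaluation bag partition.
#' @param ... unused.
#' @return numeric vector of probabilities (or integer labels).
#' @export
predict.tfnn_model <- function(object, newdata, type = c("prob", "class"),
                               level = c("speaker", "bag"), seed = 99L, ...) {
  type <- match.arg(type); level <- match.arg(level)
  p <- if (is.array(newdata) && length(dim(newdata)) == 3L) {
    model_forward(object$params, object$config, newdata)
  } else if (is.list(newdata) && length(newdata) > 0 && inherits(newdata[[1]], "speaker_record")) {
    if (level == "speaker") {
      .speaker_probs(object$params, object$config, newdata, object$bag_size,
                     seed = seed, leftover = object$train_cfg$leftover)$probs
    } else {
      bags <- .speaker_bags(newdata, object$bag_size, seed = seed,
                            leftover = object$train_cfg$leftover)
      vapply(bags, function(b) model_forward(object$params, object$config, b$tensor),
             numeric(1))
    }
  } else if (is.list(newdata)) {
    vapply(newdata, function(b) {
      ten <- if (is.list(b)) b$tensor else b
      model_forward(object$params, object$config, ten)
    }, numeric(1))
  } else stop("newdata must be a bag array, a list of bags, or speaker records")
  if (type == "class") classify_speaker(p, object$threshold) else p
}

#' Plot training history
#'
#' Training loss and dev unweighted accuracy per epoch, with the best
#' epoch marked.
#'
#' @param x a fitted `tfnn_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tfnn_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "train loss", main = x$config$architecture, ...)
  graphics::plot(h$epoch, h$dev_ua, type = "b", xlab = "epoch",
                 ylab = "dev UA", ylim = c(0, 1), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
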