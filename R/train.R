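#' Training and evaluation
#'
#' Class-weighted binary cross-entropy over bags, Adam optimization with
#' full analytic gradients, per-epoch validation at the Youden-optimal
#' threshold, and the speaker-level evaluation protocol (bags are scored
#' independently; a speaker's probability is the mean over its bags).
#'
#' @name train-eval
NULL

#' Training configuration
#'
#' @param epochs maximum epochs.
#' @param batch_size bags per optimizer step.
#' @param lr Adam learning rate.
#' @param class_weights `"balanced"` (inverse class frequency,
#'   normalized to mean 1) or a numeric vector `c(w0, w1)`.
#' @param patience early-stopping patience on dev unweighted accuracy.
#' @param seed integer seed controlling initialization, bag shuffles and
#'   batch order.
#' @param redraw_bags re-partition training bags each epoch (seeded
#'   augmentation).
#' @param leftover leftover rule passed to [make_bags()].
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, lr = 1e-3,
                         class_weights = "balanced", patience = 10L,
                         seed = 1L, redraw_bags = TRUE,
                         leftover = "drop") {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, patience >= 1L)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, class_weights = class_weights,
                 patience = as.integer(patience), seed = as.integer(seed),
                 redraw_bags = isTRUE(redraw_bags), leftover = leftover),
            class = "train_config")
}

#' Class-weighted binary cross-entropy
#'
#' `-w_y * (y * log p + (1 - y) * log(1 - p))`, with `p` clipped to
#' `[eps, 1 - eps]`. With unit weights this is standard binary
#' cross-entropy.
#'
#' @param p predicted probability.
#' @param y label 0/1.
#' @param weights length-2 vector `c(w0, w1)`.
#' @param eps clipping epsilon.
#' @return scalar loss, with attribute `"dp"` (the gradient wrt `p`).
#' @export
weighted_bce <- function(p, y, weights = c(1, 1), eps = 1e-7) {
  if (!y %in% c(0, 1)) stop("label must be 0 or 1")
  pc <- min(max(p, eps), 1 - eps)
  w <- weights[y + 1L]
  loss <- -w * (y * log(pc) + (1 - y) * log(1 - pc))
  dp <- if (p < eps || p > 1 - eps) 0 else -w * (y / pc - (1 - y) / (1 - pc))
  structure(loss, dp = dp)
}

#' Balanced class weights
#'
#' Inverse class-frequency weights normalized to mean 1; with counts
#' `n0, n1` the ratio `w_minority / w_majority` equals
#' `n_majority / n_minority`.
#'
#' @param labels 0/1 labels.
#' @return length-2 numeric vector `c(w0, w1)`.
#' @export
balanced_weights <- function(labels) {
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) stop("both classes must be present")
  w <- c(1 / n0, 1 / n1)
  w / mean(w)
}

# -- flat parameter vector utilities (Adam works on a flat view) -----------

.flatten <- function(params) {
  leaves <- .walk_params(params)
  list(v = unlist(leaves, use.names = FALSE),
       sizes = vapply(leaves, length, integer(1)),
       names = names(leaves))
}

.unflatten_into <- function(params, v) {
  i <- 0L
  rec <- function(p) {
    if (is.list(p)) {
      nms <- names(p)
      for (j in seq_along(p)) {
        if (!is.null(nms) && nms[j] %in% .BUFFERS) next
        p[[j]] <- rec(p[[j]])
      }
      p
    } else if (is.numeric(p)) {
      out <- v[(i + 1L):(i + length(p))]
      i <<- i + length(p)
      if (!is.null(dim(p))) dim(out) <- dim(p)
      out
    } else p
  }
  rec(params)
}

.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 7919 + a * 104729 + b * 31) %% 2147483647)
}

.speaker_bags <- function(speakers, k, seed, leftover = "drop") {
  out <- list()
  for (i in seq_along(speakers)) {
    b <- make_bags(speakers[[i]], k, seed = .derive_seed(seed, i), leftover = leftover)
    out <- c(out, b)
  }
  out
}

.speaker_probs <- function(params, config, speakers, k, seed, leftover = "drop") {
  probs <- numeric(length(speakers)); labels <- integer(length(speakers))
  keep <- logical(length(speakers))
  for (i in seq_along(speakers)) {
    bags <- suppressWarnings(
      make_bags(speakers[[i]], k, seed = .derive_seed(seed, i), leftover = leftover))
    labels[i] <- speakers[[i]]$label
    if (length(bags) == 0L) next
    bp <- vapply(bags, function(b) model_forward(params, config, b$tensor), numeric(1))
    probs[i] <- aggregate_speaker(bp)
    keep[i] <- TRUE
  }
  list(probs = probs[keep], labels = labels[keep],
       speaker_id = vapply(speakers, `[[`, character(1), "speaker_id")[keep])
}

#' Fit a tensor-factorized MIL model
#'
#' The package's central fitting function. Minimizes class-weighted
#' binary cross-entropy over training bags with Adam, re-drawing the
#' seeded bag partition each epoch (augmentation), evaluating the dev
#' speakers each epoch at the Youden-optimal threshold, and returning
#' the checkpoint with the best dev unweighted accuracy. Fully
#' reproducible given the seed in `train_cfg`.
#'
#' @param corpus list of [speaker_record()]s with spectrogram
#'   utterances, including `train` and `dev` splits.
#' @param architecture passed to [model_config()] unless `config` is
#'   given.
#' @param bag_size utterances per bag (k).
#' @param config optional [model_config()] (overrides `architecture`).
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `tfnn_model`: list with `params` (best
#'   checkpoint), `config`, `train_cfg`, `bag_size`, `history` (one row
#'   per epoch: train loss, dev UA, threshold), `threshold` (dev-optimal
#'   at the best epoch), `best_epoch`, `n_train_bags`.
#' @export
tfnn_fit <- function(corpus, architecture = "tfnn3d_att", bag_size = 30L,
                     config = NULL, train_cfg = train_config(),
                     verbose = FALSE) {
  train_sp <- Filter(function(s) s$split == "train", corpus)
  dev_sp <- Filter(function(s) s$split == "dev", corpus)
  if (length(train_sp) == 0L) stop("no training speakers in corpus")
  if (length(dev_sp) == 0L) stop("no dev speakers in corpus")
  tr_labels <- vapply(train_sp, `[[`, integer(1), "label")
  if (length(unique(tr_labels)) < 2L)
    stop("training data must contain both classes")
  d1 <- dim(train_sp[[1]]$utterances[[1]])
  if (is.null(config)) {
    config <- model_config(architecture, input_freq = d1[1], input_time = d1[2],
                           bag_size = bag_size)
  }
  weights <- if (identical(train_cfg$class_weights, "balanced"))
    balanced_weights(tr_labels) else train_cfg$class_weights

  params <- init_model(config, seed = train_cfg$seed)
  flat <- .flatten(params)
  theta <- flat$v
  adam <- .adam_init(length(theta))

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        dev_ua = numeric(), threshold = numeric())
  best <- list(ua = -Inf, theta = theta, epoch = 0L, tau = 0.5)
  bags0 <- NULL
  for (epoch in seq_len(train_cfg$epochs)) {
    if (train_cfg$redraw_bags || is.null(bags0)) {
      bags0 <- .speaker_bags(train_sp, bag_size,
                             seed = .derive_seed(train_cfg$seed, 0L, epoch),
                             leftover = train_cfg$leftover)
    }
    if (length(bags0) == 0L)
      stop("bag size exceeds every training speaker's utterance count")
    set.seed(.derive_seed(train_cfg$seed, 1L, epoch))
    ord <- sample.int(length(bags0))
    total_loss <- 0
    for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
      gsum <- NULL
      params_now <- .unflatten_into(params, theta)
      for (bi in idx) {
        bag <- bags0[[bi]]
        fwd <- .fwd_model(params_now, config, bag$tensor, training = TRUE)
        l <- weighted_bce(fwd$prob, bag$label, weights)
        total_loss <- total_loss + as.numeric(l)
        g <- .bwd_model(params_now, config, bag$tensor, fwd, attr(l, "dp"))
        gv <- unlist(.walk_params(g), use.names = FALSE)
        gsum <- if (is.null(gsum)) gv else gsum + gv
        if (config$architecture == "cnn_mil") {
          # persist batch-norm running statistics
          for (i in seq_along(params$blocks)) {
            params$blocks[[i]]$rmean <- fwd$slices[[1]]$bcaches[[i]]$bn$rmean
            params$blocks[[i]]$rvar <- fwd$slices[[1]]$bcaches[[i]]$bn$rvar
          }
        }
      }
      upd <- .adam_step(adam, theta, gsum / length(idx), train_cfg$lr)
      theta <- upd$theta; adam <- upd$state
    }
    params_now <- .unflatten_into(params, theta)
    dv <- .speaker_probs(params_now, config, dev_sp, bag_size,
                         seed = .derive_seed(train_cfg$seed, 2L),
                         leftover = train_cfg$leftover)
    if (length(unique(dv$labels)) < 2L)
      stop("dev split must contain both classes")
    tau <- select_threshold(dv$probs, dv$labels)
    pred <- classify_speaker(dv$probs, tau)
    cm <- confusion_matrix(dv$labels, pred)
    ua <- mil_metrics(cm)$ua
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = total_loss / length(ord),
                                         dev_ua = ua, threshold = as.numeric(tau)))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f dev UA %.3f tau %.3f",
                      epoch, total_loss / length(ord), ua, as.numeric(tau)))
    if (ua > best$ua) best <- list(ua = ua, theta = theta, epoch = epoch,
                                   tau = as.numeric(tau))
    if (epoch - best$epoch >= train_cfg$patience) break
  }
  structure(list(params = .unflatten_into(params, best$theta),
                 config = config, train_cfg = train_cfg,
                 bag_size = bag_size, history = history,
                 threshold = best$tau, best_epoch = best$epoch,
                 dev_ua = best$ua, n_train_bags = length(bags0),
                 class_weights = weights),
            class = "tfnn_model")
}

# -- metrics ----------------------------------------------------------------

#' Confusion matrix (rows = true, cols = predicted)
#'
#' @param truth,pred 0/1 vectors.
#' @return 2x2 integer matrix.
#' @export
confusion_matrix <- function(truth, pred) {
  cm <- matrix(0L, 2, 2, dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Weighted accuracy (overall fraction correct), unweighted accuracy
#' (mean of per-class recalls) and per-class F1. An F1 whose
#' denominator is zero (a class never predicted and never present) is
#' defined as 0 and flagged.
#'
#' @param cm 2x2 confusion matrix, rows = true, cols = predicted.
#' @return a `mil_metrics` list: `confusion`, `wa`, `ua`, `f1_normal`,
#'   `f1_depressed`, `f1_undefined` flag.
#' @export
mil_metrics <- function(cm) {
  total <- sum(cm)
  wa <- sum(diag(cm)) / total
  recalls <- diag(cm) / pmax(rowSums(cm), 1)
  ua <- mean(recalls)
  f1 <- numeric(2); undef <- FALSE
  for (k in 1:2) {
    denom <- 2 * cm[k, k] + (sum(cm[, k]) - cm[k, k]) + (sum(cm[k, ]) - cm[k, k])
    if (sum(cm[, k]) == 0 || denom == 0) {    # class never predicted
      f1[k] <- 0; undef <- TRUE
    } else f1[k] <- 2 * cm[k, k] / denom
  }
  structure(list(confusion = cm, wa = wa, ua = ua,
                 f1_normal = f1[1], f1_depressed = f1[2],
                 f1_undefined = undef),
            class = "mil_metrics")
}

#' @export
print.mil_metrics <- function(x, ...) {
  cat(sprintf("WA %.4f  UA %.4f  F1(normal) %.4f  F1(depressed) %.4f\n",
              x$wa, x$ua, x$f1_normal, x$f1_depressed))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted model on a speaker set
#'
#' Bag-level metrics score every bag independently against its inherited
#' speaker label; speaker-level metrics average each speaker's bag
#' probabilities and threshold at `tau`.
#'
#' @param model a fitted `tfnn_model`.
#' @param speakers list of [speaker_record()]s.
#' @param tau decision threshold; defaults to the model's dev-selected
#'   threshold.
#' @param bag_size bag size; defaults to the model's.
#' @param seed seed for the evaluation bag partition.
#' @return list with `bag` and `speaker` [mil_metrics()] and the
#'   speaker-level scores.
#' @export
evaluate_model <- function(model, speakers, tau = model$threshold,
                           bag_size = model$bag_size, seed = 99L) {
  if (length(speakers) == 0L) stop("empty speaker set")
  bag_probs <- numeric(); bag_labels <- integer()
  sp_probs <- numeric(); sp_labels <- integer(); sp_ids <- character()
  for (i in seq_along(speakers)) {
    s <- speakers[[i]]
    bags <- suppressWarnings(make_bags(s, bag_size, seed = .derive_seed(seed, i),
                                       leftover = model$train_cfg$leftover))
    if (length(bags) == 0L) next
    bp <- vapply(bags, function(b)
      model_forward(model$params, model$config, b$tensor), numeric(1))
    bag_probs <- c(bag_probs, bp)
    bag_labels <- c(bag_labels, rep(s$label, length(bp)))
    sp_probs <- c(sp_probs, aggregate_speaker(bp))
    sp_labels <- c(sp_labels, s$label)
    sp_ids <- c(sp_ids, s$speaker_id)
  }
  if (length(sp_probs) == 0L) stop("bag size exceeds every speaker's utterance count")
  bag_m <- mil_metrics(confusion_matrix(bag_labels, classify_speaker(bag_probs, tau)))
  sp_m <- mil_metrics(confusion_matrix(sp_labels, classify_speaker(sp_probs, tau)))
  list(bag = bag_m, speaker = sp_m, threshold = tau,
       scores = data.frame(speaker_id = sp_ids, label = sp_labels,
                           probability = sp_probs,
                           prediction = classify_speaker(sp_probs, tau)))
}

#' Bag-size sweep
#'
#' Trains and evaluates one model per bag size with identical seeds and
#' reports test speaker-level metrics per size. No interpolation is
#' applied to the resulting curve.
#'
#' @param corpus speaker records with train/dev/test splits.
#' @param sizes integer bag sizes.
#' @param architecture,config,train_cfg as in [tfnn_fit()].
#' @return data.frame with one row per size: `k`, `speaker_ua`,
#'   `speaker_wa`, `f1_normal`, `f1_depressed`, `threshold`.
#' @export
bag_size_sweep <- function(corpus, sizes, architecture = "tfnn3d_att",
                           config = NULL, train_cfg = train_config()) {
  test_sp <- Filter(function(s) s$split == "test", corpus)
  nmax <- max(vapply(Filter(function(s) s$split == "train", corpus),
                     function(s) length(s$utterances), integer(1)))
  if (all(sizes > nmax))
    stop("every bag size exceeds the available utterance counts")
  rows <- lapply(sizes, function(k) {
    fit <- tfnn_fit(corpus, architecture = architecture, bag_size = k,
                    config = config, train_cfg = train_cfg)
    ev <- evaluate_model(fit, test_sp)
    data.frame(k = k, speaker_ua = ev$speaker$ua, speaker_wa = ev$speaker$wa,
               f1_normal = ev$speaker$f1_normal,
               f1_depressed = ev$speaker$f1_depressed,
               threshold = ev$threshold)
  })
  do.call(rbind, rows)
}
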