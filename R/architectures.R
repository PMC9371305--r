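#' Model configurations
#'
#' Builds the configuration for one of the four bag-classification
#' architectures. Defaults reproduce the published layer dimensions for
#' 128 x 219 log-mel input:
#' \describe{
#'   \item{`cnn_mil`}{three conv blocks (64 filters 3x3, 64 filters 3x3,
#'     128 filters 2x2; ELU, 2x2 max-pool) applied per utterance with
#'     shared weights, a dense sigmoid head per utterance, and MAX
#'     aggregation of the per-utterance probabilities.}
#'   \item{`tfnn_mil`}{four shared 2D tensor feed-forward layers
#'     (120x210, 110x200, 100x180, 80x160), a tensor-sigmoid read-out
#'     per utterance (80x160 weight), MEAN aggregation.}
#'   \item{`tfnn3d`}{two 3D tensor feed-forward layers (U x 120 x 200,
#'     U x 100 x 180, RELU), one tensor-sigmoid read-out over the whole
#'     bag feature tensor.}
#'   \item{`tfnn3d_att`}{the same two 3D layers, then utterance-level
#'     attention over time (U x 100), statistics pooling (length 200),
#'     two dense layers of 256 units and a sigmoid output.}
#' }
#'
#' @param architecture one of `"cnn_mil"`, `"tfnn_mil"`, `"tfnn3d"`,
#'   `"tfnn3d_att"`.
#' @param input_freq,input_time input spectrogram dimensions.
#' @param ff_dims list of `c(freq, time)` output dims per tensor FF
#'   layer; defaults are the published dimensions for each architecture,
#'   scaled proportionally when the input is not 128 x 219.
#' @param activation activation of the tensor FF layers.
#' @param aggregation bag aggregation rule for the per-utterance
#'   architectures: `"max"` or `"mean"`.
#' @param head_dims dense head sizes for `tfnn3d_att`.
#' @param head_activation activation of the dense head layers.
#' @param use_bias include bias cores / biases (`TRUE`, standard
#'   practice; the published description is silent on biases).
#' @param utter_mode `"identity"` (weight sharing over utterances; any
#'   bag size) or `"learned"` (square utterance-mixing factor; fixes
#'   `bag_size`).
#' @param weight_mode for `tfnn3d`: `"slot"` (bag-level weight tensor
#'   indexed over utterance slots; fixes `bag_size`; not permutation
#'   invariant) or `"broadcast"` (one 2D weight shared by all slots).
#' @param bag_size required by `utter_mode = "learned"` and
#'   `weight_mode = "slot"`.
#' @param spread statistics-pooling spread: `"sd"` or `"var"`.
#' @param filters,kernels CNN baseline block sizes.
#' @return a `model_config` list.
#' @export
model_config <- function(architecture = c("tfnn3d_att", "tfnn3d", "tfnn_mil", "cnn_mil"),
                         input_freq = 128, input_time = 219,
                         ff_dims = NULL, activation = "RELU",
                         aggregation = NULL,
                         head_dims = c(256, 256), head_activation = "RELU",
                         use_bias = TRUE,
                         utter_mode = c("identity", "learned"),
                         weight_mode = c("slot", "broadcast"),
                         bag_size = NULL,
                         spread = c("sd", "var"),
                         filters = c(64, 64, 128),
                         kernels = list(c(3, 3), c(3, 3), c(2, 2))) {
  architecture <- match.arg(architecture)
  utter_mode <- match.arg(utter_mode)
  weight_mode <- match.arg(weight_mode)
  spread <- match.arg(spread)
  if (is.null(ff_dims)) {
    ff_dims <- switch(architecture,
      tfnn_mil = list(c(120, 210), c(110, 200), c(100, 180), c(80, 160)),
      tfnn3d = , tfnn3d_att = list(c(120, 200), c(100, 180)),
      cnn_mil = NULL)
    # published dims assume 128 x 219 input; scale proportionally otherwise
    if (!is.null(ff_dims) && (input_freq != 128 || input_time != 219)) {
      ff_dims <- lapply(ff_dims, function(dm)
        pmax(1L, c(floor(dm[1] * input_freq / 128),
                   floor(dm[2] * input_time / 219))))
    }
  }
  if (is.null(aggregation))
    aggregation <- if (architecture == "cnn_mil") "max" else "mean"
  aggregation <- match.arg(aggregation, c("max", "mean"))
  if (!is.null(ff_dims)) {
    prev <- c(input_freq, input_time)
    for (dm in ff_dims) {
      if (dm[1] > prev[1] || dm[2] > prev[2])
        stop("tensor FF layers must reduce or preserve dimensions along the chain")
      prev <- dm
    }
  }
  if ((utter_mode == "learned" || (architecture == "tfnn3d" && weight_mode == "slot")) &&
      is.null(bag_size))
    stop("bag_size is required for utter_mode='learned' or weight_mode='slot'")
  structure(list(architecture = architecture,
                 input_freq = input_freq, input_time = input_time,
                 ff_dims = ff_dims, activation = toupper(activation),
                 aggregation = aggregation,
                 head_dims = head_dims, head_activation = toupper(head_activation),
                 use_bias = use_bias, utter_mode = utter_mode,
                 weight_mode = weight_mode, bag_size = bag_size,
                 spread = spread, filters = filters, kernels = kernels),
            class = "model_config")
}

.glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize model parameters
#'
#' Uniform Glorot-style initialization of every learnable array of the
#' configured architecture; biases start at zero, batch-norm scales at
#' one. Fully determined by `seed`.
#'
#' @param config a [model_config()] object.
#' @param seed integer seed.
#' @return nested list of parameter arrays.
#' @export
init_model <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  arch <- config$architecture
  p <- list()
  if (arch %in% c("tfnn_mil", "tfnn3d", "tfnn3d_att")) {
    prev <- c(config$input_freq, config$input_time)
    p$ff <- lapply(config$ff_dims, function(dm) {
      l <- list(freq = .glorot(prev[1], dm[1]), time = .glorot(prev[2], dm[2]))
      if (config$use_bias) l$bias <- matrix(0, dm[1], dm[2])
      if (config$utter_mode == "learned" && arch != "tfnn_mil")
        l$utter <- diag(config$bag_size) + .glorot(config$bag_size, config$bag_size) * 0.1
      prev <<- dm
      l
    })
    last <- config$ff_dims[[length(config$ff_dims)]]
    if (arch == "tfnn_mil") {
      p$W <- .glorot(last[1], last[2]) / sqrt(last[1] * last[2] / (last[1] + last[2]))
      p$b <- 0
    } else if (arch == "tfnn3d") {
      if (config$weight_mode == "slot") {
        a <- sqrt(6 / (config$bag_size * last[1] * last[2]))
        p$W <- array(stats::runif(config$bag_size * last[1] * last[2], -a, a),
                     dim = c(config$bag_size, last[1], last[2]))
      } else {
        a <- sqrt(6 / (last[1] * last[2]))
        p$W <- matrix(stats::runif(last[1] * last[2], -a, a), last[1], last[2])
      }
      p$b <- 0
    } else {                                 # tfnn3d_att
      p$att_w <- stats::runif(last[1], -0.1, 0.1)
      din <- 2 * last[1]
      p$head <- list()
      for (h in config$head_dims) {
        p$head[[length(p$head) + 1L]] <- list(W = .glorot(h, din), b = rep(0, h))
        din <- h
      }
      p$out <- list(w = as.vector(.glorot(1, din)), b = 0)
    }
  } else {                                   # cnn_mil
    cin <- 1L
    p$blocks <- lapply(seq_along(config$filters), function(i) {
      kh <- config$kernels[[i]][1]; kw <- config$kernels[[i]][2]
      K <- config$filters[i]
      a <- sqrt(6 / (kh * kw * cin + kh * kw * K))
      blk <- list(kernel = array(stats::runif(kh * kw * cin * K, -a, a),
                                 dim = c(kh, kw, cin, K)),
                  gamma = rep(1, K), beta = rep(0, K),
                  rmean = rep(0, K), rvar = rep(1, K))
      cin <<- K
      blk
    })
    h <- config$input_freq; w <- config$input_time
    for (i in seq_along(config$filters)) { h <- h %/% 2L; w <- w %/% 2L }
    flat <- h * w * config$filters[length(config$filters)]
    p$out <- list(w = as.vector(.glorot(1, flat)), b = 0)
  }
  p
}

.tff_from_layer <- function(l, config) {
  tff_params(l$freq, l$time,
             bias_core = l$bias,
             activation = config$activation,
             utter_factor = if (is.null(l$utter)) "identity" else l$utter)
}

# forward passes ------------------------------------------------------------

.check_bag <- function(bag, config) {
  d <- dim(bag)
  if (is.null(d) || length(d) != 3L) stop("bag must be a U x F x T array")
  if (d[1] < 1L) stop("empty bag")
  if (d[2] != config$input_freq || d[3] != config$input_time)
    stop(sprintf("bag slices are %dx%d but the model expects %dx%d",
                 d[2], d[3], config$input_freq, config$input_time))
  d
}

.fwd_model <- function(params, config, bag, training = FALSE) {
  d <- .check_bag(bag, config)
  U <- d[1]
  switch(config$architecture,
    tfnn_mil = {
      sl <- lapply(seq_len(U), function(u) {
        X <- bag[u, , ]
        caches <- vector("list", length(params$ff))
        for (i in seq_along(params$ff)) {
          caches[[i]] <- .fwd_tff2d(X, .tff_from_layer(params$ff[[i]], config))
          X <- caches[[i]]$out
        }
        prob <- tensor_sigmoid(X, params$W, params$b)
        list(caches = caches, Y = X, prob = prob)
      })
      probs <- vapply(sl, `[[`, numeric(1), "prob")
      prob <- if (config$aggregation == "mean") mean(probs) else max(probs)
      list(prob = prob, slices = sl, probs = probs)
    },
    tfnn3d = {
      X <- bag
      caches <- vector("list", length(params$ff))
      for (i in seq_along(params$ff)) {
        caches[[i]] <- .fwd_tff3d(X, .tff_from_layer(params$ff[[i]], config))
        X <- caches[[i]]$out
      }
      W <- params$W
      if (config$weight_mode == "slot") {
        if (dim(W)[1] != U)
          stop(sprintf(paste0("bag has %d utterances but the slot-indexed bag-level ",
                              "weight tensor was built for %d; use weight_mode='broadcast' ",
                              "for variable bag sizes"), U, dim(W)[1]))
        logit <- sum(X * W) + params$b
      } else {
        Wb <- aperm(array(W, dim = c(dim(W), U)), c(3, 1, 2))
        logit <- sum(X * Wb) + params$b
      }
      prob <- .sigmoid(logit)
      list(prob = prob, caches = caches, Y = X)
    },
    tfnn3d_att = {
      X <- bag
      caches <- vector("list", length(params$ff))
      for (i in seq_along(params$ff)) {
        caches[[i]] <- .fwd_tff3d(X, .tff_from_layer(params$ff[[i]], config))
        X <- caches[[i]]$out
      }
      att <- lapply(seq_len(U), function(u) .fwd_attention(X[u, , ], params$att_w))
      C <- do.call(rbind, lapply(att, `[[`, "c"))          # U x D
      sp <- .fwd_statpool(C, spread = config$spread)
      hcaches <- list(); x <- sp$out
      for (i in seq_along(params$head)) {
        hcaches[[i]] <- .fwd_dense(x, params$head[[i]]$W, params$head[[i]]$b,
                                   config$head_activation)
        x <- hcaches[[i]]$out
      }
      logit <- sum(params$out$w * x) + params$out$b
      prob <- .sigmoid(logit)
      list(prob = prob, caches = caches, att = att, sp = sp,
           hcaches = hcaches, x = x)
    },
    cnn_mil = {
      sl <- lapply(seq_len(U), function(u) {
        X <- array(bag[u, , ], dim = c(d[2], d[3], 1L))
        bcaches <- vector("list", length(params$blocks))
        for (i in seq_along(params$blocks)) {
          bcaches[[i]] <- .fwd_conv_block(X, params$blocks[[i]], training = training)
          X <- bcaches[[i]]$out
        }
        v <- as.vector(X)
        logit <- sum(params$out$w * v) + params$out$b
        list(bcaches = bcaches, v = v, prob = .sigmoid(logit))
      })
      probs <- vapply(sl, `[[`, numeric(1), "prob")
      prob <- if (config$aggregation == "mean") mean(probs) else max(probs)
      list(prob = prob, slices = sl, probs = probs)
    })
}

#' Bag probability under a configured architecture
#'
#' Runs the forward pass of the configured architecture on one bag
#' (`U x F x T` array of stacked utterance spectrograms) and returns the
#' bag-level probability of the positive (depressed) class.
#'
#' @param params parameters from [init_model()] (or a fitted model's
#'   `$params`).
#' @param config a [model_config()].
#' @param bag `U x F x T` numeric array.
#' @return scalar probability.
#' @export
model_forward <- function(params, config, bag) {
  .fwd_model(params, config, bag, training = FALSE)$prob
}

# backward passes ------------------------------------------------------------

.zero_like <- function(x) if (is.list(x)) lapply(x, .zero_like) else x * 0

.bwd_model <- function(params, config, bag, fwd, dprob) {
  U <- dim(bag)[1]
  g <- list()
  switch(config$architecture,
    tfnn_mil = {
      dp_each <- if (config$aggregation == "mean") rep(dprob / U, U) else {
        v <- rep(0, U); v[which.max(fwd$probs)] <- dprob; v
      }
      g$ff <- lapply(params$ff, .zero_like)
      g$W <- params$W * 0; g$b <- 0
      for (u in seq_len(U)) {
        s <- fwd$slices[[u]]
        ts <- .bwd_tensor_sigmoid(s$Y, params$W, s$prob, dp_each[u])
        g$W <- g$W + ts$dW; g$b <- g$b + ts$db
        G <- ts$dY
        for (i in rev(seq_along(params$ff))) {
          pp <- .tff_from_layer(params$ff[[i]], config)
          bw <- .bwd_tff2d(s$caches[[i]], pp, G)
          g$ff[[i]]$freq <- g$ff[[i]]$freq + bw$d_freq
          g$ff[[i]]$time <- g$ff[[i]]$time + bw$d_time
          if (!is.null(params$ff[[i]]$bias))
            g$ff[[i]]$bias <- g$ff[[i]]$bias + bw$d_bias
          G <- bw$dX
        }
      }
    },
    tfnn3d = {
      dlogit <- dprob * fwd$prob * (1 - fwd$prob)
      if (config$weight_mode == "slot") {
        g$W <- dlogit * fwd$Y
        G <- dlogit * params$W
      } else {
        Wb <- aperm(array(params$W, dim = c(dim(params$W), U)), c(3, 1, 2))
        g$W <- apply(dlogit * fwd$Y, c(2, 3), sum)
        G <- dlogit * Wb
      }
      g$b <- dlogit
      g$ff <- vector("list", length(params$ff))
      for (i in rev(seq_along(params$ff))) {
        pp <- .tff_from_layer(params$ff[[i]], config)
        bw <- .bwd_tff3d(fwd$caches[[i]], pp, G)
        g$ff[[i]] <- list(freq = bw$d_freq, time = bw$d_time)
        if (!is.null(params$ff[[i]]$bias)) g$ff[[i]]$bias <- bw$d_bias
        if (!is.null(params$ff[[i]]$utter)) g$ff[[i]]$utter <- bw$d_utter
        G <- bw$dX
      }
    },
    tfnn3d_att = {
      dlogit <- dprob * fwd$prob * (1 - fwd$prob)
      g$out <- list(w = dlogit * fwd$x, b = dlogit)
      dx <- dlogit * params$out$w
      g$head <- vector("list", length(params$head))
      for (i in rev(seq_along(params$head))) {
        bw <- .bwd_dense(fwd$hcaches[[i]], params$head[[i]]$W, dx)
        g$head[[i]] <- list(W = bw$dW, b = bw$db)
        dx <- bw$dx
      }
      spb <- .bwd_statpool(fwd$sp, dx)
      D <- length(params$att_w)
      g$att_w <- rep(0, D)
      G <- array(0, dim = dim(fwd$caches[[length(fwd$caches)]]$out))
      for (u in seq_len(U)) {
        ab <- .bwd_attention(fwd$att[[u]], params$att_w, spb$dC[u, ])
        g$att_w <- g$att_w + ab$dw
        G[u, , ] <- ab$dH
      }
      g$ff <- vector("list", length(params$ff))
      for (i in rev(seq_along(params$ff))) {
        pp <- .tff_from_layer(params$ff[[i]], config)
        bw <- .bwd_tff3d(fwd$caches[[i]], pp, G)
        g$ff[[i]] <- list(freq = bw$d_freq, time = bw$d_time)
        if (!is.null(params$ff[[i]]$bias)) g$ff[[i]]$bias <- bw$d_bias
        if (!is.null(params$ff[[i]]$utter)) g$ff[[i]]$utter <- bw$d_utter
        G <- bw$dX
      }
    },
    cnn_mil = {
      dp_each <- if (config$aggregation == "mean") rep(dprob / U, U) else {
        v <- rep(0, U); v[which.max(fwd$probs)] <- dprob; v
      }
      g$blocks <- lapply(params$blocks, function(b)
        list(kernel = b$kernel * 0, gamma = b$gamma * 0, beta = b$beta * 0))
      g$out <- list(w = params$out$w * 0, b = 0)
      for (u in seq_len(U)) {
        s <- fwd$slices[[u]]
        if (dp_each[u] == 0) next
        dlogit <- dp_each[u] * s$prob * (1 - s$prob)
        g$out$w <- g$out$w + dlogit * s$v
        g$out$b <- g$out$b + dlogit
        G <- array(dlogit * params$out$w,
                   dim = dim(s$bcaches[[length(s$bcaches)]]$out))
        for (i in rev(seq_along(params$blocks))) {
          bw <- .bwd_conv_block(s$bcaches[[i]], params$blocks[[i]], G)
          g$blocks[[i]]$kernel <- g$blocks[[i]]$kernel + bw$dK
          g$blocks[[i]]$gamma <- g$blocks[[i]]$gamma + bw$dgamma
          g$blocks[[i]]$beta <- g$blocks[[i]]$beta + bw$dbeta
          G <- bw$dX
        }
      }
    })
  g[names(params)]   # field order must match params for the flat view
}

# parameter counting ---------------------------------------------------------

.BUFFERS <- c("rmean", "rvar")

.walk_params <- function(p, path = character()) {
  if (is.list(p)) {
    out <- list()
    for (nm in names(p)) {
      if (nm %in% .BUFFERS) next
      out <- c(out, .walk_params(p[[nm]], c(path, nm)))
    }
    if (is.null(names(p)))
      for (i in seq_along(p))
        out <- c(out, .walk_params(p[[i]], c(path, as.character(i))))
    out
  } else if (is.numeric(p)) {
    stats::setNames(list(p), paste(path, collapse = "."))
  } else list()
}

#' Count learnable parameters
#'
#' Exact count of learnable scalars of a parameter set (batch-norm
#' running statistics are buffers and excluded; `"identity"` utterance
#' factors contribute zero).
#'
#' @param params parameter list from [init_model()] or a fitted model.
#' @return integer count.
#' @export
count_parameters <- function(params) {
  if (inherits(params, "tfnn_model")) params <- params$params
  sum(vapply(.walk_params(params), length, integer(1)))
}

#' Dense-equivalent parameter count of a tensor FF layer
#'
#' The number of weights a fully-connected layer would need to map the
#' same flattened input to the same flattened output:
#' `(in_freq * in_time) * (out_freq * out_time)`. The ratio against the
#' factorized count quantifies the parameter economy of the tensor
#' layers.
#'
#' @param in_dims,out_dims `c(freq, time)` input and output dims.
#' @return a list with `factorized` (with bias core), `dense`, and
#'   `ratio`.
#' @export
dense_equivalent_count <- function(in_dims, out_dims) {
  fac <- in_dims[1] * out_dims[1] + in_dims[2] * out_dims[2] +
    out_dims[1] * out_dims[2]
  dense <- prod(in_dims) * prod(out_dims)
  list(factorized = fac, dense = dense, ratio = dense / fac)
}
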