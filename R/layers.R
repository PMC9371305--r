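#' Learnable layers
#'
#' Forward contracts for the tensor feed-forward (TFF) layers, the tensor
#' sigmoid read-out, utterance attention, statistics pooling, dense
#' layers and the convolutional baseline block. Each layer also has an
#' internal analytic backward pass (`.bwd_*`) used by the training loop;
#' all gradients are validated against central finite differences in the
#' test suite.
#'
#' @name layers
NULL

# activation registry ------------------------------------------------------

.activation <- function(id) {
  id <- toupper(id)
  switch(id,
    RELU = list(
      f = function(x) pmax(x, 0),
      df = function(pre, out) as.numeric(pre > 0)),
    ELU = list(
      f = function(x) ifelse(x > 0, x, exp(x) - 1),
      df = function(pre, out) ifelse(pre > 0, 1, out + 1)),
    SIGMOID = list(
      f = function(x) 1 / (1 + exp(-x)),
      df = function(pre, out) out * (1 - out)),
    IDENTITY = list(
      f = function(x) x,
      df = function(pre, out) rep(1, length(pre))),
    stop("unknown activation: ", id)
  )
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Tensor feed-forward layer parameters
#'
#' @param freq_factor `I_freq x P_freq` matrix applied (transposed) along
#'   the frequency mode.
#' @param time_factor `I_time x P_time` matrix applied (transposed) along
#'   the time mode.
#' @param bias_core `P_freq x P_time` additive bias (broadcast over
#'   utterances in 3D layers), or `NULL` for no bias.
#' @param activation one of `"RELU"`, `"ELU"`, `"SIGMOID"`, `"IDENTITY"`.
#' @param utter_factor `"identity"` (weight sharing over utterances, any
#'   bag size) or a square `U x U` utterance-mixing matrix (3D layers
#'   only; fixes the bag size).
#' @return a `tff_params` list.
#' @export
tff_params <- function(freq_factor, time_factor, bias_core = NULL,
                       activation = "RELU", utter_factor = "identity") {
  freq_factor <- as.matrix(freq_factor); time_factor <- as.matrix(time_factor)
  if (ncol(freq_factor) > nrow(freq_factor) || ncol(time_factor) > nrow(time_factor))
    stop("projection must reduce or preserve dimensions (P_n <= I_n)")
  if (!is.null(bias_core)) {
    bias_core <- as.matrix(bias_core)
    stopifnot(nrow(bias_core) == ncol(freq_factor),
              ncol(bias_core) == ncol(time_factor))
  }
  if (!identical(utter_factor, "identity")) {
    utter_factor <- as.matrix(utter_factor)
    if (nrow(utter_factor) != ncol(utter_factor))
      stop("utter_factor must be square (U x U)")
  }
  structure(list(freq_factor = freq_factor, time_factor = time_factor,
                 bias_core = bias_core, activation = toupper(activation),
                 utter_factor = utter_factor),
            class = "tff_params")
}

# -- 2D tensor feed-forward ------------------------------------------------

.fwd_tff2d <- function(X, p) {
  A <- p$freq_factor; B <- p$time_factor
  if (nrow(X) != nrow(A) || ncol(X) != nrow(B))
    stop(sprintf("input %dx%d does not match factors %dx%d / %dx%d",
                 nrow(X), ncol(X), nrow(A), ncol(A), nrow(B), ncol(B)))
  pre <- crossprod(A, X) %*% B
  if (!is.null(p$bias_core)) pre <- pre + p$bias_core
  act <- .activation(p$activation)
  out <- act$f(pre)
  list(out = out, pre = pre, X = X)
}

.bwd_tff2d <- function(cache, p, G) {
  act <- .activation(p$activation)
  dpre <- G * array(act$df(cache$pre, cache$out), dim = dim(G))
  A <- p$freq_factor; B <- p$time_factor; X <- cache$X
  list(d_freq = X %*% B %*% t(dpre),
       d_time = crossprod(X, A) %*% dpre,
       d_bias = if (is.null(p$bias_core)) NULL else dpre,
       dX = A %*% dpre %*% t(B))
}

#' 2D tensor feed-forward layer
#'
#' Computes `activation(t(freq_factor) %*% X %*% time_factor + bias)`,
#' the order-2 specialization of a multilinear projection: a Tucker-style
#' layer whose learnable parameters are the two per-mode factor matrices
#' and a bias core, in place of a dense weight over the flattened input.
#'
#' @param X `I_freq x I_time` input matrix (e.g. a log-mel spectrogram).
#' @param p a [tff_params()] object.
#' @return `P_freq x P_time` output matrix.
#' @export
tensor_ff_2d <- function(X, p) .fwd_tff2d(as.matrix(X), p)$out

# -- 3D tensor feed-forward ------------------------------------------------

.fwd_tff3d <- function(X, p) {
  d <- dim(X)
  if (length(d) != 3L) stop("input must be an order-3 array (utter x freq x time)")
  A <- p$freq_factor; B <- p$time_factor
  if (d[2] != nrow(A) || d[3] != nrow(B))
    stop(sprintf("bag slices are %dx%d but factors expect %dx%d input",
                 d[2], d[3], nrow(A), nrow(B)))
  core <- mode_product(mode_product(X, t(A), 2), t(B), 3)
  mixed <- core
  if (!identical(p$utter_factor, "identity")) {
    if (ncol(p$utter_factor) != d[1])
      stop(sprintf("utter_factor is %dx%d but bag has %d utterances",
                   nrow(p$utter_factor), ncol(p$utter_factor), d[1]))
    mixed <- mode_product(core, p$utter_factor, 1)
  }
  pre <- mixed
  if (!is.null(p$bias_core))
    pre <- pre + aperm(array(p$bias_core, dim = c(dim(pre)[2:3], dim(pre)[1])), c(3, 1, 2))
  act <- .activation(p$activation)
  out <- array(act$f(pre), dim = dim(pre))
  list(out = out, pre = pre, core = core, X = X)
}

.bwd_tff3d <- function(cache, p, G) {
  act <- .activation(p$activation)
  dpre <- array(act$df(cache$pre, cache$out), dim = dim(G)) * G
  d_bias <- if (is.null(p$bias_core)) NULL else apply(dpre, c(2, 3), sum)
  d_utter <- NULL
  dcore <- dpre
  if (!identical(p$utter_factor, "identity")) {
    d_utter <- unfold(dpre, 1) %*% t(unfold(cache$core, 1))
    dcore <- mode_product(dpre, t(p$utter_factor), 1)
  }
  A <- p$freq_factor; B <- p$time_factor; X <- cache$X
  R <- mode_product(X, t(B), 3)              # U x F x Pt
  S <- mode_product(X, t(A), 2)              # U x Pf x T
  list(d_freq = unfold(R, 2) %*% t(unfold(dcore, 2)),
       d_time = unfold(S, 3) %*% t(unfold(dcore, 3)),
       d_bias = d_bias, d_utter = d_utter,
       dX = mode_product(mode_product(dcore, A, 2), B, 3))
}

#' 3D tensor feed-forward layer
#'
#' Applies the frequency and time factor matrices of `p` to every
#' utterance slice of a bag tensor (`U x I_freq x I_time`). With
#' `utter_factor = "identity"` the layer shares weights across utterances
#' and slice `u` of the output equals [tensor_ff_2d()] of slice `u`; a
#' learned square utterance factor additionally mixes utterances by a
#' mode-1 product before the activation.
#'
#' @param X `U x I_freq x I_time` array.
#' @param p a [tff_params()] object.
#' @return `U x P_freq x P_time` array.
#' @export
tensor_ff_3d <- function(X, p) .fwd_tff3d(X, p)$out

# -- tensor sigmoid --------------------------------------------------------

#' Tensor sigmoid read-out
#'
#' Scalar probability `sigmoid(<Y, W> + b)` where `<.,.>` is the full
#' elementwise inner product of the feature tensor with a same-shaped
#' weight tensor.
#'
#' @param Y feature array.
#' @param W weight array, identical shape to `Y`.
#' @param b scalar bias.
#' @return probability in (0, 1).
#' @export
tensor_sigmoid <- function(Y, W, b = 0) {
  if (!identical(dim(Y), dim(W)) && !(is.null(dim(Y)) && is.null(dim(W)) && length(Y) == length(W)))
    stop("Y and W must have identical shapes")
  .sigmoid(sum(Y * W) + b)
}

.bwd_tensor_sigmoid <- function(Y, W, prob, dprob) {
  g <- dprob * prob * (1 - prob)           # d loss / d logit
  list(dW = g * Y, db = g, dY = g * W)
}

# -- attention pooling -----------------------------------------------------

.softmax <- function(s) { e <- exp(s - max(s)); e / sum(e) }

.fwd_attention <- function(H, w) {
  if (ncol(H) < 1L) stop("attention requires at least one frame")
  if (length(w) != nrow(H))
    stop(sprintf("attention weight length %d != feature dimension %d",
                 length(w), nrow(H)))
  s <- as.vector(crossprod(w, H))
  alpha <- .softmax(s)
  list(c = as.vector(H %*% alpha), alpha = alpha, H = H)
}

.bwd_attention <- function(cache, w, dc) {
  H <- cache$H; alpha <- cache$alpha
  dalpha <- as.vector(crossprod(H, dc))
  ds <- alpha * (dalpha - sum(alpha * dalpha))   # softmax Jacobian
  list(dw = as.vector(H %*% ds),
       dH = outer(dc, alpha) + outer(w, ds))
}

#' Utterance-level attention pooling
#'
#' Scores every frame vector `h_t` (column of `H`) by a learnable vector
#' `w`, normalizes the scores with a softmax into attention weights
#' `alpha_t`, and returns the attention-weighted sum `c = sum_t alpha_t h_t`.
#' The weights sum to one, so `c` lies in the convex hull of the frames.
#'
#' @param H `D x T` matrix of frame feature vectors.
#' @param w length-`D` attention weight vector.
#' @return length-`D` pooled vector, with the length-`T` attention
#'   weights attached as attribute `"alpha"`.
#' @export
attention_pool <- function(H, w) {
  r <- .fwd_attention(as.matrix(H), as.numeric(w))
  structure(r$c, alpha = r$alpha)
}

# -- statistics pooling ----------------------------------------------------

#' Statistics pooling over a set of utterance vectors
#'
#' Concatenates the per-coordinate mean and spread of the rows of `C`
#' into a single order-invariant bag summary of length `2 D`. The spread
#' is the population standard deviation by default (with a small epsilon
#' under the square root); variance is available as an option.
#'
#' @param C `U x D` matrix, one row per utterance.
#' @param spread `"sd"` (default) or `"var"`.
#' @param eps stabilizer added to the variance before the square root.
#' @return numeric vector of length `2 * ncol(C)`.
#' @export
statistics_pool <- function(C, spread = c("sd", "var"), eps = 1e-9) {
  spread <- match.arg(spread)
  C <- as.matrix(C)
  mu <- colMeans(C)
  v <- colMeans(C^2) - mu^2                 # population variance
  s <- if (spread == "sd") sqrt(pmax(v, 0) + eps) else v
  c(mu, s)
}

.fwd_statpool <- function(C, spread = "sd", eps = 1e-9) {
  mu <- colMeans(C)
  v <- colMeans(C^2) - mu^2
  sd <- sqrt(pmax(v, 0) + eps)
  out <- if (spread == "sd") c(mu, sd) else c(mu, v)
  list(out = out, mu = mu, v = v, sd = sd, C = C, spread = spread)
}

.bwd_statpool <- function(cache, dout) {
  C <- cache$C; U <- nrow(C); D <- ncol(C)
  dmu <- dout[seq_len(D)]; dspread <- dout[D + seq_len(D)]
  centered <- sweep(C, 2, cache$mu)
  dv <- if (cache$spread == "sd") dspread / (2 * cache$sd) else dspread
  dC <- matrix(dmu / U, U, D, byrow = TRUE) + sweep(centered, 2, 2 * dv / U, `*`)
  list(dC = dC)
}

# -- dense layer -----------------------------------------------------------

.fwd_dense <- function(x, W, b, activation = "RELU") {
  pre <- as.vector(W %*% x + b)
  act <- .activation(activation)
  list(out = act$f(pre), pre = pre, x = x, activation = activation)
}

.bwd_dense <- function(cache, W, dout) {
  act <- .activation(cache$activation)
  dpre <- dout * act$df(cache$pre, cache$out)
  list(dW = outer(dpre, cache$x), db = dpre, dx = as.vector(crossprod(W, dpre)))
}

# -- convolutional baseline block ------------------------------------------

#' Convolutional block parameters
#'
#' One feature-learning block of the CNN baseline: 2D convolution
#' ("same" padding, stride 1), batch normalization, ELU activation, and
#' 2x2 max pooling.
#'
#' @param kernel `kh x kw x C_in x C_out` weight array.
#' @param gamma,beta per-output-channel batch-norm scale and shift.
#' @param rmean,rvar per-channel running statistics (buffers, used at
#'   inference).
#' @return a `conv_block_params` list.
#' @export
conv_block_params <- function(kernel, gamma = NULL, beta = NULL,
                              rmean = NULL, rvar = NULL) {
  stopifnot(length(dim(kernel)) == 4L)
  K <- dim(kernel)[4]
  structure(list(kernel = kernel,
                 gamma = if (is.null(gamma)) rep(1, K) else gamma,
                 beta = if (is.null(beta)) rep(0, K) else beta,
                 rmean = if (is.null(rmean)) rep(0, K) else rmean,
                 rvar = if (is.null(rvar)) rep(1, K) else rvar),
            class = "conv_block_params")
}

.im2col <- function(P, kh, kw, H, W) {
  # P: padded (Hp x Wp x C); rows ordered (di fastest, dj, c), matching
  # column-major flattening of a (kh, kw, C) kernel slice.
  C <- dim(P)[3]
  M <- matrix(0, kh * kw * C, H * W)
  r <- 1L
  for (c0 in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    M[r, ] <- as.vector(P[di:(di + H - 1L), dj:(dj + W - 1L), c0])
    r <- r + 1L
  }
  # reorder rows from (di,dj,c) grouping (c slowest here) to column-major
  # (di fastest, dj, c): already (di, dj, c) with c slowest -> matches
  M
}

.pad_same <- function(X, kh, kw) {
  d <- dim(X)
  pt <- (kh - 1L) %/% 2L; pb <- kh - 1L - pt
  pl <- (kw - 1L) %/% 2L; pr <- kw - 1L - pl
  P <- array(0, dim = c(d[1] + kh - 1L, d[2] + kw - 1L, d[3]))
  P[pt + seq_len(d[1]), pl + seq_len(d[2]), ] <- X
  list(P = P, pt = pt, pl = pl)
}

.fwd_conv <- function(X, kernel) {
  d <- dim(X); kd <- dim(kernel)
  if (d[1] < kd[1] || d[2] < kd[2])
    stop(sprintf("input %dx%d smaller than kernel %dx%d", d[1], d[2], kd[1], kd[2]))
  if (d[3] != kd[3]) stop("channel mismatch between input and kernel")
  pad <- .pad_same(X, kd[1], kd[2])
  M <- .im2col(pad$P, kd[1], kd[2], d[1], d[2])
  Kmat <- matrix(kernel, kd[1] * kd[2] * kd[3], kd[4])
  Y <- crossprod(Kmat, M)                    # K_out x (H*W)
  out <- array(t(Y), dim = c(d[1], d[2], kd[4]))
  list(out = out, M = M, in_dim = d)
}

.bwd_conv <- function(cache, kernel, G) {
  kd <- dim(kernel); d <- cache$in_dim
  Gmat <- matrix(G, d[1] * d[2], kd[4])      # (H*W) x K
  dK <- array(cache$M %*% Gmat, dim = kd)
  # dX: scatter-add t(Kmat %*% t(Gmat)) back through im2col
  Kmat <- matrix(kernel, kd[1] * kd[2] * kd[3], kd[4])
  dM <- Kmat %*% t(Gmat)                     # (kh*kw*C) x (H*W)
  pad <- .pad_same(array(0, d), kd[1], kd[2])
  dP <- pad$P
  r <- 1L
  for (c0 in seq_len(d[3])) for (dj in seq_len(kd[2])) for (di in seq_len(kd[1])) {
    dP[di:(di + d[1] - 1L), dj:(dj + d[2] - 1L), c0] <-
      dP[di:(di + d[1] - 1L), dj:(dj + d[2] - 1L), c0] +
      matrix(dM[r, ], d[1], d[2])
    r <- r + 1L
  }
  dX <- dP[pad$pt + seq_len(d[1]), pad$pl + seq_len(d[2]), , drop = FALSE]
  list(dK = dK, dX = dX)
}

.fwd_bn <- function(X, gamma, beta, rmean, rvar, training = TRUE,
                    momentum = 0.1, eps = 1e-5) {
  d <- dim(X); K <- d[3]
  if (training) {
    mu <- apply(X, 3, mean)
    v <- apply(X, 3, function(s) mean((s - mean(s))^2))
    new_rmean <- (1 - momentum) * rmean + momentum * mu
    new_rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean; v <- rvar; new_rmean <- rmean; new_rvar <- rvar
  }
  xhat <- sweep(sweep(X, 3, mu), 3, sqrt(v + eps), `/`)
  out <- sweep(sweep(xhat, 3, gamma, `*`), 3, beta, `+`)
  list(out = out, xhat = xhat, mu = mu, v = v, eps = eps,
       training = training, rmean = new_rmean, rvar = new_rvar)
}

.bwd_bn <- function(cache, gamma, G) {
  d <- dim(G); n <- d[1] * d[2]
  dgamma <- apply(G * cache$xhat, 3, sum)
  dbeta <- apply(G, 3, sum)
  istd <- 1 / sqrt(cache$v + cache$eps)
  dX <- array(0, d)
  for (k in seq_len(d[3])) {
    g <- G[, , k] * gamma[k]
    if (cache$training) {
      xh <- cache$xhat[, , k]
      dX[, , k] <- istd[k] / n * (n * g - sum(g) - xh * sum(g * xh))
    } else {
      dX[, , k] <- g * istd[k]
    }
  }
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

.fwd_maxpool2 <- function(X) {
  d <- dim(X); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  out <- array(0, c(H2, W2, d[3]))
  amax <- array(0L, c(H2, W2, d[3]))
  for (k in seq_len(d[3])) for (j in seq_len(W2)) for (i in seq_len(H2)) {
    block <- X[(2L * i - 1L):(2L * i), (2L * j - 1L):(2L * j), k]
    m <- which.max(block)
    out[i, j, k] <- block[m]
    amax[i, j, k] <- m
  }
  list(out = out, amax = amax, in_dim = d)
}

.bwd_maxpool2 <- function(cache, G) {
  d <- cache$in_dim; H2 <- dim(G)[1]; W2 <- dim(G)[2]
  dX <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(W2)) for (i in seq_len(H2)) {
    m <- cache$amax[i, j, k] - 1L
    dX[2L * i - 1L + (m %% 2L), 2L * j - 1L + (m %/% 2L), k] <-
      dX[2L * i - 1L + (m %% 2L), 2L * j - 1L + (m %/% 2L), k] + G[i, j, k]
  }
  dX
}

.fwd_conv_block <- function(X, p, training = TRUE) {
  cv <- .fwd_conv(X, p$kernel)
  bn <- .fwd_bn(cv$out, p$gamma, p$beta, p$rmean, p$rvar, training = training)
  act <- .activation("ELU")
  a <- array(act$f(bn$out), dim = dim(bn$out))
  mp <- .fwd_maxpool2(a)
  list(out = mp$out, cv = cv, bn = bn, a = a, mp = mp)
}

.bwd_conv_block <- function(cache, p, G) {
  da <- .bwd_maxpool2(cache$mp, G)
  act <- .activation("ELU")
  dbn_out <- da * array(act$df(cache$bn$out, cache$a), dim = dim(da))
  bn <- .bwd_bn(cache$bn, p$gamma, dbn_out)
  cv <- .bwd_conv(cache$cv, p$kernel, bn$dX)
  list(dK = cv$dK, dgamma = bn$dgamma, dbeta = bn$dbeta, dX = cv$dX)
}

#' CNN feature-learning block
#'
#' Convolution ("same" padding, stride 1) -> batch normalization -> ELU
#' -> 2x2 max pooling (spatial dims halve, floor). One of the three
#' feature blocks of the convolutional MIL baseline.
#'
#' @param X `H x W x C_in` input stack.
#' @param p a [conv_block_params()] object.
#' @param training logical; `TRUE` uses batch statistics, `FALSE` the
#'   running statistics.
#' @return `floor(H/2) x floor(W/2) x C_out` output stack.
#' @export
cnn_feature_block <- function(X, p, training = FALSE) {
  .fwd_conv_block(X, p, training = training)$out
}
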