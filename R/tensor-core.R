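#' Order-3 tensor algebra
#'
#' Dense order-3 tensors are represented as base R numeric arrays with
#' `dim` of length 3, indexed `(i1, i2, i3)`. Mode-n matricization follows
#' the Kolda--Bader convention: the mode-n fibers become columns, ordered
#' so that lower-numbered remaining modes vary fastest. Under this
#' convention element `(i1, i2, i3)` of an `I1 x I2 x I3` tensor lands in
#' row `i_n` and column `1 + sum_{k != n} (i_k - 1) * J_k`, where `J_k` is
#' the product of the dimensions of the remaining modes preceding `k`.
#'
#' @name tensor-core
NULL

#' Validate and construct a dense order-3 tensor
#'
#' @param x numeric array with three dimensions, or a numeric vector
#'   together with `dims`.
#' @param dims integer vector of length 3, required when `x` is not
#'   already a 3-d array.
#' @return a numeric array of dimension 3 (invisibly classed only by its
#'   `dim` attribute; plain arrays are used throughout the package).
#' @export
dense_tensor3 <- function(x, dims = NULL) {
  if (is.null(dims)) {
    if (is.null(dim(x)) || length(dim(x)) != 3L)
      stop("x must be a 3-dimensional array, or supply `dims`")
    dims <- dim(x)
  }
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three positive integers")
  if (length(x) != prod(dims))
    stop(sprintf("element count %d does not match shape %s",
                 length(x), paste(dims, collapse = "x")))
  if (!all(is.finite(x))) stop("tensor values must be finite")
  array(as.numeric(x), dim = dims)
}

.check_mode <- function(mode) {
  if (!(length(mode) == 1L && mode %in% 1:3))
    stop("mode must be 1, 2 or 3")
  as.integer(mode)
}

#' Mode-n matricization (unfolding) of an order-3 tensor
#'
#' Returns the `I_n x (prod of remaining dims)` matrix whose columns are
#' the mode-n fibers of `x`, ordered with lower-numbered remaining modes
#' varying fastest (Kolda--Bader).
#'
#' @param x order-3 numeric array.
#' @param mode integer in 1..3.
#' @return a numeric matrix.
#' @export
unfold <- function(x, mode) {
  mode <- .check_mode(mode)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("x must be an order-3 array")
  rest <- setdiff(1:3, mode)
  # aperm to (mode, rest...) then flatten column-major: with the mode
  # first, the remaining modes vary in increasing order, lower fastest.
  m <- aperm(x, c(mode, rest))
  dim(m) <- c(d[mode], prod(d[rest]))
  m
}

#' Fold a matricized tensor back to order 3
#'
#' Exact inverse of [unfold()] under the same column-ordering convention.
#'
#' @param m numeric matrix, `shape[mode]` rows.
#' @param mode integer in 1..3.
#' @param shape target dimensions, length 3.
#' @return order-3 numeric array.
#' @export
fold <- function(m, mode, shape) {
  mode <- .check_mode(mode)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive integers")
  rest <- setdiff(1:3, mode)
  if (nrow(m) != shape[mode] || ncol(m) != prod(shape[rest]))
    stop(sprintf("matrix %dx%d inconsistent with mode %d of shape %s",
                 nrow(m), ncol(m), mode, paste(shape, collapse = "x")))
  a <- array(as.numeric(m), dim = c(shape[mode], shape[rest]))
  aperm(a, order(c(mode, rest)))
}

#' Mode-n product of a tensor with a matrix
#'
#' Computes `x ×_mode u`: every mode-n fiber of `x` is multiplied by `u`.
#' In matricized form this is `fold(u %*% unfold(x, mode), mode, ...)`;
#' the mode-n dimension `I_n` (which must equal `ncol(u)`) is replaced by
#' `nrow(u)`.
#'
#' @param x order-3 numeric array.
#' @param u numeric matrix with `ncol(u) == dim(x)[mode]`.
#' @param mode integer in 1..3.
#' @return order-3 numeric array.
#' @export
mode_product <- function(x, u, mode) {
  mode <- .check_mode(mode)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("x must be an order-3 array")
  u <- as.matrix(u)
  if (ncol(u) != d[mode])
    stop(sprintf("dimension mismatch: factor is %dx%d but mode %d of tensor %s has size %d",
                 nrow(u), ncol(u), mode, paste(d, collapse = "x"), d[mode]))
  newshape <- d
  newshape[mode] <- nrow(u)
  fold(u %*% unfold(x, mode), mode, newshape)
}

.as_factor_list <- function(factors, d) {
  if (!is.list(factors) || length(factors) != 3L)
    stop("factors must be a list of three matrices (or NULL for identity)")
  lapply(1:3, function(n) {
    f <- factors[[n]]
    if (is.null(f)) diag(d[n]) else as.matrix(f)
  })
}

#' Multilinear transformation of a core tensor
#'
#' Applies one factor matrix per mode by successive mode products:
#' `core ×_1 U1 ×_2 U2 ×_3 U3`. `NULL` entries stand for identity.
#' The order of application across distinct modes does not affect the
#' result.
#'
#' @param core order-3 numeric array.
#' @param factors list of three matrices (or `NULL`s), `factors[[n]]`
#'   applied along mode `n` with `ncol == dim(core)[n]`.
#' @return order-3 numeric array.
#' @export
multilinear_transform <- function(core, factors) {
  d <- dim(core)
  fs <- .as_factor_list(factors, d)
  y <- core
  for (n in 1:3) y <- mode_product(y, fs[[n]], n)
  y
}

#' Rank-one expansion of a multilinear transform
#'
#' Evaluates the transform as the explicit sum of `I1*I2*I3` outer
#' products of factor columns weighted by the core entries. Numerically
#' equal to [multilinear_transform()]; kept as an independent formulation
#' (and mutual oracle) of the same map.
#'
#' @inheritParams multilinear_transform
#' @return order-3 numeric array.
#' @export
rank_one_sum <- function(core, factors) {
  d <- dim(core)
  fs <- .as_factor_list(factors, d)
  out <- array(0, dim = vapply(fs, nrow, integer(1)))
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    w <- core[i1, i2, i3]
    if (w != 0)
      out <- out + w * (fs[[1]][, i1] %o% fs[[2]][, i2] %o% fs[[3]][, i3])
  }
  out
}

#' Matricized (Kronecker) form of a multilinear transform
#'
#' Returns `U(mode) %*% unfold(core, mode) %*% t(kron)` where `kron` is
#' the Kronecker product of the remaining factors in decreasing mode
#' order (the ordering the Kolda--Bader unfolding convention induces).
#' Equals `unfold(multilinear_transform(core, factors), mode)`.
#'
#' @inheritParams multilinear_transform
#' @param mode integer in 1..3, the unfolding mode.
#' @return numeric matrix.
#' @export
tucker_matricized <- function(core, factors, mode) {
  mode <- .check_mode(mode)
  d <- dim(core)
  fs <- .as_factor_list(factors, d)
  rest <- setdiff(1:3, mode)              # increasing; kron order is decreasing
  kron <- kronecker(fs[[rest[2]]], fs[[rest[1]]])
  fs[[mode]] %*% unfold(core, mode) %*% t(kron)
}

#' Serialize / deserialize a tensor to a flat binary container
#'
#' A minimal self-describing container: the ASCII magic `T3F8`, a
#' little-endian int32 order and dims, then the values as little-endian
#' float64 in R's column-major order. Used for caching spectrogram bags.
#'
#' @param x numeric array (any order >= 1).
#' @param path file path.
#' @return `read_tensor` returns the array; `write_tensor` returns
#'   `path` invisibly.
#' @export
write_tensor <- function(x, path) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("T3F8"), con)
  writeBin(as.integer(c(length(d), d)), con, size = 4L, endian = "little")
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "T3F8") stop("not a tensor container: ", path)
  ord <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  d <- readBin(con, "integer", ord, size = 4L, endian = "little")
  v <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
  array(v, dim = d)
}
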