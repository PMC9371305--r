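test_that("2D tensor FF layer matches a nested-loop oracle and identity case", {
  set.seed(1)
  X <- matrix(rnorm(12), 3, 4)
  A <- matrix(rnorm(6), 3, 2); B <- matrix(rnorm(8), 4, 2)
  p <- tff_params(A, B, matrix(0, 2, 2), "IDENTITY")
  out <- tensor_ff_2d(X, p)
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    for (f in 1:3) for (t in 1:4)
      oracle[i, j] <- oracle[i, j] + A[f, i] * X[f, t] * B[t, j]
  expect_equal(out, oracle, tolerance = 1e-12)

  pid <- tff_params(diag(3), diag(4), matrix(0, 3, 4), "IDENTITY")
  expect_equal(tensor_ff_2d(X, pid), X)
  expect_error(tensor_ff_2d(matrix(0, 5, 4), p), "does not match")
})

test_that("first-layer output of the 2D architecture is 120 x 210", {
  set.seed(2)
  p <- tff_params(matrix(rnorm(128 * 120, 0, 0.01), 128, 120),
                  matrix(rnorm(219 * 210, 0, 0.01), 219, 210),
                  activation = "RELU")
  out <- tensor_ff_2d(matrix(rnorm(128 * 219), 128, 219), p)
  expect_equal(dim(out), c(120L, 210L))
})

test_that("3D tensor FF with identity utterance factor acts slice-wise", {
  set.seed(3)
  bag <- array(rnorm(4 * 6 * 7), c(4, 6, 7))
  p <- tff_params(matrix(rnorm(6 * 5), 6, 5), matrix(rnorm(7 * 4), 7, 4),
                  matrix(rnorm(20), 5, 4), "ELU")
  out <- tensor_ff_3d(bag, p)
  expect_equal(dim(out), c(4L, 5L, 4L))
  for (u in 1:4)
    expect_equal(out[u, , ], tensor_ff_2d(bag[u, , ], p), tolerance = 1e-10)
  # permuting utterance slices permutes output slices identically
  perm <- c(3, 1, 4, 2)
  expect_equal(tensor_ff_3d(bag[perm, , ], p), out[perm, , ], tolerance = 1e-12)
  # zero input, zero bias -> activation(0)
  p0 <- tff_params(matrix(rnorm(12), 6, 2), matrix(rnorm(14), 7, 2),
                   matrix(0, 2, 2), "SIGMOID")
  expect_true(all(tensor_ff_3d(array(0, c(2, 6, 7)), p0) == 0.5))
})

test_that("3D first layer reproduces the published bag dimensions", {
  set.seed(4)
  p <- tff_params(matrix(rnorm(128 * 120, 0, 0.01), 128, 120),
                  matrix(rnorm(219 * 200, 0, 0.01), 219, 200),
                  activation = "RELU")
  out <- tensor_ff_3d(array(rnorm(2 * 128 * 219, 0, 0.1), c(2, 128, 219)), p)
  expect_equal(dim(out), c(2L, 120L, 200L))
})

test_that("tensor sigmoid is the sigmoid of the full inner product", {
  Y <- array(1, c(1, 2, 2))
  expect_equal(tensor_sigmoid(Y, Y * 0, 0), 0.5)
  expect_equal(tensor_sigmoid(Y, Y, 0), 1 / (1 + exp(-4)))
  # exhaustive summation oracle on a random pair
  set.seed(5)
  A <- array(rnorm(24), c(2, 3, 4)); W <- array(rnorm(24), c(2, 3, 4))
  acc <- 0
  for (i in 1:2) for (j in 1:3) for (k in 1:4) acc <- acc + A[i, j, k] * W[i, j, k]
  expect_equal(tensor_sigmoid(A, W, 0.3), 1 / (1 + exp(-(acc + 0.3))))
  # monotone in the bias, output in (0,1)
  bs <- seq(-10, 10, by = 2)
  ps <- vapply(bs, function(b) tensor_sigmoid(A, W, b), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps < 1))
  expect_error(tensor_sigmoid(A, array(0, c(2, 3, 5))), "identical shapes")
})

test_that("attention pooling computes softmax weights and a convex combination", {
  # w = 0 -> uniform weights, frame mean
  H <- matrix(rnorm(15), 3, 5)
  a0 <- attention_pool(H, rep(0, 3))
  expect_equal(attr(a0, "alpha"), rep(0.2, 5))
  expect_equal(as.vector(a0), rowMeans(H), tolerance = 1e-12)
  # hand-computed two-frame softmax: scores (0, ln 3) -> (0.25, 0.75)
  h1 <- c(1, 0); h2 <- c(0, 1)
  H2 <- cbind(h1, h2)
  w <- c(0, log(3))              # w.h1 = 0, w.h2 = ln 3
  a <- attention_pool(H2, w)
  expect_equal(attr(a, "alpha"), c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(as.vector(a), 0.25 * h1 + 0.75 * h2, tolerance = 1e-12)
  # weights sum to 1 on random inputs
  for (s in 1:20) {
    set.seed(s)
    Hr <- matrix(rnorm(7 * 11, 0, 3), 7, 11)
    expect_equal(sum(attr(attention_pool(Hr, rnorm(7)), "alpha")), 1,
                 tolerance = 1e-12)
  }
  # published feature slice: 100 x 180 -> length 100
  expect_length(as.vector(attention_pool(matrix(0.1, 100, 180), rnorm(100))), 100)
  expect_error(attention_pool(matrix(0, 3, 0), rep(0, 3)), "at least one frame")
})

test_that("statistics pooling concatenates mean and spread, order-invariantly", {
  c0 <- c(1, -2, 3)
  same <- rbind(c0, c0, c0)
  out <- statistics_pool(same)
  expect_equal(out[1:3], c0)
  expect_equal(out[4:6], rep(sqrt(1e-9), 3), tolerance = 1e-12)
  # hand statistics: rows (0,2),(4,6) -> means (2,4), population sd (2,2)
  out2 <- statistics_pool(rbind(c(0, 2), c(4, 6)))
  expect_equal(out2, c(2, 4, 2, 2), tolerance = 1e-4)
  # variance option
  expect_equal(statistics_pool(rbind(c(0, 2), c(4, 6)), spread = "var"),
               c(2, 4, 4, 4), tolerance = 1e-12)
  # permutation invariance
  set.seed(6)
  C <- matrix(rnorm(30 * 5), 30, 5)
  expect_identical(statistics_pool(C), statistics_pool(C[sample(30), ]))
  # published size: 30 x 100 -> 200
  expect_length(statistics_pool(matrix(rnorm(3000), 30, 100)), 200)
})

test_that("CNN feature block pools, activates and halves spatial dims", {
  # hand-checked 2x2 max pooling of a known 4x4 map
  m <- matrix(c(1, 5, 2, 0,
                3, 4, 7, 1,
                0, 2, 9, 8,
                6, 1, 3, 2), 4, 4, byrow = TRUE)
  mp <- tfnnmil:::.fwd_maxpool2(array(m, c(4, 4, 1)))
  expect_equal(mp$out[, , 1], matrix(c(5, 7, 6, 9), 2, 2, byrow = TRUE))
  # constant input through identity-like kernel and unit-stat BN = ELU(const)
  k <- array(0, c(3, 3, 1, 1)); k[2, 2, 1, 1] <- 1
  p <- conv_block_params(k)
  X <- array(2, c(4, 4, 1))
  out <- cnn_feature_block(X, p, training = FALSE)
  expect_equal(dim(out), c(2L, 2L, 1L))
  expect_true(all(abs(out - 2 / sqrt(1 + 1e-5)) < 1e-6))   # ELU(x)=x for x>0
  # spatial dims after the three published blocks on 128 x 219
  h <- 128; w <- 219
  for (i in 1:3) { h <- h %/% 2; w <- w %/% 2 }
  expect_equal(c(h, w), c(16, 27))
  expect_equal(c(128 %/% 2, 219 %/% 2), c(64, 109))
  expect_error(tfnnmil:::.fwd_conv(array(0, c(2, 2, 1)), array(0, c(3, 3, 1, 2))),
               "smaller than kernel")
})

test_that("layer forwards agree with central finite differences", {
  # per-layer gradient checks at small size: 2D FF, 3D FF, tensor sigmoid,
  # attention, statistics pooling (through tiny whole-model losses), and
  # the conv block inside the CNN baseline
  for (arch in c("tfnn_mil", "tfnn3d", "tfnn3d_att")) {
    pair <- model_grad_pair(tiny_setup(arch))
    expect_lt(max_rel_err(pair$analytic, pair$numeric, floor = 1e-4), 1e-4,
              label = paste("gradient", arch))
  }
  pair <- model_grad_pair(tiny_setup("cnn_mil", nf = 8, nt = 9))
  expect_lt(max_rel_err(pair$analytic, pair$numeric, floor = 1e-4), 1e-4)
  # learned utterance-mixing factor
  pair <- model_grad_pair(tiny_setup("tfnn3d_att", utter_mode = "learned"))
  expect_lt(max_rel_err(pair$analytic, pair$numeric, floor = 1e-4), 1e-4)
})
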