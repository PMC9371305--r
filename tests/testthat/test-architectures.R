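test_that("the four published configurations build and reproduce every stated dimension", {
  # 2D MIL chain: 128x219 -> 120x210 -> 110x200 -> 100x180 -> 80x160
  cfg2 <- model_config("tfnn_mil")
  expect_equal(cfg2$ff_dims, list(c(120, 210), c(110, 200), c(100, 180), c(80, 160)))
  p2 <- init_model(cfg2, seed = 1)
  expect_equal(dim(p2$W), c(80L, 160L))
  set.seed(1)
  bag <- array(rnorm(2 * 128 * 219, 0, 0.1), c(2, 128, 219))
  fwd <- tfnnmil:::.fwd_model(p2, cfg2, bag)
  dims <- lapply(fwd$slices[[1]]$caches, function(cc) dim(cc$out))
  expect_equal(dims, list(c(120L, 210L), c(110L, 200L), c(100L, 180L), c(80L, 160L)))

  # 3D chain: U x 128 x 219 -> U x 120 x 200 -> U x 100 x 180
  cfg3 <- model_config("tfnn3d", bag_size = 2)
  p3 <- init_model(cfg3, seed = 1)
  fwd3 <- tfnnmil:::.fwd_model(p3, cfg3, bag)
  expect_equal(dim(fwd3$caches[[1]]$out), c(2L, 120L, 200L))
  expect_equal(dim(fwd3$caches[[2]]$out), c(2L, 100L, 180L))
  expect_equal(dim(p3$W), c(2L, 100L, 180L))

  # attention variant: attention U x 100, statistics pooling 200, head 256/256
  cfga <- model_config("tfnn3d_att")
  pa <- init_model(cfga, seed = 1)
  fwda <- tfnnmil:::.fwd_model(pa, cfga, bag)
  C <- do.call(rbind, lapply(fwda$att, `[[`, "c"))
  expect_equal(dim(C), c(2L, 100L))
  expect_length(fwda$sp$out, 200L)
  expect_equal(vapply(pa$head, function(h) nrow(h$W), integer(1)), c(256L, 256L))

  # CNN baseline filter stack
  cfgc <- model_config("cnn_mil")
  expect_equal(cfgc$filters, c(64, 64, 128))
  expect_equal(cfgc$kernels, list(c(3, 3), c(3, 3), c(2, 2)))
})

test_that("per-utterance aggregation follows the configured rule", {
  s <- tiny_setup("tfnn_mil")
  fwd <- tfnnmil:::.fwd_model(s$params, s$cfg, s$bag)
  expect_equal(fwd$prob, mean(fwd$probs))       # MEAN is the 2D-MIL default
  cfg_max <- s$cfg; cfg_max$aggregation <- "max"
  expect_equal(tfnnmil:::.fwd_model(s$params, cfg_max, s$bag)$prob, max(fwd$probs))
  # hand values
  probs <- c(0.2, 0.9, 0.4)
  expect_equal(max(probs), 0.9)
  expect_equal(mean(probs), 0.5)
  # single utterance: both rules coincide
  b1 <- s$bag[1, , , drop = FALSE]
  expect_equal(tfnnmil:::.fwd_model(s$params, s$cfg, b1)$prob,
               tfnnmil:::.fwd_model(s$params, cfg_max, b1)$prob)
  expect_error(model_forward(s$params, s$cfg, array(0, c(0, 6, 7))), "empty")
})

test_that("bag probability is invariant under utterance permutation where claimed", {
  set.seed(11)
  perm <- c(3, 1, 2)
  for (arch in c("tfnn_mil", "cnn_mil", "tfnn3d_att")) {
    s <- tiny_setup(arch, nf = 8, nt = 9)
    p1 <- model_forward(s$params, s$cfg, s$bag)
    p2 <- model_forward(s$params, s$cfg, s$bag[perm, , ])
    expect_lt(abs(p1 - p2), 1e-10, label = paste("permutation", arch))
  }
  # the slot-indexed 3D weight tensor is NOT permutation invariant
  s3 <- tiny_setup("tfnn3d")
  p1 <- model_forward(s3$params, s3$cfg, s3$bag)
  p2 <- model_forward(s3$params, s3$cfg, s3$bag[perm, , ])
  expect_gt(abs(p1 - p2), 1e-12)
  # but the broadcast variant is invariant
  sb <- tiny_setup("tfnn3d", weight_mode = "broadcast")
  expect_lt(abs(model_forward(sb$params, sb$cfg, sb$bag) -
                model_forward(sb$params, sb$cfg, sb$bag[perm, , ])), 1e-12)
})

test_that("3D logit decomposes into per-slice inner products with identity factors", {
  s <- tiny_setup("tfnn3d")
  fwd <- tfnnmil:::.fwd_model(s$params, s$cfg, s$bag)
  Y <- fwd$Y
  logit <- sum(vapply(seq_len(dim(Y)[1]),
                      function(u) sum(Y[u, , ] * s$params$W[u, , ]), numeric(1))) +
    s$params$b
  expect_equal(fwd$prob, 1 / (1 + exp(-logit)), tolerance = 1e-12)
  # zero weights and bias -> 0.5 regardless of input
  pz <- s$params; pz$W <- pz$W * 0; pz$b <- 0
  expect_equal(model_forward(pz, s$cfg, s$bag), 0.5)
  # wrong bag size against a slot-indexed weight tensor is explained
  expect_error(model_forward(s$params, s$cfg, s$bag[1:2, , ]), "slot-indexed")
})

test_that("attention variant with zero attention weight reduces to frame-mean stats pooling", {
  s <- tiny_setup("tfnn3d_att")
  s$params$att_w <- s$params$att_w * 0
  fwd <- tfnnmil:::.fwd_model(s$params, s$cfg, s$bag)
  # shortcut: frame means of the last feature tensor, then stats pool + head
  Y <- fwd$caches[[length(fwd$caches)]]$out
  C <- t(apply(Y, 1, function(m) rowMeans(m)))
  sp <- statistics_pool(C)
  x <- sp
  for (i in seq_along(s$params$head)) {
    x <- pmax(s$params$head[[i]]$W %*% x + s$params$head[[i]]$b, 0)
  }
  logit <- sum(s$params$out$w * x) + s$params$out$b
  expect_equal(fwd$prob, 1 / (1 + exp(-logit)), tolerance = 1e-10)
})

test_that("forward passes are deterministic given fixed parameters", {
  for (arch in c("tfnn_mil", "tfnn3d", "tfnn3d_att", "cnn_mil")) {
    s <- tiny_setup(arch, nf = 8, nt = 9)
    expect_identical(model_forward(s$params, s$cfg, s$bag),
                     model_forward(s$params, s$cfg, s$bag))
  }
})

test_that("parameter counts match arithmetic and dwarf the dense equivalent", {
  # first 3D FF layer of the published configuration, identity utterance mode
  layer <- list(freq = matrix(0, 128, 120), time = matrix(0, 219, 200),
                bias = matrix(0, 120, 200))
  expect_equal(count_parameters(layer), 128 * 120 + 219 * 200 + 120 * 200)
  expect_equal(count_parameters(layer), 83160)
  de <- dense_equivalent_count(c(128, 219), c(120, 200))
  expect_equal(de$dense, 672768000)
  expect_gt(de$ratio, 1000)
  # identity utterance factors contribute zero; buffers are not counted
  cfgc <- model_config("cnn_mil", input_freq = 8, input_time = 8,
                       filters = c(2), kernels = list(c(3, 3)))
  pc <- init_model(cfgc, seed = 1)
  manual <- length(pc$blocks[[1]]$kernel) + 2 * 2 + length(pc$out$w) + 1
  expect_equal(count_parameters(pc), manual)
})

test_that("model configurations validate their dimension chain", {
  expect_error(model_config("tfnn3d", ff_dims = list(c(140, 200), c(100, 180)),
                            bag_size = 2), "reduce or preserve")
  expect_error(model_config("tfnn3d"), "bag_size")
  cfg <- model_config("tfnn3d", weight_mode = "broadcast")  # no bag size needed
  expect_equal(cfg$weight_mode, "broadcast")
})
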