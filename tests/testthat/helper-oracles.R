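# shared oracles and fixtures, built in code at test time

# central finite-difference gradient of a scalar function of a flat vector
numeric_gradient <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(a) + abs(b), floor))
}

# independent Kolda-Bader index map: element (i1,i2,i3) of an I1xI2xI3
# tensor sits at (row, col) of the mode-n unfolding
kb_index <- function(idx, n, dims) {
  rest <- setdiff(1:3, n)
  J <- c(1, dims[rest[1]])
  col <- 1 + (idx[rest[1]] - 1) * J[1] + (idx[rest[2]] - 1) * J[2]
  c(row = idx[n], col = col)
}

# small random tensor with reproducible entries
rand_tensor <- function(dims, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dim = dims)
}

# tiny architecture config + bag for whole-model gradient checks
tiny_setup <- function(arch, U = 3, nf = 6, nt = 7, seed = 7, ...) {
  cfg <- model_config(arch, input_freq = nf, input_time = nt,
                      ff_dims = if (arch == "cnn_mil") NULL else list(c(5, 6), c(4, 5)),
                      filters = c(2, 3), kernels = list(c(3, 3), c(2, 2)),
                      head_dims = c(4, 4), bag_size = U, ...)
  params <- init_model(cfg, seed = seed)
  set.seed(seed + 1)
  bag <- array(stats::rnorm(U * nf * nt), c(U, nf, nt))
  list(cfg = cfg, params = params, bag = bag)
}

# loss gradient of a model on one bag, analytic and numeric
model_grad_pair <- function(setup, y = 1, weights = c(1, 1.5)) {
  fl <- tfnnmil:::.flatten(setup$params)
  loss_of <- function(theta) {
    p <- tfnnmil:::.unflatten_into(setup$params, theta)
    fwd <- tfnnmil:::.fwd_model(p, setup$cfg, setup$bag, training = TRUE)
    as.numeric(weighted_bce(fwd$prob, y, weights))
  }
  fwd <- tfnnmil:::.fwd_model(setup$params, setup$cfg, setup$bag, training = TRUE)
  l <- weighted_bce(fwd$prob, y, weights)
  g <- tfnnmil:::.bwd_model(setup$params, setup$cfg, setup$bag, fwd, attr(l, "dp"))
  list(analytic = unlist(tfnnmil:::.walk_params(g), use.names = FALSE),
       numeric = numeric_gradient(loss_of, fl$v))
}

# small fast spectrogram corpus for training tests
small_corpus <- function(seed, snr_db = 20, nf = 16L, nt = 20L, ...) {
  cfg <- sim_config(n_train = c(6, 6), n_dev = c(3, 3), n_test = c(3, 3),
                    utterances_per_speaker = c(6, 8), rho = 0.5,
                    snr_db = snr_db, signature_bands = 5:10, seed = seed, ...)
  simulate_spectrogram_corpus(cfg, n_freq = nf, n_time = nt)
}

small_model_config <- function(bag_size = 3L, arch = "tfnn3d_att") {
  model_config(arch, input_freq = 16, input_time = 20,
               ff_dims = list(c(12, 16), c(8, 12)), head_dims = c(8, 8),
               bag_size = bag_size)
}
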