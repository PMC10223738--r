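# Shared fixtures built in code at test time.

# Random complex field; `cut` band-limits the spectrum to cut * Nyquist
# (the domain where padded ASM and the direct RS sum both approximate
# continuum propagation).
rand_field <- function(n, grid, seed, cut = NULL) {
  rng <- odnn:::.seeded_rng(seed)
  vals <- matrix(complex(real = rng$rnorm(n * n),
                         imaginary = rng$rnorm(n * n)), n, n)
  if (!is.null(cut)) {
    f <- odnn:::.fft_freqs(n, 1)
    m <- outer(f, f, function(a, b) sqrt(a^2 + b^2)) <= cut * 0.5
    vals <- stats::fft(vals * m, inverse = TRUE) / (n * n)
  }
  complex_field(vals, grid)
}

rel_l2 <- function(a, b) {
  if (inherits(a, "complex_field")) a <- a$values
  if (inherits(b, "complex_field")) b <- b$values
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

tiny_network <- function(n = 32L, layers = 2L, seed = 1L, pad_factor = 2L,
                         readout_mode = "magnitude") {
  cfg <- network_config(network_size = n, num_layers = layers, input_size = n,
                        detector_layout = default_detector_layout(n, readout_mode),
                        pad_factor = pad_factor)
  d2nn_network(cfg, seed = seed)
}

# The reduced-scale detection experiment shared by the training and scan
# acceptance checks: trained once per test run, then cached. 100x100 grid,
# 3 layers, 200 training / 100 validation patches, 30 epochs (held-out
# accuracy is read from the epoch-10 point of the same seeded trajectory).
.fixture_env <- new.env(parent = emptyenv())

trained_detection_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  ds <- gen_dataset(150, 150, seed = 0)
  idx_tr <- c(1:100, 151:250)
  idx_va <- c(101:150, 251:300)
  cfg <- network_config(network_size = 100L, num_layers = 3L, input_size = 50L,
                        detector_layout = default_detector_layout(100))
  net <- d2nn_network(cfg, seed = 0)
  fit <- train_d2nn(net,
                    list(images = ds$images[idx_tr], labels = ds$labels[idx_tr]),
                    list(images = ds$images[idx_va], labels = ds$labels[idx_va]),
                    hyperparams(batch_size = 32L, epochs = 30L, seed = 0),
                    task = "detection")
  .fixture_env$fit <- fit
  fit
}
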