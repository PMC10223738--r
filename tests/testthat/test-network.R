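test_that("input encoding maps pixel values to field amplitude with zero phase", {
  g <- grid_spec(8)
  ones <- encode_input(matrix(1, 8, 8), g)
  expect_equal(ones$values, matrix(1 + 0i, 8, 8))
  zeros <- encode_input(matrix(0, 8, 8), g)
  expect_equal(zeros$values, matrix(0 + 0i, 8, 8))
  im <- matrix(0, 8, 8); im[3, 5] <- 0.5
  f <- encode_input(im, g)
  expect_equal(f$values[3, 5], 0.5 + 0i)
  expect_equal(sum(Mod(f$values)), 0.5)
  expect_error(encode_input(matrix(1.5, 8, 8), g), "normalized")
})

test_that("layer modulation acts elementwise as a*exp(j*phi)", {
  g <- grid_spec(8)
  u <- rand_field(8, g, seed = 1)
  ident <- diffractive_layer(matrix(0, 8, 8))
  expect_equal(apply_layer(u, ident)$values, u$values)
  pi_layer <- diffractive_layer(matrix(pi, 8, 8))
  expect_equal(apply_layer(u, pi_layer)$values, -u$values, tolerance = 1e-12)
  dark <- diffractive_layer(matrix(0, 8, 8), amplitude = 0)
  expect_true(all(apply_layer(u, dark)$values == 0))
  expect_error(diffractive_layer(matrix(0, 8, 8), amplitude = 1.2), "passive")
})

test_that("detector layouts reject overlap and out-of-grid regions", {
  expect_error(detector_layout(list(c(1, 5, 1, 5), c(3, 8, 3, 8)), 10), "overlap")
  expect_error(detector_layout(list(c(1, 5, 1, 5), c(1, 5, 8, 12)), 10),
               "outside")
  expect_error(detector_layout(list(c(1, 5, 1, 5)), 10), "at least 2")
  lay <- default_detector_layout(200)
  expect_length(lay$regions, 2L)
  expect_equal(lay$regions[[1]][2] - lay$regions[[1]][1] + 1L, 40L)  # 20% of side
})

test_that("detector readout sums magnitude or intensity over regions", {
  n <- 20L
  lay <- detector_layout(list(c(1, 4, 1, 4), c(10, 13, 10, 13)), n)
  vals <- matrix(0 + 0i, n, n)
  vals[1:4, 1:4] <- 1
  f <- complex_field(vals, grid_spec(n))
  expect_equal(as.numeric(read_detectors(f, lay)), c(16, 0))
  lay_i <- detector_layout(list(c(1, 4, 1, 4), c(10, 13, 10, 13)), n, "intensity")
  expect_equal(as.numeric(read_detectors(f, lay_i)), c(16, 0))
  vals[1:4, 1:4] <- 2i    # magnitude 2: modes now disagree by a factor 2
  f2 <- complex_field(vals, grid_spec(n))
  expect_equal(as.numeric(read_detectors(f2, lay)), c(32, 0))
  expect_equal(as.numeric(read_detectors(f2, lay_i)), c(64, 0))
  zero <- complex_field(matrix(0 + 0i, n, n), grid_spec(n))
  expect_equal(as.numeric(read_detectors(zero, lay)), c(0, 0))
})

test_that("prediction takes the argmax with ties toward the lowest class", {
  expect_identical(predict_class(c(5, 3)), 0L)
  expect_identical(predict_class(c(1, 4)), 1L)
  expect_identical(predict_class(c(2, 2)), 0L)
})

test_that("identity layers collapse to one free-space propagation", {
  n <- 32L
  cfg <- network_config(network_size = n, num_layers = 3L, input_size = n,
                        detector_layout = default_detector_layout(n),
                        pad_factor = 1L)      # periodic: composition is exact
  net <- d2nn_network(cfg, seed = 1)
  for (l in seq_along(net$layers))
    net$layers[[l]]$phase <- matrix(0, n, n)
  rng <- odnn:::.seeded_rng(4)
  img <- matrix(rng$runif(n * n), n, n)
  out <- forward_field(net, img)
  direct <- propagate_asm(encode_input(img, cfg$grid),
                          (cfg$num_layers + 1) * cfg$dz, pad_factor = 1L)
  expect_lt(rel_l2(out, direct), 1e-6)
})

test_that("zero layers degenerate to a single propagation and zero input stays dark", {
  n <- 32L
  cfg <- network_config(network_size = n, num_layers = 0L, input_size = n,
                        detector_layout = default_detector_layout(n))
  net <- d2nn_network(cfg, seed = 1)
  expect_length(net$layers, 0L)
  rng <- odnn:::.seeded_rng(9)
  img <- matrix(rng$runif(n * n), n, n)
  out <- forward_field(net, img)
  direct <- propagate_asm(encode_input(img, cfg$grid), cfg$dz, pad_factor = 2L)
  expect_equal(out$values, direct$values)

  dark <- forward_field(net, matrix(0, n, n))
  expect_true(all(dark$values == 0))
  lay <- cfg$detector_layout
  expect_equal(as.numeric(read_detectors(dark, lay)), c(0, 0))
})

test_that("the network is passive: detector-plane power never exceeds input power", {
  for (seed in 1:3) {
    net <- tiny_network(n = 32L, layers = 3L, seed = seed)
    rng <- odnn:::.seeded_rng(100 + seed)
    img <- matrix(rng$runif(32 * 32), 32, 32)
    pin <- field_power(encode_input(img, net$config$grid))
    pout <- field_power(forward_field(net, img))
    expect_lte(pout, pin * (1 + 1e-12))
  }
})

test_that("forward inference is bit-reproducible", {
  net <- tiny_network(seed = 2)
  rng <- odnn:::.seeded_rng(3)
  img <- matrix(rng$runif(32 * 32), 32, 32)
  expect_identical(forward_field(net, img)$values, forward_field(net, img)$values)
})

test_that("analytic phase gradients match central finite differences", {
  net <- tiny_network(n = 32L, layers = 2L, seed = 3)
  rng <- odnn:::.seeded_rng(5)
  img <- matrix(rng$runif(32 * 32), 32, 32)
  for (task in c("detection", "classification")) {
    gc_ <- gradient_check(net, img, label = 1, task = task,
                          n_probe = 4, step = 1e-4, seed = 11)
    expect_lt(gc_$rel_err, 1e-4)
  }
  # intensity-mode readout differentiates too
  net_i <- tiny_network(n = 32L, layers = 2L, seed = 3, readout_mode = "intensity")
  gc_i <- gradient_check(net_i, img, label = 0, task = "detection",
                         n_probe = 4, step = 1e-4, seed = 12)
  expect_lt(gc_i$rel_err, 1e-4)
})

test_that("network checkpoints round-trip bit-exactly", {
  net <- tiny_network(seed = 7)
  path <- tempfile(fileext = ".rds")
  save_network(net, path)
  net2 <- load_network(path)
  expect_identical(net2$layers, net$layers)
  expect_identical(net2$config$dz, net$config$dz)
  rng <- odnn:::.seeded_rng(8)
  img <- matrix(rng$runif(32 * 32), 32, 32)
  expect_identical(forward_field(net2, img)$values, forward_field(net, img)$values)
  # save -> load -> save produces identical bytes
  path2 <- tempfile(fileext = ".rds")
  save_network(net2, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  saveRDS(list(format = "something_else"), path2)
  expect_error(load_network(path2), "versioned-format")
})
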