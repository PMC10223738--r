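test_that("transfer function has the analytic DC phase, unit propagating band, zero evanescent band", {
  g <- grid_spec(32, pitch = 4e-6, wavelength = 632.8e-9)
  H0 <- transfer_function(g, 0, pad_factor = 2L)$values
  f <- odnn:::.fft_freqs(64, 4e-6)
  band <- outer(f^2, f^2, `+`) <= 1 / g$wavelength^2
  expect_true(all(Mod(H0[band] - 1) < 1e-12))      # dz = 0 is the identity

  H <- transfer_function(g, 10e-3, pad_factor = 2L)$values
  expect_equal(H[1, 1], exp(2i * pi * 10e-3 / 632.8e-9), tolerance = 1e-12)
  expect_true(all(abs(Mod(H[band]) - 1) < 1e-12))

  # evanescent frequencies are hard-zeroed: use a sub-wavelength pitch so
  # the grid actually reaches beyond 1/lambda
  gs <- grid_spec(32, pitch = 0.25e-6)
  Hs <- transfer_function(gs, 1e-3, pad_factor = 1L)$values
  fs <- odnn:::.fft_freqs(32, 0.25e-6)
  evan <- outer(fs^2, fs^2, `+`) > 1 / gs$wavelength^2
  expect_true(any(evan))
  expect_true(all(Hs[evan] == 0))
})

test_that("invalid grids are rejected", {
  expect_error(grid_spec(0), "invalid grid")
  expect_error(grid_spec(32, pitch = -1), "invalid grid")
  expect_error(grid_spec(32, wavelength = 0), "invalid grid")
})

test_that("uniform and zero fields propagate analytically", {
  g <- grid_spec(32)
  zero <- complex_field(matrix(0 + 0i, 32, 32), g)
  expect_equal(propagate_asm(zero, 10e-3)$values, zero$values)

  ones <- complex_field(matrix(1 + 0i, 32, 32), g)
  out <- propagate_asm(ones, 10e-3, pad_factor = 1L)   # periodic: pure DC
  expect_equal(out$values,
               matrix(exp(2i * pi * 10e-3 / g$wavelength), 32, 32),
               tolerance = 1e-10)
})

test_that("propagation is unitary and invertible on the periodic grid", {
  g <- grid_spec(64)
  u <- rand_field(64, g, seed = 7)
  fwd <- propagate_asm(u, 10e-3, pad_factor = 1L)
  expect_lt(abs(field_power(fwd) - field_power(u)) / field_power(u), 1e-6)
  back <- propagate_asm(fwd, -10e-3, pad_factor = 1L)
  expect_lt(rel_l2(back, u), 1e-6)
})

test_that("propagation is linear", {
  g <- grid_spec(32)
  u <- rand_field(32, g, seed = 1)
  v <- rand_field(32, g, seed = 2)
  a <- 0.7 - 1.3i; b <- -0.4 + 0.2i
  lhs <- propagate_asm(complex_field(a * u$values + b * v$values, g), 5e-3)
  rhs <- a * propagate_asm(u, 5e-3)$values + b * propagate_asm(v, 5e-3)$values
  expect_lt(max(Mod(lhs$values - rhs)), 1e-10)
})

test_that("translation of the input translates the output", {
  g <- grid_spec(64)
  u <- rand_field(64, g, seed = 3, cut = 0.2)
  m <- 3L
  shift <- function(x, m) x[c((64 - m + 1):64, 1:(64 - m)), ]
  # periodic grid: propagation commutes with the cyclic shift exactly
  o1 <- shift(propagate_asm(u, 10e-3, pad_factor = 1L)$values, m)
  o2 <- propagate_asm(complex_field(shift(u$values, m), g), 10e-3,
                      pad_factor = 1L)$values
  expect_lt(max(Mod(o1 - o2)), 1e-8)
  # padded grid: a compact beam built at two positions gives outputs that
  # are exact translates inside the guard band
  gauss_at <- function(r0, c0) {
    y <- (seq_len(64) - r0) * g$pitch
    x <- (seq_len(64) - c0) * g$pitch
    complex_field(exp(-outer(y^2, x^2, `+`) / (6 * g$pitch)^2) + 0i, g)
  }
  o3 <- propagate_asm(gauss_at(32, 32), 10e-3, pad_factor = 4L)$values
  o4 <- propagate_asm(gauss_at(32 + m, 32), 10e-3, pad_factor = 4L)$values
  rows <- 1:(64 - m)
  expect_lt(max(Mod(o3[rows, ] - o4[rows + m, ])), 1e-8)
})

test_that("RS kernel magnitude is radially symmetric, peaked on axis, and matches Eq-level closed form", {
  g <- grid_spec(32, pitch = 4e-6, wavelength = 632.8e-9)
  ker <- rs_kernel(g, 10e-3)
  w <- ker$values
  expect_equal(dim(w), c(63, 63))
  k <- wave_number(g)
  expect_equal(Mod(w[32, 32]),
               (1 / (2 * pi * 10e-3)) * sqrt(1 / 10e-3^2 + k^2),
               tolerance = 1e-12)
  expect_equal(Mod(w[32, 32]), 1.5803e8, tolerance = 1e-4)   # ~ 1/(lambda dz)
  # inversion symmetry and monotone decay
  expect_equal(w, w[63:1, 63:1], tolerance = 1e-14)
  expect_gt(Mod(w[32, 32]), Mod(w[32, 42]))
  expect_gt(Mod(w[32, 42]), Mod(w[32, 62]))
  expect_error(rs_kernel(g, 0), "singular")
})

test_that("direct RS propagation of a point source reproduces the kernel", {
  g <- grid_spec(16)
  u <- matrix(0 + 0i, 16, 16); u[5, 9] <- 1
  out <- propagate_rs_direct(complex_field(u, g), 10e-3)
  ker <- rs_kernel(g, 10e-3)$values
  # output at (i, j) is kernel at offset (i-5, j-9) times pitch^2
  expect_equal(out$values[11, 3], ker[11 - 5 + 16, 3 - 9 + 16] * g$pitch^2,
               tolerance = 1e-12)
  expect_equal(out$values[5, 9], ker[16, 16] * g$pitch^2, tolerance = 1e-12)

  zero <- propagate_rs_direct(complex_field(matrix(0 + 0i, 16, 16), g), 10e-3)
  expect_true(all(zero$values == 0))
})

test_that("ASM agrees with the direct RS oracle on band-limited fields", {
  # spot check; the full (n, dz) grid runs in the acceptance suite
  g <- grid_spec(16)
  u <- rand_field(16, g, seed = 11, cut = 0.2)
  a <- propagate_asm(u, 10e-3, pad_factor = 32L)
  b <- propagate_rs_direct(u, 10e-3)
  expect_lt(rel_l2(a, b), 1e-2)
})

test_that("Gaussian beam expands by the closed-form waist law", {
  g <- grid_spec(128)
  w0 <- 80e-6
  x <- (seq_len(128) - 64.5) * g$pitch
  r2 <- outer(x^2, x^2, `+`)
  beam <- complex_field(exp(-r2 / w0^2) + 0i, g)
  zR <- pi * w0^2 / g$wavelength
  out <- propagate_asm(beam, zR, pad_factor = 2L)
  I <- Mod(out$values)^2
  w_meas <- sqrt(2 * sum(I * r2) / sum(I))
  expect_equal(w_meas, w0 * sqrt(2), tolerance = 0.01)
})

test_that("fields round-trip through serialization losslessly", {
  g <- grid_spec(16)
  u <- rand_field(16, g, seed = 5)
  path <- tempfile(fileext = ".rds")
  save_field(u, path)
  v <- load_field(path)
  expect_identical(v$values, u$values)
  expect_identical(v$grid, u$grid)
})
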