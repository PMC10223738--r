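#' @section Transform conventions:
#' The forward transform is `exp(-j*2*pi*(u*x + v*y))` (R's [stats::fft()]
#' forward convention); the inverse is normalized so the round trip is the
#' identity. Time dependence is `exp(-j*w*t)`, so outgoing waves carry
#' `exp(+j*k*r)` and the angular-spectrum transfer function is
#' `exp(+j*2*pi*gamma*dz)`.
#' @name odnn-conventions
NULL

# Cache of transfer functions keyed by (N, pitch, wavelength, dz).  The same
# H is reused thousands of times during training; computing it once matters.
.tf_cache <- new.env(parent = emptyenv())

# FFT-order spatial frequencies for an N-sample axis of spacing `pitch`.
.fft_freqs <- function(N, pitch) {
  half <- N %/% 2
  c(0:(half - 1 + N %% 2), -half:-1) / (N * pitch)
}

#' Band-limited angular-spectrum transfer function
#'
#' Builds `H(u, v) = exp(j*2*pi*gamma*dz)` with
#' `gamma = sqrt(1/lambda^2 - u^2 - v^2)` on the frequency grid of the
#' zero-padded array (`pad_factor * n` samples per side, frequency spacing
#' `1 / (pad_factor * n * pitch)`). Evanescent components
#' (`u^2 + v^2 > 1/lambda^2`) are set to exactly zero, which keeps the
#' operator bounded for any `dz` and matches far-field physics at
#' millimeter distances.
#'
#' @param grid A [grid_spec()].
#' @param dz Propagation distance in meters; may be negative (backward
#'   propagation uses the conjugate kernel).
#' @param pad_factor Integer >= 1; the transfer function is sampled on the
#'   padded grid.
#' @return An object of class `transfer_function` with elements `values`
#'   (the padded-frequency-grid complex matrix), `dz`, `grid`, `pad_factor`.
#' @export
transfer_function <- function(grid, dz, pad_factor = 2L) {
  stopifnot(inherits(grid, "grid_spec"))
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L) stop("pad_factor must be >= 1")
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz))
    stop("dz must be a finite scalar (meters)")
  key <- sprintf("%d|%.17g|%.17g|%.17g", pad_factor * grid$n, grid$pitch,
                 grid$wavelength, dz)
  hit <- .tf_cache[[key]]
  if (!is.null(hit))
    return(structure(list(values = hit, dz = dz, grid = grid,
                          pad_factor = pad_factor),
                     class = "transfer_function"))
  N <- pad_factor * grid$n
  f <- .fft_freqs(N, grid$pitch)
  f2 <- outer(f^2, f^2, `+`)
  radicand <- 1 / grid$wavelength^2 - f2
  H <- matrix(0 + 0i, N, N)
  ok <- radicand >= 0
  H[ok] <- exp(2i * pi * sqrt(radicand[ok]) * dz)
  .tf_cache[[key]] <- H
  structure(list(values = H, dz = dz, grid = grid, pad_factor = pad_factor),
            class = "transfer_function")
}

# Index range of the n x n window inside the N x N padded array.
.pad_window <- function(n, N) {
  off <- (N - n) %/% 2
  off + seq_len(n)
}

# Core padded-FFT propagation of a bare complex matrix.
.asm_core <- function(values, grid, dz, pad_factor) {
  n <- grid$n
  N <- pad_factor * n
  H <- transfer_function(grid, dz, pad_factor)$values
  if (N == n) {
    padded <- values
  } else {
    padded <- matrix(0 + 0i, N, N)
    idx <- .pad_window(n, N)
    padded[idx, idx] <- values
  }
  out <- stats::fft(stats::fft(padded) * H, inverse = TRUE) / (N * N)
  if (N == n) out else out[.pad_window(n, N), .pad_window(n, N)]
}

#' Propagate a field by the band-limited angular spectrum method
#'
#' Zero-pads the field to `pad_factor * n` per side (field centered), takes
#' the 2D FFT, multiplies by [transfer_function()], inverse-transforms and
#' crops back to `n` x `n`. Linear in the input; exactly unitary on the
#' propagating band when `pad_factor = 1` (no crop loss).
#'
#' Padding suppresses circular-convolution wraparound: light diffracting
#' beyond the aperture must be accommodated by the guard band, so strongly
#' diffracting configurations need larger `pad_factor`.
#'
#' @param field A [complex_field()].
#' @param dz Propagation distance in meters (negative for backward).
#' @param pad_factor Integer >= 1, default 2.
#' @return The propagated [complex_field()].
#' @export
propagate_asm <- function(field, dz, pad_factor = 2L) {
  stopifnot(inherits(field, "complex_field"))
  complex_field(.asm_core(field$values, field$grid, dz, pad_factor),
                field$grid)
}

#' Rayleigh-Sommerfeld impulse response on a sampled offset grid
#'
#' The scalar point-source response between two parallel planes separated by
#' `dz`: `w(dx, dy) = (1/(2*pi)) * (dz/r) * (1/r - j*k) * exp(j*k*r) / r`
#' with `r = sqrt(dx^2 + dy^2 + dz^2)`, evaluated on the
#' `(2n-1) x (2n-1)` lattice of lateral offsets reachable between two
#' `n` x `n` grids.
#'
#' @param grid A [grid_spec()].
#' @param dz Plane separation in meters; must be strictly positive (the
#'   kernel is singular at `dz = 0`).
#' @return An object of class `rs_kernel` with elements `values`
#'   (`(2n-1) x (2n-1)` complex), `dz`, `grid`. Row/column `n` is zero
#'   lateral offset.
#' @export
rs_kernel <- function(grid, dz) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz) || dz <= 0)
    stop("singular kernel: rs_kernel requires dz > 0")
  n <- grid$n
  k <- wave_number(grid)
  off <- ((-(n - 1)):(n - 1)) * grid$pitch
  rho2 <- outer(off^2, off^2, `+`)
  r <- sqrt(rho2 + dz^2)
  w <- (1 / (2 * pi)) * (dz / r) * (1 / r - 1i * k) * exp(1i * k * r) / r
  structure(list(values = w, dz = dz, grid = grid), class = "rs_kernel")
}

#' Direct Rayleigh-Sommerfeld propagation (brute-force oracle)
#'
#' Exact discrete superposition of secondary waves:
#' `out(x) = sum_k in(k) * w(x - k) * pitch^2` over all source samples,
#' using [rs_kernel()]. Quadratic cost per output sample -- intended as an
#' independent oracle for [propagate_asm()] at small `n` (<= 64), never for
#' production propagation.
#'
#' @inheritParams propagate_asm
#' @return The propagated [complex_field()].
#' @export
propagate_rs_direct <- function(field, dz) {
  stopifnot(inherits(field, "complex_field"))
  n <- field$grid$n
  w <- rs_kernel(field$grid, dz)$values
  u <- field$values
  out <- matrix(0 + 0i, n, n)
  src <- seq_len(n)
  for (i in src) {
    wi <- w[(i - src) + n, , drop = FALSE]
    for (j in src) {
      out[i, j] <- sum(u * wi[, (j - src) + n])
    }
  }
  complex_field(out * field$grid$pitch^2, field$grid)
}
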