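#' Sampling grid for a scalar optical field
#'
#' A `grid_spec` describes the physical sampling of an `n` x `n` complex
#' field: the pixel pitch (sample spacing) and the illumination wavelength.
#' The physical side length is `n * pitch` and the wave number `k = 2*pi /
#' wavelength` is always derived, never stored.
#'
#' @param n Integer number of samples per side.
#' @param pitch Sample spacing in meters. Default 4 um, the pixel size of a
#'   200 x 200 layer spanning 0.8 mm.
#' @param wavelength Wavelength in meters. Default 632.8 nm (He-Ne laser).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(200)
#' g$n * g$pitch   # 0.8 mm physical aperture
#' @export
grid_spec <- function(n, pitch = 4e-6, wavelength = 632.8e-9) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n <= 0L)
    stop("invalid grid: 'n' must be a positive integer")
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("invalid grid: 'pitch' must be a positive number (meters)")
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      !is.finite(wavelength) || wavelength <= 0)
    stop("invalid grid: 'wavelength' must be a positive number (meters)")
  structure(list(n = n, pitch = pitch, wavelength = wavelength),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d, pitch %.3g um, wavelength %.4g nm, side %.3g mm\n",
              x$n, x$n, x$pitch * 1e6, x$wavelength * 1e9, x$n * x$pitch * 1e3))
  invisible(x)
}

#' Wave number of a grid
#'
#' @param grid A [grid_spec()].
#' @return `2*pi / wavelength` in rad/m.
#' @export
wave_number <- function(grid) 2 * pi / grid$wavelength

#' Complex-valued sampled optical field
#'
#' Couples an `n` x `n` complex matrix of field samples to the [grid_spec()]
#' describing its physical sampling. Arrays are indexed `(row, col)` =
#' `(y, x)` with the physical origin at the array center.
#'
#' @param values `n` x `n` complex (or numeric) matrix of field samples.
#' @param grid The [grid_spec()] the samples live on.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(values) || nrow(values) != grid$n || ncol(values) != grid$n)
    stop("field/grid mismatch: values must be an n x n matrix matching grid$n")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite")
  storage.mode(values) <- "complex"
  structure(list(values = values, grid = grid), class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("complex_field: %d x %d, total power %.6g\n",
              x$grid$n, x$grid$n, field_power(x)))
  invisible(x)
}

#' Total power carried by a field
#'
#' Discrete power integral `sum(|u|^2) * pitch^2`.
#'
#' @param field A [complex_field()].
#' @return Nonnegative scalar (units of |u|^2 m^2).
#' @export
field_power <- function(field) {
  sum(Mod(field$values)^2) * field$grid$pitch^2
}

#' @export
as.matrix.complex_field <- function(x, ...) x$values

#' Serialize a field (or any sampled plane) with its physical metadata
#'
#' Fields round-trip losslessly through R's native serialization; the grid
#' metadata (n, pitch, wavelength) travels with the samples.
#'
#' @param field A [complex_field()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_field <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  obj <- list(format = "odnn_field", version = 1L,
              n = field$grid$n, pitch = field$grid$pitch,
              wavelength = field$grid$wavelength,
              re = Re(field$values), im = Im(field$values))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "odnn_field"))
    stop("not an odnn field file: ", path)
  g <- grid_spec(obj$n, obj$pitch, obj$wavelength)
  complex_field(matrix(complex(real = obj$re, imaginary = obj$im),
                       obj$n, obj$n), g)
}
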