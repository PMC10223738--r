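#' Trainable diffractive layer
#'
#' One passive optical mask: per-pixel modulation `t = a * exp(j*phi)` with
#' amplitude `a` in `[0, 1]` and phase `phi` in radians. Both can be flagged
#' trainable; the default configuration trains phase only (the standard
#' fabrication target), keeping `a` frozen at 1.
#'
#' @param phase `n` x `n` numeric matrix of phases (radians).
#' @param amplitude `n` x `n` numeric matrix in `[0, 1]`, or a scalar
#'   (recycled). Default 1.
#' @param train_phase,train_amplitude Logical trainability flags.
#' @return An object of class `diffractive_layer`.
#' @export
diffractive_layer <- function(phase, amplitude = 1,
                              train_phase = TRUE, train_amplitude = FALSE) {
  stopifnot(is.matrix(phase), nrow(phase) == ncol(phase))
  n <- nrow(phase)
  if (length(amplitude) == 1L) amplitude <- matrix(amplitude, n, n)
  stopifnot(is.matrix(amplitude), all(dim(amplitude) == n))
  if (any(amplitude < 0) || any(amplitude > 1))
    stop("passive layer: amplitude must lie in [0, 1]")
  structure(list(phase = phase, amplitude = amplitude,
                 train_phase = isTRUE(train_phase),
                 train_amplitude = isTRUE(train_amplitude)),
            class = "diffractive_layer")
}

# Complex modulation t = a * exp(j*phi).
.layer_t <- function(layer) layer$amplitude * exp(1i * layer$phase)

#' Detector-region layout on the output plane
#'
#' One axis-aligned rectangle per class, in class order. Regions must be
#' pairwise disjoint and lie inside the grid. `readout_mode` selects the
#' per-region scalar: `"magnitude"` sums `|u|`, `"intensity"` sums `|u|^2`.
#'
#' @param regions List of length >= 2; each element is
#'   `c(row0, row1, col0, col1)` -- 1-based inclusive index ranges.
#' @param n Grid side the regions live on.
#' @param readout_mode `"magnitude"` (default; sum of field amplitude) or
#'   `"intensity"` (sum of `|u|^2`, what a physical detector records).
#' @return An object of class `detector_layout`.
#' @export
detector_layout <- function(regions, n, readout_mode = c("magnitude", "intensity")) {
  readout_mode <- match.arg(readout_mode)
  if (length(regions) < 2L) stop("need at least 2 detector regions")
  occ <- matrix(FALSE, n, n)
  for (r in regions) {
    stopifnot(length(r) == 4L)
    if (r[1] < 1 || r[3] < 1 || r[2] > n || r[4] > n || r[1] > r[2] || r[3] > r[4])
      stop("detector region outside grid or degenerate")
    block <- occ[r[1]:r[2], r[3]:r[4]]
    if (any(block)) stop("detector regions overlap")
    occ[r[1]:r[2], r[3]:r[4]] <- TRUE
  }
  structure(list(regions = regions, n = as.integer(n),
                 readout_mode = readout_mode),
            class = "detector_layout")
}

#' Default two-class detector geometry
#'
#' Two square regions, each 20% of the grid side, vertically centered and
#' horizontally centered at 25% and 75% of the width. Class 0 (left,
#' no-nodule / benign) and class 1 (right, nodule / malignant).
#'
#' @inheritParams detector_layout
#' @return A [detector_layout()].
#' @export
default_detector_layout <- function(n, readout_mode = "magnitude") {
  s <- max(1L, round(0.2 * n))
  half <- s %/% 2
  row0 <- round(n / 2) - half
  mk <- function(cc) {
    c0 <- round(cc * n) - half
    c(row0 + 1L, row0 + s, c0 + 1L, c0 + s)
  }
  detector_layout(list(mk(0.25), mk(0.75)), n, readout_mode)
}

#' Network architecture and physics configuration
#'
#' @param network_size Neurons per layer side (200 for detection, 400 for
#'   classification in the reference setup).
#' @param num_layers Number of diffractive layers (default 5).
#' @param dz Layer spacing in meters, also used from the input plane to the
#'   first layer and from the last layer to the detector plane (default 10 mm).
#' @param input_size Side of the raw input patches (default 50); must divide
#'   `network_size` (nearest-neighbor upsampling factor is integral).
#' @param pitch,wavelength Physical sampling, see [grid_spec()].
#' @param detector_layout A [detector_layout()]; default
#'   [default_detector_layout()] on the network grid.
#' @param modulation_mode `"phase"` (phase-only layers, default) or
#'   `"phase+amplitude"`.
#' @param pad_factor FFT zero-padding factor for propagation (default 2).
#' @return An object of class `network_config`.
#' @export
network_config <- function(network_size = 200L, num_layers = 5L, dz = 10e-3,
                           input_size = 50L, pitch = 4e-6,
                           wavelength = 632.8e-9, detector_layout = NULL,
                           modulation_mode = c("phase", "phase+amplitude"),
                           pad_factor = 2L) {
  modulation_mode <- match.arg(modulation_mode)
  network_size <- as.integer(network_size)
  input_size <- as.integer(input_size)
  num_layers <- as.integer(num_layers)
  if (num_layers < 0L) stop("num_layers must be >= 0")
  if (network_size %% input_size != 0L)
    stop("network_size must be an integer multiple of input_size")
  grid <- grid_spec(network_size, pitch, wavelength)
  if (is.null(detector_layout))
    detector_layout <- default_detector_layout(network_size)
  stopifnot(inherits(detector_layout, "detector_layout"),
            detector_layout$n == network_size)
  structure(list(grid = grid, network_size = network_size,
                 num_layers = num_layers, dz = dz, input_size = input_size,
                 detector_layout = detector_layout,
                 modulation_mode = modulation_mode,
                 pad_factor = as.integer(pad_factor)),
            class = "network_config")
}

#' Create a diffractive network with seeded random phase initialization
#'
#' Phases are initialized independently uniform on `[0, 2*pi)`; amplitudes
#' start at 1 (trainable only in `"phase+amplitude"` mode).
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the phase initialization.
#' @return An object of class `d2nn` with elements `config` and `layers`.
#' @export
d2nn_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  n <- config$network_size
  rng <- .seeded_rng(seed)
  layers <- lapply(seq_len(config$num_layers), function(l) {
    ph <- matrix(rng$runif(n * n) * 2 * pi, n, n)
    diffractive_layer(ph, 1,
                      train_phase = TRUE,
                      train_amplitude = config$modulation_mode == "phase+amplitude")
  })
  structure(list(config = config, layers = layers, seed = as.integer(seed)),
            class = "d2nn")
}

#' @export
print.d2nn <- function(x, ...) {
  cat(sprintf(
    "d2nn: %d layers of %d x %d (%s), dz = %g mm, lambda = %g nm\n",
    x$config$num_layers, x$config$network_size, x$config$network_size,
    x$config$modulation_mode, x$config$dz * 1e3,
    x$config$grid$wavelength * 1e9))
  invisible(x)
}

#' Encode a real image as the input optical field
#'
#' Pixel values in `[0, 1]` become the field amplitude; phase is zero
#' (uniform plane-wave illumination modulated in amplitude).
#'
#' @param image Numeric matrix with values in `[0, 1]`, sized
#'   `network_size` x `network_size`.
#' @param grid The network [grid_spec()].
#' @return A [complex_field()].
#' @export
encode_input <- function(image, grid) {
  stopifnot(is.matrix(image))
  if (any(image < 0) || any(image > 1) || any(!is.finite(image)))
    stop("input image must be normalized to [0, 1]")
  complex_field(image + 0i, grid)
}

#' Apply one diffractive layer to a field
#'
#' Elementwise modulation `out = t * field` with `t = a * exp(j*phi)`.
#'
#' @param field A [complex_field()].
#' @param layer A [diffractive_layer()].
#' @return The modulated [complex_field()].
#' @export
apply_layer <- function(field, layer) {
  stopifnot(inherits(field, "complex_field"), inherits(layer, "diffractive_layer"))
  if (!all(dim(layer$phase) == field$grid$n))
    stop("layer/field shape mismatch")
  complex_field(.layer_t(layer) * field$values, field$grid)
}

# Forward pass returning all intermediate planes (needed for backprop).
# Returns list(fields = list of post-layer fields, detector = final field).
.forward_tape <- function(network, image) {
  cfg <- network$config
  u <- encode_input(image, cfg$grid)$values
  pre <- vector("list", cfg$num_layers)   # field arriving at layer l
  post <- vector("list", cfg$num_layers)  # field leaving layer l
  for (l in seq_len(cfg$num_layers)) {
    v <- .asm_core(u, cfg$grid, cfg$dz, cfg$pad_factor)
    pre[[l]] <- v
    u <- .layer_t(network$layers[[l]]) * v
    post[[l]] <- u
  }
  det <- .asm_core(u, cfg$grid, cfg$dz, cfg$pad_factor)
  list(pre = pre, post = post, detector = det)
}

#' Run the optical forward model to the detector plane
#'
#' Encodes the image, then alternates free-space propagation over `dz` and
#' layer modulation for each diffractive layer, and propagates a final `dz`
#' to the detector plane. With zero layers this degenerates to a single
#' free-space propagation of the encoded input.
#'
#' @param network A [d2nn_network()].
#' @param image `network_size` x `network_size` numeric matrix in `[0, 1]`
#'   (upsample 50 x 50 patches with [resize_nearest()] first).
#' @return The detector-plane [complex_field()].
#' @export
forward_field <- function(network, image) {
  stopifnot(inherits(network, "d2nn"))
  cfg <- network$config
  if (!is.matrix(image) || !all(dim(image) == cfg$network_size))
    stop("image must be network_size x network_size; resize first")
  complex_field(.forward_tape(network, image)$detector, cfg$grid)
}

#' Read per-class detector energies from the output plane
#'
#' In `"magnitude"` mode `A_i = sum(|u|)` over region `i`; in
#' `"intensity"` mode `A_i = sum(|u|^2)`.
#'
#' @param field Detector-plane [complex_field()].
#' @param layout A [detector_layout()].
#' @return Numeric vector of nonnegative readouts, one per region, of class
#'   `detector_readout` with the mode as attribute.
#' @export
read_detectors <- function(field, layout) {
  stopifnot(inherits(field, "complex_field"), inherits(layout, "detector_layout"))
  m <- Mod(field$values)
  if (layout$readout_mode == "intensity") m <- m^2
  A <- vapply(layout$regions,
              function(r) sum(m[r[1]:r[2], r[3]:r[4]]), numeric(1))
  structure(A, class = "detector_readout", readout_mode = layout$readout_mode)
}

#' Predicted class from a detector readout
#'
#' Index (0-based, matching class labels) of the maximum readout; ties break
#' toward the lowest index.
#'
#' @param readout Numeric vector of detector readouts.
#' @return Integer class index in `0 .. length(readout) - 1`.
#' @export
predict_class <- function(readout) {
  which.max(as.numeric(readout)) - 1L
}

#' Save / load a trained network checkpoint
#'
#' The checkpoint holds every layer's phase and amplitude plus the full
#' [network_config()]; the round trip is bit-exact.
#'
#' @param network A [d2nn_network()].
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_network()` returns the network.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "d2nn"))
  obj <- list(format = "odnn_network", version = 1L, network = network)
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "odnn_network"))
    stop("versioned-format error: not an odnn network checkpoint: ", path)
  net <- obj$network
  n <- net$config$network_size
  for (l in net$layers)
    if (!all(dim(l$phase) == n))
      stop("versioned-format error: layer shape does not match grid metadata")
  net
}
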