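#' Write a labeled patch dataset as a PNG directory
#'
#' The adapter surface for any patch data: `images/*.png` (grayscale,
#' values in `[0, 1]`) plus `labels.csv` with columns `filename`, `label`,
#' `case_id`. Slices are written the same way with a `truth.csv` of
#' nodule centers.
#'
#' @param dataset List with `images`, `labels`, `case_ids` (see
#'   [gen_dataset()]).
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  fns <- sprintf("patch%05d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(dataset$images[[i]], file.path(dir, "images", fns[i]))
  utils::write.csv(
    data.frame(filename = fns, label = dataset$labels,
               case_id = dataset$case_ids),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         colClasses = c(case_id = "character"))
  images <- lapply(lab$filename, function(fn) {
    im <- png::readPNG(file.path(dir, "images", fn))
    if (length(dim(im)) == 3L) im <- im[, , 1]
    im
  })
  list(images = images, labels = lab$label, case_ids = lab$case_id)
}

#' Write / read a synthetic slice with its ground truth
#'
#' @param slice A `synthetic_slice` from [gen_slice()].
#' @param prefix Path prefix; writes `<prefix>.png` and
#'   `<prefix>_truth.csv`.
#' @return Paths (write) or the slice (read), invisibly.
#' @export
write_slice <- function(slice, prefix) {
  stopifnot(inherits(slice, "synthetic_slice"))
  png::writePNG(slice$image, paste0(prefix, ".png"))
  utils::write.csv(as.data.frame(slice$truth_centers),
                   paste0(prefix, "_truth.csv"), row.names = FALSE)
  invisible(paste0(prefix, c(".png", "_truth.csv")))
}

#' @rdname write_slice
#' @export
read_slice <- function(prefix) {
  im <- png::readPNG(paste0(prefix, ".png"))
  if (length(dim(im)) == 3L) im <- im[, , 1]
  tc <- as.matrix(utils::read.csv(paste0(prefix, "_truth.csv")))
  structure(list(image = im, truth_centers = tc), class = "synthetic_slice")
}

#' Map CT numbers to the unit interval
#'
#' Fixed window `[-1000, 400]` HU mapped linearly onto `[0, 1]` and
#' clipped, for feeding real CT slices to the network; synthetic slices are
#' generated in `[0, 1]` directly and need no windowing.
#'
#' @param hu Numeric matrix of Hounsfield units.
#' @param lo,hi Window bounds in HU.
#' @return Matrix in `[0, 1]`.
#' @export
normalize_hu <- function(hu, lo = -1000, hi = 400) {
  pmin(pmax((hu - lo) / (hi - lo), 0), 1)
}
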