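#' Sliding-window scan configuration
#'
#' @param window Window side in pixels (default 50, the patch size).
#' @param stride Scan stride in pixels (default 10; per-pixel scanning is
#'   available but quadratically slower).
#' @param threshold Score threshold in `[0, 1]` for candidate calls
#'   (default 0.5; raising it trades recall for fewer false positives).
#' @param b0,b1 Detection normalization biases used at inference.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(window = 50L, stride = 10L, threshold = 0.5,
                        b0 = 0.01, b1 = 0.01) {
  stopifnot(window > 0, stride >= 1, stride <= window,
            threshold >= 0, threshold <= 1)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 threshold = threshold, b0 = b0, b1 = b1),
            class = "scan_config")
}

# Window top-left positions along one axis: stride lattice, out-of-bounds
# windows skipped (boundary policy: skip, not pad).
.scan_positions <- function(side, window, stride) {
  seq(1L, side - window + 1L, by = stride)
}

#' Scan a slice for nodules with a trained network
#'
#' Every window on the stride lattice is clipped, upsampled by nearest
#' interpolation to the network size, run through the optical forward
#' model, read out, detection-normalized and scored; the nodule-class score
#' is recorded at the window center. Windows that would cross the slice
#' boundary are skipped.
#'
#' @param network A trained [d2nn_network()].
#' @param slice 2D numeric matrix in `[0, 1]`, each side >= `window`.
#' @param config A [scan_config()].
#' @param verbose Report progress.
#' @return A `candidate_map`: list with `score_map` (matrix of scores, one
#'   row/col per lattice position, dimnames = window-center coordinates),
#'   `mask` (score strictly above threshold), `candidates` (data.frame
#'   `row`, `col`, `score` of window centers, sorted by descending score)
#'   and `config`.
#' @export
scan_slice <- function(network, slice, config = scan_config(), verbose = FALSE) {
  stopifnot(inherits(network, "d2nn"), is.matrix(slice))
  w <- config$window
  if (nrow(slice) < w || ncol(slice) < w)
    stop("slice smaller than scan window")
  cfg <- network$config
  rows <- .scan_positions(nrow(slice), w, config$stride)
  cols <- .scan_positions(ncol(slice), w, config$stride)
  score_map <- matrix(NA_real_, length(rows), length(cols))
  half <- (w - 1) / 2
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      patch <- slice[rows[ri]:(rows[ri] + w - 1), cols[ci]:(cols[ci] + w - 1)]
      im <- resize_nearest(patch, cfg$network_size)
      A <- read_detectors(forward_field(network, im), cfg$detector_layout)
      s <- nodule_score(normalize_detection(A, config$b0, config$b1))
      score_map[ri, ci] <- s[2]
    }
    if (verbose) message("scanned row ", ri, "/", length(rows))
  }
  centers_r <- rows + half
  centers_c <- cols + half
  dimnames(score_map) <- list(centers_r, centers_c)
  mask <- score_map > config$threshold
  idx <- which(mask, arr.ind = TRUE)
  cand <- data.frame(row = centers_r[idx[, 1]], col = centers_c[idx[, 2]],
                     score = score_map[idx])
  cand <- cand[order(-cand$score), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(score_map = score_map, mask = mask, candidates = cand,
                 config = config),
            class = "candidate_map")
}

#' Evaluate a scan against ground-truth nodule centers
#'
#' A truth center counts as detected if any candidate lies within
#' `match_radius` (Euclidean, strict: a candidate exactly at
#' `match_radius + 1` does not match). Every candidate not matching any
#' truth center counts as one false positive.
#'
#' @param candidates Data.frame with `row`, `col` columns (e.g. from
#'   [scan_slice()]), or a `candidate_map`.
#' @param truth_centers Matrix or data.frame with columns `row`, `col`.
#' @param match_radius Match radius in pixels (default 25, half the scan
#'   window).
#' @return List with `recall`, `detected`, `total_truth`,
#'   `false_positives`.
#' @export
evaluate_scan <- function(candidates, truth_centers, match_radius = 25) {
  stopifnot(match_radius > 0)
  if (inherits(candidates, "candidate_map")) candidates <- candidates$candidates
  tc <- as.matrix(as.data.frame(truth_centers))
  nt <- nrow(tc)
  if (is.null(nt)) nt <- 0
  if (nrow(candidates) == 0L)
    return(list(recall = if (nt > 0) 0 else NaN, detected = 0L,
                total_truth = nt, false_positives = 0L))
  cm <- as.matrix(candidates[, c("row", "col")])
  matched_cand <- rep(FALSE, nrow(cm))
  detected <- 0L
  if (nt > 0) {
    for (i in seq_len(nt)) {
      d <- sqrt((cm[, 1] - tc[i, 1])^2 + (cm[, 2] - tc[i, 2])^2)
      hit <- d <= match_radius
      if (any(hit)) {
        detected <- detected + 1L
        matched_cand <- matched_cand | hit
      }
    }
  }
  list(recall = if (nt > 0) detected / nt else NaN,
       detected = detected, total_truth = nt,
       false_positives = sum(!matched_cand))
}

#' Export a candidate map to disk
#'
#' Writes the score map and the binary mask as grayscale PNGs and the
#' candidate list as CSV.
#'
#' @param cmap A `candidate_map` from [scan_slice()].
#' @param prefix Output path prefix; writes `<prefix>_scores.png`,
#'   `<prefix>_mask.png`, `<prefix>_candidates.csv`.
#' @return Invisibly, the paths written.
#' @export
export_candidate_map <- function(cmap, prefix) {
  stopifnot(inherits(cmap, "candidate_map"))
  paths <- paste0(prefix, c("_scores.png", "_mask.png", "_candidates.csv"))
  png::writePNG(pmin(pmax(cmap$score_map, 0), 1), paths[1])
  png::writePNG(cmap$mask * 1, paths[2])
  utils::write.csv(cmap$candidates, paths[3], row.names = FALSE)
  invisible(paths)
}
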