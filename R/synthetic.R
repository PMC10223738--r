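#' Parameters of the synthetic CT-like patch generator
#'
#' The generator emulates 50 x 50 lung-CT patches: a textured background
#' (band-limited correlated noise around a mean gray level) and, for the
#' positive class, a soft-edged, roughly round bright blob at the patch
#' center. The benign/malignant pair differs in size (radius multiplier)
#' and boundary irregularity (low-order radial harmonics plus spicules).
#' All intensities stay in `[0, 1]` and the nodule contrast exceeds the
#' texture amplitude, so class separability is guaranteed by construction.
#'
#' @param size Patch side in pixels.
#' @param bg_mean Background mean gray level.
#' @param bg_jitter Half-range of the per-patch background level: each
#'   patch draws its level uniformly from `bg_mean +/- bg_jitter`,
#'   emulating the varying local brightness of lung fields (the slice
#'   generator's dark lung shading and bright streaks span the same
#'   range, so patches and slices form one generative family).
#' @param texture_amplitude Standard deviation of the correlated background
#'   texture.
#' @param texture_corr Texture correlation length in pixels.
#' @param radius_range Nodule radius range in pixels (uniform draw).
#' @param contrast Peak nodule contrast above background.
#' @param edge_softness Half-width of the smoothstep edge in pixels.
#' @param malig_radius_mult Malignant radius multiplier.
#' @param malig_irregularity Relative amplitude of the malignant boundary
#'   perturbation (harmonics 2-5).
#' @param malig_spicules Number of radial spicules on malignant nodules.
#' @return An object of class `patch_params`.
#' @export
patch_params <- function(size = 50L, bg_mean = 0.30, bg_jitter = 0.11,
                         texture_amplitude = 0.12,
                         texture_corr = 8, radius_range = c(5, 10),
                         contrast = 0.45, edge_softness = 2,
                         malig_radius_mult = 1.5, malig_irregularity = 0.25,
                         malig_spicules = 6L) {
  stopifnot(size > 0, texture_amplitude >= 0, contrast > texture_amplitude,
            all(radius_range > 0), max(radius_range) < size / 2,
            edge_softness > 0, bg_jitter >= 0, bg_jitter < bg_mean)
  structure(list(size = as.integer(size), bg_mean = bg_mean,
                 bg_jitter = bg_jitter,
                 texture_amplitude = texture_amplitude,
                 texture_corr = texture_corr, radius_range = radius_range,
                 contrast = contrast, edge_softness = edge_softness,
                 malig_radius_mult = malig_radius_mult,
                 malig_irregularity = malig_irregularity,
                 malig_spicules = as.integer(malig_spicules)),
            class = "patch_params")
}

# Band-limited (low-pass filtered white) noise field with unit sd.
.texture_field <- function(nr, nc, corr, rng) {
  noise <- matrix(rng$rnorm(nr * nc), nr, nc)
  if (corr <= 0) return(noise)
  fr <- .fft_freqs(nr, 1); fc <- .fft_freqs(nc, 1)
  G <- exp(-2 * pi^2 * corr^2 * outer(fr^2, fc^2, `+`))
  sm <- Re(stats::fft(stats::fft(noise) * G, inverse = TRUE) / (nr * nc))
  s <- stats::sd(as.vector(sm))
  if (s > 0) sm / s else sm
}

# Soft-edged blob: 1 inside radius(theta), 0 outside, smoothstep edge.
.blob_mask <- function(nr, nc, center, radius_fun, softness) {
  ry <- seq_len(nr) - center[1]
  cx <- seq_len(nc) - center[2]
  dy <- matrix(ry, nr, nc)
  dx <- matrix(cx, nr, nc, byrow = TRUE)
  r <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  rad <- radius_fun(theta)
  t <- pmin(pmax((rad + softness - r) / (2 * softness), 0), 1)
  t * t * (3 - 2 * t)
}

.background <- function(nr, nc, params, rng, jitter = TRUE) {
  level <- params$bg_mean +
    if (jitter && params$bg_jitter > 0)
      rng$runif(1, -params$bg_jitter, params$bg_jitter) else 0
  img <- level +
    params$texture_amplitude * .texture_field(nr, nc, params$texture_corr, rng)
  pmin(pmax(img, 0), 1)
}

#' Generate one labeled nodule / background patch
#'
#' Background patches are textured noise around the mean gray level;
#' nodule patches additionally carry a soft-edged, radially symmetric
#' bright blob at the patch center with radius drawn from the configured
#' range. Deterministic given `seed`.
#'
#' @param params A [patch_params()].
#' @param label `"nodule"` or `"background"`.
#' @param seed Integer seed.
#' @return A `labeled_patch`: list with `image` (matrix in `[0, 1]`),
#'   `label` (1 = nodule), and `provenance` (label, seed).
#' @export
gen_patch <- function(params = patch_params(),
                      label = c("nodule", "background"), seed = 1L) {
  label <- match.arg(label)
  rng <- .seeded_rng(seed)
  n <- params$size
  img <- .background(n, n, params, rng)
  if (label == "nodule") {
    radius <- rng$runif(1, params$radius_range[1], params$radius_range[2])
    blob <- .blob_mask(n, n, c((n + 1) / 2, (n + 1) / 2),
                       function(theta) rep(radius, length(theta)),
                       params$edge_softness)
    img <- pmin(img + params$contrast * blob, 1)
  }
  structure(list(image = img, label = as.integer(label == "nodule"),
                 provenance = list(label = label, seed = seed)),
            class = "labeled_patch")
}

#' Generate one benign / malignant nodule patch
#'
#' Benign nodules are small smooth blobs; malignant nodules are larger
#' (radius multiplier), with a boundary modulated by seeded low-order
#' harmonics (irregularity) and radial spicules. Both classes share the
#' same background family. Label 1 = malignant.
#'
#' @inheritParams gen_patch
#' @param label `"benign"` or `"malignant"`.
#' @return A `labeled_patch` with `label` 0 (benign) or 1 (malignant).
#' @export
gen_benign_malignant <- function(params = patch_params(),
                                 label = c("benign", "malignant"), seed = 1L) {
  label <- match.arg(label)
  rng <- .seeded_rng(seed)
  n <- params$size
  img <- .background(n, n, params, rng)
  base_r <- rng$runif(1, params$radius_range[1], params$radius_range[2])
  if (label == "benign") {
    radius_fun <- function(theta) rep(base_r, length(theta))
  } else {
    base_r <- base_r * params$malig_radius_mult
    nh <- 4L                                  # harmonics 2..5
    amp <- rng$rnorm(nh) * params$malig_irregularity / sqrt(nh)
    pha <- rng$runif(nh, 0, 2 * pi)
    ns <- params$malig_spicules
    sp_ang <- if (ns > 0) rng$runif(ns, 0, 2 * pi) else numeric(0)
    sp_len <- if (ns > 0) rng$runif(ns, 0.3, 0.6) * base_r else numeric(0)
    radius_fun <- function(theta) {
      r <- base_r * (1 + Reduce(`+`, lapply(seq_len(nh), function(h)
        amp[h] * cos((h + 1) * theta + pha[h])), rep(0, length(theta))))
      if (ns > 0) {
        for (s in seq_len(ns)) {
          d <- atan2(sin(theta - sp_ang[s]), cos(theta - sp_ang[s]))
          r <- r + sp_len[s] * exp(-(d / 0.12)^2)
        }
      }
      pmax(r, 1)
    }
  }
  blob <- .blob_mask(n, n, c((n + 1) / 2, (n + 1) / 2), radius_fun,
                     params$edge_softness)
  img <- pmin(img + params$contrast * blob, 1)
  structure(list(image = img, label = as.integer(label == "malignant"),
                 provenance = list(label = label, seed = seed)),
            class = "labeled_patch")
}

#' Generate a synthetic CT-like slice with planted nodules
#'
#' A textured background of the same family as [gen_patch()], shaded by
#' dark elliptical lung fields and crossed by a few bright streaks
#' (vessel-like), with `n_nodules` blobs planted at rejection-sampled
#' centers: every center is at least `margin` pixels from the border and
#' centers are pairwise at least `min_sep` pixels apart.
#'
#' @inheritParams gen_patch
#' @param H,W Slice height and width in pixels.
#' @param n_nodules Number of planted nodules (>= 0).
#' @param margin Minimum center distance from the border (default 25, half
#'   the scan window).
#' @param min_sep Minimum pairwise center distance (default 50, the scan
#'   window).
#' @return A `synthetic_slice`: list with `image` (H x W in `[0, 1]`) and
#'   `truth_centers` (matrix with columns `row`, `col`; zero rows when
#'   `n_nodules = 0`).
#' @export
gen_slice <- function(params = patch_params(), H = 256L, W = 256L,
                      n_nodules = 3L, seed = 1L, margin = 25, min_sep = 50) {
  stopifnot(H >= params$size, W >= params$size, n_nodules >= 0)
  rng <- .seeded_rng(seed)
  img <- .background(H, W, params, rng, jitter = FALSE)

  # dark lung-field shading: two smooth elliptical depressions
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (cx in c(0.3, 0.7)) {
    e <- exp(-(((yy - 0.5 * H) / (0.42 * H))^2 + ((xx - cx * W) / (0.26 * W))^2))
    img <- img * (1 - 0.25 * e)
  }
  # bright vessel-like streaks
  n_streak <- 4L
  for (s in seq_len(n_streak)) {
    r0 <- rng$runif(1, 0.1, 0.9) * H; c0 <- rng$runif(1, 0.1, 0.9) * W
    ang <- rng$runif(1, 0, pi)
    d <- abs((yy - r0) * cos(ang) - (xx - c0) * sin(ang))
    along <- abs((yy - r0) * sin(ang) + (xx - c0) * cos(ang))
    img <- img + 0.10 * exp(-(d / 1.5)^2) * (along < 0.25 * min(H, W))
  }
  img <- pmin(pmax(img, 0), 1)

  centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  tries <- 0
  while (nrow(centers) < n_nodules) {
    cand <- c(rng$runif(1, margin + 1, H - margin),
              rng$runif(1, margin + 1, W - margin))
    cand <- round(cand)
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep)) {
      centers <- rbind(centers, cand)
    }
    tries <- tries + 1
    if (tries > 10000) stop("could not place nodules with the separation constraints")
  }
  for (i in seq_len(n_nodules)) {
    radius <- rng$runif(1, params$radius_range[1], params$radius_range[2])
    blob <- .blob_mask(H, W, centers[i, ],
                       function(theta) rep(radius, length(theta)),
                       params$edge_softness)
    img <- pmin(img + params$contrast * blob, 1)
  }
  dimnames(centers) <- list(NULL, c("row", "col"))
  structure(list(image = img, truth_centers = centers),
            class = "synthetic_slice")
}

#' Dihedral-group augmentation of a square patch
#'
#' Returns the 8 variants generated by the 4 right-angle rotations and the
#' horizontal flip, original first; labels are preserved by the caller.
#'
#' @param image Square numeric matrix (or a `labeled_patch`).
#' @return List of 8 matrices (or 8 `labeled_patch` objects).
#' @export
augment <- function(image) {
  if (inherits(image, "labeled_patch")) {
    ims <- augment(image$image)
    return(lapply(ims, function(m) {
      p <- image; p$image <- m; p
    }))
  }
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  fliph <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  out <- vector("list", 8L)
  cur <- image
  for (k in 0:3) {
    out[[2 * k + 1]] <- cur
    out[[2 * k + 2]] <- fliph(cur)
    cur <- rot90(cur)
  }
  out
}

#' Nearest-neighbor (pixel replication) upsampling
#'
#' Replicates each source pixel into a `k` x `k` block where
#' `k = target_n / n`; the value set is preserved exactly and
#' block-subsampling at stride `k` recovers the original.
#'
#' @param image Square numeric matrix.
#' @param target_n Target side; must be an integer multiple of the source
#'   side.
#' @return `target_n` x `target_n` matrix.
#' @export
resize_nearest <- function(image, target_n) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  if (target_n %% n != 0) stop("target_n must be an integer multiple of the source side")
  k <- target_n %/% n
  if (k == 1L) return(image)
  image[rep(seq_len(n), each = k), rep(seq_len(n), each = k)]
}

#' Generate a labeled synthetic patch dataset
#'
#' Convenience wrapper drawing `n_pos` positive and `n_neg` negative
#' patches with per-item child seeds derived from `seed`; each patch gets
#' its own case id.
#'
#' @param n_pos,n_neg Patch counts per class.
#' @param params A [patch_params()].
#' @param task `"detection"` (nodule vs background) or `"classification"`
#'   (malignant vs benign).
#' @param seed Integer master seed.
#' @return List with `images` (list of matrices), `labels` (0/1 vector) and
#'   `case_ids`.
#' @export
gen_dataset <- function(n_pos, n_neg, params = patch_params(),
                        task = c("detection", "classification"), seed = 1L) {
  task <- match.arg(task)
  gen <- function(lbl, i) {
    s <- .child_seed(seed, paste0(lbl, i))
    if (task == "detection") gen_patch(params, lbl, s)
    else gen_benign_malignant(params, lbl, s)
  }
  poslab <- if (task == "detection") "nodule" else "malignant"
  neglab <- if (task == "detection") "background" else "benign"
  patches <- c(lapply(seq_len(n_pos), function(i) gen(poslab, i)),
               lapply(seq_len(n_neg), function(i) gen(neglab, i)))
  list(images = lapply(patches, `[[`, "image"),
       labels = vapply(patches, `[[`, integer(1), "label"),
       case_ids = sprintf("case%05d", seq_along(patches)))
}
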