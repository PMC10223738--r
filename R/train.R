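#' Training hyperparameters
#'
#' Defaults follow the reference setup: batch size 64, 120 epochs, learning
#' rate 0.005 for the detection task and 0.001 for classification (pass
#' `learning_rate = NULL` to pick the task default), adaptive-moment
#' gradient descent.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate Step size, or `NULL` for the task default.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling shuffling (and recorded in run
#'   manifests).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param train_bias Detection only: learn the normalization biases
#'   `b0`, `b1` (softplus-parameterized, initialized at 0.01).
#' @param alpha Classification only: target scale of the MSE loss.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(batch_size = 64L, learning_rate = NULL, epochs = 120L,
                        seed = 1L, optimizer = c("adam", "sgd"),
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        train_bias = TRUE, alpha = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, epochs >= 0, alpha > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), optimizer = optimizer,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 train_bias = isTRUE(train_bias), alpha = alpha),
            class = "hyperparams")
}

.task_lr <- function(task) if (task == "detection") 0.005 else 0.001

# --- loss head: normalized readout + loss + gradient w.r.t. raw readouts ---

# Returns list(loss, gA = dL/dA, gb = dL/db (detection, length 2) ).
.loss_head <- function(A, label_onehot, task, b = c(0, 0), alpha = 1) {
  if (task == "detection") {
    S <- sum(A) + sum(b)
    Ap <- A / S
    z <- Ap - max(Ap)
    p <- exp(z) / sum(exp(z))
    loss <- -sum(label_onehot * (z - log(sum(exp(z)))))
    gAp <- p - label_onehot
    common <- sum(gAp * A) / S^2
    gA <- gAp / S - common
    gb <- c(-common, -common)
  } else {
    M <- max(A)
    m <- which.max(A)
    Ap <- alpha * A / M
    loss <- sum((Ap - alpha * label_onehot)^2)
    gAp <- 2 * (Ap - alpha * label_onehot)
    gA <- alpha * gAp / M
    gA[m] <- gA[m] - (alpha / M^2) * sum(gAp * A)
    gb <- c(0, 0)
  }
  list(loss = loss, gA = gA, gb = gb)
}

# --- backpropagation through the optical model -----------------------------

# Wirtinger cogradient D = dL/du transported backward through one
# propagation: transpose of (crop o IFFT o H o FFT o pad).
.bp_propagate <- function(D, grid, dz, pad_factor) {
  Conj(.asm_core(Conj(D), grid, -dz, pad_factor))
}

# Full loss + gradients for one (image, label) pair.
# Returns list(loss, gphase = list, gamp = list, gb = c(.,.), A = readout).
.loss_and_grad <- function(network, image, label, task, b = c(0, 0), alpha = 1) {
  cfg <- network$config
  tape <- .forward_tape(network, image)
  f <- tape$detector
  mode <- cfg$detector_layout$readout_mode
  m <- Mod(f)
  A <- vapply(cfg$detector_layout$regions,
              function(r) if (mode == "intensity")
                sum(m[r[1]:r[2], r[3]:r[4]]^2)
              else sum(m[r[1]:r[2], r[3]:r[4]]), numeric(1))
  y <- c(label == 0, label == 1) + 0
  head <- .loss_head(A, y, task, b, alpha)

  # dL/df on the detector plane (Wirtinger derivative w.r.t. f)
  D <- matrix(0 + 0i, cfg$network_size, cfg$network_size)
  for (i in seq_along(cfg$detector_layout$regions)) {
    r <- cfg$detector_layout$regions[[i]]
    sub <- f[r[1]:r[2], r[3]:r[4]]
    if (mode == "intensity") {
      D[r[1]:r[2], r[3]:r[4]] <- head$gA[i] * Conj(sub)
    } else {
      msub <- Mod(sub)
      g <- matrix(0 + 0i, nrow(sub), ncol(sub))
      nz <- msub > 0
      g[nz] <- head$gA[i] * Conj(sub[nz]) / (2 * msub[nz])
      D[r[1]:r[2], r[3]:r[4]] <- g
    }
  }

  L <- cfg$num_layers
  gphase <- vector("list", L)
  gamp <- vector("list", L)
  D <- .bp_propagate(D, cfg$grid, cfg$dz, cfg$pad_factor)
  for (l in rev(seq_len(L))) {
    lay <- network$layers[[l]]
    post <- tape$post[[l]]
    # real-parameter gradients: dL/dx = 2 Re(D * du/dx)
    gphase[[l]] <- -2 * Im(D * post)
    gamp[[l]] <- 2 * Re(D * exp(1i * lay$phase) * tape$pre[[l]])
    D <- .layer_t(lay) * D
    D <- .bp_propagate(D, cfg$grid, cfg$dz, cfg$pad_factor)
  }
  list(loss = head$loss, gphase = gphase, gamp = gamp, gb = head$gb, A = A)
}

#' Check analytic gradients against central finite differences
#'
#' Perturbs a random sample of layer-phase pixels by `+/- step` and compares
#' the analytic gradient of the task loss with the central finite-difference
#' quotient.
#'
#' @param network A [d2nn_network()].
#' @param image Network-sized input image.
#' @param label Binary label (0/1).
#' @param task `"detection"` or `"classification"`.
#' @param n_probe Number of randomly probed phase pixels.
#' @param step Finite-difference step in radians.
#' @param seed Seed for the probe selection.
#' @return List with `rel_err` (max relative error over probes), `analytic`
#'   and `numeric` gradient samples.
#' @export
gradient_check <- function(network, image, label, task = "detection",
                           n_probe = 6L, step = 1e-4, seed = 1L) {
  b <- c(0.01, 0.01)
  g <- .loss_and_grad(network, image, label, task, b)
  rng <- .seeded_rng(seed)
  n <- network$config$network_size
  L <- network$config$num_layers
  analytic <- numeric(0); numeric_ <- numeric(0)
  for (p in seq_len(n_probe)) {
    l <- rng$rint(1, L)
    ij <- rng$rint(2, n)
    pert <- function(h) {
      net2 <- network
      net2$layers[[l]]$phase[ij[1], ij[2]] <-
        net2$layers[[l]]$phase[ij[1], ij[2]] + h
      .loss_and_grad(net2, image, label, task, b)$loss
    }
    fd <- (pert(step) - pert(-step)) / (2 * step)
    analytic <- c(analytic, g$gphase[[l]][ij[1], ij[2]])
    numeric_ <- c(numeric_, fd)
  }
  denom <- pmax(abs(numeric_), 1e-12)
  list(rel_err = max(abs(analytic - numeric_) / denom),
       analytic = analytic, numeric = numeric_)
}

# --- dataset plumbing ------------------------------------------------------

# Standardize a dataset to network-sized images.
.prep_images <- function(images, cfg) {
  lapply(images, function(im) {
    if (all(dim(im) == cfg$network_size)) im
    else resize_nearest(im, cfg$network_size)
  })
}

#' Evaluate a network on labeled patches
#'
#' Runs the forward model on every image and returns predicted classes and
#' positive-class scores (detection normalization with the supplied biases).
#'
#' @param network A [d2nn_network()].
#' @param images List of image matrices (input-sized or network-sized).
#' @param b0,b1 Detection normalization biases.
#' @return A data.frame with columns `pred` and `score` (positive-class
#'   probability).
#' @export
evaluate_patches <- function(network, images, b0 = 0.01, b1 = 0.01) {
  cfg <- network$config
  images <- .prep_images(images, cfg)
  res <- lapply(images, function(im) {
    f <- forward_field(network, im)
    A <- read_detectors(f, cfg$detector_layout)
    s <- nodule_score(normalize_detection(A, b0, b1))
    c(pred = predict_class(A), score = s[2])
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("pred", "score")
  out
}

#' Train a diffractive network by backpropagation through the optics
#'
#' Minibatch gradient optimization of the task loss -- softmax cross-entropy
#' on the bias-normalized readout for `"detection"`, mean square error on
#' the alpha-normalized readout for `"classification"` -- over the layer
#' phases (and amplitudes in `"phase+amplitude"` mode, and the detection
#' biases `b0`, `b1` when `train_bias` is set). Fully reproducible given
#' the hyperparameter seed.
#'
#' @param network A [d2nn_network()].
#' @param train,val Datasets: lists with elements `images` (list of
#'   matrices in `[0, 1]`, either `input_size` or `network_size` per side)
#'   and `labels` (0/1 vector).
#' @param hyper A [hyperparams()].
#' @param task `"detection"` or `"classification"`.
#' @param verbose Print one line per epoch.
#' @return List of class `d2nn_fit`: `network` (trained), `b` (learned
#'   biases), `history` (data.frame epoch/train_loss/val_accuracy),
#'   `task`, `hyper`.
#' @export
train_d2nn <- function(network, train, val, hyper = hyperparams(),
                       task = c("detection", "classification"),
                       verbose = FALSE) {
  task <- match.arg(task)
  stopifnot(inherits(network, "d2nn"), inherits(hyper, "hyperparams"))
  if (length(train$images) == 0L) stop("empty training set")
  cfg <- network$config
  lr <- if (is.null(hyper$learning_rate)) .task_lr(task) else hyper$learning_rate
  tr_im <- .prep_images(train$images, cfg)
  tr_lab <- as.integer(train$labels)
  va_im <- .prep_images(val$images, cfg)
  va_lab <- as.integer(val$labels)

  L <- cfg$num_layers
  n <- cfg$network_size
  train_amp <- cfg$modulation_mode == "phase+amplitude"
  # unconstrained parameters: phase as-is; amplitude via logistic squash;
  # biases via softplus (b = log(1 + exp(beta)), init b = 0.01)
  amp_rho <- if (train_amp)
    lapply(network$layers, function(l)
      stats::qlogis(pmin(pmax(l$amplitude, 1e-6), 1 - 1e-6)))
  else NULL
  beta_b <- rep(log(expm1(0.01)), 2)
  b_cur <- function() log1p(exp(beta_b))

  # Adam state
  zero <- function() matrix(0, n, n)
  m_ph <- lapply(seq_len(L), function(i) zero()); v_ph <- lapply(seq_len(L), function(i) zero())
  m_am <- if (train_amp) lapply(seq_len(L), function(i) zero()) else NULL
  v_am <- if (train_amp) lapply(seq_len(L), function(i) zero()) else NULL
  m_b <- c(0, 0); v_b <- c(0, 0)
  tstep <- 0

  rng <- .seeded_rng(hyper$seed)
  ntr <- length(tr_im)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))

  val_acc <- function() {
    if (length(va_im) == 0L) return(NA_real_)
    preds <- vapply(va_im, function(im) {
      f <- forward_field(network, im)
      predict_class(read_detectors(f, cfg$detector_layout))
    }, integer(1))
    mean(preds == va_lab)
  }

  for (epoch in seq_len(hyper$epochs)) {
    ord <- rng$sample(ntr)
    batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      acc_ph <- lapply(seq_len(L), function(i) zero())
      acc_am <- if (train_amp) lapply(seq_len(L), function(i) zero()) else NULL
      acc_b <- c(0, 0)
      bl <- 0
      b <- if (task == "detection") b_cur() else c(0, 0)
      for (idx in batch) {
        g <- .loss_and_grad(network, tr_im[[idx]], tr_lab[idx], task,
                            b, hyper$alpha)
        if (!is.finite(g$loss))
          stop("NaN/Inf loss at epoch ", epoch, " sample ", idx,
               "; readouts: ", paste(signif(g$A, 4), collapse = ", "))
        bl <- bl + g$loss
        for (l in seq_len(L)) {
          acc_ph[[l]] <- acc_ph[[l]] + g$gphase[[l]]
          if (train_amp) acc_am[[l]] <- acc_am[[l]] + g$gamp[[l]]
        }
        acc_b <- acc_b + g$gb
      }
      nb <- length(batch)
      ep_loss <- ep_loss + bl
      tstep <- tstep + 1
      adam <- function(m, v, grad) {
        m <- hyper$beta1 * m + (1 - hyper$beta1) * grad
        v <- hyper$beta2 * v + (1 - hyper$beta2) * grad^2
        mh <- m / (1 - hyper$beta1^tstep)
        vh <- v / (1 - hyper$beta2^tstep)
        list(m = m, v = v, step = mh / (sqrt(vh) + hyper$eps))
      }
      for (l in seq_len(L)) {
        gph <- acc_ph[[l]] / nb
        if (hyper$optimizer == "adam") {
          st <- adam(m_ph[[l]], v_ph[[l]], gph)
          m_ph[[l]] <- st$m; v_ph[[l]] <- st$v
          network$layers[[l]]$phase <- network$layers[[l]]$phase - lr * st$step
        } else {
          network$layers[[l]]$phase <- network$layers[[l]]$phase - lr * gph
        }
        if (train_amp) {
          a <- network$layers[[l]]$amplitude
          grho <- (acc_am[[l]] / nb) * a * (1 - a)   # chain through squash
          if (hyper$optimizer == "adam") {
            st <- adam(m_am[[l]], v_am[[l]], grho)
            m_am[[l]] <- st$m; v_am[[l]] <- st$v
            amp_rho[[l]] <- amp_rho[[l]] - lr * st$step
          } else amp_rho[[l]] <- amp_rho[[l]] - lr * grho
          network$layers[[l]]$amplitude <- stats::plogis(amp_rho[[l]])
        }
      }
      if (task == "detection" && hyper$train_bias) {
        gbeta <- acc_b / nb * stats::plogis(beta_b)  # softplus chain
        if (hyper$optimizer == "adam") {
          m_b <- hyper$beta1 * m_b + (1 - hyper$beta1) * gbeta
          v_b <- hyper$beta2 * v_b + (1 - hyper$beta2) * gbeta^2
          beta_b <- beta_b - lr * (m_b / (1 - hyper$beta1^tstep)) /
            (sqrt(v_b / (1 - hyper$beta2^tstep)) + hyper$eps)
        } else beta_b <- beta_b - lr * gbeta
      }
    }
    acc <- val_acc()
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / ntr,
                                         val_accuracy = acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val acc %s", epoch,
                      ep_loss / ntr,
                      ifelse(is.na(acc), "-", sprintf("%.3f", acc))))
  }
  structure(list(network = network, b = b_cur(), history = history,
                 task = task, hyper = hyper),
            class = "d2nn_fit")
}

#' @export
print.d2nn_fit <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  cat(sprintf("d2nn_fit (%s): %d epochs, final train loss %.5f, val accuracy %s\n",
              x$task, nrow(x$history),
              if (nrow(x$history)) last$train_loss else NA,
              if (nrow(x$history) && !is.na(last$val_accuracy))
                sprintf("%.3f", last$val_accuracy) else "-"))
  invisible(x)
}
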