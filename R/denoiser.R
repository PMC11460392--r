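# Nonexpansive residual denoiser. A stack of zero-padded stride-1
# convolutions with ReLU between them estimates the noise field of its
# input; the denoiser map is D(X) = X - net(X). After every optimizer step
# each convolution is rescaled so its operator norm (estimated by power
# iteration on the full convolution operator at training image size) stays
# <= 1, the layerwise route to a nonexpansive network. Because the residual
# subtraction X - net(X) is not covered by the layerwise bound, the
# end-to-end Lipschitz constant is audited empirically (estimate_lipschitz)
# and recorded rather than assumed.

#' Denoiser architecture specification
#'
#' @param depth number of convolutional layers (>= 3). ReLU follows every
#'   layer except the last.
#' @param width channels in the hidden layers (>= 8).
#' @param kernel odd spatial kernel size.
#' @param power_iterations power-iteration steps per spectral-normalization
#'   call during training (warm-started, so few are needed).
#' @return a `denoiser_spec`.
#' @export
denoiser_spec <- function(depth = 7, width = 32, kernel = 3,
                          power_iterations = 3) {
  if (depth < 3) stopf("depth must be >= 3")
  if (width < 8) stopf("width must be >= 8")
  if (kernel %% 2 != 1) stopf("kernel size must be odd")
  if (power_iterations < 1) stopf("power_iterations must be >= 1")
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 kernel = as.integer(kernel),
                 power_iterations = as.integer(power_iterations)),
            class = "denoiser_spec")
}

#' Training configuration for the denoiser
#'
#' @param epochs passes over the training set (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size images per optimizer step.
#' @param noise_sigma Gaussian noise level on the 0-255 intensity scale
#'   (the corpus convention); the stored pairs are on [0, 1].
#' @param seed seed for the train/validation split, shuffling and
#'   initialization.
#' @return a `training_config`.
#' @export
training_config <- function(epochs = 3, learning_rate = 1e-3,
                            batch_size = 16, noise_sigma = 15, seed = 1) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (noise_sigma < 0) stopf("noise_sigma must be nonnegative")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "training_config")
}

#' Build an untrained denoiser
#'
#' He-initialized hidden layers; the final layer is zero-initialized so the
#' residual estimate is exactly zero at initialization, i.e. D(X) = X.
#'
#' @param spec a `denoiser_spec`.
#' @param seed initialization seed.
#' @return a `denoiser_model` (untrained).
#' @export
build_denoiser <- function(spec, seed = 1) {
  if (!inherits(spec, "denoiser_spec")) stopf("spec must be a denoiser_spec")
  k <- spec$kernel
  chans <- c(1L, rep(spec$width, spec$depth - 1L), 1L)
  layers <- with_seed(seed, lapply(seq_len(spec$depth), function(l) {
    cin <- chans[l]; cout <- chans[l + 1]
    fan_in <- cin * k * k
    w <- if (l == spec$depth) matrix(0, fan_in, cout)
         else matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                     fan_in, cout)
    list(w = w, b = numeric(cout), cin = cin, cout = cout,
         sn_v = NULL, sn_sigma = NA_real_)
  }))
  structure(list(spec = spec, layers = layers, trained = FALSE,
                 config = NULL, val_mse = NA_real_, audit = NULL,
                 init_seed = as.integer(seed)),
            class = "denoiser_model")
}

#' @export
print.denoiser_model <- function(x, ...) {
  cat(sprintf(
    "<denoiser_model depth=%d width=%d kernel=%d, %strained%s>\n",
    x$spec$depth, x$spec$width, x$spec$kernel,
    if (x$trained) "" else "un",
    if (is.finite(x$val_mse)) sprintf(", val_mse=%.3e", x$val_mse) else ""))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Residual (noise) estimate for one H x W image (single-precision
# whole-network kernel).
net_forward <- function(model, x) {
  cpp_net_forward(x, lapply(model$layers, `[[`, "w"),
                  lapply(model$layers, function(l) as.numeric(l$b)),
                  model$spec$kernel)
}

#' Apply the denoiser to a real image
#'
#' @param model `denoiser_model`.
#' @param x numeric matrix (the training range is `[0, 1]`).
#' @return denoised matrix `x - net(x)`.
#' @export
denoise_image <- function(model, x) x - net_forward(model, x)

# Power iteration on one convolution layer's operator at image size
# `size`; returns list(sigma, v) with v the warm-started right vector.
layer_spectral_norm <- function(lay, k, size, n_iter, v = NULL, tol = 0.02) {
  if (!is.null(v) && length(v) != size * size * lay$cin) v <- NULL
  if (is.null(v)) {
    # cold start: no warm vector yet, spend more iterations
    n_iter <- max(n_iter, 15L)
    v <- rnorm(size * size * lay$cin)
  }
  out <- cpp_power_iter(lay$w, lay$cin, k, size, n_iter, as.numeric(v))
  list(sigma = out$sigma, v = out$v, converged = out$delta <= tol)
}

#' Spectrally normalize every layer
#'
#' Estimates each convolution's operator norm by power iteration on the
#' full (zero-padded) convolution operator at image size `size` and divides
#' the weights by the norm wherever it exceeds 1, so every layer ends with
#' operator norm <= 1; layers already inside the unit ball are left alone.
#' Warm-started singular vectors are stored on the layers, so repeated
#' calls (once per optimizer step during training) are cheap.
#'
#' @param model `denoiser_model`.
#' @param size image size at which the operator norm is measured.
#' @param n_iter power-iteration count (defaults to the spec value).
#' @param strict warn and apply a conservative extra division when the
#'   power iteration has not settled within its budget. The per-step
#'   normalization during training disables this (warm-started estimates
#'   settle across steps, and the end-of-training pass guarantees the
#'   bound); explicit calls keep it.
#' @return the model with rescaled weights and recorded `sn_sigma` per
#'   layer (the norm measured before rescaling).
#' @export
spectral_normalize <- function(model, size = 128, n_iter = NULL,
                               strict = TRUE) {
  k <- model$spec$kernel
  if (is.null(n_iter)) n_iter <- model$spec$power_iterations
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    sn <- layer_spectral_norm(lay, k, size, n_iter, v = lay$sn_v)
    if (strict && !sn$converged && sn$sigma > 1) {
      warning(sprintf(
        "power iteration for layer %d not converged after %d steps; applying conservative extra rescale",
        l, n_iter), call. = FALSE)
      sn$sigma <- sn$sigma * 1.05
    }
    if (sn$sigma > 1) model$layers[[l]]$w <- lay$w / sn$sigma
    model$layers[[l]]$sn_v <- sn$v
    model$layers[[l]]$sn_sigma <- sn$sigma
  }
  model
}

#' Measured operator norm of every layer
#'
#' Fresh, thoroughly converged power iteration per layer (no warm start,
#' many iterations); used by tests and the audit.
#'
#' @inheritParams spectral_normalize
#' @return numeric vector of per-layer operator norms.
#' @export
layer_norms <- function(model, size = 64, n_iter = 50) {
  k <- model$spec$kernel
  vapply(model$layers, function(lay)
    layer_spectral_norm(lay, k, size, n_iter)$sigma, numeric(1))
}


#' Train the denoiser on noisy/clean pairs
#'
#' Minimizes the mean squared error between the network output and the
#' noise field `X - Y` over the training split (90/10 train/validation,
#' seeded), with Adam, applying [spectral_normalize()] after every
#' optimizer step. Pairs must be on the `[0, 1]` intensity scale. Fully
#' deterministic given the config seed.
#'
#' @param model an untrained (or previously trained) `denoiser_model`.
#' @param dataset list of `training_pair`s (see [build_training_dataset()]).
#' @param config a `training_config`.
#' @return trained `denoiser_model` with `val_mse` (held-out MSE of D(X)
#'   against Y) and the per-epoch loss trace in `history`.
#' @export
train_denoiser <- function(model, dataset, config) {
  if (length(dataset) == 0) stopf("training dataset is empty")
  size <- nrow(dataset[[1]]$clean)
  n <- length(dataset)
  idx <- with_seed(config$seed, sample.int(n))
  n_val <- max(1L, floor(0.1 * n))
  val_ids <- idx[seq_len(n_val)]
  train_ids <- idx[-seq_len(n_val)]
  if (!length(train_ids)) stopf("dataset too small for a train/val split")

  L <- length(model$layers)
  adam <- lapply(model$layers, function(lay)
    list(mw = lay$w * 0, vw = lay$w * 0,
         mb = numeric(lay$cout), vb = numeric(lay$cout)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  lr <- config$learning_rate
  history <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    order <- with_seed(config$seed + 1000L * ep, sample(train_ids))
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    ep_loss <- 0; ep_px <- 0
    for (batch in batches) {
      bk <- cpp_net_backward_batch(
        lapply(batch, function(id) dataset[[id]]$noisy),
        lapply(batch, function(id) dataset[[id]]$clean),
        lapply(model$layers, `[[`, "w"),
        lapply(model$layers, function(l) as.numeric(l$b)),
        model$spec$kernel)
      npix <- length(batch) * size * size
      if (!is.finite(bk$loss))
        stopf("training aborted: non-finite loss at epoch %d", ep)
      ep_loss <- ep_loss + bk$loss; ep_px <- ep_px + npix
      t_step <- t_step + 1L
      for (l in seq_len(L)) {
        gw <- bk$gw[[l]] / npix; gb <- as.numeric(bk$gb[[l]]) / npix
        adam[[l]]$mw <- b1 * adam[[l]]$mw + (1 - b1) * gw
        adam[[l]]$vw <- b2 * adam[[l]]$vw + (1 - b2) * gw^2
        adam[[l]]$mb <- b1 * adam[[l]]$mb + (1 - b1) * gb
        adam[[l]]$vb <- b2 * adam[[l]]$vb + (1 - b2) * gb^2
        mhat_w <- adam[[l]]$mw / (1 - b1^t_step)
        vhat_w <- adam[[l]]$vw / (1 - b2^t_step)
        mhat_b <- adam[[l]]$mb / (1 - b1^t_step)
        vhat_b <- adam[[l]]$vb / (1 - b2^t_step)
        model$layers[[l]]$w <- model$layers[[l]]$w -
          lr * mhat_w / (sqrt(vhat_w) + eps)
        model$layers[[l]]$b <- model$layers[[l]]$b -
          lr * mhat_b / (sqrt(vhat_b) + eps)
      }
      model <- with_seed(config$seed + 7L * t_step,
                         spectral_normalize(model, size = size,
                                            strict = FALSE))
    }
    history[ep] <- ep_loss / ep_px
  }
  # final thorough normalization: iterate fresh, well-converged estimates
  # until every measured layer norm sits inside the unit ball, with a
  # small margin absorbing the power-iteration estimation noise
  model <- with_seed(config$seed, {
    for (round in 1:4) {
      nrm <- layer_norms(model, size = size, n_iter = 60)
      if (all(nrm <= 1 - 5e-4)) break
      for (l in which(nrm > 1 - 5e-4))
        model$layers[[l]]$w <- model$layers[[l]]$w * (1 - 5e-4) / nrm[l]
    }
    model
  })
  val_mse <- mean(vapply(val_ids, function(id) {
    pr <- dataset[[id]]
    mean((denoise_image(model, pr$noisy) - pr$clean)^2)
  }, numeric(1)))
  model$trained <- TRUE
  model$config <- config
  model$val_mse <- val_mse
  model$history <- history
  model$val_ids <- val_ids
  model
}

#' Denoise a complex field part-by-part
#'
#' Applies the real-image denoiser to the real and imaginary parts
#' separately -- never to amplitude/phase, which would be exposed to phase
#' wrapping. Each part is affinely mapped from its own min/max onto
#' [0.1, 0.9] (a margin inside the training range) before the network and
#' inverse-mapped after; a part with (near-)degenerate range bypasses the
#' network unchanged.
#'
#' @param O complex matrix.
#' @param model trained `denoiser_model`.
#' @return complex matrix of the same shape.
#' @export
denoise_complex <- function(O, model) {
  part <- function(x) {
    lo <- min(x); hi <- max(x)
    if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12 * max(1, abs(hi)))
      return(x)
    u <- 0.1 + 0.8 * (x - lo) / (hi - lo)
    d <- denoise_image(model, u)
    lo + (d - 0.1) * (hi - lo) / 0.8
  }
  complex(real = part(Re(O)), imaginary = part(Im(O))) |>
    matrix(nrow = nrow(O))
}

#' Identity denoiser
#'
#' Pluggable stand-in: leaves any field unchanged, so the PINE relaxation
#' collapses and the loop is testable without training.
#'
#' @return a function of one matrix argument.
#' @export
identity_denoiser <- function() function(O) O

#' Gaussian-blur denoiser
#'
#' Pluggable classical smoother: Fourier-domain Gaussian low-pass with
#' standard deviation `sigma` pixels, applied linearly (works on real and
#' complex fields alike).
#'
#' @param sigma blur standard deviation in pixels.
#' @return a function of one matrix argument.
#' @export
blur_denoiser <- function(sigma = 1) {
  function(O) {
    n <- nrow(O); m <- ncol(O)
    fx <- freq_index(n) / n; fy <- freq_index(m) / m
    G <- exp(-2 * pi^2 * sigma^2 * outer(fx^2, fy^2, "+"))
    out <- uifft2(ufft2(O) * G)
    if (is.complex(O)) out else Re(out)
  }
}

#' Empirical Lipschitz audit of a denoiser
#'
#' Maximum of `||D(x) - D(y)|| / ||x - y||` over `n_pairs` seeded random
#' image pairs on `[0, 1]`, alternating independent pairs with
#' adversarially close ones (`y = x + 1e-3 * noise`). The attaining pair
#' index and a flag for estimates above `1 + 1e-3` are attached as
#' attributes.
#'
#' @param model `denoiser_model` or a function on real matrices.
#' @param n_pairs number of probe pairs.
#' @param seed RNG seed.
#' @param size probe image size.
#' @return the Lipschitz estimate (attributes `pair`, `exceeds_one`).
#' @export
estimate_lipschitz <- function(model, n_pairs = 100, seed = 1, size = 64) {
  D <- if (is.function(model)) model else function(x) denoise_image(model, x)
  ratios <- with_seed(seed, vapply(seq_len(n_pairs), function(i) {
    x <- matrix(runif(size * size), size)
    y <- if (i %% 2 == 0) matrix(runif(size * size), size)
         else x + 1e-3 * matrix(rnorm(size * size), size)
    dxy <- sqrt(sum((x - y)^2))
    if (dxy == 0) return(0)
    sqrt(sum((D(x) - D(y))^2)) / dxy
  }, numeric(1)))
  out <- max(ratios)
  attr(out, "pair") <- which.max(ratios)
  attr(out, "exceeds_one") <- out > 1 + 1e-3
  out
}

#' Save / load a trained denoiser
#'
#' Single-file archive (RDS) holding weights, architecture spec, training
#' config and any recorded audit results.
#'
#' @param model `denoiser_model`.
#' @param path file path.
#' @export
save_denoiser <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "denoiser_model"))
    stopf("'%s' does not contain a denoiser_model", path)
  model
}
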