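# Formula-driven training corpus: dead-leaves images. Shapes (circles,
# triangles, rectangles) with power-law sizes are layered front-to-back --
# each new shape paints only still-uncovered pixels, the occlusion-
# equivalent of back-to-front stacking -- until the canvas is covered.
# "diverse" fills shapes with uniform random grays; "textured" fills them
# with oriented band-limited noise pushed through a random monotone tone
# curve. Rasterization and texturing work on each shape's bounding box
# only, so rendering stays fast at corpus scale.

# Power-law radius p(r) ~ r^-3 on [rmin, rmax] via inverse-CDF sampling:
# the classic scale-invariance choice for dead-leaves models.
sample_radius <- function(rmin, rmax) {
  u <- runif(1)
  1 / sqrt((1 - u) / rmin^2 + u / rmax^2)
}

# One random shape: kind, center, circumradius, orientation. Returns the
# bounding box (clipped to the canvas) and the logical mask inside it; all
# randomness comes from the current RNG stream.
draw_shape <- function(n) {
  kind <- sample(c("circle", "triangle", "rectangle"), 1)
  r <- sample_radius(4, n / 3)
  cx <- runif(1, 1, n); cy <- runif(1, 1, n)
  th <- runif(1, 0, 2 * pi)
  rb <- if (kind == "rectangle") r * sqrt(2) else r   # corner reach
  lo_i <- max(1L, floor(cx - rb)); hi_i <- min(n, ceiling(cx + rb))
  lo_j <- max(1L, floor(cy - rb)); hi_j <- min(n, ceiling(cy + rb))
  if (lo_i > hi_i || lo_j > hi_j) return(NULL)
  dx <- matrix((lo_i:hi_i) - cx, hi_i - lo_i + 1, hi_j - lo_j + 1)
  dy <- matrix((lo_j:hi_j) - cy, hi_i - lo_i + 1, hi_j - lo_j + 1,
               byrow = TRUE)
  mask <- if (kind == "circle") {
    dx^2 + dy^2 <= r^2
  } else if (kind == "rectangle") {
    asp <- runif(1, 0.3, 1)
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    abs(u) <= r & abs(v) <= asp * r
  } else {
    ang <- th + c(0, 2 * pi / 3, 4 * pi / 3)
    vx <- r * cos(ang); vy <- r * sin(ang)
    s1 <- (vx[2] - vx[1]) * (dy - vy[1]) - (vy[2] - vy[1]) * (dx - vx[1])
    s2 <- (vx[3] - vx[2]) * (dy - vy[2]) - (vy[3] - vy[2]) * (dx - vx[2])
    s3 <- (vx[1] - vx[3]) * (dy - vy[3]) - (vy[1] - vy[3]) * (dx - vx[3])
    (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  list(rows = lo_i:hi_i, cols = lo_j:hi_j, mask = mask)
}

# Oriented band-limited texture on an nr x nc patch: white noise low-passed
# by an anisotropic Gaussian aligned with a random orientation, rank-
# normalized to (0, 1), then a random monotone tone curve (gamma plus a
# random sub-range) compresses it around a random mean gray.
texture_patch <- function(nr, nc) {
  th <- runif(1, 0, pi)
  lam <- runif(1, 2, 12)               # correlation length along the grain
  noise <- matrix(rnorm(nr * nc), nr, nc)
  fr <- freq_index(nr) / nr; fc <- freq_index(nc) / nc
  fu <- outer(fr * cos(th), fc * sin(th), "+")
  fv <- outer(-fr * sin(th), fc * cos(th), "+")
  H <- exp(-2 * pi^2 * (lam^2 * fu^2 + (lam / 4)^2 * fv^2))
  t <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (nr * nc)
  t <- (rank(t) - 0.5) / length(t)
  g <- runif(1, 0.5, 2)
  lo <- runif(1, 0, 0.6); hi <- lo + runif(1, 0.25, 1 - lo)
  matrix(lo + (hi - lo) * t^g, nr, nc)
}

#' Render one dead-leaves image
#'
#' Draws random shapes until every pixel is covered (front-to-back, so
#' earlier shapes occlude later ones). Deterministic given the seed; values
#' lie in `[0, 1]`.
#'
#' @param kind `"diverse"` (uniform gray fills) or `"textured"`
#'   (band-limited noise fills).
#' @param size canvas size in pixels (>= 32).
#' @param seed RNG seed.
#' @param max_shapes shape budget before an error is raised.
#' @return numeric `size x size` matrix in `[0, 1]`.
#' @export
render_dead_leaves <- function(kind = c("diverse", "textured"), size = 128,
                               seed = 1, max_shapes = 10000) {
  kind <- match.arg(kind)
  if (size < 32) stopf("size must be >= 32")
  with_seed(seed, {
    img <- matrix(NA_real_, size, size)
    uncovered <- size * size
    shapes <- 0L
    while (uncovered > 0) {
      shapes <- shapes + 1L
      if (shapes > max_shapes)
        stopf("canvas not covered within %d shapes", max_shapes)
      sh <- draw_shape(size)
      if (is.null(sh)) next
      sub <- img[sh$rows, sh$cols, drop = FALSE]
      m <- sh$mask & is.na(sub)
      if (kind == "diverse") {
        fill <- runif(1)
        if (any(m)) sub[m] <- fill
      } else {
        tex <- texture_patch(length(sh$rows), length(sh$cols))
        if (any(m)) sub[m] <- tex[m]
      }
      if (any(m)) {
        img[sh$rows, sh$cols] <- sub
        uncovered <- uncovered - sum(m)
      }
    }
    img
  })
}

#' Noisy/clean training pair
#'
#' @param clean `[0, 1]` image.
#' @param noisy clean image plus Gaussian noise (unclipped float).
#' @param meta generator metadata.
#' @export
training_pair <- function(clean, noisy, meta = list()) {
  structure(list(clean = clean, noisy = noisy, meta = meta),
            class = "training_pair")
}

#' Build the synthetic denoising corpus
#'
#' `n_per_model` images from each of the two dead-leaves variants
#' (`2 * n_per_model` pairs in total). Noise is drawn once per image with
#' standard deviation `sigma` on the 0-255 scale, then both images are kept
#' on `[0, 1]` (noise sd `sigma / 255`), the convention of 8-bit corpora.
#' Per-image seeds are derived from `seed`, so the corpus is reproducible
#' and each image distinct.
#'
#' @param n_per_model images per variant (>= 1).
#' @param size canvas size.
#' @param sigma noise standard deviation on the 0-255 scale.
#' @param seed master seed.
#' @return list of `training_pair`s (diverse first, then textured).
#' @export
build_training_dataset <- function(n_per_model = 500, size = 128,
                                   sigma = 15, seed = 1) {
  if (n_per_model < 1) stopf("n_per_model must be >= 1")
  n_tot <- 2L * n_per_model
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n_tot))
  kinds <- rep(c("diverse", "textured"), each = n_per_model)
  lapply(seq_len(n_tot), function(i) {
    clean <- render_dead_leaves(kinds[i], size, seed = sub[i])
    noise <- with_seed(sub[n_tot + i],
                       matrix(rnorm(size * size, sd = sigma / 255), size))
    training_pair(clean, clean + noise,
                  meta = list(kind = kinds[i], seed = sub[i],
                              sigma = sigma, index = i))
  })
}
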