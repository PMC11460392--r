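# Reconstruction quality. Before any comparison the gauge ambiguity
# (O, P) -> (cO, P/c) must be removed and the reconstruction aligned to the
# truth; then Fourier ring correlation quantifies agreement per spatial
# frequency.

#' Register a reconstruction to the ground truth
#'
#' Three steps, in order: (i) periphery masking -- pixels whose accumulated
#' illumination falls below 1% of its maximum are set to vacuum (1+0i) in
#' both fields; (ii) gauge fix -- the closed-form least-squares complex
#' scalar `c = sum(truth * Conj(recon)) / sum(|recon|^2)` is applied to the
#' reconstruction, removing the amplitude-scale and phase-offset ambiguity;
#' (iii) subpixel alignment seeded by phase-only correlation: the
#' normalized cross-power spectrum is inverse-transformed and the peak
#' located (integer part, plus the one-sided sinc-ratio estimator
#' `delta = r1 / (r0 + r1)` for the fractional part, exact for a
#' sinc-shaped peak); the estimate is then polished by maximizing the
#' cross-correlation magnitude over fractional shifts in the Fourier
#' domain, and the shift applied by Fourier interpolation.
#'
#' @param recon reconstructed `object_field`.
#' @param truth true `object_field` (same shape and pixel size).
#' @param illum nonnegative illumination map (see [illumination_map()]);
#'   `NULL` skips masking.
#' @return registered `object_field`; attributes `gauge` (the applied
#'   complex scalar), `shift` (row/col, pixels) and `mask` (logical matrix
#'   of retained pixels).
#' @export
register_to_truth <- function(recon, truth, illum = NULL) {
  if (!all(dim(recon$values) == dim(truth$values)))
    stopf("recon and truth must share dimensions")
  rv <- recon$values; tv <- truth$values
  keep <- matrix(TRUE, nrow(rv), ncol(rv))
  if (!is.null(illum)) {
    if (max(illum) <= 0)
      stopf("registration impossible: every pixel masked (no illumination)")
    keep <- illum >= 0.01 * max(illum)
    if (!any(keep)) stopf("registration impossible: every pixel masked")
  }
  # gauge estimated from the kept pixels only: the masked periphery is
  # replaced by vacuum afterwards and must not pin the global phase
  denom <- sum(Mod(rv[keep])^2)
  if (denom == 0) stopf("registration impossible: empty reconstruction")
  cc <- sum(tv[keep] * Conj(rv[keep])) / denom
  rv <- cc * rv
  rv[!keep] <- 1 + 0i
  tv[!keep] <- 1 + 0i

  sh <- poc_shift(tv, rv)
  sh <- refine_shift(tv, rv, sh)
  rv <- fourier_shift(rv, sh)

  # re-fit the scalar on the aligned field (a fractional shift slightly
  # perturbs the first fit); near-1 when the initial gauge was right
  c2 <- sum(tv[keep] * Conj(rv[keep])) / sum(Mod(rv[keep])^2)
  rv <- c2 * rv

  out <- object_field(rv, pixel_size = recon$pixel_size)
  attr(out, "gauge") <- cc * c2
  attr(out, "shift") <- sh
  attr(out, "mask") <- keep
  out
}

# Polish the integer/ratio POC estimate by maximizing the correlation
# magnitude |sum(F(ref)* . F(moving) . ramp(s))| over fractional shifts --
# evaluated wholly in the Fourier domain, where the score is smooth in s
# and shift-invariant norms drop out.
refine_shift <- function(ref, moving, init) {
  n <- nrow(ref); m <- ncol(ref)
  X <- Conj(ufft2(ref)) * ufft2(moving)
  fx <- freq_index(n) / n; fy <- freq_index(m) / m
  FX <- outer(fx, rep(1, m)); FY <- outer(rep(1, n), fy)
  score <- function(s)
    -Mod(sum(X * exp(-2i * pi * (FX * s[1] + FY * s[2]))))
  opt <- stats::optim(init, score, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  opt$par
}

# Phase-only correlation shift estimate: shift to apply to `moving` so it
# aligns with `ref` (ref(x) ~= moving(x - s)).
poc_shift <- function(ref, moving) {
  n <- nrow(ref); m <- ncol(ref)
  q <- ufft2(ref) * Conj(ufft2(moving))
  mq <- Mod(q)
  nz <- mq > 1e-12 * max(mq)
  q[nz] <- q[nz] / mq[nz]
  q[!nz] <- 0
  r <- Re(uifft2(q))
  p <- which(r == max(r), arr.ind = TRUE)[1, ]
  subpx <- function(axis) {
    len <- if (axis == 1) n else m
    at <- function(d) {
      i <- p
      i[axis] <- ((i[axis] - 1 + d) %% len) + 1
      r[i[1], i[2]]
    }
    r0 <- at(0); rp <- at(1); rm <- at(-1)
    if (rp >= rm) {
      if (r0 + rp <= 0) 0 else rp / (r0 + rp)
    } else {
      if (r0 + rm <= 0) 0 else -rm / (r0 + rm)
    }
  }
  base <- p - 1
  base[1] <- if (base[1] > n / 2) base[1] - n else base[1]
  base[2] <- if (base[2] > m / 2) base[2] - m else base[2]
  unname(base + c(subpx(1), subpx(2)))
}

# Circularly shift an image by a possibly fractional (row, col) offset via
# a Fourier-domain phase ramp: out(x) = img(x - s).
fourier_shift <- function(img, shift) {
  n <- nrow(img); m <- ncol(img)
  fx <- freq_index(n) / n; fy <- freq_index(m) / m
  ramp <- exp(-2i * pi * (outer(fx * shift[1], fy * shift[2], "+")))
  out <- uifft2(ufft2(img) * ramp)
  if (is.complex(img)) out else Re(out)
}

#' Fourier ring correlation
#'
#' Per ring of (rounded) integer frequency radius up to Nyquist:
#' `Re(sum(F1 * Conj(F2))) / sqrt(sum|F1|^2 * sum|F2|^2)`, where F1/F2 are
#' the unitary Fourier transforms of the two fields. 1 means perfect
#' agreement at that spatial frequency, -1 a sign flip. Empty rings (none
#' exist with integer-radius binning, but coarser binnings can create them)
#' are marked `NA`, never silently zero.
#'
#' @param recon,truth `object_field`s (registered; same shape).
#' @param n_rings optional coarser ring count; the default bins by integer
#'   radius (one ring per frequency pixel), standard FRC practice.
#' @return an `frc_curve`: data.frame with `radius` (ring index), `freq`
#'   (cycles per length unit), `frac_nyquist`, `value`, `n_px`.
#' @export
frc <- function(recon, truth, n_rings = NULL) {
  if (!all(dim(recon$values) == dim(truth$values)))
    stopf("fields must share dimensions")
  n <- nrow(recon$values)
  F1 <- ufft2(recon$values)
  F2 <- ufft2(truth$values)
  f <- freq_index(n)
  rad <- round(sqrt(outer(f^2, f^2, "+")))
  nyq <- n %/% 2
  if (is.null(n_rings)) {
    ring_of <- rad
    radii <- 0:nyq
  } else {
    width <- nyq / n_rings
    ring_of <- pmin(ceiling(rad / width), n_rings)
    radii <- c(0, (seq_len(n_rings) - 0.5) * width)
  }
  keep <- rad <= nyq
  fac <- factor(ring_of[keep], levels = 0:(length(radii) - 1))
  num <- tapply(Re(F1[keep] * Conj(F2[keep])), fac, sum)
  d1 <- tapply(Mod(F1[keep])^2, fac, sum)
  d2 <- tapply(Mod(F2[keep])^2, fac, sum)
  npx <- tapply(rep(1, sum(keep)), fac, sum)
  den <- sqrt(d1 * d2)
  val <- ifelse(is.na(npx) | den == 0, NA_real_, num / den)
  px <- recon$pixel_size
  curve <- data.frame(radius = radii,
                      freq = radii / (n * px),
                      frac_nyquist = radii / nyq,
                      value = as.numeric(val),
                      n_px = as.integer(ifelse(is.na(npx), 0L, npx)))
  class(curve) <- c("frc_curve", "data.frame")
  attr(curve, "nyquist") <- 1 / (2 * px)
  curve
}

#' Interpolate an FRC curve at a spatial frequency
#'
#' Linear interpolation between adjacent populated rings. Address the
#' frequency either absolutely (`freq`, cycles per length) or as a fraction
#' of the Nyquist frequency (`frac`), e.g. `frac = 0.5` for half Nyquist.
#'
#' @param curve an `frc_curve`.
#' @param freq absolute spatial frequency.
#' @param frac fraction of Nyquist (used when `freq` is missing).
#' @return interpolated FRC value.
#' @export
frc_at <- function(curve, freq = NULL, frac = NULL) {
  ok <- !is.na(curve$value)
  if (is.null(freq)) {
    if (is.null(frac)) stopf("supply freq or frac")
    x <- curve$frac_nyquist[ok]; xq <- frac
  } else {
    x <- curve$freq[ok]; xq <- freq
  }
  if (xq < min(x) || xq > max(x))
    stopf("frequency %g outside the curve range [%g, %g]", xq, min(x), max(x))
  stats::approx(x, curve$value[ok], xout = xq, ties = "ordered")$y
}
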