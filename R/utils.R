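#' @useDynLib ptypine, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif rpois median approx sd dist
#' @importFrom utils tail write.csv
NULL

# Unitary 2-D DFT pair: Parseval holds exactly (sum |x|^2 == sum |X|^2),
# so forward and inverse are mutual adjoints and the modulus projection is
# an orthogonal projection in the image domain as well.

#' Unitary two-dimensional Fourier transform
#'
#' Orthonormal DFT with DC at index (1,1). `uifft2()` is its exact inverse
#' (and adjoint). Both preserve the Frobenius norm.
#'
#' @param x complex (or numeric) matrix.
#' @return complex matrix of the same dimensions.
#' @export
ufft2 <- function(x) stats::fft(x) / sqrt(length(x))

#' @rdname ufft2
#' @export
uifft2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Evaluate expr under a temporary RNG state; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Centered integer frequency coordinate along one axis of length n:
# 0, 1, ..., n/2-1, -n/2, ..., -1 (matches unshifted DFT ordering).
freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_square <- function(x) is.matrix(x) && nrow(x) == ncol(x)
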