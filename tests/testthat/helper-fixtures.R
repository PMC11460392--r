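# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the default run stays fast.

# Small noiseless simulation: 64x64 object, 32x32 probe, 3x3 grid scan.
tiny_problem <- function(seed = 3, noise_kind = "none", I0 = 1e6,
                         step = 8) {
  O <- make_particle_phantom(
    phantom_spec(canvas_size = 64, particle_count = 8,
                 radius_range = c(3, 7)), seed = seed)
  P <- make_bump_probe(32, 12, total_power = 1)
  plan <- make_scan("grid", rows = 3, cols = 3, step = step, extent = 32)
  ds <- simulate_dataset(O, P, plan, I0 = I0, noise_kind = noise_kind,
                         seed = seed + 100)
  list(O = O, P = P, plan = plan, ds = ds, probe_cal = attr(ds, "probe"))
}

random_complex <- function(n, m = n, seed = 1) {
  with_seed(seed, matrix(complex(real = rnorm(n * m),
                                 imaginary = rnorm(n * m)), n, m))
}

# RNG-scoped helper mirroring the package-internal one.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Brute-force unitary DFT by explicit double loop (oracle).
dft2_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0i, n, m)
  for (u in 0:(n - 1)) for (v in 0:(m - 1)) {
    s <- 0i
    for (i in 0:(n - 1)) for (j in 0:(m - 1))
      s <- s + x[i + 1, j + 1] * exp(-2i * pi * (u * i / n + v * j / m))
    out[u + 1, v + 1] <- s
  }
  out / sqrt(n * m)
}
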