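test_that("grid scans form the expected lattice and respect bounds", {
  plan <- make_scan("grid", rows = 3, cols = 3, step = 20, extent = 40)
  expect_equal(nrow(plan$offsets), 9)
  expect_setequal(unique(plan$offsets[, 1]), c(0, 20, 40))
  expect_setequal(unique(plan$offsets[, 2]), c(0, 20, 40))

  single <- make_scan("grid", rows = 1, cols = 1, step = 5, extent = 10)
  expect_equal(unname(single$offsets[1, ]), c(0L, 0L))

  expect_error(make_scan("grid", rows = 4, cols = 4, step = 20, extent = 40),
               "outside")
})

test_that("fermat scans give unique in-bounds offsets at the right spacing", {
  plan <- make_scan("fermat", count = 50, spacing = 8, extent = 150)
  off <- plan$offsets
  expect_equal(nrow(off), 50)
  expect_equal(nrow(unique(off)), 50)
  expect_true(all(off >= 0 & off <= 150))
  # brute-force pairwise nearest-neighbour distances
  d <- as.matrix(dist(off)); diag(d) <- Inf
  med <- median(apply(d, 1, min))
  expect_gt(med, 8 * 0.7)
  expect_lt(med, 8 * 1.3)
})

test_that("overlap ratio follows the linear definition", {
  plan <- make_scan("grid", rows = 3, cols = 3, step = 16, extent = 64)
  expect_equal(overlap_ratio(plan, 64), 0.75)
  plan40 <- make_scan("grid", rows = 2, cols = 2, step = 40, extent = 64)
  expect_equal(overlap_ratio(plan40, 64), 0.375)
  # overlap beyond the diameter clips at zero
  expect_equal(overlap_ratio(plan40, 30), 0)
  # fermat plan at spacing 32 with diameter 64 sits near 50%
  fp <- make_scan("fermat", count = 40, spacing = 32, extent = 400)
  expect_equal(overlap_ratio(fp, 64), 0.5, tolerance = 0.1)
  single <- make_scan("grid", rows = 1, cols = 1, step = 5, extent = 10)
  expect_error(overlap_ratio(single, 64), "single-position")
})

test_that("bump probe is normalized, compactly supported and peaked", {
  P <- make_bump_probe(64, 16, total_power = 1)
  expect_equal(sum(Mod(P$values)^2), 1, tolerance = 1e-12)
  c0 <- (64 - 1) / 2
  r2 <- outer((0:63 - c0)^2, (0:63 - c0)^2, "+")
  expect_true(all(Mod(P$values)[r2 >= 16^2] == 0))

  # support radius M/2: the bump still vanishes (to numerical zero)
  # on the boundary ring
  Pedge <- make_bump_probe(64, 32, total_power = 1)
  edge_max <- max(Mod(Pedge$values[c(1, 64), ]), Mod(Pedge$values[, c(1, 64)]))
  expect_lt(edge_max, 1e-12 * max(Mod(Pedge$values)))

  # same power, smaller support => higher peak
  P8 <- make_bump_probe(64, 8, total_power = 1)
  expect_gt(max(Mod(P8$values)), max(Mod(P$values)))

  expect_error(make_bump_probe(64, 16, total_power = 0), "positive")
  expect_error(make_bump_probe(64, 40, 1), "support_radius")
})

test_that("particle phantom honours its contract", {
  # no particles -> vacuum
  vac <- make_particle_phantom(phantom_spec(canvas_size = 48,
                                            particle_count = 0), seed = 1)
  expect_true(all(vac$values == 1 + 0i))

  # single particle: phase minimum equals -phase_contrast at the center
  sp <- phantom_spec(canvas_size = 64, particle_count = 1,
                     radius_range = c(10, 10), amplitude_contrast = 0.2,
                     phase_contrast = 0.5)
  one <- make_particle_phantom(sp, seed = 4)
  expect_equal(min(Arg(one$values)), -0.5, tolerance = 1e-10)
  expect_equal(min(Mod(one$values)), 0.8, tolerance = 1e-10)

  # determinism
  again <- make_particle_phantom(sp, seed = 4)
  expect_identical(one$values, again$values)
  other <- make_particle_phantom(sp, seed = 5)
  expect_false(identical(one$values, other$values))
})

test_that("diffraction pattern matches the forward model", {
  # identity object: pattern is |F(P)|^2
  O1 <- object_field(matrix(1 + 0i, 48, 48))
  P <- make_bump_probe(16, 6, 1)
  pat <- diffraction_pattern(O1, P, c(10, 10))
  expect_equal(pat, Mod(ufft2(P$values))^2, tolerance = 1e-12)

  # 4x4 brute-force DFT oracle
  Ov <- random_complex(4, seed = 11)
  Pv <- random_complex(4, seed = 12)
  O <- object_field(rbind(cbind(Ov, Ov), cbind(Ov, Ov)))  # 8x8 canvas
  Ps <- probe_field(Pv)
  pat4 <- diffraction_pattern(O, Ps, c(0, 0))
  oracle <- Mod(dft2_oracle(Ov * Pv))^2
  expect_equal(pat4, oracle, tolerance = 1e-10)

  expect_error(diffraction_pattern(O, Ps, c(7, 0)), "out of bounds")
})

test_that("Parseval and patch round-trip invariants hold", {
  prob <- tiny_problem(seed = 9)
  for (r in c(1, 5, 9)) {
    off <- prob$plan$offsets[r, ]
    exit <- ptypine:::extract_patch(prob$O$values, off, 32) *
      prob$probe_cal$values
    pat <- diffraction_pattern(prob$O, prob$probe_cal, off)
    expect_equal(sum(pat), sum(Mod(exit)^2),
                 tolerance = 1e-9 * sum(Mod(exit)^2))
  }
  # replacing a patch with itself is a no-op
  Ov <- prob$O$values
  patch <- ptypine:::extract_patch(Ov, c(5, 17), 32)
  expect_identical(ptypine:::replace_patch(Ov, c(5, 17), patch), Ov)
})

test_that("dose calibration and Poisson noise behave as specified", {
  vac <- object_field(matrix(1 + 0i, 64, 64))
  P <- make_bump_probe(32, 12, 1)
  plan <- make_scan("grid", rows = 2, cols = 2, step = 16, extent = 32)
  ds <- simulate_dataset(vac, P, plan, I0 = 1e6, noise_kind = "none")
  # vacuum exposure's DC pixel equals I0 exactly
  expect_equal(ds$intensities[1, 1, 1], 1e6, tolerance = 1e-9)

  # noiseless output carries no seed dependence
  ds2 <- simulate_dataset(vac, P, plan, I0 = 1e6, noise_kind = "none",
                          seed = 999)
  expect_identical(ds$intensities, ds2$intensities)

  # Poisson: integer counts, reproducible
  dsp <- simulate_dataset(vac, P, plan, I0 = 1e6, noise_kind = "poisson",
                          seed = 42)
  expect_true(all(dsp$intensities == round(dsp$intensities)))
  dsp2 <- simulate_dataset(vac, P, plan, I0 = 1e6, noise_kind = "poisson",
                           seed = 42)
  expect_identical(dsp$intensities, dsp2$intensities)
  expect_false(identical(
    dsp$intensities,
    simulate_dataset(vac, P, plan, I0 = 1e6, "poisson", seed = 43)$intensities))

  expect_error(simulate_dataset(vac, P, plan, I0 = 0), "positive")
})

test_that("Poisson DC statistics follow the 1/sqrt(I0) law and the mean
           converges to the noiseless pattern", {
  vac <- object_field(matrix(1 + 0i, 48, 48))
  P <- make_bump_probe(24, 10, 1)
  plan <- make_scan("grid", rows = 1, cols = 1, step = 1, extent = 24)
  I0 <- 1e8
  dc <- vapply(1:100, function(s)
    simulate_dataset(vac, P, plan, I0 = I0, "poisson", seed = s)$
      intensities[1, 1, 1], numeric(1))
  expect_equal(sd(dc) / I0, 1 / sqrt(I0), tolerance = 0.3)

  # Monte-Carlo mean of a modest-dose pattern matches the noiseless one
  spec <- phantom_spec(canvas_size = 48, particle_count = 5,
                       radius_range = c(3, 8))
  O <- make_particle_phantom(spec, seed = 2)
  clean <- simulate_dataset(O, P, plan, I0 = 1e4, "none")$intensities
  acc <- 0
  nrep <- 60
  for (s in 1:nrep)
    acc <- acc + simulate_dataset(O, P, plan, I0 = 1e4, "poisson",
                                  seed = s)$intensities
  avg <- acc / nrep
  se <- sqrt(pmax(clean, 1e-12) / nrep)
  frac_within <- mean(abs(avg - clean) <= 3 * se)
  expect_gt(frac_within, 0.98)
})
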