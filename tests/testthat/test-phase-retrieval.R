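test_that("modified sign has unit modulus and the chosen zero convention", {
  expect_equal(modified_sign(matrix(3 + 4i)), matrix(0.6 + 0.8i))
  expect_equal(modified_sign(matrix(0 + 0i)), matrix(1 + 0i))
  z <- random_complex(8, seed = 21)
  z[3, 5] <- 0
  s <- modified_sign(z)
  expect_equal(Mod(s), matrix(1, 8, 8), tolerance = 1e-12)
  # sign times modulus reproduces the input
  expect_equal(s * Mod(z), z, tolerance = 1e-12)
})

test_that("modulus projection is feasible, idempotent and optimal", {
  W <- random_complex(8, seed = 31)
  a <- with_seed(32, matrix(abs(rnorm(64)), 8))
  Psi <- project_modulus(W, a)
  # feasibility: |F(Psi)| = a
  expect_lt(max(abs(Mod(ufft2(Psi)) - a)), 1e-9 * max(a))
  # idempotence
  expect_equal(project_modulus(Psi, a), Psi, tolerance = 1e-12)
  # a feasible W is a fixed point
  Wf <- uifft2(a * exp(1i * with_seed(33, matrix(runif(64, -pi, pi), 8))))
  expect_equal(project_modulus(Wf, a), Wf, tolerance = 1e-12)
  # zero amplitudes project to zero
  expect_equal(project_modulus(W, matrix(0, 8, 8)), matrix(0i, 8, 8),
               tolerance = 1e-15)
  # optimality against random feasible points (distances in Fourier
  # domain, equal by Parseval under the unitary transform)
  FW <- ufft2(W)
  d_proj <- sqrt(sum(Mod(a * modified_sign(FW) - FW)^2))
  worst <- with_seed(34, min(vapply(1:2000, function(i) {
    Z <- a * exp(1i * matrix(runif(64, -pi, pi), 8))
    sqrt(sum(Mod(Z - FW)^2))
  }, numeric(1))))
  expect_lte(d_proj, worst + 1e-12)
  expect_error(project_modulus(W, -a), "nonnegative")
})

test_that("object and probe steps match their closed forms and gradients", {
  O_r <- random_complex(6, seed = 41)
  P <- random_complex(6, seed = 42)
  Psi <- random_complex(6, seed = 43)

  # zero residual leaves both unchanged
  expect_equal(object_step(O_r, P, O_r * P, 0.7), O_r, tolerance = 1e-14)
  expect_equal(probe_step(O_r, P, O_r * P, 0.7), P, tolerance = 1e-14)

  # flat probe, alpha = 1: exact solve O_r <- Psi / c
  Pc <- matrix(2 - 1i, 6, 6)
  expect_equal(object_step(O_r, Pc, Psi, 1), Psi / (2 - 1i),
               tolerance = 1e-12)
  # vacuum patch, beta = 1: P <- Psi
  expect_equal(probe_step(matrix(1 + 0i, 6, 6), P, Psi, 1), Psi,
               tolerance = 1e-12)

  # central-difference gradient oracle for f = ||O*P - Psi||_F^2
  f_obj <- function(Ov) sum(Mod(Ov * P - Psi)^2)
  h <- 1e-5
  gnum <- matrix(0i, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    e <- matrix(0i, 6, 6); e[i, j] <- h
    gre <- (f_obj(O_r + e) - f_obj(O_r - e)) / (2 * h)
    gim <- (f_obj(O_r + 1i * e) - f_obj(O_r - 1i * e)) / (2 * h)
    gnum[i, j] <- gre + 1i * gim
  }
  alpha <- 0.9
  upd <- object_step(O_r, P, Psi, alpha)
  # step = -alpha/(2 max|P|^2) * (gradRe + i gradIm)
  expected <- O_r - alpha / (2 * max(Mod(P)^2)) * gnum
  expect_equal(upd, expected, tolerance = 1e-6)

  f_prb <- function(Pv) sum(Mod(O_r * Pv - Psi)^2)
  gnum_p <- matrix(0i, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    e <- matrix(0i, 6, 6); e[i, j] <- h
    gre <- (f_prb(P + e) - f_prb(P - e)) / (2 * h)
    gim <- (f_prb(P + 1i * e) - f_prb(P - 1i * e)) / (2 * h)
    gnum_p[i, j] <- gre + 1i * gim
  }
  beta <- 1.3
  expect_equal(probe_step(O_r, P, Psi, beta),
               P - beta / (2 * max(Mod(O_r)^2)) * gnum_p,
               tolerance = 1e-6)

  expect_error(object_step(O_r, matrix(0i, 6, 6), Psi, 1), "all-zero")
  expect_error(probe_step(matrix(0i, 6, 6), P, Psi, 1), "all-zero")
})

test_that("a consistent state is a fixed point of the sweep", {
  prob <- tiny_problem(seed = 51)
  # data generated from (O, P): the current truth must not move
  st <- reconstruction_state(prob$O, prob$probe_cal)
  hy <- hyperparams("epie", alpha = 1, beta = 1, n_iterations = 1,
                    shuffle_seed = 7)
  st2 <- sgd_sweep(st, prob$ds, hy)
  expect_lt(max(Mod(st2$object$values - prob$O$values)), 1e-10)
  expect_lt(max(Mod(st2$probe$values - prob$probe_cal$values)), 1e-10)
})

test_that("sweeps are deterministic and reduce the misfit", {
  prob <- tiny_problem(seed = 52)
  init_o <- object_field(matrix(1 + 0i, 64, 64))
  init_p <- make_bump_probe(32, 12, sum(Mod(prob$probe_cal$values)^2))
  hy <- hyperparams("epie", alpha = 0.5, beta = 0.5, n_iterations = 5,
                    shuffle_seed = 3)
  a <- run_reconstruction(prob$ds, init_o, init_p, hy)
  b <- run_reconstruction(prob$ds, init_o, init_p, hy)
  expect_identical(a$object$values, b$object$values)
  expect_identical(a$probe$values, b$probe$values)
  expect_equal(nrow(a$log), 5)
  expect_true(all(is.finite(a$log$misfit)))
  # empirical descent over random initializations: misfit after one
  # sweep below the starting misfit in at least 95% of trials
  worse <- 0
  n_trial <- 20
  for (s in 1:n_trial) {
    init <- object_field(matrix(1 + 0i, 64, 64) +
                           0.2 * random_complex(64, seed = 600 + s))
    st0 <- reconstruction_state(init, prob$probe_cal)
    m0 <- modulus_misfit(st0, prob$ds)
    hy1 <- hyperparams("epie", alpha = 0.8, beta = 0.5, n_iterations = 1,
                       shuffle_seed = s, update_probe = FALSE)
    m1 <- modulus_misfit(sgd_sweep(st0, prob$ds, hy1), prob$ds)
    if (m1 >= m0) worse <- worse + 1
  }
  expect_lte(worse / n_trial, 0.05)
})

test_that("denoise relaxation follows its linear form", {
  O <- random_complex(16, seed = 61)
  expect_identical(denoise_relax(O, identity_denoiser(), 0.49), O)
  zero_map <- function(x) x * 0
  expect_equal(denoise_relax(O, zero_map, 0.49), 0.51 * O,
               tolerance = 1e-15)
  bad_shape <- function(x) x[1:4, 1:4]
  expect_error(denoise_relax(O, bad_shape, 0.3), "shape")
  expect_error(denoise_relax(O, identity_denoiser(), 0.6), "rho")
})

test_that("hyperparameter guards enforce the convergence windows", {
  expect_error(hyperparams("epie", alpha = 2), "alpha")
  expect_error(hyperparams("epie", beta = 0), "beta")
  expect_error(hyperparams("pine", rho = 0.5), "rho")
  expect_error(hyperparams("pine", rho = 0), "rho")
  expect_error(hyperparams("rpie", alpha = 1.2), "alpha")
  expect_error(hyperparams("rpie", beta = 5.5), "beta")
  expect_silent(hyperparams("rpie", alpha = 1, beta = 5))
  expect_error(run_reconstruction(NULL, NULL, NULL,
                                  hyperparams("pine", n_iterations = 1)),
               "denoiser")
})

test_that("PINE with an identity denoiser reproduces ePIE bit for bit", {
  prob <- tiny_problem(seed = 53)
  init_o <- object_field(matrix(1 + 0i, 64, 64))
  init_p <- make_bump_probe(32, 12, sum(Mod(prob$probe_cal$values)^2))
  hy_e <- hyperparams("epie", alpha = 0.6, beta = 0.4, n_iterations = 8,
                      shuffle_seed = 9)
  hy_p <- hyperparams("pine", alpha = 0.6, beta = 0.4, rho = 0.49,
                      n_iterations = 8, shuffle_seed = 9)
  a <- run_reconstruction(prob$ds, init_o, init_p, hy_e)
  b <- run_reconstruction(prob$ds, init_o, init_p, hy_p,
                          denoiser = identity_denoiser())
  expect_identical(a$object$values, b$object$values)
  expect_identical(a$probe$values, b$probe$values)
})

test_that("n_iterations = 0 returns the initial state", {
  prob <- tiny_problem(seed = 54)
  init_o <- object_field(matrix(1 + 0i, 64, 64))
  hy <- hyperparams("epie", n_iterations = 0)
  st <- run_reconstruction(prob$ds, init_o, prob$probe_cal, hy)
  expect_identical(st$object$values, init_o$values)
  expect_equal(st$epoch, 0L)
  expect_equal(nrow(st$log), 0)
})

test_that("misfit is zero on consistent data, positive otherwise, and
           matches hand arithmetic on a 2x2 case", {
  prob <- tiny_problem(seed = 55)
  st_true <- reconstruction_state(prob$O, prob$probe_cal)
  expect_lt(modulus_misfit(st_true, prob$ds), 1e-12)
  st_vac <- reconstruction_state(object_field(matrix(1 + 0i, 64, 64)),
                                 prob$probe_cal)
  expect_gt(modulus_misfit(st_vac, prob$ds), 1e-4)

  # pencil-and-paper 2x2, single pattern: O = 1, P = [[1,0],[0,0]],
  # exit = P, F(P) = 0.5 * ones, I = 0.25 everywhere.
  # With data amplitudes a = 1: misfit = sum((0.5-1)^2)/sum(1) = 0.25.
  O2 <- object_field(matrix(1 + 0i, 3, 3))
  P2 <- probe_field(matrix(c(1, 0, 0, 0) + 0i, 2, 2))
  plan1 <- scan_plan(matrix(c(0L, 0L), 1))
  data1 <- diffraction_set(array(1, c(2, 2, 1)), plan1, I0 = 1)
  st22 <- reconstruction_state(O2, P2)
  expect_equal(modulus_misfit(st22, data1), 0.25, tolerance = 1e-12)
})

test_that("the measurement model and misfit are gauge invariant", {
  prob <- tiny_problem(seed = 56)
  cgauge <- 1.7 * exp(1i * 0.8)
  Og <- object_field(prob$O$values * cgauge)
  Pg <- probe_field(prob$probe_cal$values / cgauge)
  for (r in c(1, 4)) {
    off <- prob$plan$offsets[r, ]
    expect_equal(diffraction_pattern(Og, Pg, off),
                 diffraction_pattern(prob$O, prob$probe_cal, off),
                 tolerance = 1e-9)
  }
  st_g <- reconstruction_state(Og, Pg)
  expect_lt(modulus_misfit(st_g, prob$ds), 1e-12)
})
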