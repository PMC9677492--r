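test_that("exchange and recombination follow the exponential distance law", {
  laws <- coupling_laws(J0 = 10, beta = 1.4, r0 = 17.8)
  expect_equal(exchange_coupling(laws$r0, laws), 10)
  # J0 = 10 MHz, beta = 1.4 /A, r = r0 + 3 A -> 10 exp(-4.2)
  expect_equal(exchange_coupling(laws$r0 + 3, laws), 10 * exp(-4.2))
  expect_equal(exchange_coupling(laws$r0 + 3, laws), 0.1499558, tolerance = 1e-6)
  # strictly decreasing magnitude, sign preserved
  rr <- seq(10, 30, by = 0.5)
  expect_true(all(diff(abs(exchange_coupling(rr, laws))) < 0))
  lawsn <- coupling_laws(J0 = -10)
  expect_true(all(exchange_coupling(rr, lawsn) < 0))

  laws0 <- coupling_laws()
  expect_equal(recombination_rate(laws0$r0, laws0), 2)
  expect_equal(recombination_rate(laws0$r0 + 3, laws0), 2 * exp(-4.2))
  expect_true(all(recombination_rate(rr, laws0) > 0))
})

test_that("dipolar tensor is traceless, axial, and follows the 1/r^3 law", {
  laws <- coupling_laws(D0 = -13.7)
  Tz <- dipolar_tensor(c(0, 0, laws$r0), laws)
  expect_lt(abs(sum(diag(Tz))), 1e-12)
  expect_equal(Tz[3, 3], -13.7)
  expect_equal(Tz[1, 1], 13.7 / 2)
  expect_lt(max(abs(Tz - t(Tz))), 1e-15)
  T2 <- dipolar_tensor(c(0, 0, 2 * laws$r0), laws)
  expect_equal(T2[3, 3], -13.7 / 8)
  expect_equal(T2[3, 3], -1.7125)
  # axis covariance: tensor aligned with the vector direction
  n <- c(1, 2, 2) / 3
  Tn <- dipolar_tensor(laws$r0 * n, laws)
  expect_equal(as.numeric(n %*% Tn %*% n), -13.7)
  expect_error(dipolar_tensor(c(0, 0, 0), laws), "nonzero")
})

test_that("harmonic trajectory hits the quoted turning points", {
  laws <- coupling_laws(J0 = 10)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 2)
  n <- 0:3
  full <- trajectory(n / sp$nu_d, sp, laws)
  expect_equal(full$r, rep(laws$r0, 4), tolerance = 1e-9)
  half <- trajectory((2 * n + 1) / (2 * sp$nu_d), sp, laws)
  expect_equal(half$r, rep(laws$r0 + 3, 4), tolerance = 1e-9)
  # J(t) oscillates in [J0 exp(-beta Delta_d), J0]
  tt <- seq(0, 2, length.out = 400)
  J <- exchange_coupling(trajectory(tt, sp, laws)$r, laws)
  expect_true(all(J <= 10 + 1e-9))
  expect_true(all(J >= 10 * exp(-1.4 * 3) - 1e-9))
})

test_that("negative amplitude reduces distance and increases couplings", {
  laws <- coupling_laws(J0 = 10)
  sp <- trajectory_spec("harmonic", delta_d = -2, nu_d = 2)
  half <- trajectory(1 / (2 * sp$nu_d), sp, laws)
  expect_equal(half$r, laws$r0 - 2, tolerance = 1e-9)
  expect_gt(abs(exchange_coupling(half$r, laws)), abs(laws$J0))
  expect_gt(recombination_rate(half$r, laws), laws$kb0)
})

test_that("damped trajectory reduces to harmonic at zero damping and decays otherwise", {
  laws <- coupling_laws()
  tt <- seq(0, 3, length.out = 200)
  sp0 <- trajectory_spec("damped", delta_d = 3, nu_d = 2, damping_rate = 0)
  sph <- trajectory_spec("harmonic", delta_d = 3, nu_d = 2)
  expect_equal(trajectory(tt, sp0, laws)$r, trajectory(tt, sph, laws)$r)
  spd <- trajectory_spec("damped", delta_d = 3, nu_d = 2, damping_rate = 2)
  d <- trajectory(tt, spd, laws)$delta
  expect_true(all(abs(d) <= 3 * exp(-2 * tt) + 1e-12))
})

test_that("off-axis displacement keeps the dipolar axis normalized and moving", {
  laws <- coupling_laws()
  sp <- trajectory_spec("harmonic",
    delta_d = 3, nu_d = 2,
    direction = c(1, 0, 0), n0 = c(0, 0, 1)
  )
  tt <- seq(0, 1, length.out = 50)
  tr <- trajectory(tt, sp, laws)
  expect_equal(sqrt(rowSums(tr$n^2)), rep(1, 50), tolerance = 1e-12)
  expect_gt(max(abs(tr$n[, 1])), 0.01) # the axis tilts during the drive
})

test_that("brownian trajectory is seeded-reproducible and noiseless at zero diffusion", {
  laws <- coupling_laws()
  tt <- seq(0, 2, by = 0.01)
  sp0 <- trajectory_spec("brownian", diffusion = 0)
  expect_equal(trajectory(tt, sp0, laws)$r, rep(laws$r0, length(tt)))
  sp <- trajectory_spec("brownian", diffusion = 1, friction = 20, stiffness = 400, seed = 11)
  r1 <- trajectory(tt, sp, laws)$r
  r2 <- trajectory(tt, sp, laws)$r
  expect_identical(r1, r2)
  sp2 <- trajectory_spec("brownian", diffusion = 1, friction = 20, stiffness = 400, seed = 12)
  expect_false(identical(r1, trajectory(tt, sp2, laws)$r))
})

test_that("trajectories that collapse the pair distance error out", {
  laws <- coupling_laws()
  sp <- trajectory_spec("harmonic", delta_d = -laws$r0, nu_d = 1)
  expect_error(trajectory(0.5, sp, laws), "distance")
})

test_that("coupling law invariants are enforced", {
  expect_error(coupling_laws(beta = -1))
  expect_error(coupling_laws(r0 = 0))
  expect_error(coupling_laws(kb0 = -1))
  expect_error(exchange_coupling(-1, coupling_laws()))
})
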