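test_that("effective Hamiltonian splits into Hermitian and dissipative parts", {
  mod <- one_n(J0 = 10, D0 = -13.7)
  fld <- field_spec(50, "perpendicular")
  H0 <- effective_hamiltonian(mod$system, fld, mod$laws, include_decay = FALSE)
  expect_hermitian(H0)
  H <- effective_hamiltonian(mod$system, fld, mod$laws)
  ev <- eigen(H, only.values = TRUE)$values
  expect_true(all(Im(ev) <= 1e-12))
  # anti-Hermitian part: -(kb + kf)/2 on singlet states, -kf/2 on triplets
  K <- (H - Conj(t(H))) / 2
  evK <- sort(Im(eigen(K, only.values = TRUE)$values))
  kb <- mod$laws$kb0
  kf <- mod$laws$kf
  expect_equal(evK,
    c(rep(-(kb + kf) / 2, 3), rep(-kf / 2, 9)),
    tolerance = 1e-12
  )
})

test_that("exchange convention gives a singlet-triplet splitting of 2J", {
  sys <- bare_pair()
  laws <- coupling_laws(J0 = 10)
  H <- effective_hamiltonian(sys, field_spec(0), laws, include_decay = FALSE)
  ev <- sort(Re(eigen(H, only.values = TRUE)$values)) / (2 * pi)
  # electronic energies: singlet at -J, triplets at +J
  expect_equal(ev, c(-10, 10, 10, 10), tolerance = 1e-10)
})

test_that("closed (non-recombining) period propagator is unitary; static limit is one exponential", {
  mod <- one_n(J0 = 5)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  fld <- field_spec(50, "perpendicular")
  h0 <- hamiltonian_fn(mod$system, fld, mod$laws, sp, include_decay = FALSE)
  U <- period_propagator(h0, 1 / 3, 128)
  expect_lt(max(abs(Conj(t(U)) %*% U - diag(mod$system$dim))), 1e-10)
  # dissipative propagator is a contraction
  h1 <- hamiltonian_fn(mod$system, fld, mod$laws, sp)
  sv <- svd(period_propagator(h1, 1 / 3, 128))$d
  expect_true(all(sv <= 1 + 1e-10))
  # static trajectory: product collapses to a single matrix exponential
  hst <- hamiltonian_fn(mod$system, fld, mod$laws, trajectory_spec("static"))
  U1 <- period_propagator(hst, 0.2, 64)
  U2 <- rpdrive:::expm_complex(-1i * hst(0) * 0.2)
  expect_lt(max(abs(U1 - U2)), 1e-10)
})

test_that("period propagator matches adaptive complex-ODE integration", {
  mod <- one_n(J0 = 5)
  sys <- mod$system
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  hfun <- hamiltonian_fn(sys, field_spec(50, "perpendicular"), mod$laws, sp)
  T <- 1 / 3
  d <- sys$dim
  rhs <- function(t, y, parms) {
    list(as.vector(-1i * hfun(t) %*% matrix(y, d, d)))
  }
  sol <- deSolve::zvode(as.vector(diag(d) + 0i), c(0, T), rhs,
    parms = NULL, rtol = 1e-12, atol = 1e-12
  )
  Uref <- matrix(sol[2, -1], d, d)
  Ucf4 <- period_propagator(hfun, T, 512, scheme = "cf4")
  expect_lt(max(abs(Ucf4 - Uref)), 1e-8)
})

test_that("no-mixing static pair recombines with the closed-form branching ratio", {
  # no hyperfine, J = D = 0: the singlet is stationary under the Zeeman term,
  # so Phi_S = kb/(kb + kf) = 2/3 at kb = 2 /us, kf = 1 /us
  y <- propagate_yield_floquet(
    bare_pair(), field_spec(50, "parallel"),
    coupling_laws(), trajectory_spec("static")
  )
  expect_equal(y$phi_s, 2 / 3, tolerance = 1e-10)
  expect_equal(y$phi_s + y$phi_f, 1, tolerance = 1e-10)
})

test_that("Floquet and direct integration agree and conserve probability", {
  mod <- one_n(J0 = 5)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  for (orient in c("parallel", "perpendicular")) {
    fld <- field_spec(50, orient)
    yf <- propagate_yield_floquet(mod$system, fld, mod$laws, sp)
    yd <- propagate_yield_direct(mod$system, fld, mod$laws, sp)
    expect_equal(yf$phi_s, yd$phi_s, tolerance = 1e-6)
    expect_lt(abs(yf$phi_s + yf$phi_f - 1), 1e-6)
    expect_lt(abs(yd$phi_s + yd$phi_f - 1), 1e-6)
    expect_equal(yf$per_state$phi_s, yd$per_state$phi_s, tolerance = 1e-6)
  }
})

test_that("yields are invariant under halving the step size at default tolerances", {
  mod <- one_n(J0 = 5)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  fld <- field_spec(50, "perpendicular")
  y <- propagate_yield_floquet(mod$system, fld, mod$laws, sp,
    n_steps = 256, check_convergence = TRUE
  )
  expect_lt(y$meta$step_doubling_delta, 1e-6)
})

test_that("wavefunction yield agrees with density-matrix Liouvillian integration", {
  # independent formulation: vectorize the master equation for rho as
  # d vec(rho)/dt = L vec(rho); since all Liouvillian modes decay, the
  # total singlet yield is the closed form kb * vec(PS)^H (-L)^-1 vec(rho0)
  mod <- one_n(J0 = 5)
  sys <- mod$system
  laws <- mod$laws
  fld <- field_spec(50, "perpendicular")
  d <- sys$dim
  PS <- singlet_projector(sys)
  H0 <- effective_hamiltonian(sys, fld, laws, include_decay = FALSE)
  kb <- recombination_rate(laws$r0, laws)
  Id <- diag(d) + 0i
  L <- -1i * (kronecker(Id, H0) - kronecker(t(H0), Id)) -
    (kb / 2) * (kronecker(Id, PS) + kronecker(t(PS), Id)) -
    laws$kf * diag(d * d)
  rho0 <- PS / sys$Z
  phi_ref <- Re(kb * sum(Conj(as.vector(PS)) * solve(-L, as.vector(rho0))))
  y <- propagate_yield_floquet(sys, fld, laws, trajectory_spec("static"))
  expect_equal(y$phi_s, phi_ref, tolerance = 1e-8)
})

test_that("yields are invariant under a global rotation of the laboratory frame", {
  th <- 0.9
  R <- rbind(
    c(cos(th), 0, sin(th)),
    c(0, 1, 0),
    c(-sin(th), 0, cos(th))
  )
  A <- diag(c(-2.6, -2.6, 49.2))
  sysA <- one_n()$system
  sysR <- spin_system(tibble::tibble(
    label = "N5", radical = "A", spin = 1,
    tensor = list(R %*% A %*% t(R))
  ))
  laws <- coupling_laws(J0 = 3, D0 = -13.7)
  b <- c(0.2, -0.4, 0.89)
  sp1 <- trajectory_spec("harmonic", delta_d = 2, nu_d = 4, n0 = c(0, 0, 1))
  sp2 <- trajectory_spec("harmonic",
    delta_d = 2, nu_d = 4,
    n0 = as.vector(R %*% c(0, 0, 1))
  )
  y1 <- propagate_yield_floquet(sysA, field_spec(50, b), laws, sp1)
  y2 <- propagate_yield_floquet(sysR, field_spec(50, as.vector(R %*% b)), laws, sp2)
  expect_equal(y1$phi_s, y2$phi_s, tolerance = 1e-8)
})

test_that("zero-amplitude driving reduces identically to the static path", {
  mod <- one_n(J0 = 5)
  fld <- field_spec(50, "perpendicular")
  y0 <- propagate_yield_floquet(
    mod$system, fld, mod$laws,
    trajectory_spec("harmonic", delta_d = 0, nu_d = 3)
  )
  ys <- propagate_yield_floquet(
    mod$system, fld, mod$laws,
    trajectory_spec("static")
  )
  expect_identical(y0$phi_s, ys$phi_s)
  yd0 <- propagate_yield_direct(
    mod$system, fld, mod$laws,
    trajectory_spec("damped", delta_d = 0, nu_d = 3, damping_rate = 2)
  )
  expect_identical(yd0$phi_s, ys$phi_s)
})

test_that("damped driving with zero damping reproduces the harmonic yield", {
  mod <- one_n(J0 = 5)
  fld <- field_spec(50, "perpendicular")
  yh <- propagate_yield_direct(
    mod$system, fld, mod$laws,
    trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  )
  yd <- propagate_yield_direct(
    mod$system, fld, mod$laws,
    trajectory_spec("damped", delta_d = 3, nu_d = 3, damping_rate = 0)
  )
  expect_equal(yh$phi_s, yd$phi_s, tolerance = 1e-8)
})

test_that("survival probability never increases along the propagation", {
  mod <- one_n(J0 = 20)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  ser <- coherence_series(mod$system, field_spec(50, "perpendicular"),
    mod$laws, sp,
    thin = 1L
  )
  expect_true(all(diff(ser$survival) <= 1e-12))
})

test_that("stochastic ensemble is reproducible and collapses to static without noise", {
  mod <- one_n(J0 = 5)
  fld <- field_spec(50, "perpendicular")
  sp0 <- trajectory_spec("brownian", diffusion = 0, friction = 10, stiffness = 400)
  yb <- propagate_yield_direct(mod$system, fld, mod$laws, sp0)
  ys <- propagate_yield_floquet(mod$system, fld, mod$laws, trajectory_spec("static"))
  expect_equal(yb$phi_s, ys$phi_s, tolerance = 1e-8)

  sp <- trajectory_spec("brownian", diffusion = 0.5, friction = 20, stiffness = 400)
  y1 <- propagate_yield_stochastic(mod$system, fld, mod$laws, sp,
    n_trajectories = 3, seed = 5, dt = 0.02
  )
  y2 <- propagate_yield_stochastic(mod$system, fld, mod$laws, sp,
    n_trajectories = 3, seed = 5, dt = 0.02
  )
  expect_identical(y1$phi_s, y2$phi_s)
  expect_true(is.finite(y1$meta$se))
})

test_that("stochastic standard error shrinks like 1/sqrt(N)", {
  # cheap spin system (no nuclei) so many trajectories are affordable;
  # SE computed on nested prefixes of one ensemble
  sys <- bare_pair()
  laws <- coupling_laws(J0 = 2)
  fld <- field_spec(50, "perpendicular")
  sp <- trajectory_spec("brownian", diffusion = 2, friction = 20, stiffness = 400)
  y <- propagate_yield_stochastic(sys, fld, laws, sp,
    n_trajectories = 128, seed = 2, dt = 0.05
  )
  phis <- y$meta$per_trajectory
  se <- function(x) stats::sd(x) / sqrt(length(x))
  r1 <- se(phis[1:32]) / se(phis)
  # exact ratio 2 up to sampling noise in the sd estimates
  expect_gt(r1, 1.0)
  expect_lt(r1, 4.0)
})

test_that("non-convergent propagation fails with diagnostics", {
  mod <- one_n(J0 = 5, kf = 0, kb0 = 0)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  expect_error(
    suppressWarnings(propagate_yield_floquet(
      mod$system, field_spec(50, "parallel"), mod$laws, sp
    )),
    "spectral radius|converge"
  )
  expect_error(
    propagate_yield_direct(
      mod$system, field_spec(50, "parallel"), mod$laws, sp
    ),
    "k_f"
  )
})
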