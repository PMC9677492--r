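test_that("one-nitrogen model carries the axial N5 tensor and printed rates", {
  mod <- one_nitrogen_model()
  expect_equal(mod$system$dim, 12L)
  A <- mod$system$nuclei$tensor[[1]]
  expect_equal(diag(A), c(-2.6, -2.6, 49.2))
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev[1], ev[2]) # axial: two equal principal values
  expect_equal(mod$laws$r0, 17.8)
  expect_equal(mod$laws$kb0, 2)
  expect_equal(mod$laws$kf, 1)
  expect_equal(mod$laws$beta, 1.4)
})

test_that("four-spin flavin-tryptophan model has the right Hilbert space", {
  mod <- four_spin_model()
  expect_equal(mod$system$dim, 216L) # 4 * 3 * 3 * 3 * 2
  expect_equal(mod$system$Z, 54L)
  expect_equal(mod$laws$D0, -13.7)
  expect_equal(mod$system$nuclei$label, c("N5", "N10", "N1", "H1"))
  expect_equal(mod$system$nuclei$radical, c("A", "A", "B", "B"))
  # all Z initial singlet states enumerated
  W <- rpdrive:::singlet_state_matrix(mod$system)
  expect_equal(ncol(W), 54L)
  expect_lt(max(abs(Conj(t(W)) %*% W - diag(54L))), 1e-12)
})

test_that("four-spin tensor overrides are applied and validated", {
  Aover <- diag(c(1, 2, 3))
  mod <- four_spin_model(tensors = list(N10 = Aover))
  expect_equal(mod$system$nuclei$tensor[[2]], Aover)
  expect_error(four_spin_model(tensors = list(XX = Aover)), "unknown nucleus")
})

test_that("two-level model has the LZSM gap and freezes without coupling", {
  laws <- coupling_laws(J0 = 10)
  tl <- two_level_model(coupling = 49.2, laws = laws)
  H <- tl$hamiltonian(laws$r0, include_decay = FALSE)
  gap <- diff(sort(Re(eigen(H, only.values = TRUE)$values))) / (2 * pi)
  expect_equal(gap, sqrt(4 * 10^2 + 49.2^2), tolerance = 1e-10)
  # zero coupling: populations frozen
  tl0 <- two_level_model(coupling = 0, laws = laws)
  U <- rpdrive:::expm_complex(-1i * tl0$hamiltonian(laws$r0) * 0.7)
  expect_lt(abs(U[1, 2]), 1e-12)
  expect_lt(abs(U[2, 1]), 1e-12)
})

test_that("two-level model reproduces the (T0, S) block of the reduced one-nitrogen pair", {
  # parallel field, A_perp = 0, m_I = 1: the (T0, S) sub-block is exactly the
  # two-level Hamiltonian with coupling a = A_par / 2
  laws <- coupling_laws(J0 = 10)
  fld <- field_spec(50, "parallel")
  blk <- block_hamiltonian(1, fld, laws)
  sub <- blk[c(2, 4), c(2, 4)]
  tl <- two_level_model(coupling = 49.2, laws = laws)
  expect_lt(max(abs(sub - tl$hamiltonian(laws$r0))), 1e-10)

  # driven comparison: singlet transition probability over one period
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  T <- 1 / 3
  n <- 256
  dt <- T / n
  U2 <- diag(2) + 0i
  U4 <- diag(4) + 0i
  for (j in seq_len(n)) {
    r <- rpdrive::trajectory((j - 0.5) * dt, sp, laws)$r
    U2 <- rpdrive:::expm_complex(-1i * tl$hamiltonian(r) * dt) %*% U2
    B <- block_hamiltonian(1, fld, laws, r = r)
    U4 <- rpdrive:::expm_complex(-1i * B * dt) %*% U4
  }
  p2 <- Mod(U2[1, 2])^2 # S -> T0 in the two-level model
  p4 <- Mod(U4[2, 4])^2 # S -> T0 inside the 4x4 block
  expect_equal(p2, p4, tolerance = 0.1 * max(p2, 1e-3))
})

test_that("block Hamiltonian reproduces the LZSM structure of the reduced model", {
  laws <- coupling_laws(J0 = 10)
  fld <- field_spec(50, "perpendicular")
  for (m in c(1, -1)) {
    blk <- block_hamiltonian(m, fld, laws)
    # S-T0 coupling magnitude a = A_par/2 = 24.6 MHz
    expect_equal(abs(blk[4, 2]) / (2 * pi), 24.6, tolerance = 1e-10)
  }
  blk0 <- block_hamiltonian(0, fld, laws)
  expect_lt(abs(blk0[4, 2]) / (2 * pi), 1e-12)
  expect_error(block_hamiltonian(1, fld, laws, A_perp = -2.6), "A_perp")
})

test_that("the three m_I blocks direct-sum to the full reduced Hamiltonian", {
  laws <- coupling_laws(J0 = 10)
  fld <- field_spec(50, "perpendicular")
  mod <- one_nitrogen_model(A_perp = 0)
  H <- effective_hamiltonian(mod$system, fld, laws)
  U <- singlet_triplet_basis(mod$system)
  Hst <- Conj(t(U)) %*% H %*% U
  Z <- mod$system$Z
  perm <- as.vector(vapply(1:Z, function(nuc) (0:3) * Z + nuc, integer(4)))
  Hperm <- Hst[perm, perm]
  blocks <- lapply(c(1, 0, -1), function(m) block_hamiltonian(m, fld, laws))
  Hdirect <- matrix(0i, 12, 12)
  for (k in 1:3) {
    idx <- (k - 1) * 4 + 1:4
    Hdirect[idx, idx] <- blocks[[k]]
  }
  expect_lt(max(abs(Hperm - Hdirect)), 1e-10)
})

test_that("driving sweeps the reduced model through its avoided crossing", {
  # instantaneous S/T0 adiabatic gap is smallest where J(t) is smallest
  laws <- coupling_laws(J0 = 50)
  sp <- trajectory_spec("harmonic", delta_d = 3, nu_d = 3)
  tt <- seq(0, 1 / 3, length.out = 201)
  J <- exchange_coupling(trajectory(tt, sp, laws)$r, laws)
  gap <- 2 * sqrt(J^2 + 24.6^2)
  expect_equal(which.min(gap), which.min(abs(J)))
  # the trapped-singlet drive sweeps J(t) through the a ~ J crossing region
  expect_lt(min(J), 24.6)
  expect_gt(max(J), 24.6)
})

test_that("model registry resolves names and the synthetic axis is unit length", {
  expect_equal(model_registry("one_nitrogen")$system$dim, 12L)
  expect_equal(model_registry("four_spin_fad_trp")$system$dim, 216L)
  expect_true(is.function(model_registry("two_level")$hamiltonian))
  expect_error(model_registry("no_such_model"))
  ax <- fad_trp_dipolar_axis()
  expect_equal(sqrt(sum(ax^2)), 1)
  expect_equal(fad_trp_dipolar_axis(0), c(0, 0, 1))
})
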