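# Dense complex linear algebra used by the propagators. Dimensions in scope
# are small (<= 216), so everything is dense and exact.

norm1 <- function(A) max(colSums(abs(A)))

#' Matrix exponential of a complex matrix
#'
#' Scaling-and-squaring with a degree-13 Pade approximant (Higham's
#' algorithm), valid for general complex matrices; used for the per-step
#' propagator exponentials `exp(-i H_eff dt)`.
#'
#' @param A A square complex (or real) matrix.
#' @return The matrix exponential `exp(A)` as a complex matrix.
#' @keywords internal
expm_complex <- function(A) {
  A <- as.matrix(A) + 0i
  d <- nrow(A)
  theta13 <- 5.371920351148152
  nrm <- norm1(A)
  s <- max(0L, ceiling(log2(nrm / theta13)))
  A <- A / 2^s
  b <- c(
    64764752532480000, 32382376266240000, 7771770303897600,
    1187353796428800, 129060195264000, 10559470521600, 670442572800,
    33522128640, 1323241920, 40840800, 960960, 16380, 182, 1
  )
  Id <- diag(d) + 0i
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
    b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * Id)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * Id
  E <- solve(V - U, V + U)
  for (k in seq_len(s)) E <- E %*% E
  E
}

# phi(z, dt) = (exp(z*dt) - 1)/z, elementwise with the z -> 0 limit dt
phi_elem <- function(z, dt) {
  out <- ifelse(abs(z) * dt < 1e-8,
    dt * (1 + z * dt / 2),
    (exp(z * dt) - 1) / z
  )
  out
}

#' Exact step propagator and yield integrals for a constant Hamiltonian
#'
#' For one piecewise-constant step of the effective (non-Hermitian)
#' Hamiltonian `H` (rad/us) held for `dt` (us), computes the propagator
#' `U = exp(-i H dt)` and the exact accumulation operators
#' `Y_Q = integral_0^dt U(s)^dagger Q U(s) ds` for `Q = k_b P_S` (singlet
#' channel) and `Q = k_f I` (forward channel), via the eigendecomposition
#' `H = V L V^-1`. Falls back to the Pade exponential with Simpson substep
#' quadrature if the eigendecomposition is ill-conditioned.
#'
#' @param H Complex effective Hamiltonian (rad/us; anti-Hermitian part
#'   included).
#' @param dt Step duration, us.
#' @param QS Singlet accumulation operator `k_b(r) P_S` (1/us units).
#' @param kf Forward rate (1/us).
#' @return List with `U`, `YS`, `YF` (complex matrices).
#' @keywords internal
step_operators <- function(H, dt, QS, kf) {
  d <- nrow(H)
  eg <- tryCatch(eigen(H), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    V <- eg$vectors
    lam <- eg$values
    Vinv <- tryCatch(solve(V), error = function(e) NULL)
    if (!is.null(Vinv)) {
      resid <- norm1(V %*% (lam * Vinv) - H) / max(norm1(H), 1)
      ok <- resid < 1e-9
    }
  }
  if (ok) {
    U <- V %*% (exp(-1i * lam * dt) * Vinv)
    # z_ij = i(conj(lam_i) - lam_j); integral of exp(z s) over [0, dt]
    Zmat <- 1i * outer(Conj(lam), lam, `-`)
    Phi <- phi_elem(Zmat, dt)
    VH <- Conj(t(V))
    VinvH <- Conj(t(Vinv))
    GS <- (VH %*% QS %*% V) * Phi
    YS <- VinvH %*% GS %*% Vinv
    GF <- (VH %*% V) * Phi * kf
    YF <- VinvH %*% GF %*% Vinv
    return(list(U = U, YS = YS, YF = YF))
  }
  # fallback: Pade exponential over substeps + Simpson quadrature
  nsub <- 16L
  h <- dt / nsub
  Usub <- expm_complex(-1i * H * h)
  Id <- diag(d) + 0i
  Bs <- vector("list", nsub + 1L)
  Bs[[1]] <- Id
  for (j in seq_len(nsub)) Bs[[j + 1]] <- Usub %*% Bs[[j]]
  w <- c(1, rep(c(4, 2), length.out = nsub - 1L), 1) * h / 3
  YS <- matrix(0i, d, d)
  YF <- matrix(0i, d, d)
  for (j in seq_len(nsub + 1L)) {
    Bj <- Bs[[j]]
    BjH <- Conj(t(Bj))
    YS <- YS + w[j] * (BjH %*% QS %*% Bj)
    YF <- YF + w[j] * kf * (BjH %*% Bj)
  }
  list(U = Bs[[nsub + 1L]], YS = YS, YF = YF)
}
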