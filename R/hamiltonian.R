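# Assembly of the effective (non-Hermitian) spin Hamiltonian:
# Zeeman + hyperfine + exchange + dipolar, minus (i/2)(k_b(t) P_S + k_f I).

# free-electron gyromagnetic ratio / 2pi, MHz per uT (g = 2.002319)
GAMMA_E_MHZ_PER_UT <- 0.028024951

#' Specify the applied magnetic field
#'
#' @param magnitude Field magnitude in uT. Default 50 (geomagnetic; electron
#'   Larmor frequency about 1.4 MHz).
#' @param orientation Unit 3-vector, or one of `"parallel"` / `"perpendicular"`
#'   for axial models (z and x axes respectively, with z the symmetry axis).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(magnitude = 50, orientation = "parallel") {
  if (is.character(orientation)) {
    orientation <- switch(match.arg(orientation, c("parallel", "perpendicular")),
      parallel = c(0, 0, 1),
      perpendicular = c(1, 0, 0)
    )
  }
  nrm <- sqrt(sum(orientation^2))
  stopifnot(nrm > 0, magnitude >= 0)
  structure(
    list(magnitude = magnitude, orientation = orientation / nrm),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(
    "<field_spec> %g uT along (%.3f, %.3f, %.3f)\n",
    x$magnitude, x$orientation[1], x$orientation[2], x$orientation[3]
  ))
  invisible(x)
}

# Hermitian part of the Hamiltonian in rad/us for a given geometry sample.
# J in MHz, Dtens a 3x3 MHz tensor (or NULL).
hamiltonian_hermitian <- function(system, field, J, Dtens) {
  ops <- system$ops
  d <- system$dim
  S1 <- ops$e1
  S2 <- ops$e2
  axis <- field$orientation
  nuL <- GAMMA_E_MHZ_PER_UT * field$magnitude # MHz
  H <- nuL * (
    axis[1] * (S1$Sx + S2$Sx) +
      axis[2] * (S1$Sy + S2$Sy) +
      axis[3] * (S1$Sz + S2$Sz))
  if (nrow(system$nuclei)) {
    for (k in seq_len(nrow(system$nuclei))) {
      Sel <- if (system$nuclei$radical[[k]] == "A") S1 else S2
      Ik <- ops[[system$nuclei$label[[k]]]]
      A <- system$nuclei$tensor[[k]]
      Sv <- list(Sel$Sx, Sel$Sy, Sel$Sz)
      Iv <- list(Ik$Sx, Ik$Sy, Ik$Sz)
      for (a in 1:3) {
        for (b in 1:3) {
          if (A[a, b] != 0) H <- H + A[a, b] * (Sv[[a]] %*% Iv[[b]])
        }
      }
    }
  }
  dot12 <- S1$Sx %*% S2$Sx + S1$Sy %*% S2$Sy + S1$Sz %*% S2$Sz
  if (J != 0) {
    # convention J(t) * (1/2 + 2 S1.S2): singlet-triplet splitting 2 J
    H <- H + J * (diag(d) / 2 + 2 * dot12)
  }
  if (!is.null(Dtens)) {
    S1v <- list(S1$Sx, S1$Sy, S1$Sz)
    S2v <- list(S2$Sx, S2$Sy, S2$Sz)
    for (a in 1:3) {
      for (b in 1:3) {
        if (Dtens[a, b] != 0) H <- H + Dtens[a, b] * (S1v[[a]] %*% S2v[[b]])
      }
    }
  }
  2 * pi * H # MHz -> rad/us
}

#' Effective Hamiltonian at one geometry sample
#'
#' Assembles `H_eff = H(t) - (i/2) (k_b(t) P_S + k_f I)` where the Hermitian
#' part `H(t)` contains Zeeman (both electrons, equal isotropic g), hyperfine
#' `S.A_k.I_k`, exchange `J(t) (1/2 + 2 S1.S2)` and dipolar `S1.D(t).S2`
#' terms, all converted from MHz to angular frequency; the anti-Hermitian
#' part implements Haberkorn singlet recombination at rate `k_b(r(t))` plus
#' the spin-independent forward channel at `k_f` (linear rates, 1/us).
#'
#' @param system A [spin_system()].
#' @param field A [field_spec()].
#' @param laws A [coupling_laws()].
#' @param r Inter-radical distance at this instant, Angstrom.
#' @param n Unit inter-radical vector at this instant (dipolar axis).
#' @param include_decay If `FALSE`, return only the Hermitian part
#'   (`k_b = k_f = 0`).
#' @return A complex `dim x dim` matrix in rad/us; with decay included the
#'   imaginary parts of all its eigenvalues are non-positive.
#' @export
effective_hamiltonian <- function(system, field, laws, r = laws$r0,
                                  n = c(0, 0, 1), include_decay = TRUE) {
  J <- exchange_coupling(r, laws)
  Dtens <- if (laws$D0 != 0) dipolar_tensor(r * n, laws) else NULL
  H <- hamiltonian_hermitian(system, field, J, Dtens)
  if (include_decay) {
    PS <- singlet_projector(system)
    kb <- recombination_rate(r, laws)
    H <- H - (1i / 2) * (kb * PS + laws$kf * diag(system$dim))
  }
  H
}
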