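# Preset model systems: the one-nitrogen radical pair, the reduced two-level
# singlet/T0 model, and the four-spin flavin-tryptophan pair.

#' One-nitrogen radical pair model
#'
#' A single hyperfine-coupled spin-1 nitrogen (the dominant flavin N5) on
#' radical A and no hyperfine interactions on radical B. The hyperfine tensor
#' is axial with `A_perp = -2.6` MHz and `A_par = 49.2` MHz along z. Coupling
#' laws default to `r0 = 17.8` A, `kb0 = 2` /us, `kf = 1` /us,
#' `beta = 1.4` /A.
#'
#' @param J0 Exchange coupling at `r0`, MHz.
#' @param D0 Axial EED coupling at `r0`, MHz (0 disables EED).
#' @param A_perp,A_par Transverse / axial hyperfine principal values, MHz.
#' @param ... Further arguments to [coupling_laws()].
#' @return A list with elements `system` ([spin_system()]) and `laws`
#'   ([coupling_laws()]).
#' @export
one_nitrogen_model <- function(J0 = 0, D0 = 0, A_perp = -2.6, A_par = 49.2,
                               ...) {
  sys <- spin_system(tibble::tibble(
    label = "N5", radical = "A", spin = 1,
    tensor = list(diag(c(A_perp, A_perp, A_par)))
  ))
  list(system = sys, laws = coupling_laws(J0 = J0, D0 = D0, ...))
}

#' Four-spin flavin-tryptophan radical pair model
#'
#' Two nuclear spins per radical: N5 and N10 (both spin-1) on the flavin
#' radical A, N1 (spin-1) and H1 (spin-1/2) on the tryptophan radical B;
#' Hilbert-space dimension `4 * 3 * 3 * 3 * 2 = 216`, `Z = 54`. Default EED
#' coupling `D(r0) = -13.7` MHz. Hyperfine tensors default to the shipped
#' parameter file `four_spin_hyperfine_synthetic.yaml`: synthetic axial
#' placeholders representative of flavin/tryptophan literature couplings
#' (N5 matching the one-nitrogen model), intended to be replaced by
#' refined tensors via `tensors`.
#'
#' @param tensors Optional named list of 3x3 symmetric hyperfine tensors
#'   (MHz) overriding the defaults; names among `N5`, `N10`, `N1`, `H1`.
#' @param J0 Exchange coupling at `r0`, MHz.
#' @param D0 Axial EED coupling at `r0`, MHz. Default -13.7.
#' @param ... Further arguments to [coupling_laws()].
#' @return A list with elements `system` and `laws`.
#' @export
four_spin_model <- function(tensors = NULL, J0 = 0, D0 = -13.7, ...) {
  path <- system.file("extdata", "four_spin_hyperfine_synthetic.yaml",
    package = "rpdrive"
  )
  defaults <- lapply(yaml::read_yaml(path)$tensors, function(m) {
    do.call(rbind, m) * 1
  })
  if (!is.null(tensors)) {
    bad <- setdiff(names(tensors), names(defaults))
    if (length(bad)) {
      stop("unknown nucleus in tensor overrides: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    defaults[names(tensors)] <- tensors
  }
  spins <- c(N5 = 1, N10 = 1, N1 = 1, H1 = 0.5)
  radicals <- c(N5 = "A", N10 = "A", N1 = "B", H1 = "B")
  nuc <- tibble::tibble(
    label = names(spins),
    radical = unname(radicals),
    spin = unname(spins),
    tensor = defaults[names(spins)]
  )
  list(
    system = spin_system(nuc),
    laws = coupling_laws(J0 = J0, D0 = D0, ...)
  )
}

#' Reduced two-level singlet/T0 model
#'
#' The minimal driven level-crossing model: basis `(|T0>, |S>)`, detuning
#' `2 J(t)` between the states (triplet at `+J`, singlet at `-J`) and a
#' constant Rabi coupling `c` standing in for the hyperfine mixing (the
#' off-diagonal matrix element is `c/2`, so the static mixing frequency is
#' `sqrt(4 J^2 + c^2)`). Haberkorn recombination acts on `|S>` at rate
#' `k_b(r(t))` and the forward channel at `k_f`. Exposes the
#' small-amplitude Landau-Zener-Stuckelberg-Majorana regime of the full
#' model: with `c = A_par` this is exactly the `(T0, S)` sub-block of the
#' reduced (`A_perp = 0`) one-nitrogen pair at `m_I = 1` in a parallel
#' field, whose S-T0 element is `a = A_par / 2`.
#'
#' @param coupling Rabi coupling `c`, MHz. Default the one-nitrogen
#'   `A_par = 49.2`.
#' @param laws A [coupling_laws()].
#' @return A list with `hamiltonian(r)`: function returning the 2x2
#'   effective Hamiltonian (rad/us) at distance `r`; `PS`: the 2x2 singlet
#'   projector; `basis_labels`.
#' @export
two_level_model <- function(coupling = 49.2, laws = coupling_laws(J0 = 10)) {
  PS <- matrix(c(0, 0, 0, 1), 2, 2) + 0i
  hamiltonian <- function(r, include_decay = TRUE) {
    J <- exchange_coupling(r, laws)
    cc <- coupling / 2
    H <- 2 * pi * matrix(c(J, cc, cc, -J), 2, 2) + 0i
    if (include_decay) {
      kb <- recombination_rate(r, laws)
      H <- H - (1i / 2) * (kb * PS + laws$kf * diag(2))
    }
    H
  }
  list(
    hamiltonian = hamiltonian, PS = PS, laws = laws,
    basis_labels = c("T0", "S")
  )
}

#' Synthetic flavin-tryptophan inter-radical axis
#'
#' Reference inter-radical (dipolar) axis expressed in the flavin hyperfine
#' frame, in which the dominant N5 coupling is axial along z. In
#' cryptochrome the FAD-Trp separation vector makes a substantial angle
#' with the flavin normal, so the EED tensor is not aligned with the
#' hyperfine frame and the radical pair lacks axial symmetry. The refined
#' relative orientation is not shipped; this helper returns a synthetic
#' stand-in axis tilted `tilt_deg` degrees (default 60) from z in the x-z
#' plane, for sphere-measure anisotropy runs with EED included. Pass it as
#' `n0` to [trajectory_spec()].
#'
#' @param tilt_deg Tilt angle from the hyperfine z axis, degrees.
#' @return A unit 3-vector.
#' @export
fad_trp_dipolar_axis <- function(tilt_deg = 60) {
  th <- tilt_deg * pi / 180
  c(sin(th), 0, cos(th))
}

#' Named model registry
#'
#' Models addressable by name, as used by sweep configurations and the CLI
#' script: `one_nitrogen`, `four_spin_fad_trp`, `two_level`.
#'
#' @param name Model name.
#' @param ... Passed to the model constructor.
#' @return The constructor's value.
#' @export
model_registry <- function(name = c("one_nitrogen", "four_spin_fad_trp",
                             "two_level"), ...) {
  name <- match.arg(name)
  switch(name,
    one_nitrogen = one_nitrogen_model(...),
    four_spin_fad_trp = four_spin_model(...),
    two_level = two_level_model(...)
  )
}

#' Nuclear-spin-projection block of the one-nitrogen Hamiltonian
#'
#' With `A_perp = 0` the one-nitrogen effective Hamiltonian commutes with
#' the nuclear `I_z`, so it splits into three 4x4 blocks labelled by the
#' magnetic quantum number `m_I`. The block is obtained by numerically
#' projecting the full 12-dimensional effective Hamiltonian onto the `m_I`
#' subspace in the singlet-triplet basis `(|T+>, |T0>, |T->, |S>)`. The
#' S-T0 hyperfine coupling element equals `(A_par / 2) * m_I` (constant
#' for `m_I != 0`, absent for `m_I = 0`), the structure of a driven
#' Landau-Zener-Stuckelberg-Majorana two-level crossing.
#'
#' @param m_I Nuclear magnetic quantum number: 1, 0 or -1.
#' @param field A [field_spec()] (e.g. `"parallel"` or `"perpendicular"`).
#' @param laws A [coupling_laws()].
#' @param r Inter-radical distance, Angstrom (geometry state).
#' @param n Unit inter-radical vector.
#' @param A_par Axial hyperfine component, MHz.
#' @param A_perp Transverse hyperfine component; must be 0 (the block
#'   decomposition only exists for a purely axial coupling).
#' @param include_decay Include the anti-Hermitian recombination part.
#' @return A 4x4 complex matrix in the basis `(|T+>, |T0>, |T->, |S>)`.
#' @export
block_hamiltonian <- function(m_I, field, laws, r = laws$r0, n = c(0, 0, 1),
                              A_par = 49.2, A_perp = 0, include_decay = TRUE) {
  stopifnot(m_I %in% c(-1, 0, 1))
  if (A_perp != 0) {
    stop("the m_I block decomposition requires A_perp = 0", call. = FALSE)
  }
  mod <- one_nitrogen_model(A_perp = 0, A_par = A_par)
  # reuse the supplied laws so the block tracks the caller's couplings
  mod$laws <- laws
  sys <- mod$system
  H <- effective_hamiltonian(sys, field, laws,
    r = r, n = n,
    include_decay = include_decay
  )
  U <- singlet_triplet_basis(sys)
  Hst <- Conj(t(U)) %*% H %*% U
  # ST-basis ordering: electronic slot major, nuclear m_I in {+1, 0, -1}
  nuc_idx <- match(m_I, c(1, 0, -1))
  rows <- (seq_len(4) - 1L) * sys$Z + nuc_idx
  blk <- Hst[rows, rows]
  # verify reducibility: the discarded couplings must vanish for A_perp = 0
  off <- Hst[rows, -rows, drop = FALSE]
  if (max(abs(off)) > 1e-9 * max(abs(Hst))) {
    stop("Hamiltonian is not block-diagonal; block_hamiltonian() requires A_perp = 0",
      call. = FALSE
    )
  }
  blk
}
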