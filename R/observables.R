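# Directional magnetic-field-effect measures and the relative entropy of
# coherence.

#' Relative anisotropy for an axially symmetric model
#'
#' `chi = (Phi_par - Phi_perp) / Phi_bar` with the axial orientation average
#' `Phi_bar = (Phi_par + 2 Phi_perp) / 3` (one parallel and two equivalent
#' perpendicular axes). Signed; swapping the arguments flips the sign of the
#' numerator. The normalisation is isolated here so an alternative
#' convention is a one-line change.
#'
#' @param phi_par,phi_perp Singlet yields for the field parallel /
#'   perpendicular to the symmetry axis (each in `[0, 1]`).
#' @return The dimensionless relative anisotropy.
#' @export
relative_anisotropy_axial <- function(phi_par, phi_perp) {
  stopifnot(
    all(phi_par >= 0 & phi_par <= 1),
    all(phi_perp >= 0 & phi_perp <= 1)
  )
  denom <- axial_mean_yield(phi_par, phi_perp)
  if (any(denom <= 0)) {
    stop("mean singlet yield is zero; relative anisotropy undefined",
      call. = FALSE
    )
  }
  (phi_par - phi_perp) / denom
}

axial_mean_yield <- function(phi_par, phi_perp) (phi_par + 2 * phi_perp) / 3

#' Icosphere orientation grid
#'
#' Vertices of an icosahedron subdivided at frequency `f` and projected to
#' the unit sphere: `10 f^2 + 2` near-uniform orientations with a
#' deterministic ordering (`f = 16` gives the 2562-orientation grid used for
#' sphere-averaged anisotropies).
#'
#' @param subdivision_frequency Integer `f >= 1`.
#' @return A tibble with columns `x`, `y`, `z` (unit vectors) and `theta`,
#'   `phi` (polar/azimuthal angles, radians).
#' @export
orientation_grid <- function(subdivision_frequency = 16L) {
  f <- as.integer(subdivision_frequency)
  stopifnot(f >= 1)
  gr <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, gr, 0), c(1, gr, 0), c(-1, -gr, 0), c(1, -gr, 0),
    c(0, -1, gr), c(0, 1, gr), c(0, -1, -gr), c(0, 1, -gr),
    c(gr, 0, -1), c(gr, 0, 1), c(-gr, 0, -1), c(-gr, 0, 1)
  )
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  pts <- list()
  idx <- 1L
  for (fa in seq_len(nrow(faces))) {
    a <- verts[faces[fa, 1], ]
    b <- verts[faces[fa, 2], ]
    c3 <- verts[faces[fa, 3], ]
    for (i in 0:f) {
      for (j in 0:(f - i)) {
        k <- f - i - j
        p <- (i * a + j * b + k * c3) / f
        pts[[idx]] <- p / sqrt(sum(p^2))
        idx <- idx + 1L
      }
    }
  }
  P <- do.call(rbind, pts)
  key <- apply(round(P, 9), 1, paste, collapse = ",")
  P <- P[!duplicated(key), , drop = FALSE]
  ord <- order(round(P[, 3], 9), round(P[, 1], 9), round(P[, 2], 9),
    decreasing = TRUE
  )
  P <- P[ord, , drop = FALSE]
  tibble::tibble(
    x = P[, 1], y = P[, 2], z = P[, 3],
    theta = acos(pmin(1, pmax(-1, P[, 3]))),
    phi = atan2(P[, 2], P[, 1])
  )
}

#' Sphere-measure relative anisotropy
#'
#' `chi = (Phi_max - Phi_min) / <Phi>` over a set of per-orientation singlet
#' yields, with `<Phi>` the unweighted mean over grid orientations and the
#' extrema taken over grid points without interpolation. Non-negative, and
#' invariant under any permutation of the orientation list.
#'
#' @param yields Numeric vector of singlet yields (length `>= 2`).
#' @return The dimensionless sphere-measure anisotropy.
#' @export
anisotropy_over_sphere <- function(yields) {
  stopifnot(length(yields) >= 2, all(is.finite(yields)))
  m <- mean(yields)
  if (m <= 0) stop("mean singlet yield is zero; anisotropy undefined",
    call. = FALSE
  )
  (max(yields) - min(yields)) / m
}

#' Singlet yields over an orientation grid
#'
#' Evaluates the singlet yield for the magnetic field along each orientation
#' of a grid (rows of [orientation_grid()] or any tibble with `x`, `y`, `z`),
#' returning a tidy table ready for [anisotropy_over_sphere()] or plotting.
#'
#' @inheritParams propagate_yield_floquet
#' @param orientations Tibble with unit-vector columns `x`, `y`, `z`.
#' @param magnitude Field magnitude, uT.
#' @param method `"floquet"` (periodic specs) or `"direct"`.
#' @param ... Passed to the propagator.
#' @return The `orientations` tibble with a `phi_s` column appended.
#' @export
orientation_yields <- function(system, laws, spec, orientations,
                               magnitude = 50, method = c("floquet", "direct"),
                               ...) {
  method <- match.arg(method)
  fun <- if (method == "floquet") propagate_yield_floquet else propagate_yield_direct
  ys <- vapply(seq_len(nrow(orientations)), function(i) {
    fld <- field_spec(magnitude, c(
      orientations$x[i], orientations$y[i], orientations$z[i]
    ))
    fun(system, fld, laws, spec, ...)$phi_s
  }, numeric(1))
  dplyr::mutate(orientations, phi_s = ys)
}

# ---- coherence --------------------------------------------------------------

von_neumann_entropy <- function(p) {
  p <- p[p > 1e-15]
  -sum(p * log2(p))
}

#' Relative entropy of coherence
#'
#' `C_r(rho) = S(Delta(rho)) - S(rho)` in bits, where `Delta` deletes the
#' off-diagonal elements in the electronic singlet-triplet product basis and
#' `S` is the von Neumann entropy (log base 2). The state is normalised to
#' unit trace before evaluation (the propagated density operator decays).
#'
#' @param rho Density operator (complex matrix) in the Zeeman product basis,
#'   or already in the singlet-triplet basis if `basis = NULL`.
#' @param basis Unitary whose columns define the reference basis (default
#'   the singlet-triplet product basis of `system`); pass `NULL` if `rho`
#'   is already expressed in the reference basis.
#' @param system A [spin_system()] (used when `basis` is missing).
#' @return Coherence in bits, in `[0, log2(d)]`.
#' @export
relative_entropy_coherence <- function(rho, system = NULL, basis = NULL) {
  if (is.null(basis) && !is.null(system)) basis <- singlet_triplet_basis(system)
  if (!is.null(basis)) rho <- Conj(t(basis)) %*% rho %*% basis
  tr <- Re(sum(diag(rho)))
  if (tr <= 1e-14) stop("state has (near-)zero trace", call. = FALSE)
  rho <- rho / tr
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("state is not positive semidefinite (min eigenvalue ",
      format(min(ev)), ")",
      call. = FALSE
    )
  }
  ev <- pmax(ev, 0)
  S_rho <- von_neumann_entropy(ev)
  S_diag <- von_neumann_entropy(pmax(Re(diag(rho)), 0))
  max(S_diag - S_rho, 0)
}

#' Coherence time series along the driven reaction
#'
#' Propagates the density operator `rho(t)` from the initial singlet state
#' and evaluates the relative entropy of coherence of the normalised state
#' on a step grid, until the survival probability falls below
#' `survival_floor` (default `1e-3`, beyond which the remaining population
#' is negligible).
#'
#' @inheritParams propagate_yield_direct
#' @param survival_floor Propagation horizon criterion.
#' @param thin Evaluate the coherence every `thin`-th step (the propagation
#'   itself always uses the full step resolution).
#' @param t_max Optional hard time horizon (us), needed when the state does
#'   not decay (`k_b = k_f = 0`).
#' @return A tibble with columns `t` (us), `coherence` (bits) and
#'   `survival`.
#' @export
coherence_series <- function(system, field, laws, spec, n_steps = 256L,
                             survival_floor = 1e-3, thin = 4L,
                             max_periods = 1e4, t_max = Inf) {
  if (spec$kind == "brownian") {
    stop("coherence_series() supports deterministic trajectories", call. = FALSE)
  }
  U_st <- singlet_triplet_basis(system)
  rho <- singlet_projector(system) / system$Z
  dt <- if (spec$kind == "static") 0.02 else 1 / (spec$nu_d * n_steps)
  PSnull <- matrix(0i, system$dim, system$dim)
  out_t <- numeric(0)
  out_c <- numeric(0)
  out_s <- numeric(0)
  t <- 0
  step <- 0L
  # static: constant propagator reused
  so_static <- NULL
  repeat {
    surv <- Re(sum(diag(rho)))
    if (step %% thin == 0L) {
      out_t <- c(out_t, t)
      out_c <- c(out_c, relative_entropy_coherence(rho, basis = U_st))
      out_s <- c(out_s, surv)
    }
    if (surv < survival_floor || t >= t_max) break
    if (step > max_periods * n_steps) {
      stop("coherence horizon not reached within the step budget", call. = FALSE)
    }
    if (spec$kind == "static") {
      if (is.null(so_static)) {
        g <- trajectory(0, spec, laws)
        H <- effective_hamiltonian(system, field, laws, r = g$r[1], n = g$n[1, ])
        so_static <- step_operators(H, dt, PSnull, 0)
      }
      so <- so_static
    } else {
      g <- trajectory(t + dt / 2, spec, laws)
      H <- effective_hamiltonian(system, field, laws, r = g$r[1], n = g$n[1, ])
      so <- step_operators(H, dt, PSnull, 0)
    }
    rho <- so$U %*% rho %*% Conj(t(so$U))
    t <- t + dt
    step <- step + 1L
  }
  tibble::tibble(t = out_t, coherence = out_c, survival = out_s)
}

#' Time-integrated average coherence over the axial orientations
#'
#' Mean over the parallel and perpendicular field orientations of the
#' time-averaged relative entropy of coherence
#' `(1/T_int) int_0^T_int C_r(rho(t)) dt`, with the horizon `T_int` set by
#' the survival probability falling below `survival_floor`.
#'
#' @inheritParams coherence_series
#' @param magnitude Field magnitude, uT.
#' @return Average coherence in bits.
#' @export
time_averaged_coherence <- function(system, laws, spec, magnitude = 50,
                                    n_steps = 256L, survival_floor = 1e-3,
                                    thin = 4L) {
  vals <- vapply(c("parallel", "perpendicular"), function(orient) {
    ser <- coherence_series(system, field_spec(magnitude, orient), laws, spec,
      n_steps = n_steps, survival_floor = survival_floor, thin = thin
    )
    if (nrow(ser) < 2) return(ser$coherence[1])
    # trapezoidal time average
    dtv <- diff(ser$t)
    sum(dtv * (utils::head(ser$coherence, -1) + utils::tail(ser$coherence, -1)) / 2) /
      (max(ser$t) - min(ser$t))
  }, numeric(1))
  mean(vals)
}
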