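# Distance-to-interaction maps: exchange, dipolar coupling, recombination
# rate, and the inter-radical distance trajectory r(t).

#' Coupling laws of the radical pair
#'
#' Collects the parameters that map inter-radical geometry to interactions:
#' exchange coupling and singlet recombination rate both decay exponentially
#' away from the reference separation `r0`, the electron-electron dipolar
#' (EED) coupling follows the point-dipole `1/r^3` law, and the forward
#' (spin-independent) reaction proceeds at a constant rate.
#'
#' @param J0 Exchange coupling at `r0`, MHz (signed).
#' @param beta Exponential decay constant, 1/Angstrom. Default 1.4.
#' @param r0 Reference inter-radical distance, Angstrom. Default 17.8.
#' @param D0 Axial EED coupling at `r0`, MHz (signed; 0 disables EED).
#' @param kb0 Singlet recombination rate at `r0`, 1/us. Default 2.
#' @param kf Spin-independent forward rate, 1/us. Default 1.
#' @return An object of class `coupling_laws` (a named list).
#' @export
coupling_laws <- function(J0 = 0, beta = 1.4, r0 = 17.8, D0 = 0,
                          kb0 = 2, kf = 1) {
  stopifnot(beta > 0, r0 > 0, kb0 >= 0, kf >= 0)
  structure(
    list(J0 = J0, beta = beta, r0 = r0, D0 = D0, kb0 = kb0, kf = kf),
    class = "coupling_laws"
  )
}

#' @export
print.coupling_laws <- function(x, ...) {
  cat(sprintf(
    "<coupling_laws> J0 = %g MHz, D0 = %g MHz, beta = %g 1/A, r0 = %g A, kb0 = %g /us, kf = %g /us\n",
    x$J0, x$D0, x$beta, x$r0, x$kb0, x$kf
  ))
  invisible(x)
}

#' Distance-dependent exchange coupling
#'
#' `J(r) = J0 * exp(-beta * (r - r0))` (MHz); the sign of `J0` is preserved.
#'
#' @param r Inter-radical distance(s), Angstrom (`> 0`).
#' @param laws A [coupling_laws()] object.
#' @return Exchange coupling(s) in MHz.
#' @export
exchange_coupling <- function(r, laws) {
  stopifnot(all(r > 0))
  laws$J0 * exp(-laws$beta * (r - laws$r0))
}

#' Distance-dependent singlet recombination rate
#'
#' `k_b(r) = k_b0 * exp(-beta * (r - r0))` (1/us), reflecting the
#' exponential distance dependence of the electron-transfer recombination.
#'
#' @inheritParams exchange_coupling
#' @return Recombination rate(s) in 1/us (non-negative).
#' @export
recombination_rate <- function(r, laws) {
  stopifnot(all(r > 0))
  laws$kb0 * exp(-laws$beta * (r - laws$r0))
}

#' Point-dipole electron-electron dipolar tensor
#'
#' Traceless axial tensor aligned with the inter-radical vector. The axial
#' component (along the axis) is `D(r) = D0 * (r0/|r|)^3`; transverse
#' components are `-D(r)/2`, i.e. `T = D(r) * (3 n n' - I) / 2` with `n` the
#' unit inter-radical vector. The Hamiltonian contraction is `S1 . T . S2`.
#'
#' @param r_vec Inter-radical vector, Angstrom (length-3, nonzero).
#' @inheritParams exchange_coupling
#' @return A 3x3 real symmetric traceless matrix in MHz.
#' @export
dipolar_tensor <- function(r_vec, laws) {
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("inter-radical vector must be nonzero", call. = FALSE)
  n <- r_vec / r
  D <- laws$D0 * (laws$r0 / r)^3
  D * (3 * outer(n, n) - diag(3)) / 2
}

#' Specify the inter-radical distance trajectory
#'
#' The displacement waveform applied to the inter-radical separation. The
#' harmonic drive is `delta(t) = Delta_d * sin^2(pi * nu_d * t)` along the
#' displacement direction `u`, so the pair starts at the reference geometry
#' `r0 * n0`, returns to it at every full period `n / nu_d`, and reaches the
#' maximal displacement `Delta_d` at half periods `(2n + 1) / (2 nu_d)`. The
#' damped variant multiplies the displacement by `exp(-damping_rate * t)`;
#' the Brownian variant replaces it by an underdamped Langevin excursion
#' confined about the reference separation.
#'
#' @param kind One of `"static"`, `"harmonic"`, `"damped"`, `"brownian"`.
#' @param delta_d Signed oscillation amplitude `Delta_d`, Angstrom (negative
#'   values drive the radicals closer together).
#' @param nu_d Driving frequency `nu_d`, MHz (cycles per us).
#' @param damping_rate Amplitude decay rate `gamma`, 1/us (damped kind).
#' @param direction Unit 3-vector `u`: displacement direction. Default the
#'   reference inter-radical axis `n0`.
#' @param n0 Unit 3-vector: reference inter-radical axis (dipolar axis at
#'   rest). Default `c(0, 0, 1)`.
#' @param diffusion,friction,stiffness Brownian parameters: diffusion
#'   coefficient (A^2/us), velocity friction (1/us), harmonic confinement
#'   stiffness (1/us^2) about `r0`.
#' @param seed Integer seed for the Brownian path.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(kind = c("static", "harmonic", "damped", "brownian"),
                            delta_d = 0, nu_d = 1, damping_rate = 0,
                            direction = NULL, n0 = c(0, 0, 1),
                            diffusion = 0, friction = 10, stiffness = 100,
                            seed = 1L) {
  kind <- match.arg(kind)
  n0 <- n0 / sqrt(sum(n0^2))
  direction <- if (is.null(direction)) n0 else direction / sqrt(sum(direction^2))
  if (kind %in% c("harmonic", "damped") && nu_d <= 0) {
    stop("driving frequency nu_d must be positive", call. = FALSE)
  }
  structure(
    list(
      kind = kind, delta_d = delta_d, nu_d = nu_d,
      damping_rate = damping_rate, direction = direction, n0 = n0,
      diffusion = diffusion, friction = friction, stiffness = stiffness,
      seed = as.integer(seed)
    ),
    class = "trajectory_spec"
  )
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat(sprintf(
    "<trajectory_spec> %s: Delta_d = %g A, nu_d = %g MHz\n",
    x$kind, x$delta_d, x$nu_d
  ))
  invisible(x)
}

# scalar displacement delta(t) for the deterministic kinds
displacement_at <- function(t, spec) {
  switch(spec$kind,
    static = rep(0, length(t)),
    harmonic = spec$delta_d * sin(pi * spec$nu_d * t)^2,
    damped = spec$delta_d * exp(-spec$damping_rate * t) *
      sin(pi * spec$nu_d * t)^2,
    stop("displacement_at() is for deterministic trajectories", call. = FALSE)
  )
}

# sample an underdamped Langevin displacement path on a fixed grid
# dx = v dt; dv = (-friction v - stiffness x) dt + friction * sqrt(2 D) dW
brownian_path <- function(t_grid, spec) {
  n <- length(t_grid)
  x <- numeric(n)
  v <- numeric(n)
  sigma <- spec$friction * sqrt(2 * spec$diffusion)
  # seed locally, restoring the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(spec$seed)
  for (j in seq_len(n - 1)) {
    dt <- t_grid[j + 1] - t_grid[j]
    x[j + 1] <- x[j] + v[j] * dt
    v[j + 1] <- v[j] - (spec$friction * v[j] + spec$stiffness * x[j]) * dt +
      sigma * sqrt(dt) * stats::rnorm(1)
  }
  x
}

#' Evaluate the inter-radical geometry along a trajectory
#'
#' Returns the distance `r(t)` and unit inter-radical vector `n(t)` obtained
#' by applying the displacement waveform along `u` to the reference geometry
#' `r0 * n0`. For the Brownian kind the path is generated once on the given
#' grid from the spec's seed (reproducible).
#'
#' @param t Time(s), us (non-negative, increasing for `"brownian"`).
#' @param spec A [trajectory_spec()].
#' @param laws A [coupling_laws()] (supplies `r0`).
#' @return A list with `r` (numeric vector, Angstrom), `n` (matrix,
#'   `length(t)` x 3, unit rows) and `delta` (scalar displacements).
#' @export
trajectory <- function(t, spec, laws) {
  stopifnot(all(t >= 0))
  delta <- if (spec$kind == "brownian") {
    brownian_path(t, spec)
  } else {
    displacement_at(t, spec)
  }
  base <- laws$r0 * spec$n0
  vecs <- matrix(base, nrow = length(t), ncol = 3, byrow = TRUE) +
    outer(delta, spec$direction)
  r <- sqrt(rowSums(vecs^2))
  if (any(r <= 1e-9)) {
    stop("trajectory parameters drive the inter-radical distance to zero",
      call. = FALSE
    )
  }
  list(r = r, n = vecs / r, delta = delta)
}
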