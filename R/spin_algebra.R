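# Spin operators and singlet/triplet algebra for a two-electron radical pair
# with an arbitrary set of spin-1/2 / spin-1 nuclei.
#
# Unit convention (used throughout the package): couplings are entered in MHz
# and converted to angular frequency (rad/us, i.e. x 2*pi) when Hamiltonians
# are assembled; reaction rates k_b, k_f are linear rates in 1/us (no 2*pi).

#' Define a radical-pair spin system
#'
#' A spin system always contains two electron spins (one per radical) plus an
#' arbitrary list of hyperfine-coupled nuclei of spin 1/2 or 1. The Hilbert
#' space is the tensor product of the two electron doublets (ordered first)
#' and the nuclear multiplets in declaration order, so the total dimension is
#' `4 * Z` with `Z` the product of the nuclear multiplicities `2I + 1`.
#'
#' @param nuclei A data frame (or tibble) with one row per nucleus and columns
#'   `radical` (`"A"` or `"B"`: which electron the nucleus couples to), `spin`
#'   (`0.5` or `1`), and `tensor` (a list-column of 3x3 real symmetric
#'   hyperfine tensors in MHz). An empty data frame (or `NULL`) gives a bare
#'   two-electron pair. Optionally a column `label` names each nucleus.
#'
#' @return An object of class `spin_system`: a list with elements `nuclei`
#'   (tibble as above), `Z` (nuclear-subspace dimension `Z = Z_A * Z_B`),
#'   `dim` (total Hilbert-space dimension `4 * Z`), and precomputed spin
#'   operators (see [build_spin_operators()]).
#' @examples
#' sys <- spin_system(tibble::tibble(
#'   label = "N5", radical = "A", spin = 1,
#'   tensor = list(diag(c(-2.6, -2.6, 49.2)))
#' ))
#' sys$dim # 12
#' @export
spin_system <- function(nuclei = NULL) {
  if (is.null(nuclei) || nrow(as.data.frame(nuclei)) == 0L) {
    nuclei <- tibble::tibble(
      label = character(), radical = character(),
      spin = numeric(), tensor = list()
    )
  } else {
    nuclei <- tibble::as_tibble(nuclei)
    if (!all(c("radical", "spin", "tensor") %in% names(nuclei))) {
      stop("`nuclei` needs columns radical, spin, tensor", call. = FALSE)
    }
    if (!"label" %in% names(nuclei)) {
      nuclei$label <- paste0("I", seq_len(nrow(nuclei)))
    }
    if (!all(nuclei$radical %in% c("A", "B"))) {
      stop("nucleus `radical` must be \"A\" or \"B\"", call. = FALSE)
    }
    if (!all(nuclei$spin %in% c(0.5, 1))) {
      stop("unsupported nuclear spin quantum number; only 1/2 and 1 are supported",
        call. = FALSE
      )
    }
    for (k in seq_len(nrow(nuclei))) {
      A <- nuclei$tensor[[k]]
      if (!is.matrix(A) || !all(dim(A) == c(3L, 3L)) || !is.numeric(A)) {
        stop("hyperfine tensors must be numeric 3x3 matrices (MHz)", call. = FALSE)
      }
      scale <- max(abs(A), 1)
      if (max(abs(A - t(A))) > 1e-12 * scale) {
        stop("hyperfine tensor for nucleus ", nuclei$label[[k]],
          " is not symmetric",
          call. = FALSE
        )
      }
    }
  }
  mult <- if (nrow(nuclei)) as.integer(2 * nuclei$spin + 1) else integer()
  Z <- prod(c(1L, mult))
  sys <- structure(
    list(
      electron_count = 2L,
      nuclei = nuclei,
      multiplicities = mult,
      Z = as.integer(Z),
      dim = as.integer(4L * Z)
    ),
    class = "spin_system"
  )
  sys$ops <- build_spin_operators(sys)
  sys
}

#' @export
print.spin_system <- function(x, ...) {
  cat(
    "<spin_system> 2 electrons + ", nrow(x$nuclei), " nuclei; Z = ", x$Z,
    "; dim = ", x$dim, "\n",
    sep = ""
  )
  if (nrow(x$nuclei)) {
    print(tibble::as_tibble(x$nuclei[c("label", "radical", "spin")]))
  }
  invisible(x)
}

# single-particle spin matrices (complex), spin s in {1/2, 1}
spin_matrices <- function(s) {
  if (!s %in% c(0.5, 1)) {
    stop("unsupported spin quantum number: ", s, call. = FALSE)
  }
  m <- seq(s, -s) # projection quantum numbers, descending
  d <- length(m)
  Sz <- diag(m) + 0i
  # raising operator: <m+1|S+|m> = sqrt(s(s+1) - m(m+1))
  Sp <- matrix(0i, d, d)
  for (j in seq_len(d - 1)) {
    Sp[j, j + 1] <- sqrt(s * (s + 1) - m[j + 1] * (m[j + 1] + 1))
  }
  Sm <- Conj(t(Sp))
  list(
    Sx = (Sp + Sm) / 2,
    Sy = (Sp - Sm) / (2i),
    Sz = Sz
  )
}

# Kronecker embedding of a single-particle operator at slot `which` among
# particle dimensions `dims` (order: electron 1, electron 2, nuclei)
embed_op <- function(op, which, dims) {
  left <- prod(c(1, dims[seq_len(which - 1)]))
  right <- prod(c(1, dims[-seq_len(which)]))
  kronecker(diag(left) + 0i, kronecker(op, diag(right) + 0i))
}

#' Build embedded spin operators for every particle
#'
#' Returns Cartesian spin operators for each particle of the system, embedded
#' in the full product space (electron 1, electron 2, then nuclei in
#' declaration order). Operators of distinct particles commute exactly.
#'
#' @param system A [spin_system()] (the bare list form, before operators are
#'   attached, is also accepted).
#' @return A list with one element per particle (`e1`, `e2`, then nuclear
#'   labels), each a list of complex `dim x dim` matrices `Sx`, `Sy`, `Sz`.
#' @export
build_spin_operators <- function(system) {
  mult <- system$multiplicities
  dims <- c(2L, 2L, mult)
  spins <- c(0.5, 0.5, if (length(mult)) system$nuclei$spin else numeric())
  labels <- c("e1", "e2", if (length(mult)) system$nuclei$label else character())
  ops <- vector("list", length(dims))
  names(ops) <- labels
  for (p in seq_along(dims)) {
    sm <- spin_matrices(spins[p])
    ops[[p]] <- lapply(sm, embed_op, which = p, dims = dims)
  }
  ops
}

#' Singlet projection operator
#'
#' The projector onto the electronic singlet manifold,
#' `P_S = I/4 - S1.S2`, tensored with the identity on the nuclear subspace.
#' It is idempotent and has trace `Z` (one singlet state per nuclear
#' configuration).
#'
#' @inheritParams build_spin_operators
#' @return A complex `dim x dim` matrix.
#' @export
singlet_projector <- function(system) {
  S1 <- system$ops$e1
  S2 <- system$ops$e2
  dot <- S1$Sx %*% S2$Sx + S1$Sy %*% S2$Sy + S1$Sz %*% S2$Sz
  diag(system$dim) / 4 - dot
}

#' Singlet-triplet product basis
#'
#' Unitary change of basis from the up/down Zeeman product basis to the
#' electronic singlet-triplet basis tensored with the nuclear Zeeman basis.
#' Electronic columns are ordered `|T+>, |T0>, |T->, |S>`.
#'
#' @inheritParams build_spin_operators
#' @return A complex unitary `dim x dim` matrix `U` whose columns are the
#'   basis states; transform operators as `Conj(t(U)) %*% O %*% U`.
#' @export
singlet_triplet_basis <- function(system) {
  s2 <- 1 / sqrt(2)
  # electron product order: |uu>, |ud>, |du>, |dd>
  U_el <- matrix(
    c(
      1, 0, 0, 0, # T+
      0, s2, s2, 0, # T0
      0, 0, 0, 1, # T-
      0, s2, -s2, 0 # S
    ),
    nrow = 4, ncol = 4
  ) + 0i
  kronecker(U_el, diag(system$Z) + 0i)
}

# index of the electronic singlet slot in the ST basis ordering
ST_SINGLET_SLOT <- 4L

# columns spanning the Z singlet (x) nuclear basis states, in the Zeeman
# product basis: used as initial wavefunctions for yield propagation
singlet_state_matrix <- function(system) {
  U <- singlet_triplet_basis(system)
  U[, (ST_SINGLET_SLOT - 1L) * system$Z + seq_len(system$Z), drop = FALSE]
}
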