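# Pairwise geometry helpers shared by the tensor builders.
.pair_blocks <- function(n) {
  # index helper: rows/cols of atom A's 3x3 block
  function(a) (3 * (a - 1) + 1):(3 * a)
}

#' Bare point-dipole interaction tensor
#'
#' Builds the 3N x 3N dipole-dipole coupling matrix with 3 x 3 blocks
#' \deqn{T_{AB} = \frac{\mathbf{1} - 3\hat R \hat R^T}{R^3},}
#' i.e. the Hessian of the Coulomb kernel with respect to the two dipole
#' positions.  For two atoms aligned along z this gives
#' \eqn{T_{zz} = -2/R^3} and \eqn{T_{xx} = T_{yy} = +1/R^3}.  Diagonal
#' (self) blocks are zero.
#'
#' @param coords N x 3 matrix of positions (Bohr).
#' @return 3N x 3N symmetric matrix.
#' @export
bare_dipole_tensor <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  T <- matrix(0, 3 * n, 3 * n)
  blk <- .pair_blocks(n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      r <- coords[b, ] - coords[a, ]
      d <- sqrt(sum(r^2))
      if (d == 0) stop(sprintf("coincident atoms %d and %d", a, b))
      rhat <- r / d
      blkT <- (diag(3) - 3 * tcrossprod(rhat)) / d^3
      T[blk(a), blk(b)] <- blkT
      T[blk(b), blk(a)] <- blkT
    }
  }
  T
}

#' Gaussian width of a Drude charge distribution
#'
#' The oscillator ground-state charge cloud is a Gaussian whose width is
#' tied to the (dynamic) polarizability:
#' \eqn{\sigma_A = (\sqrt{2/\pi}\,\alpha_A/3)^{1/3}}.
#'
#' @param alpha polarizabilities (Bohr^3), any shape.
#' @return widths (Bohr), same shape.
#' @export
gaussian_width <- function(alpha) (sqrt(2 / pi) * alpha / 3)^(1 / 3)

#' Dipole tensor between Gaussian charge distributions
#'
#' Finite-width version of [bare_dipole_tensor()] for atoms whose dipole
#' density is a Gaussian of width \eqn{\sigma_A}: the Coulomb kernel
#' \eqn{1/R} is replaced by \eqn{\mathrm{erf}(\zeta)/R} with
#' \eqn{\zeta = R/\sigma_{AB}}, \eqn{\sigma_{AB}^2=\sigma_A^2+\sigma_B^2}.
#' The result is
#' \deqn{T^{gg}_{AB} = \left[\mathrm{erf}(\zeta)
#'   - \frac{2\zeta}{\sqrt\pi} e^{-\zeta^2}\right] T_{AB}
#'   + \frac{4}{\sqrt\pi}\,\zeta^3 e^{-\zeta^2}\,
#'     \frac{\mathbf{R}\mathbf{R}^T}{R^5},}
#' which tends to the bare tensor for \eqn{R \gg \sigma} and stays finite
#' (isotropic, value \eqn{4/(3\sqrt\pi\,\sigma_{AB}^3)\,\mathbf 1}) as
#' \eqn{R \to 0}.
#'
#' @param coords N x 3 matrix of positions (Bohr).
#' @param sigma per-atom Gaussian widths (Bohr).
#' @return 3N x 3N symmetric matrix.
#' @export
gaussian_dipole_tensor <- function(coords, sigma) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(sigma) == 1) sigma <- rep(sigma, n)
  stopifnot(length(sigma) == n, all(sigma > 0))
  T <- matrix(0, 3 * n, 3 * n)
  blk <- .pair_blocks(n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      r <- coords[b, ] - coords[a, ]
      d <- sqrt(sum(r^2))
      sab <- sqrt(sigma[a]^2 + sigma[b]^2)
      if (d < 1e-12) {
        blkT <- diag(3) * 4 / (3 * sqrt(pi) * sab^3)
      } else {
        zeta <- d / sab
        rhat <- r / d
        bare <- (diag(3) - 3 * tcrossprod(rhat)) / d^3
        # erf(z) - (2z/sqrt(pi)) exp(-z^2) suffers catastrophic
        # cancellation for small z; switch to its Taylor series there
        damp <- if (zeta < 0.05) {
          2 / sqrt(pi) * (2 * zeta^3 / 3 - 2 * zeta^5 / 5 + zeta^7 / 7)
        } else {
          pracma::erf(zeta) - 2 * zeta / sqrt(pi) * exp(-zeta^2)
        }
        blkT <- damp * bare +
          4 / sqrt(pi) * zeta^3 * exp(-zeta^2) * tcrossprod(rhat) / d^3
      }
      T[blk(a), blk(b)] <- blkT
      T[blk(b), blk(a)] <- blkT
    }
  }
  T
}

#' Fermi damping factors for range separation
#'
#' Per-pair switching function
#' \eqn{f(R_{AB}) = 1/(1 + e^{-a (R_{AB}/S_{AB} - 1)})} with
#' \eqn{S_{AB} = \beta (R_{vdw,A} + R_{vdw,B})}; \eqn{f = 1/2} exactly at
#' \eqn{R_{AB} = S_{AB}}.
#'
#' @param coords N x 3 positions (Bohr).
#' @param rvdw per-atom van der Waals radii (Bohr).
#' @param a damping steepness (default 6).
#' @param beta range-separation parameter (default 0.83, the published
#'   value tuned for use with the PBE functional).
#' @return N x N matrix of damping factors (diagonal zero).
#' @export
fermi_damping <- function(coords, rvdw, a = 6, beta = 0.83) {
  if (beta <= 0) stop("range-separation parameter beta must be positive")
  n <- nrow(coords)
  if (length(rvdw) == 1) rvdw <- rep(rvdw, n)
  d <- as.matrix(stats::dist(coords))
  s <- beta * outer(rvdw, rvdw, "+")
  f <- 1 / (1 + exp(-a * (d / s - 1)))
  diag(f) <- 0
  dimnames(f) <- NULL
  f
}

#' Range-separated dipole tensors
#'
#' Splits the dipole coupling into a long-range part used in the MBD
#' Hamiltonian and a short-range part used in the Dyson screening:
#' \eqn{T^{lr} = f \cdot T^{bare}} (point dipoles) and
#' \eqn{T^{sr} = (1-f) \cdot T^{gg}} (Gaussian widths), with the Fermi
#' factor of [fermi_damping()] applied per atom pair.
#'
#' @param coords N x 3 positions (Bohr).
#' @param sigma per-atom Gaussian widths (Bohr), see [gaussian_width()].
#' @param rvdw per-atom van der Waals radii (Bohr).
#' @param a damping steepness.
#' @param beta range-separation parameter.
#' @return an object of class `mbd_tensors`: list with `T_bare`, `T_sr`,
#'   `T_lr`, the damping matrix `f`, and the parameters used.
#' @export
range_separate <- function(coords, sigma, rvdw, a = 6, beta = 0.83) {
  coords <- as.matrix(coords)
  T_bare <- bare_dipole_tensor(coords)
  T_gg <- gaussian_dipole_tensor(coords, sigma)
  f <- fermi_damping(coords, rvdw, a = a, beta = beta)
  fx <- .expand_pair_factor(f)
  structure(
    list(T_bare = T_bare,
         T_sr = (1 - fx) * T_gg,
         T_lr = fx * T_bare,
         f = f, a = a, beta = beta,
         coords = coords, rvdw = rvdw, sigma = sigma),
    class = "mbd_tensors"
  )
}

# expand an N x N pair factor to 3N x 3N (constant over each block),
# zero diagonal blocks
.expand_pair_factor <- function(f) {
  n <- nrow(f)
  fx <- f[rep(seq_len(n), each = 3), rep(seq_len(n), each = 3)]
  for (a in seq_len(n)) {
    idx <- (3 * (a - 1) + 1):(3 * a)
    fx[idx, idx] <- 0
  }
  fx
}
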