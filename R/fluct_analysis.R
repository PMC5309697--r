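#' Correlated ground-state wavefunction of the coupled oscillators
#'
#' The coupled ground state is a product of Gaussians in the normal-mode
#' coordinates; in the mass-weighted atomic displacements its covariance
#' is \deqn{\langle \xi \xi^T \rangle = \tfrac12 \sum_i
#' \tilde\xi_i \tilde\xi_i^T / \tilde\omega_i.}  With unit pseudoelectron
#' charge the effective masses follow from \eqn{\alpha_0 = q^2/(m
#' \omega^2)}, i.e. \eqn{m_A = 1/(\bar\alpha_{0,A}\,\bar\omega_A^2)}, and
#' each atom's position covariance is its diagonal 3 x 3 block divided by
#' \eqn{m_A}.
#'
#' @param solution an `mbd_solution` (must carry `omega_atoms` and
#'   `alpha0_atoms`, as produced via [diagonalize_hamiltonian()] with
#'   `params`).
#' @param structure the `mbd_structure` (for atom positions).
#' @return class `mbd_wavefunction`: list with `coords`, `mass` (per
#'   atom), `sigma_cov` (list of per-atom 3 x 3 position covariance
#'   matrices), `solution`.
#' @export
build_wavefunction <- function(solution, structure) {
  if (is.null(solution$omega_atoms) || is.null(solution$alpha0_atoms)) {
    stop("solution must carry per-atom parameters (diagonalize with params)")
  }
  n <- length(solution$omega_atoms)
  mass <- 1 / (solution$alpha0_atoms * solution$omega_atoms^2)
  xi_cov <- 0.5 * solution$modes %*%
    (t(solution$modes) / solution$freq)
  sigma <- vector("list", n)
  for (a in seq_len(n)) {
    rows <- (3 * (a - 1) + 1):(3 * a)
    S <- xi_cov[rows, rows] / mass[a]
    sigma[[a]] <- (S + t(S)) / 2
  }
  structure(
    list(coords = structure$coords, mass = mass, sigma_cov = sigma,
         solution = solution),
    class = "mbd_wavefunction"
  )
}

#' Build a regular density grid around a structure
#'
#' Orthogonal grid with uniform spacing, padded beyond the bounding box of
#' the atoms.
#'
#' @param structure an `mbd_structure` (or N x 3 coordinate matrix, Bohr).
#' @param spacing voxel edge in Bohr (default 0.4).
#' @param padding margin around the atoms in angstrom (default 4).
#' @return an `mbd_grid` of zeros.
#' @export
density_grid <- function(structure, spacing = 0.4, padding = 4) {
  coords <- if (inherits(structure, "mbd_structure")) structure$coords
            else as.matrix(structure)
  pad <- angstrom_to_bohr(padding)
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  mbd_grid(lo, diag(spacing, 3), shape)
}

#' Charge density of the correlated wavefunction
#'
#' Expectation value of the charge-density operator for unit-charge
#' pseudoelectrons: a sum of normalized anisotropic Gaussians
#' \eqn{\rho(\mathbf r) = \sum_A G(\mathbf r; \mathbf R_A, \Sigma_A)}
#' with the per-atom position covariances of the wavefunction.  The
#' integral over all space is the number of oscillators N.
#'
#' @param wavefunction an `mbd_wavefunction`.
#' @param grid an `mbd_grid` (default: [density_grid()] around the atoms).
#' @param cutoff evaluation radius per atom in standard deviations
#'   (default 8; Gaussian tails beyond this are dropped).
#' @return an `mbd_grid` with the density in its `values`; attribute
#'   `coarse_atoms` lists atoms whose smallest covariance eigenvalue is
#'   under-resolved by the voxel diagonal (empty when the grid is fine
#'   enough).
#' @export
charge_density <- function(wavefunction, grid = NULL, cutoff = 8) {
  if (is.null(grid)) grid <- density_grid(wavefunction$coords)
  vals <- array(0, dim = grid$shape)
  step <- sqrt(rowSums(grid$axes^2))
  vox_diag <- sqrt(sum((colSums(grid$axes))^2))
  coarse <- integer(0)
  for (a in seq_along(wavefunction$mass)) {
    S <- wavefunction$sigma_cov[[a]]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (sqrt(min(ev)) < vox_diag) coarse <- c(coarse, a)
    vals <- vals + .gaussian_on_grid(grid, wavefunction$coords[a, ], S,
                                     cutoff = cutoff, step = step)
  }
  out <- mbd_grid(grid$origin, grid$axes, grid$shape, vals)
  attr(out, "coarse_atoms") <- coarse
  if (length(coarse) > 0) {
    warning(sprintf("grid too coarse for %d atom(s); densities smoothed",
                    length(coarse)))
  }
  out
}

# evaluate one normalized Gaussian N(center, S) on the (orthogonal-axis)
# grid, restricted to a bounding sub-box of `cutoff` max-std-devs
.gaussian_on_grid <- function(grid, center, S, cutoff = 8, step = NULL) {
  if (is.null(step)) step <- sqrt(rowSums(grid$axes^2))
  ev <- eigen(S, symmetric = TRUE)
  sd_max <- sqrt(max(ev$values))
  rel <- center - grid$origin
  # grid index window (axes assumed orthogonal for windowing; exact
  # evaluation below works for any axes)
  idx0 <- as.vector(rel %*% solve(grid$axes))
  half <- cutoff * sd_max / step
  lo <- pmax(1L, as.integer(floor(idx0 - half)) + 1L)
  hi <- pmin(grid$shape, as.integer(ceiling(idx0 + half)) + 1L)
  out <- array(0, dim = grid$shape)
  if (any(lo > hi)) return(out)
  i <- lo[1]:hi[1]; j <- lo[2]:hi[2]; k <- lo[3]:hi[3]
  pts <- as.matrix(expand.grid(i = i - 1, j = j - 1, k = k - 1))
  xyz <- sweep(pts %*% grid$axes, 2, grid$origin - 0, "+")
  d <- sweep(xyz, 2, center, "-")
  Sinv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  q <- rowSums((d %*% Sinv) * d)
  norm <- 1 / sqrt((2 * pi)^3 * prod(ev$values))
  out[i, j, k] <- array(norm * exp(-0.5 * q),
                        dim = c(length(i), length(j), length(k)))
  out
}

#' Density difference between a complex and its fragments
#'
#' \eqn{\Delta\rho = \rho_{complex} - \sum_f \rho_{fragment,f}} on a
#' shared grid.  Since fragments keep their positions in the complex, the
#' difference integrates to zero (charge conservation) and visualizes the
#' charge polarization induced by the long-range correlation.
#'
#' @param complex_wf `mbd_wavefunction` of the complex.
#' @param fragment_wfs list of `mbd_wavefunction`s of the fragments; their
#'   atoms must jointly match the complex atom positions.
#' @param grid shared `mbd_grid` (default: built around the complex).
#' @param cutoff see [charge_density()].
#' @return an `mbd_grid` holding \eqn{\Delta\rho}.
#' @export
density_difference <- function(complex_wf, fragment_wfs, grid = NULL,
                               cutoff = 8) {
  if (is.null(grid)) grid <- density_grid(complex_wf$coords)
  frag_coords <- do.call(rbind, lapply(fragment_wfs, `[[`, "coords"))
  if (nrow(frag_coords) != nrow(complex_wf$coords)) {
    stop(sprintf("fragments have %d atoms, complex has %d",
                 nrow(frag_coords), nrow(complex_wf$coords)))
  }
  rho <- charge_density(complex_wf, grid, cutoff)
  vals <- rho$values
  for (wf in fragment_wfs) {
    vals <- vals - charge_density(wf, grid, cutoff)$values
  }
  mbd_grid(grid$origin, grid$axes, grid$shape, vals)
}

#' Total displaced charge
#'
#' Integral of a density difference over the charge-accumulating region
#' (all voxels with \eqn{\Delta\rho > 0}), voxel-volume weighted.
#'
#' @param delta_grid an `mbd_grid` holding a density difference.
#' @return displaced charge in electrons.
#' @export
displaced_charge <- function(delta_grid) {
  v <- delta_grid$values
  sum(v[v > 0]) * voxel_volume(delta_grid)
}

#' Smoothed density of oscillation states
#'
#' Places a unit-area Gaussian of the given half-width at every coupled
#' fluctuation energy \eqn{\hbar\tilde\omega_i} (converted to eV) and
#' evaluates the sum on a uniform energy grid; the curve integrates to the
#' number of modes.
#'
#' @param freq coupled frequencies in Hartree (e.g. `solution$freq`), or
#'   an `mbd_solution`.
#' @param half_width Gaussian half-width in eV (default 0.06).
#' @param energy optional energy grid in eV; by default spans the spectrum
#'   with a 5-half-width margin at ~2000 points.
#' @return data.frame with columns `energy_ev` and `dos`.
#' @export
energy_spectrum <- function(freq, half_width = 0.06, energy = NULL) {
  if (inherits(freq, "mbd_solution")) freq <- freq$freq
  if (half_width <= 0) stop("half_width must be positive")
  e_modes <- hartree_to_ev(freq)
  if (is.null(energy)) {
    lo <- max(0, min(e_modes) - 5 * half_width)
    hi <- max(e_modes) + 5 * half_width
    energy <- seq(lo, hi, length.out = 2001)
  }
  dos <- rep(0, length(energy))
  for (e in e_modes) {
    dos <- dos + stats::dnorm(energy, mean = e, sd = half_width)
  }
  data.frame(energy_ev = energy, dos = dos)
}

#' Per-atom dipole amplitude field of one fluctuation mode
#'
#' The arrow field visualizing a mode: atom A's vector is the mode's
#' displacement components on A scaled by \eqn{q/\sqrt{m_A}} (the dipole
#' amplitude of unit-charge pseudoelectrons).  Atoms whose amplitude falls
#' below `threshold` times the largest amplitude are zeroed for display.
#'
#' @param wavefunction an `mbd_wavefunction` (supplies masses), or an
#'   `mbd_solution` plus explicit `mass`.
#' @param mode_index which coupled mode (1-based, ascending frequency).
#' @param threshold visibility cutoff as a fraction of the largest atomic
#'   amplitude (default 0.05); use 0 to keep all atoms.
#' @param mass optional per-atom masses when passing a bare solution.
#' @return N x 3 matrix of dipole-amplitude vectors; attribute `kept`
#'   flags the atoms above threshold.
#' @export
mode_dipole_field <- function(wavefunction, mode_index, threshold = 0.05,
                              mass = NULL) {
  if (inherits(wavefunction, "mbd_wavefunction")) {
    sol <- wavefunction$solution
    mass <- wavefunction$mass
  } else {
    sol <- wavefunction
    if (is.null(mass)) mass <- 1 / (sol$alpha0_atoms * sol$omega_atoms^2)
  }
  nmode <- length(sol$freq)
  if (mode_index < 1 || mode_index > nmode) {
    stop(sprintf("mode index %d out of range 1..%d", mode_index, nmode))
  }
  v <- matrix(sol$modes[, mode_index], ncol = 3, byrow = TRUE)
  v <- v / sqrt(mass)
  amp <- sqrt(rowSums(v^2))
  kept <- amp >= threshold * max(amp)
  v[!kept, ] <- 0
  attr(v, "kept") <- kept
  v
}

#' Expand complex fluctuation modes in the fragment-mode basis
#'
#' Embeds each fragment's modes into the full displacement space (zeros
#' outside the fragment) and projects:
#' \eqn{c_{ij} = \tilde\xi_i^{complex} \cdot \tilde\xi_j^{fragment}}.
#' Because the fragments partition the atoms, the embedded fragment modes
#' form a complete orthonormal basis, so the coefficient matrix is
#' orthogonal and every row satisfies \eqn{\sum_j c_{ij}^2 = 1}.
#'
#' @param complex_solution `mbd_solution` of the complex.
#' @param fragment_solutions list of `mbd_solution`s, one per fragment, in
#'   fragment order.
#' @param structure the complex `mbd_structure` (supplies the fragment
#'   partition).
#' @return class `mbd_mode_expansion`: list with `coeff` (3N x 3N,
#'   rows = complex modes), `fragment` (per column), `within` (mode index
#'   within its fragment), `omega_fragment` (per column), `freq_complex`.
#' @export
project_modes <- function(complex_solution, fragment_solutions, structure) {
  n <- n_atoms(structure)
  nf <- n_fragments(structure)
  if (length(fragment_solutions) != nf) {
    stop(sprintf("%d fragment solutions supplied for %d fragments",
                 length(fragment_solutions), nf))
  }
  basis <- matrix(0, 3 * n, 3 * n)
  frag_id <- integer(3 * n)
  within <- integer(3 * n)
  omega_frag <- numeric(3 * n)
  col <- 0L
  for (f in seq_len(nf)) {
    idx <- fragment_atoms(structure, f)
    sol_f <- fragment_solutions[[f]]
    if (length(sol_f$freq) != 3 * length(idx)) {
      stop(sprintf("fragment %d solution has %d modes, expected %d",
                   f, length(sol_f$freq), 3 * length(idx)))
    }
    rows <- as.vector(t(outer(idx - 1, 1:3, function(i, c) 3 * i + c)))
    for (j in seq_along(sol_f$freq)) {
      col <- col + 1L
      basis[rows, col] <- sol_f$modes[, j]
      frag_id[col] <- f
      within[col] <- j
      omega_frag[col] <- sol_f$freq[j]
    }
  }
  coeff <- crossprod(complex_solution$modes, basis)
  structure(
    list(coeff = coeff, fragment = frag_id, within = within,
         omega_fragment = omega_frag,
         freq_complex = complex_solution$freq),
    class = "mbd_mode_expansion"
  )
}

#' @export
print.mbd_mode_expansion <- function(x, ...) {
  cat(sprintf("<mbd_mode_expansion: %d complex modes over %d fragment modes>\n",
              nrow(x$coeff), ncol(x$coeff)))
  invisible(x)
}

#' Collectivity of a fluctuation mode
#'
#' Inverse participation of a complex mode in the fragment-mode basis.
#' With the squared convention (the default) a normalized expansion with
#' three equal components yields exactly 3; a mode identical to a single
#' fragment mode yields 1.  The value lies in \eqn{[1, 3N]}.  The `linear`
#' convention, \eqn{1/\max_j |c_{ij}|}, is also available for comparison
#' (the same three-component example then gives \eqn{\sqrt 3}).
#'
#' @param expansion an `mbd_mode_expansion`, or a numeric vector/matrix of
#'   expansion coefficients (rows = modes).
#' @param mode_index mode(s) to evaluate; default all.
#' @param convention `"squared"` (inverse participation ratio,
#'   \eqn{1/\max_j c_{ij}^2}) or `"linear"`.
#' @return numeric vector of collectivity values.
#' @export
collectivity <- function(expansion, mode_index = NULL,
                         convention = c("squared", "linear")) {
  convention <- match.arg(convention)
  coeff <- if (inherits(expansion, "mbd_mode_expansion")) expansion$coeff
           else rbind(expansion)
  if (is.null(mode_index)) mode_index <- seq_len(nrow(coeff))
  vapply(mode_index, function(i) {
    m <- max(coeff[i, ]^2)
    if (convention == "squared") 1 / m else 1 / sqrt(m)
  }, numeric(1))
}

#' Per-mode contributions to the interfragment binding energy
#'
#' Defined so that the contributions sum exactly to the interfragment
#' plasmon-pole energy at fixed screened parameters:
#' \deqn{\Delta E_i = \tfrac12\left(\tilde\omega_i -
#'   \sum_j c_{ij}^2\, \omega_j^{fragment}\right).}
#' Each coupled mode is charged with the weighted zero-point energy of the
#' fragment modes it is built from; row normalization of the expansion
#' guarantees \eqn{\sum_i \Delta E_i = E_{MBD}(complex) - \sum_f
#' E_{MBD}(fragments)} when complex and fragments share per-atom
#' parameters.  This decomposition is a defined convention of this
#' package, not a unique physical observable.
#'
#' @param expansion an `mbd_mode_expansion` (carries both frequency sets).
#' @return numeric vector, one energy (Ha) per complex mode, most binding
#'   (most negative) first in mode order.
#' @export
mode_binding_contributions <- function(expansion) {
  0.5 * (expansion$freq_complex -
           as.numeric(expansion$coeff^2 %*% expansion$omega_fragment))
}
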