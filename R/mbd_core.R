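#' Assemble the coupled-oscillator (MBD) Hamiltonian matrix
#'
#' In mass-weighted displacement coordinates the Hamiltonian of the
#' dipole-coupled Drude oscillators is biquadratic; its potential-energy
#' matrix has 3 x 3 blocks
#' \deqn{C_{AA} = \omega_A^2 \mathbf{1}, \qquad
#'   C_{AB} = \omega_A \omega_B \sqrt{\alpha_{0,A}\alpha_{0,B}}\,
#'   T^{lr}_{AB},}
#' built here from (screened) per-atom parameters and the long-range
#' dipole tensor.
#'
#' @param params a data.frame with columns `alpha0` and `omega` (typically
#'   an `mbd_screened` or `mbd_vdw_params` object).
#' @param T_lr 3N x 3N long-range dipole tensor (see [range_separate()]).
#' @return 3N x 3N symmetric matrix.
#' @export
build_hamiltonian <- function(params, T_lr) {
  n <- nrow(params)
  stopifnot(all(dim(T_lr) == 3 * n))
  wsa <- rep(params$omega * sqrt(params$alpha0), each = 3)
  C <- (wsa %o% wsa) * T_lr
  diag(C) <- diag(C) + rep(params$omega^2, each = 3)
  (C + t(C)) / 2
}

#' Diagonalize the MBD Hamiltonian
#'
#' Direct diagonalization of the biquadratic Hamiltonian: the coupled
#' fluctuation frequencies are \eqn{\tilde\omega_i = \sqrt{\lambda_i}} and
#' the columns of the mode matrix are the mass-weighted harmonic modes
#' \eqn{\tilde\xi_i}.  Frequencies are returned in ascending order with a
#' deterministic sign convention (largest-magnitude component of each mode
#' positive).
#'
#' @param C symmetric 3N x 3N matrix from [build_hamiltonian()].
#' @param params optional parameter table; if given, the uncoupled
#'   frequencies and polarizabilities are stored in the solution.
#' @param coords optional N x 3 coordinates, used only to improve the
#'   error message for unstable spectra.
#' @param tol eigenvalues below `tol` raise an error (imaginary coupled
#'   frequency).
#' @return class `mbd_solution`: list with `freq` (3N coupled frequencies,
#'   Ha, ascending), `modes` (3N x 3N orthonormal columns), `lambda`
#'   (eigenvalues), and, when `params` is given, `omega_atoms`,
#'   `alpha0_atoms`.
#' @export
diagonalize_hamiltonian <- function(C, params = NULL, coords = NULL,
                                    tol = 1e-12) {
  eig <- eigen(C, symmetric = TRUE)
  lambda <- rev(eig$values)
  modes <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  if (any(lambda <= tol)) {
    msg <- sprintf("imaginary coupled frequency: min eigenvalue %.3g",
                   min(lambda))
    if (!is.null(coords) && nrow(coords) > 1) {
      d <- as.matrix(stats::dist(coords)); diag(d) <- Inf
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      msg <- sprintf(paste0("%s; closest atoms %d-%d at %.3f Bohr ",
                            "(overlapping atoms or too-large beta)"),
                     msg, ij[1], ij[2], min(d))
    }
    stop(msg)
  }
  for (i in seq_len(ncol(modes))) {
    j <- which.max(abs(modes[, i]))
    if (modes[j, i] < 0) modes[, i] <- -modes[, i]
  }
  sol <- list(freq = sqrt(lambda), modes = modes, lambda = lambda)
  if (!is.null(params)) {
    sol$omega_atoms <- params$omega
    sol$alpha0_atoms <- params$alpha0
  }
  structure(sol, class = "mbd_solution")
}

#' @export
print.mbd_solution <- function(x, ...) {
  cat(sprintf("<mbd_solution: %d modes, freq range [%.4f, %.4f] Ha>\n",
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Plasmon-pole MBD energy
#'
#' Zero-point energy difference between coupled and uncoupled
#' fluctuations:
#' \deqn{E = \tfrac12 \sum_i \tilde\omega_i
#'   - \tfrac32 \sum_A \omega_A.}
#'
#' @param solution an `mbd_solution` carrying `omega_atoms`, or pass the
#'   uncoupled frequencies via `omega_atoms`.
#' @param omega_atoms optional per-atom uncoupled frequencies (Ha).
#' @return energy in Hartree.
#' @export
mbd_energy <- function(solution, omega_atoms = NULL) {
  if (is.null(omega_atoms)) omega_atoms <- solution$omega_atoms
  if (is.null(omega_atoms)) {
    stop("uncoupled frequencies not available; pass omega_atoms")
  }
  0.5 * sum(solution$freq) - 1.5 * sum(omega_atoms)
}

#' RPA (log-determinant) dispersion energy with order decomposition
#'
#' The random phase approximation expression
#' \deqn{E = \frac{1}{2\pi}\int_0^\infty
#'   \mathrm{Tr}\,\ln\!\left(1 + A(i\omega) T^{lr}\right) d\omega}
#' is evaluated on an imaginary-frequency quadrature grid;
#' \eqn{A(i\omega)} is the block-diagonal matrix of Lorentzian atomic
#' polarizabilities and \eqn{T^{lr}} the long-range tensor in this
#' package's sign convention (\eqn{T_{zz} = -2/R^3} for a z-aligned pair,
#' the same matrix that enters the Hamiltonian; in the convention with the
#' opposite tensor sign the familiar \eqn{\ln(1 - AT)} form is
#' recovered).  The result is fully equivalent to the plasmon-pole
#' formula, as both equal
#' \eqn{\frac{1}{2\pi}\int \ln\left[\det(C + \omega^2)/\det(\Omega^2 +
#' \omega^2)\right] d\omega}, and additionally yields the expansion in
#' orders of the coupling, \eqn{E_n = -\frac{1}{2\pi n}\int
#' \mathrm{Tr}\,[(-A T^{lr})^n]\, d\omega}, whose \eqn{n = 2} term is the
#' pairwise (London) limit.
#'
#' @param params data.frame with `alpha0`, `omega` per atom.
#' @param T_lr long-range dipole tensor.
#' @param grid an [imfreq_grid()].
#' @param max_order highest order of the series to report (0 for none).
#' @return list with `total` (Ha), `orders` (named vector `order2` ...,
#'   Ha), `converged` (`FALSE` if the coupling spectral radius reached 1
#'   at some frequency, in which case the series is unreliable but the
#'   log-det total is still returned).
#' @export
rpa_energy <- function(params, T_lr, grid = imfreq_grid(), max_order = 0) {
  n <- nrow(params)
  orders <- if (max_order >= 2) numeric(max_order - 1) else numeric(0)
  total <- 0
  converged <- TRUE
  for (k in seq_along(grid$omega)) {
    alpha_k <- params$alpha0 / (1 + (grid$omega[k] / params$omega)^2)
    s <- rep(sqrt(alpha_k), each = 3)
    M <- (s %o% s) * T_lr
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (max(abs(ev)) >= 1) converged <- FALSE
    total <- total + grid$weight[k] * sum(log1p(ev))
    if (max_order >= 2) {
      for (m in 2:max_order) {
        orders[m - 1] <- orders[m - 1] -
          grid$weight[k] * sum((-ev)^m) / m
      }
    }
  }
  total <- total / (2 * pi)
  if (length(orders) > 0) {
    orders <- orders / (2 * pi)
    names(orders) <- paste0("order", 2:max_order)
  }
  list(total = total, orders = orders, converged = converged)
}

#' Full MBD pipeline for one structure
#'
#' Scales free-atom parameters by the Hirshfeld ratios, screens them
#' self-consistently, rebuilds the long-range tensor with the screened
#' van der Waals radii, diagonalizes the Hamiltonian and evaluates the
#' plasmon-pole energy.
#'
#' @param structure an `mbd_structure`.
#' @param ratios per-atom Hirshfeld volume ratios.
#' @param reference free-atom reference table.
#' @param grid an [imfreq_grid()].
#' @param a,beta damping parameters.
#' @param screen if `FALSE`, skip Dyson screening and use the bare scaled
#'   parameters in the Hamiltonian.
#' @return class `mbd_system`: list with `structure`, `params`
#'   (unscreened), `screened`, `T_lr`, `solution`, `energy` (Ha).
#' @export
mbd_system <- function(structure, ratios = 1,
                       reference = free_atom_reference(),
                       grid = imfreq_grid(), a = 6, beta = 0.83,
                       screen = TRUE) {
  params <- scale_vdw_params(structure, ratios, reference)
  eff <- if (screen) {
    screen_parameters(structure, params, grid = grid, a = a, beta = beta)
  } else {
    params
  }
  f <- fermi_damping(structure$coords, eff$rvdw, a = a, beta = beta)
  T_lr <- .expand_pair_factor(f) * bare_dipole_tensor(structure$coords)
  C <- build_hamiltonian(eff, T_lr)
  sol <- diagonalize_hamiltonian(C, params = eff, coords = structure$coords)
  structure(
    list(structure = structure, params = params, screened = eff,
         T_lr = T_lr, solution = sol, energy = mbd_energy(sol),
         a = a, beta = beta, grid = grid, screen = screen),
    class = "mbd_system"
  )
}

#' @export
print.mbd_system <- function(x, ...) {
  cat(sprintf("<mbd_system: %d atoms, E_MBD = %.8f Ha (%.4f kcal/mol)>\n",
              n_atoms(x$structure), x$energy,
              hartree_to_kcalmol(x$energy)))
  invisible(x)
}

#' Interaction energy between the fragments of a complex
#'
#' \eqn{E_{int} = E_{MBD}(\mathrm{complex}) - \sum_f
#' E_{MBD}(\mathrm{fragment}_f)}, with each fragment taken as the rigid
#' sub-geometry of the complex.  By default every fragment is re-screened
#' in isolation (its screened parameters depend on its own environment
#' only); `rescreen = FALSE` instead freezes the complex-screened
#' parameters and re-diagonalizes the fragment sub-blocks, which isolates
#' the long-range coupling contribution.
#'
#' @param structure an `mbd_structure` with at least one fragment.
#' @param ratios per-atom Hirshfeld volume ratios.
#' @param reference,grid,a,beta as in [mbd_system()].
#' @param rescreen logical, see above.
#' @return class `mbd_interaction`: list with `e_int` (Ha),
#'   `e_int_kcalmol`, `e_complex`, `e_fragments` (vector), and the
#'   underlying `complex` and `fragments` system objects.
#' @export
mbd_interaction_energy <- function(structure, ratios = 1,
                                   reference = free_atom_reference(),
                                   grid = imfreq_grid(), a = 6, beta = 0.83,
                                   rescreen = TRUE) {
  nf <- n_fragments(structure)
  if (length(ratios) == 1) ratios <- rep(ratios, n_atoms(structure))
  complex_sys <- mbd_system(structure, ratios, reference, grid, a, beta)
  if (nf == 1) {
    return(structure(
      list(e_int = 0, e_int_kcalmol = 0, e_complex = complex_sys$energy,
           e_fragments = numeric(0), complex = complex_sys,
           fragments = list()),
      class = "mbd_interaction"))
  }
  frag_sys <- vector("list", nf)
  e_frag <- numeric(nf)
  for (f in seq_len(nf)) {
    idx <- fragment_atoms(structure, f)
    sub <- extract_fragment(structure, f)
    if (rescreen) {
      frag_sys[[f]] <- mbd_system(sub, ratios[idx], reference, grid, a, beta)
      e_frag[f] <- frag_sys[[f]]$energy
    } else {
      eff <- complex_sys$screened[idx, , drop = FALSE]
      rows <- as.vector(t(outer(idx - 1, 1:3, function(i, c) 3 * i + c)))
      T_sub <- complex_sys$T_lr[rows, rows, drop = FALSE]
      sol <- diagonalize_hamiltonian(build_hamiltonian(eff, T_sub),
                                     params = eff, coords = sub$coords)
      frag_sys[[f]] <- list(structure = sub, screened = eff, T_lr = T_sub,
                            solution = sol, energy = mbd_energy(sol))
      e_frag[f] <- frag_sys[[f]]$energy
    }
  }
  e_int <- complex_sys$energy - sum(e_frag)
  structure(
    list(e_int = e_int, e_int_kcalmol = hartree_to_kcalmol(e_int),
         e_complex = complex_sys$energy, e_fragments = e_frag,
         complex = complex_sys, fragments = frag_sys,
         rescreen = rescreen),
    class = "mbd_interaction"
  )
}

#' @export
print.mbd_interaction <- function(x, ...) {
  cat(sprintf("<mbd_interaction: E_int = %.8f Ha (%.4f kcal/mol)>\n",
              x$e_int, x$e_int_kcalmol))
  invisible(x)
}

#' Pairwise Tkatchenko-Scheffler interaction energy
#'
#' Damped London sum over interfragment atom pairs,
#' \deqn{E = -\sum_{A<B} f(R_{AB})\, C_{6,AB} / R_{AB}^6,}
#' with the Fermi damping of [fermi_damping()] and unscreened
#' volume-scaled parameters.  This is the pairwise baseline that neglects
#' all higher-order correlation.
#'
#' @param structure an `mbd_structure` (pairs within one fragment are
#'   skipped; with a single fragment the energy is 0).
#' @param params unscreened `mbd_vdw_params`.
#' @param a,beta damping parameters.
#' @return energy in Hartree.
#' @export
pairwise_ts_energy <- function(structure, params, a = 6, beta = 0.83) {
  n <- n_atoms(structure)
  if (n < 2) return(0)
  f <- fermi_damping(structure$coords, params$rvdw, a = a, beta = beta)
  d <- as.matrix(stats::dist(structure$coords))
  e <- 0
  for (A in seq_len(n - 1)) {
    for (B in (A + 1):n) {
      if (structure$fragments[A] == structure$fragments[B]) next
      c6ab <- combine_c6(params$c6[A], params$alpha0[A],
                         params$c6[B], params$alpha0[B])
      e <- e - f[A, B] * c6ab / d[A, B]^6
    }
  }
  e
}

#' Many-body decomposition of the interaction energy
#'
#' Expands the interfragment dispersion energy in orders of the RPA
#' coupling (complex minus fragments at each order) and reports the
#' reduction of the full many-body interaction energy relative to its
#' second-order (pairwise) truncation,
#' \eqn{100\,(1 - E_{int}/E_{int}^{(2)})} percent, as well as the
#' comparison against the unscreened pairwise TS baseline.
#'
#' @param structure an `mbd_structure` with >= 2 fragments.
#' @param ratios per-atom Hirshfeld volume ratios.
#' @param reference,grid,a,beta as in [mbd_system()].
#' @param max_order highest series order to report.
#' @param rescreen logical, fragment re-screening as in
#'   [mbd_interaction_energy()].
#' @return class `mbd_decomposition`: list with `e_int` (full, Ha),
#'   `orders_int` (interfragment energy per order, Ha),
#'   `reduction_percent` (vs screened second order), `e_ts` (unscreened
#'   pairwise baseline, Ha), `reduction_vs_ts_percent`, `converged`.
#' @export
many_body_decomposition <- function(structure, ratios = 1,
                                    reference = free_atom_reference(),
                                    grid = imfreq_grid(), a = 6,
                                    beta = 0.83, max_order = 8,
                                    rescreen = TRUE) {
  if (n_fragments(structure) < 2) stop("need at least two fragments")
  if (length(ratios) == 1) ratios <- rep(ratios, n_atoms(structure))
  inter <- mbd_interaction_energy(structure, ratios, reference, grid, a,
                                  beta, rescreen = rescreen)
  rc <- rpa_energy(inter$complex$screened, inter$complex$T_lr, grid,
                   max_order = max_order)
  orders_int <- rc$orders
  converged <- rc$converged
  for (fs in inter$fragments) {
    rf <- rpa_energy(fs$screened, fs$T_lr, grid, max_order = max_order)
    orders_int <- orders_int - rf$orders
    converged <- converged && rf$converged
  }
  e2 <- orders_int[["order2"]]
  params <- inter$complex$params
  e_ts <- pairwise_ts_energy(structure, params, a = a, beta = beta)
  structure(
    list(e_int = inter$e_int,
         orders_int = orders_int,
         reduction_percent = 100 * (1 - inter$e_int / e2),
         e_ts = e_ts,
         reduction_vs_ts_percent = 100 * (1 - inter$e_int / e_ts),
         converged = converged,
         interaction = inter),
    class = "mbd_decomposition"
  )
}

#' @export
print.mbd_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<mbd_decomposition: E_int = %.6f Ha, ",
                     "many-body reduction %.1f%% vs 2nd order>\n"),
              x$e_int, x$reduction_percent))
  invisible(x)
}
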