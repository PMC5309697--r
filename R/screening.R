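#' Imaginary-frequency quadrature grid
#'
#' Gauss-Legendre nodes on \eqn{[-1, 1]} mapped to \eqn{[0, \infty)} via
#' \eqn{\omega = \omega_0 (1+u)/(1-u)}, the standard grid for
#' Casimir-Polder integrals.  The default 15 nodes integrate products of
#' Lorentzian polarizabilities to better than 1e-10 relative accuracy;
#' convergence can be verified by doubling `n`.
#'
#' @param n number of nodes (default 15).
#' @param omega0 scale of the transformation (Ha, default 0.5).
#' @return a list with `omega` (nodes, Ha) and `weight` (quadrature
#'   weights including the Jacobian), class `mbd_freq_grid`.
#' @export
imfreq_grid <- function(n = 15, omega0 = 0.5) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  structure(
    list(omega = omega0 * (1 + gl$x) / (1 - gl$x),
         weight = gl$w * 2 * omega0 / (1 - gl$x)^2,
         n = n, omega0 = omega0),
    class = "mbd_freq_grid"
  )
}

#' Solve the Dyson screening equation
#'
#' Dresses the bare atomic polarizabilities with the short-range dipole
#' coupling at every frequency of the grid (plus the static point
#' \eqn{\omega = 0}):
#' \deqn{B(i\omega) = \left(A(i\omega)^{-1} + T^{sr}(i\omega)\right)^{-1},}
#' where \eqn{A(i\omega)} is the block-diagonal matrix of atomic
#' Lorentzian polarizabilities and \eqn{T^{sr}} the short-range
#' (Fermi-damped, Gaussian-width) dipole tensor.  The Gaussian widths are
#' frequency dependent through \eqn{\sigma_A(i\omega) \propto
#' \alpha_A(i\omega)^{1/3}}, so the short-range tensor is rebuilt at each
#' node from the geometry and damping factors stored in `tensors`.
#'
#' @param params an `mbd_vdw_params` table.
#' @param tensors an `mbd_tensors` object from [range_separate()] (supplies
#'   geometry, damping factors and radii; its stored `T_sr` corresponds to
#'   the static widths).
#' @param grid an [imfreq_grid()].
#' @return class `mbd_nonlocal`: list with `freq` (vector, first entry 0),
#'   `B` (list of 3N x 3N matrices), `grid`.
#' @export
solve_dyson <- function(params, tensors, grid = imfreq_grid()) {
  n <- nrow(params)
  freq <- c(0, grid$omega)
  fx <- .expand_pair_factor(tensors$f)
  Bs <- vector("list", length(freq))
  for (k in seq_along(freq)) {
    alpha_k <- params$alpha0 / (1 + (freq[k] / params$omega)^2)
    sigma_k <- gaussian_width(alpha_k)
    T_sr_k <- (1 - fx) * gaussian_dipole_tensor(tensors$coords, sigma_k)
    M <- T_sr_k
    diag(M) <- diag(M) + rep(1 / alpha_k, each = 3)
    B <- tryCatch(
      solve(M),
      error = function(e) {
        sv <- svd(M, nu = 0, nv = 0)$d
        stop(sprintf(paste0(
          "Dyson screening matrix singular at imaginary frequency ",
          "%.6g Ha (smallest singular value %.3g); atoms may be ",
          "unphysically close"), freq[k], min(sv)))
      }
    )
    Bs[[k]] <- (B + t(B)) / 2
  }
  structure(list(freq = freq, B = Bs, grid = grid), class = "mbd_nonlocal")
}

#' Contract the non-local polarizability to per-atom screened parameters
#'
#' Each atom's screened dynamic polarizability is the isotropic average of
#' the row sum of its block row,
#' \eqn{\bar\alpha_A(i\omega) = \tfrac13 \mathrm{tr}
#'   \sum_B B_{AB}(i\omega)}, so that every atom feels its full molecular
#' environment.  The static value gives \eqn{\bar\alpha_{0,A}}; the
#' screened \eqn{\bar C_{6,A}} follows by Casimir-Polder quadrature of
#' \eqn{\bar\alpha_A(i\omega)^2}; the screened frequency and radius by the
#' Lorentzian closure \eqn{\bar\omega_A = \tfrac43 \bar C_6 /
#' \bar\alpha_0^2} and \eqn{\bar R_{vdw} = R_{vdw}
#' (\bar\alpha_0/\alpha_0)^{1/3}}.  The molecular polarizability tensor is
#' the sum of all 3 x 3 blocks of the static matrix.
#'
#' @param nonlocal an `mbd_nonlocal` from [solve_dyson()].
#' @param structure the `mbd_structure`.
#' @param params the unscreened `mbd_vdw_params`.
#' @return class `mbd_screened`: data.frame with columns `symbol`,
#'   `alpha0`, `c6`, `omega`, `rvdw` (all screened), plus attributes
#'   `molecular_alpha` (3 x 3), `alpha_freq` (N x n_freq screened dynamic
#'   polarizabilities at the nonzero nodes), `B0` (static non-local
#'   matrix), `grid`, `unscreened`.
#' @export
contract_to_atoms <- function(nonlocal, structure, params) {
  n <- n_atoms(structure)
  nf <- length(nonlocal$freq)
  alpha_af <- matrix(0, n, nf)
  for (k in seq_len(nf)) {
    B <- nonlocal$B[[k]]
    for (a in seq_len(n)) {
      rows <- (3 * (a - 1) + 1):(3 * a)
      # row-sum of 3x3 blocks: sum columns grouped by Cartesian component
      P <- matrix(0, 3, 3)
      for (c in 1:3) {
        P[, c] <- rowSums(B[rows, seq(c, 3 * n, by = 3), drop = FALSE])
      }
      alpha_af[a, k] <- sum(diag(P)) / 3
    }
  }
  alpha0_s <- alpha_af[, 1]
  if (any(alpha0_s <= 0)) {
    bad <- which(alpha0_s <= 0)
    stop(sprintf(paste0("negative screened polarizability on atom(s) %s; ",
                        "geometry is in an unphysical regime"),
                 paste(bad, collapse = ", ")))
  }
  w <- nonlocal$grid$weight
  c6_s <- 3 / pi * as.numeric(alpha_af[, -1, drop = FALSE]^2 %*% w)
  out <- data.frame(
    symbol = structure$symbols,
    alpha0 = alpha0_s,
    c6 = c6_s,
    omega = 4 / 3 * c6_s / alpha0_s^2,
    rvdw = params$rvdw * (alpha0_s / params$alpha0)^(1 / 3),
    stringsAsFactors = FALSE
  )
  B0 <- nonlocal$B[[1]]
  mol <- matrix(0, 3, 3)
  for (c1 in 1:3) for (c2 in 1:3) {
    mol[c1, c2] <- sum(B0[seq(c1, 3 * n, by = 3), seq(c2, 3 * n, by = 3)])
  }
  attr(out, "molecular_alpha") <- (mol + t(mol)) / 2
  attr(out, "alpha_freq") <- alpha_af[, -1, drop = FALSE]
  attr(out, "B0") <- B0
  attr(out, "grid") <- nonlocal$grid
  attr(out, "unscreened") <- params
  class(out) <- c("mbd_screened", "data.frame")
  out
}

#' Self-consistent screening pipeline
#'
#' Convenience wrapper chaining [range_separate()], [solve_dyson()] and
#' [contract_to_atoms()].
#'
#' @param structure an `mbd_structure`.
#' @param params unscreened `mbd_vdw_params`.
#' @param grid an [imfreq_grid()].
#' @param a,beta damping parameters, see [fermi_damping()].
#' @return an `mbd_screened` object (see [contract_to_atoms()]).
#' @export
screen_parameters <- function(structure, params, grid = imfreq_grid(),
                              a = 6, beta = 0.83) {
  tensors <- range_separate(structure$coords, gaussian_width(params$alpha0),
                            params$rvdw, a = a, beta = beta)
  nl <- solve_dyson(params, tensors, grid)
  contract_to_atoms(nl, structure, params)
}

#' Interfragment block of the non-local polarizability
#'
#' Extracts one Cartesian component of the static atom-pair blocks
#' \eqn{B_{AB}(0)} between two fragments, as an `N_A x N_B` matrix
#' suitable for heat-map rendering of the intermolecular correlation
#' structure.
#'
#' @param screened an `mbd_screened` object (carrying the static non-local
#'   matrix), or a bare 3N x 3N matrix.
#' @param structure the `mbd_structure`.
#' @param frag_a,frag_b two distinct fragment indices.
#' @param component two-letter Cartesian component, e.g. `"xy"`.
#' @return matrix with rownames/colnames the atom indices of the two
#'   fragments.
#' @export
interfragment_block <- function(screened, structure, frag_a, frag_b,
                                component = "xy") {
  if (frag_a == frag_b) stop("frag_a and frag_b must be distinct fragments")
  B0 <- if (is.matrix(screened)) screened else attr(screened, "B0")
  comp <- match(strsplit(component, "")[[1]], c("x", "y", "z"))
  if (length(comp) != 2 || anyNA(comp)) {
    stop("component must be two of x, y, z (e.g. 'xy')")
  }
  ia <- fragment_atoms(structure, frag_a)
  ib <- fragment_atoms(structure, frag_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty fragment")
  out <- B0[3 * (ia - 1) + comp[1], 3 * (ib - 1) + comp[2], drop = FALSE]
  dimnames(out) <- list(ia, ib)
  out
}
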