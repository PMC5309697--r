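#' Free-atom van der Waals reference data
#'
#' Loads the bundled table of free-atom static polarizabilities
#' \eqn{\alpha_0} (Bohr^3), homoatomic \eqn{C_6} coefficients
#' (Ha Bohr^6) and van der Waals radii (Bohr), or a user-supplied table in
#' the same format (tab/whitespace separated, columns
#' `element alpha0 c6 rvdw`).
#'
#' @param path optional path to an alternative reference table.
#' @return a data.frame with columns `element`, `alpha0`, `c6`, `rvdw`.
#' @export
free_atom_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "free_atom_vdw.tsv", package = "mbdtools",
                        mustWork = TRUE)
  }
  ref <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("element", "alpha0", "c6", "rvdw")
  if (!all(need %in% names(ref))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(ref$alpha0 <= 0 | ref$c6 <= 0 | ref$rvdw <= 0)) {
    stop("reference table entries must be positive")
  }
  ref
}

#' Scale free-atom parameters by Hirshfeld volume ratios
#'
#' The response of each atom in its molecular environment is obtained by
#' scaling the free-atom values with the ratio \eqn{v_A} of the Hirshfeld
#' volume of the atom in the molecule to the free atom:
#' \deqn{\alpha_{0,A} = v_A \alpha_0^{free},\quad
#'       C_{6,A} = v_A^2 C_6^{free},\quad
#'       R_{vdw,A} = v_A^{1/3} R_{vdw}^{free}.}
#' The characteristic (Drude) frequency follows from the single-pole
#' Lorentzian closure \eqn{\omega_A = \frac{4}{3} C_{6,A}/\alpha_{0,A}^2},
#' which makes the Casimir-Polder integral of
#' \eqn{\alpha(i\omega)=\alpha_0/(1+(\omega/\omega_A)^2)} recover
#' \eqn{C_{6,A}} exactly.
#'
#' @param structure an `mbd_structure`.
#' @param ratios per-atom Hirshfeld volume ratios (see
#'   [read_volume_ratios()]).
#' @param reference free-atom reference table (see [free_atom_reference()]).
#' @return an object of class `mbd_vdw_params`: a data.frame with one row
#'   per atom and columns `symbol`, `ratio`, `alpha0`, `c6`, `omega`,
#'   `rvdw`.
#' @export
scale_vdw_params <- function(structure, ratios,
                             reference = free_atom_reference()) {
  n <- n_atoms(structure)
  ratios <- as.numeric(ratios)
  if (length(ratios) == 1) ratios <- rep(ratios, n)
  if (length(ratios) != n) {
    stop(sprintf("ratio vector length %d does not match atom count %d",
                 length(ratios), n))
  }
  if (any(ratios <= 0)) stop("volume ratios must be positive")
  m <- match(structure$symbols, reference$element)
  if (anyNA(m)) {
    miss <- unique(structure$symbols[is.na(m)])
    stop("element(s) missing from free-atom reference: ",
         paste(miss, collapse = ", "))
  }
  alpha0 <- ratios * reference$alpha0[m]
  c6 <- ratios^2 * reference$c6[m]
  out <- data.frame(
    symbol = structure$symbols,
    ratio = ratios,
    alpha0 = alpha0,
    c6 = c6,
    omega = 4 / 3 * c6 / alpha0^2,
    rvdw = ratios^(1 / 3) * reference$rvdw[m],
    stringsAsFactors = FALSE
  )
  class(out) <- c("mbd_vdw_params", "data.frame")
  out
}

#' Dynamic polarizability on the imaginary frequency axis
#'
#' Single-pole Lorentzian model
#' \eqn{\alpha(i\omega) = \alpha_0 / (1 + (\omega/\omega_A)^2)}, the unique
#' dynamic response of a charged harmonic (Drude) oscillator.
#'
#' @param alpha0 static polarizabilities (vector over atoms).
#' @param omega_a characteristic frequencies (same length).
#' @param freq imaginary frequency node(s), Ha.
#' @return a `length(alpha0) x length(freq)` matrix of
#'   \eqn{\alpha(i\omega)}.
#' @export
alpha_dynamic <- function(alpha0, omega_a, freq) {
  outer(seq_along(alpha0), seq_along(freq),
        function(a, k) alpha0[a] / (1 + (freq[k] / omega_a[a])^2))
}

#' Combine homoatomic C6 coefficients into a pair coefficient
#'
#' Harmonic-mean combination rule of the Tkatchenko-Scheffler scheme:
#' \deqn{C_{6,AB} = \frac{2\, C_{6,A} C_{6,B}}
#'   {\frac{\alpha_B}{\alpha_A} C_{6,A} + \frac{\alpha_A}{\alpha_B} C_{6,B}}.}
#' For two Drude oscillators this equals the Casimir-Polder integral
#' \eqn{\frac{3}{2}\alpha_A\alpha_B \omega_A\omega_B/(\omega_A+\omega_B)}
#' exactly.
#'
#' @param c6_a,c6_b homoatomic C6 coefficients (vectorized).
#' @param alpha_a,alpha_b static polarizabilities.
#' @return pair coefficient(s) `C6_AB`.
#' @export
combine_c6 <- function(c6_a, alpha_a, c6_b, alpha_b) {
  2 * c6_a * c6_b / ((alpha_b / alpha_a) * c6_a + (alpha_a / alpha_b) * c6_b)
}

#' Casimir-Polder C6 from dynamic polarizabilities by quadrature
#'
#' \eqn{C_{6,AB} = \frac{3}{\pi}\int_0^\infty
#'   \alpha_A(i\omega)\,\alpha_B(i\omega)\, d\omega}, evaluated on an
#' imaginary-frequency quadrature grid.
#'
#' @param alpha_a,alpha_b dynamic polarizabilities evaluated at the grid
#'   nodes (vectors of length `length(grid$omega)`), or functions of
#'   frequency.
#' @param grid an imaginary-frequency grid from [imfreq_grid()].
#' @return the pair dispersion coefficient (Ha Bohr^6).
#' @export
casimir_polder_c6 <- function(alpha_a, alpha_b = alpha_a,
                              grid = imfreq_grid()) {
  if (is.function(alpha_a)) alpha_a <- alpha_a(grid$omega)
  if (is.function(alpha_b)) alpha_b <- alpha_b(grid$omega)
  3 / pi * sum(grid$weight * alpha_a * alpha_b)
}
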