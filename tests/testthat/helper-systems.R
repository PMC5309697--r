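# Shared builders for small test systems.

# Two identical Drude oscillators on the z axis with unit parameters
# (alpha0 = 1, omega = 1 a.u.), bare point-dipole coupling.
two_oscillators <- function(R = 10, alpha0 = 1, omega = 1) {
  st <- mbd_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, R)))
  params <- data.frame(symbol = c("C", "C"), alpha0 = alpha0,
                       c6 = 0.75 * alpha0^2 * omega, omega = omega,
                       rvdw = 3.0, stringsAsFactors = FALSE)
  list(structure = st, params = params,
       T_bare = bare_dipole_tensor(st$coords))
}

# Closed-form eigenvalues of the two-oscillator Hamiltonian for a coupling
# block diag(t_xx, t_yy, t_zz): per axis, omega^2 (1 +/- alpha * t).
two_oscillator_lambda <- function(alpha0, omega, t_diag) {
  sort(c(omega^2 * (1 + alpha0 * t_diag), omega^2 * (1 - alpha0 * t_diag)))
}

# Random seeded cluster with carbon-like parameters, small enough for
# closed-form cross checks.
random_cluster_system <- function(n, seed, spacing = 5.5) {
  fx <- generate_fixture("random_cluster", n_atoms = n, spacing = spacing,
                         element = "C", ratios = c(0.7, 1.2), seed = seed,
                         min_dist = 3.0)
  params <- scale_vdw_params(fx$structure, fx$ratios)
  list(structure = fx$structure, params = params,
       T_bare = bare_dipole_tensor(fx$structure$coords))
}

# A pi-stacking toy: two parallel carbon rings, two fragments.
stacked_ring_system <- function(n = 6, spacing = 2.7, separation = 6.6,
                                ratios = 0.9) {
  fx <- generate_fixture("stacked_rings", n_atoms = n, spacing = spacing,
                         separation = separation, element = "C",
                         ratios = ratios, seed = 7)
  fx
}

# Two distinct random clusters (generically non-degenerate spectra)
# stacked along z at a given closest-approach separation; two fragments.
two_cluster_system <- function(separation = 150) {
  a <- generate_fixture("random_cluster", n_atoms = 4, spacing = 5.5,
                        ratios = c(0.7, 1.0), seed = 11, min_dist = 3)
  b <- generate_fixture("random_cluster", n_atoms = 5, spacing = 5.5,
                        ratios = c(0.9, 1.2), seed = 12, min_dist = 3)
  cb <- b$structure$coords
  cb[, 3] <- cb[, 3] - min(cb[, 3]) + max(a$structure$coords[, 3]) +
    separation
  st <- mbd_structure(c(a$structure$symbols, b$structure$symbols),
                      rbind(a$structure$coords, cb),
                      fragments = rep(1:2, c(4, 5)))
  list(structure = st, ratios = c(a$ratios, b$ratios))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
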