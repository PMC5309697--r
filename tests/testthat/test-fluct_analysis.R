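test_that("uncoupled wavefunction has the harmonic ground-state width", {
  sys <- random_cluster_system(3, seed = 17)
  sol <- diagonalize_hamiltonian(
    build_hamiltonian(sys$params, matrix(0, 9, 9)), params = sys$params)
  wf <- build_wavefunction(sol, sys$structure)
  for (a in 1:3) {
    m <- 1 / (sys$params$alpha0[a] * sys$params$omega[a]^2)
    expect_equal(wf$sigma_cov[[a]],
                 diag(1 / (2 * m * sys$params$omega[a]), 3),
                 tolerance = 1e-12)
  }
})

test_that("coupling stretches the covariance along the binding axis", {
  sys <- two_oscillators(R = 4)
  sol <- diagonalize_hamiltonian(
    build_hamiltonian(sys$params, sys$T_bare), params = sys$params)
  wf <- build_wavefunction(sol, sys$structure)
  uncoupled <- 1 / (2 * (1 / (1 * 1^2)) * 1)  # 1/(2 m omega) = 1/2
  # z is the attractive (aligned) axis: variance grows most there
  expect_gt(wf$sigma_cov[[1]][3, 3], uncoupled)
  expect_gt(wf$sigma_cov[[1]][3, 3], wf$sigma_cov[[1]][1, 1])
  # closed form: mixture of symmetric/antisymmetric mode widths
  tz <- -2 / 4^3
  expect_equal(wf$sigma_cov[[1]][3, 3],
               0.25 * (1 / sqrt(1 + tz) + 1 / sqrt(1 - tz)),
               tolerance = 1e-12)
})

test_that("wavefunction covariances are rotation equivariant", {
  sys <- random_cluster_system(4, seed = 23)
  f <- fermi_damping(sys$structure$coords, sys$params$rvdw)
  T_lr <- mbdtools:::.expand_pair_factor(f) * sys$T_bare
  sol <- diagonalize_hamiltonian(build_hamiltonian(sys$params, T_lr),
                                 params = sys$params)
  wf <- build_wavefunction(sol, sys$structure)
  set.seed(3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- sys$structure
  rot$coords <- rot$coords %*% t(R)
  T_rot <- mbdtools:::.expand_pair_factor(f) * bare_dipole_tensor(rot$coords)
  sol_r <- diagonalize_hamiltonian(build_hamiltonian(sys$params, T_rot),
                                   params = sys$params)
  wf_r <- build_wavefunction(sol_r, rot)
  for (a in 1:4) {
    expect_equal(wf_r$sigma_cov[[a]], R %*% wf$sigma_cov[[a]] %*% t(R),
                 tolerance = 1e-8)
  }
})

test_that("charge densities integrate to the number of oscillators", {
  st <- mbd_structure("C", matrix(c(0, 0, 0), 1, 3))
  p <- scale_vdw_params(st, 0.9)
  sol <- diagonalize_hamiltonian(build_hamiltonian(p, matrix(0, 3, 3)),
                                 params = p)
  wf <- build_wavefunction(sol, st)
  g <- density_grid(st, spacing = 0.35, padding = 4)
  rho <- charge_density(wf, g)
  expect_equal(grid_integral(rho), 1, tolerance = 1e-6)
  # maximum at the atom site for the isotropic case
  pts <- grid_points(g)
  imax <- which.max(rho$values)
  expect_lt(sqrt(sum(pts[imax, ]^2)), 0.4)

  fx <- stacked_ring_system()
  sysm <- mbd_system(fx$structure, fx$ratios)
  wfm <- build_wavefunction(sysm$solution, fx$structure)
  gm <- density_grid(fx$structure, spacing = 0.4, padding = 4)
  rhom <- charge_density(wfm, gm)
  expect_equal(grid_integral(rhom), 12, tolerance = 1e-6)
})

test_that("density differences conserve charge and localize between
           stacked fragments", {
  fx <- stacked_ring_system()
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  cwf <- build_wavefunction(inter$complex$solution, fx$structure)
  fwfs <- lapply(inter$fragments,
                 function(fs) build_wavefunction(fs$solution, fs$structure))
  g <- density_grid(fx$structure, spacing = 0.4, padding = 4)
  dg <- density_difference(cwf, fwfs, g)
  expect_lt(abs(grid_integral(dg)), 1e-6)
  dq <- displaced_charge(dg)
  expect_gt(dq, 0)
  # accumulation in the interfragment midplane (on the ring axis between
  # the two rings)
  pts <- grid_points(g)
  mid <- colMeans(fx$structure$coords)
  near_mid <- which(sqrt(rowSums(sweep(pts, 2, mid, "-")^2)) < 1.0)
  expect_gt(mean(dg$values[near_mid]), 0)

  # zero interfragment coupling leaves no density difference
  far <- stacked_ring_system(separation = 120)
  inter_f <- mbd_interaction_energy(far$structure, far$ratios,
                                    rescreen = FALSE)
  cwf_f <- build_wavefunction(inter_f$complex$solution, far$structure)
  fwfs_f <- lapply(inter_f$fragments,
                   function(fs) build_wavefunction(fs$solution,
                                                   fs$structure))
  gf <- density_grid(far$structure, spacing = 0.8, padding = 3)
  dgf <- density_difference(cwf_f, fwfs_f, gf)
  expect_lt(max(abs(dgf$values)), 1e-10)
  expect_lt(displaced_charge(dgf), 1e-8)
})

test_that("displaced charge is grid converged", {
  fx <- stacked_ring_system()
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  cwf <- build_wavefunction(inter$complex$solution, fx$structure)
  fwfs <- lapply(inter$fragments,
                 function(fs) build_wavefunction(fs$solution, fs$structure))
  q <- vapply(c(0.4, 0.2), function(h) {
    g <- density_grid(fx$structure, spacing = h, padding = 4)
    displaced_charge(density_difference(cwf, fwfs, g))
  }, numeric(1))
  expect_lt(abs(q[2] - q[1]) / q[1], 0.01)
})

test_that("energy spectrum is a unit-area Gaussian per mode", {
  sp <- energy_spectrum(0.5, half_width = 0.06)
  de <- diff(sp$energy_ev[1:2])
  expect_equal(sum(sp$dos) * de, 1, tolerance = 1e-6)
  expect_equal(sp$energy_ev[which.max(sp$dos)], hartree_to_ev(0.5),
               tolerance = 0.01)

  fx <- stacked_ring_system()
  sys <- mbd_system(fx$structure, fx$ratios)
  sp2 <- energy_spectrum(sys$solution)
  expect_equal(sum(sp2$dos) * diff(sp2$energy_ev[1:2]),
               length(sys$solution$freq), tolerance = 1e-6)
})

test_that("complex spectra broaden relative to the isolated fragments", {
  fx <- stacked_ring_system(separation = 5.6)
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  pooled <- unlist(lapply(inter$fragments,
                          function(fs) fs$solution$freq))
  expect_gte(stats::var(inter$complex$solution$freq), stats::var(pooled))
})

test_that("mode dipole fields respect thresholding and mode structure", {
  sys <- random_cluster_system(4, seed = 31)
  sol0 <- diagonalize_hamiltonian(
    build_hamiltonian(sys$params, matrix(0, 12, 12)), params = sys$params)
  wf0 <- build_wavefunction(sol0, sys$structure)
  v <- mode_dipole_field(wf0, 1, threshold = 0)
  expect_equal(sum(rowSums(v^2) > 1e-20), 1)  # single-atom mode

  sys2 <- two_oscillators(R = 4)
  sol2 <- diagonalize_hamiltonian(
    build_hamiltonian(sys2$params, sys2$T_bare), params = sys2$params)
  wf2 <- build_wavefunction(sol2, sys2$structure)
  # lowest mode: symmetric z-aligned (binding) combination
  vb <- mode_dipole_field(wf2, 1, threshold = 0)
  expect_gt(abs(vb[1, 3]), 1e-6)
  expect_equal(vb[1, ], vb[2, ], tolerance = 1e-10)

  v100 <- mode_dipole_field(wf0, 1, threshold = 1.0)
  expect_lte(sum(attr(v100, "kept")), 1)
  expect_error(mode_dipole_field(wf0, 99), "out of range")
})

test_that("fragment-mode projection is orthogonal and reconstructs the
           complex modes", {
  fx <- stacked_ring_system()
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  frag_sols <- lapply(inter$fragments, `[[`, "solution")
  exp <- project_modes(inter$complex$solution, frag_sols, fx$structure)
  expect_equal(rowSums(exp$coeff^2), rep(1, 36), tolerance = 1e-10)
  expect_equal(crossprod(exp$coeff), diag(36), tolerance = 1e-10)
  # round trip: modes = coeff %*% embedded basis
  n <- 12
  basis <- matrix(0, 3 * n, 3 * n)
  col <- 0
  for (f in 1:2) {
    idx <- fragment_atoms(fx$structure, f)
    rows <- as.vector(t(outer(idx - 1, 1:3, function(i, c) 3 * i + c)))
    for (j in seq_len(3 * length(idx))) {
      col <- col + 1
      basis[rows, col] <- frag_sols[[f]]$modes[, j]
    }
  }
  recon <- basis %*% t(exp$coeff)
  expect_equal(max(abs(recon - inter$complex$solution$modes)), 0,
               tolerance = 1e-10)
})

test_that("zero interfragment coupling yields localized modes", {
  far <- two_cluster_system(separation = 600)
  inter <- mbd_interaction_energy(far$structure, far$ratios,
                                  rescreen = FALSE)
  exp <- project_modes(inter$complex$solution,
                       lapply(inter$fragments, `[[`, "solution"),
                       far$structure)
  coll <- collectivity(exp)
  expect_equal(coll, rep(1, 27), tolerance = 1e-6)
  # each row concentrates on a single fragment mode (permutation-like)
  expect_true(all(apply(exp$coeff^2, 1, max) > 1 - 1e-6))
})

test_that("symmetric homodimer binding modes weight both fragments
           equally", {
  fx <- stacked_ring_system(separation = 5.6)
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  exp <- project_modes(inter$complex$solution,
                       lapply(inter$fragments, `[[`, "solution"),
                       fx$structure)
  w_frag1 <- rowSums(exp$coeff[, exp$fragment == 1]^2)
  expect_equal(w_frag1, rep(0.5, 36), tolerance = 1e-6)
})

test_that("collectivity follows the inverse-participation convention", {
  expect_equal(collectivity(c(1, 0, 0)), 1)
  expect_equal(collectivity(rep(1 / sqrt(3), 3)), 3, tolerance = 1e-12)
  expect_equal(collectivity(rep(1 / sqrt(3), 3), convention = "linear"),
               sqrt(3), tolerance = 1e-12)
  for (N in c(2, 5, 12)) {
    expect_equal(collectivity(rep(1 / sqrt(N), N)), N, tolerance = 1e-12)
  }
  fx <- stacked_ring_system()
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  exp <- project_modes(inter$complex$solution,
                       lapply(inter$fragments, `[[`, "solution"),
                       fx$structure)
  coll <- collectivity(exp)
  expect_true(all(coll >= 1 - 1e-12 & coll <= 36))
})

test_that("per-mode binding contributions sum to the interfragment
           energy at fixed parameters", {
  fx <- stacked_ring_system()
  inter <- mbd_interaction_energy(fx$structure, fx$ratios,
                                  rescreen = FALSE)
  exp <- project_modes(inter$complex$solution,
                       lapply(inter$fragments, `[[`, "solution"),
                       fx$structure)
  contrib <- mode_binding_contributions(exp)
  expect_equal(sum(contrib), inter$e_int, tolerance = 1e-10)
  # zero coupling: no contributions
  far <- two_cluster_system(separation = 600)
  inter_f <- mbd_interaction_energy(far$structure, far$ratios,
                                    rescreen = FALSE)
  exp_f <- project_modes(inter_f$complex$solution,
                         lapply(inter_f$fragments, `[[`, "solution"),
                         far$structure)
  expect_lt(max(abs(mode_binding_contributions(exp_f))), 1e-9)

  # the most binding mode of the stacked toy is collective: it spreads
  # over both fragments
  i_best <- which.min(contrib)
  expect_gt(collectivity(exp, i_best), 1.5)
})
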