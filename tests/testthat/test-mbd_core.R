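test_that("uncoupled Hamiltonian is diagonal with zero energy", {
  sys <- random_cluster_system(4, seed = 1)
  C <- build_hamiltonian(sys$params, matrix(0, 12, 12))
  expect_equal(C, diag(rep(sys$params$omega^2, each = 3)))
  sol <- diagonalize_hamiltonian(C, params = sys$params)
  expect_equal(sort(sol$freq), sort(rep(sys$params$omega, each = 3)),
               tolerance = 1e-12)
  expect_equal(mbd_energy(sol), 0, tolerance = 1e-12)
  r <- rpa_energy(sys$params, matrix(0, 12, 12), max_order = 4)
  expect_equal(r$total, 0, tolerance = 1e-14)
  expect_equal(unname(r$orders), rep(0, 3))
})

test_that("two-oscillator spectrum matches the closed form", {
  sys <- two_oscillators(R = 10)
  C <- build_hamiltonian(sys$params, sys$T_bare)
  expect_equal(C, t(C))
  sol <- diagonalize_hamiltonian(C, params = sys$params)
  lam_ref <- two_oscillator_lambda(1, 1, c(1, 1, -2) / 1000)
  expect_equal(sol$lambda, lam_ref, tolerance = 1e-12)
  expect_equal(max(abs(crossprod(sol$modes) - diag(6))), 0,
               tolerance = 1e-10)

  e <- mbd_energy(sol)
  expect_rel_equal(e, -0.75 * 1 * 1 / 10^6, 1e-3)  # London limit

  # trace identity: sum of eigenvalues equals the Hamiltonian trace
  expect_equal(sum(sol$lambda), sum(diag(C)), tolerance = 1e-12)
})

test_that("unstable spectra raise an informative error", {
  sys <- two_oscillators(R = 1.2)  # alpha T > 1: imaginary frequency
  C <- build_hamiltonian(sys$params, sys$T_bare)
  expect_error(
    diagonalize_hamiltonian(C, params = sys$params,
                            coords = sys$structure$coords),
    "imaginary coupled frequency")
})

test_that("plasmon-pole energy is non-positive along a distance sweep", {
  for (R in c(3.5, 5, 8, 12, 20)) {
    sys <- two_oscillators(R = R)
    sol <- diagonalize_hamiltonian(
      build_hamiltonian(sys$params, sys$T_bare), params = sys$params)
    expect_lte(mbd_energy(sol), 0)
  }
})

test_that("RPA log-det equals the plasmon-pole energy on random clusters", {
  grid <- imfreq_grid(20)
  for (seed in 1:6) {
    n <- 3 + (seed %% 4)
    sys <- random_cluster_system(n, seed = 100 + seed)
    f <- fermi_damping(sys$structure$coords, sys$params$rvdw)
    T_lr <- mbdtools:::.expand_pair_factor(f) * sys$T_bare
    sol <- diagonalize_hamiltonian(build_hamiltonian(sys$params, T_lr),
                                   params = sys$params)
    e_pp <- mbd_energy(sol)
    e_rpa <- rpa_energy(sys$params, T_lr, grid)$total
    expect_lt(abs(e_pp - e_rpa), 1e-8)
  }
})

test_that("second-order RPA term reduces to the damped London pair term", {
  sys <- two_oscillators(R = 12)
  params <- sys$params
  f <- fermi_damping(sys$structure$coords, params$rvdw)
  T_lr <- mbdtools:::.expand_pair_factor(f) * sys$T_bare
  r <- rpa_energy(params, T_lr, imfreq_grid(30), max_order = 3)
  c6 <- combine_c6(params$c6[1], params$alpha0[1],
                   params$c6[2], params$alpha0[2])
  expect_rel_equal(r$orders[["order2"]], -f[1, 2]^2 * c6 / 12^6, 1e-8)
  # in the saturated-damping regime (f ~ 1) the pairwise TS baseline and
  # the second-order term coincide
  sys2 <- two_oscillators(R = 16)
  f2 <- fermi_damping(sys2$structure$coords, sys2$params$rvdw)
  T2 <- mbdtools:::.expand_pair_factor(f2) * sys2$T_bare
  r2 <- rpa_energy(sys2$params, T2, imfreq_grid(30), max_order = 2)
  st2 <- sys2$structure
  st2$fragments <- c(1L, 2L)
  expect_rel_equal(pairwise_ts_energy(st2, sys2$params),
                   r2$orders[["order2"]], 1e-5)
})

test_that("energies are invariant under rigid motion of the system", {
  fx <- stacked_ring_system()
  e0 <- mbd_interaction_energy(fx$structure, fx$ratios)$e_int
  moved <- fx$structure
  set.seed(33)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  moved$coords <- sweep(moved$coords %*% t(R), 2, c(4, 4, -9), "+")
  e1 <- mbd_interaction_energy(moved, fx$ratios)$e_int
  expect_lt(abs(e0 - e1), 1e-10)
})

test_that("interaction energy is size consistent", {
  fx <- stacked_ring_system()
  expect_equal(
    mbd_interaction_energy(extract_fragment(fx$structure, 1),
                           fx$ratios[1:6])$e_int, 0)
  # separate the fragments far beyond their extent
  far <- stacked_ring_system(separation = 150)
  e_far <- mbd_interaction_energy(far$structure, far$ratios)$e_int
  expect_lt(abs(e_far), 1e-9)
  # binding weakens monotonically with separation beyond contact
  es <- vapply(c(6, 8, 11, 15), function(sep) {
    f <- stacked_ring_system(separation = sep)
    mbd_interaction_energy(f$structure, f$ratios)$e_int
  }, numeric(1))
  expect_true(all(diff(es) > 0))
  expect_true(all(es < 0))
})

test_that("pairwise TS energy reduces to a single damped London term", {
  st <- mbd_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 7)),
                      fragments = c(1L, 2L))
  p <- scale_vdw_params(st, 1)
  f <- fermi_damping(st$coords, p$rvdw)
  expect_equal(pairwise_ts_energy(st, p),
               -f[1, 2] * combine_c6(p$c6[1], p$alpha0[1],
                                     p$c6[2], p$alpha0[2]) / 7^6,
               tolerance = 1e-14)
  one_frag <- mbd_structure(c("C", "C"), st$coords)
  expect_equal(pairwise_ts_energy(one_frag, p), 0)
})

test_that("many-body reduction vanishes in the pair limit", {
  red <- vapply(c(8, 12, 18), function(R) {
    st <- mbd_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, R)),
                        fragments = c(1L, 2L))
    many_body_decomposition(st, 0.9, max_order = 6)$reduction_percent
  }, numeric(1))
  expect_true(all(abs(red) < 2))
  expect_true(all(diff(abs(red)) < 0))
  expect_lt(abs(red[3]), 0.05)
})

test_that("TS overbinds MBD more strongly for compact stacked geometries", {
  tight <- stacked_ring_system(separation = 5.6)
  open <- stacked_ring_system(separation = 7.5)
  d_of <- function(fx) {
    dec <- many_body_decomposition(fx$structure, fx$ratios)
    dec$e_ts - dec$e_int
  }
  d_tight <- d_of(tight)
  d_open <- d_of(open)
  expect_lt(d_tight, 0)   # TS below (more binding than) MBD
  expect_lt(d_tight, d_open)  # larger in magnitude when compact
})
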