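# Run `expr` with a private RNG stream so fixture generation never
# disturbs (or depends on) the caller's random state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded synthetic geometry generator
#'
#' Builds small oscillator clusters for testing and exploration: dimers,
#' linear chains, regular rings, pairs of stacked rings (a pi-pi stacking
#' toy) and random clusters with a minimum-distance floor.  The same seed
#' and arguments always reproduce the identical geometry and ratio table.
#'
#' @param topology one of `"dimer"`, `"chain"`, `"ring"`,
#'   `"stacked_rings"`, `"random_cluster"`.
#' @param n_atoms number of atoms (per ring for `stacked_rings`).
#' @param spacing nearest-neighbour spacing in Bohr (bond length for
#'   rings/chains, dimer separation, target density scale for clusters).
#' @param element element symbol(s), recycled over atoms.
#' @param ratios volume ratios: a single value, a per-atom vector, or a
#'   length-2 interval `c(min, max)` sampled uniformly per atom.
#' @param seed integer seed driving all randomness.
#' @param separation ring-plane separation for `stacked_rings` (Bohr,
#'   default 6.6).
#' @param min_dist minimum allowed interatomic distance (Bohr, default
#'   1.8); `random_cluster` rejects closer placements.
#' @param max_tries placement retries per atom before giving up.
#' @return a list with `structure` (an `mbd_structure`; stacked rings are
#'   labelled as two fragments) and `ratios` (numeric vector).
#' @export
generate_fixture <- function(topology = c("dimer", "chain", "ring",
                                          "stacked_rings",
                                          "random_cluster"),
                             n_atoms = 2, spacing = 4.0, element = "C",
                             ratios = 1.0, seed = 1, separation = 6.6,
                             min_dist = 1.8, max_tries = 200) {
  topology <- match.arg(topology)
  if (spacing < min_dist && topology != "random_cluster") {
    stop(sprintf("spacing %.3g below the minimum-distance floor %.3g",
                 spacing, min_dist))
  }
  coords <- switch(
    topology,
    dimer = {
      n_atoms <- 2L
      cbind(0, 0, c(0, spacing))
    },
    chain = cbind(0, 0, spacing * (seq_len(n_atoms) - 1)),
    ring = .ring_coords(n_atoms, spacing),
    stacked_rings = {
      ring1 <- .ring_coords(n_atoms, spacing)
      ring2 <- ring1
      ring2[, 3] <- ring2[, 3] + separation
      rbind(ring1, ring2)
    },
    random_cluster = .cluster_coords(n_atoms, spacing, min_dist,
                                     max_tries, seed)
  )
  ntot <- nrow(coords)
  symbols <- rep_len(element, ntot)
  frag <- if (topology == "stacked_rings") {
    rep(1:2, each = n_atoms)
  } else rep(1L, ntot)
  rat <- .with_seed(seed + 1L, {
    if (length(ratios) == 2 && ntot != 2) {
      stats::runif(ntot, ratios[1], ratios[2])
    } else rep_len(ratios, ntot)
  })
  list(structure = mbd_structure(symbols, coords, fragments = frag,
                                 comment = sprintf("fixture %s seed %d",
                                                   topology, seed)),
       ratios = rat)
}

.ring_coords <- function(n, bond) {
  if (n < 3) stop("ring needs at least 3 atoms")
  r <- bond / (2 * sin(pi / n))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(theta), r * sin(theta), 0)
}

.cluster_coords <- function(n, spacing, min_dist, max_tries, seed) {
  box <- spacing * max(2, n^(1 / 3) * 1.5)
  .with_seed(seed, {
    coords <- matrix(0, n, 3)
    coords[1, ] <- stats::runif(3, 0, box)
    for (i in seq_len(n)[-1]) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- stats::runif(3, 0, box)
        d <- sqrt(rowSums(sweep(coords[seq_len(i - 1), , drop = FALSE],
                                2, cand, "-")^2))
        if (all(d >= min_dist)) {
          coords[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not place atom %d after %d tries (floor %.2g)",
                     i, max_tries, min_dist))
      }
    }
    coords
  })
}

#' Constructed benzene-dimer geometries with synthetic volume ratios
#'
#' Idealized benzene dimer in its two nearly degenerate conformations,
#' built from a regular hexagonal monomer (C-C 1.3915 A, C-H 1.087 A).
#' The parallel-displaced conformer uses an interplane separation of
#' 3.47 A and an in-plane slip of 1.75 A; the T-shaped conformer places
#' the second (perpendicular) ring at a center-to-center distance of
#' 4.96 A with one C-H bond pointing at the first ring.  The accompanying
#' Hirshfeld volume ratios are synthetic representative values typical of
#' aromatic hydrocarbons (C 0.85, H 0.66); real applications should use
#' ratios computed from a DFT density.
#'
#' @param conformer `"parallel_displaced"` or `"t_shaped"`.
#' @return a list with `structure` (two fragments of 12 atoms) and
#'   `ratios`.
#' @export
benzene_dimer <- function(conformer = c("parallel_displaced", "t_shaped")) {
  conformer <- match.arg(conformer)
  cc <- 1.3915
  ch <- 1.087
  theta <- (2 * pi * (0:5) / 6) - pi / 2
  ring <- function(radius) cbind(radius * cos(theta),
                                 radius * sin(theta), 0)
  mono <- rbind(ring(cc), ring(cc + ch))   # 6 C then 6 H, xy plane
  symbols <- c(rep("C", 6), rep("H", 6))
  if (conformer == "parallel_displaced") {
    m2 <- mono
    m2[, 1] <- m2[, 1] + 1.75
    m2[, 3] <- m2[, 3] + 3.47
  } else {
    # rotate monomer into the xz-plane; atom at theta = -90 deg then
    # points along -z, toward the center of the first ring
    rot <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
    m2 <- mono %*% t(rot)
    m2[, 3] <- m2[, 3] + 4.96
  }
  coords <- angstrom_to_bohr(rbind(mono, m2))
  st <- mbd_structure(c(symbols, symbols), coords,
                      fragments = rep(1:2, each = 12),
                      comment = sprintf("benzene dimer (%s), constructed",
                                        conformer))
  list(structure = st,
       ratios = rep(c(rep(0.85, 6), rep(0.66, 6)), 2))
}
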