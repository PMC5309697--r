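# Nuclear charges for elements handled by the I/O layer (cube files need Z).
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34, Br = 35,
  Kr = 36, I = 53
)

.normalize_symbol <- function(sym) {
  paste0(toupper(substr(sym, 1, 1)), tolower(substring(sym, 2)))
}

#' Molecular structure with fragment labels
#'
#' Constructs the basic geometric container used throughout the package: a
#' set of atoms with element symbols, Cartesian coordinates in Bohr, and a
#' per-atom fragment index.  Fragment indices are 1-based and contiguous
#' (fragment 1, 2, ...), following R's native indexing convention.
#'
#' @param symbols character vector of element symbols.
#' @param coords N x 3 numeric matrix of coordinates in Bohr.
#' @param fragments per-atom integer fragment index, or a list of atom-index
#'   vectors (one per fragment) that partition `1:N`, or `NULL` for a single
#'   fragment.
#' @param comment optional comment string carried through file I/O.
#' @return an object of class `mbd_structure` with fields `symbols`,
#'   `coords` (Bohr), `fragments` (per-atom integer), `comment`.
#' @export
mbd_structure <- function(symbols, coords, fragments = NULL, comment = "") {
  symbols <- .normalize_symbol(as.character(symbols))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(symbols)
  if (n < 1) stop("structure must contain at least one atom")
  if (!all(dim(coords) == c(n, 3))) {
    stop(sprintf("coords must be %d x 3, got %d x %d",
                 n, nrow(coords), ncol(coords)))
  }
  unknown <- setdiff(unique(symbols), names(.element_z))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (n > 1) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    if (any(d == 0)) {
      ij <- which(d == 0, arr.ind = TRUE)[1, ]
      stop(sprintf("coincident atoms %d and %d", ij[1], ij[2]))
    }
  }
  fragments <- .resolve_fragments(fragments, n)
  structure(
    list(symbols = symbols, coords = coords, fragments = fragments,
         comment = comment),
    class = "mbd_structure"
  )
}

.resolve_fragments <- function(fragments, n) {
  if (is.null(fragments)) return(rep(1L, n))
  if (is.list(fragments)) {
    idx <- unlist(fragments)
    if (anyDuplicated(idx)) {
      dup <- idx[duplicated(idx)][1]
      stop(sprintf("overlapping fragment ranges: atom %d assigned twice", dup))
    }
    if (!setequal(idx, seq_len(n))) {
      stop(sprintf("fragment ranges must partition all %d atoms (got %d)",
                   n, length(unique(idx))))
    }
    out <- integer(n)
    for (f in seq_along(fragments)) out[fragments[[f]]] <- f
    return(out)
  }
  fragments <- as.integer(fragments)
  if (length(fragments) != n) {
    stop(sprintf("fragment vector length %d does not match atom count %d",
                 length(fragments), n))
  }
  u <- sort(unique(fragments))
  if (!identical(u, seq_along(u))) {
    stop("fragment indices must be contiguous starting at 1")
  }
  fragments
}

#' @export
print.mbd_structure <- function(x, ...) {
  cat(sprintf("<mbd_structure: %d atoms, %d fragment(s)>\n",
              length(x$symbols), n_fragments(x)))
  tab <- table(x$symbols)
  cat("  composition:", paste(names(tab), tab, sep = "", collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms / fragments in a structure
#' @param structure an `mbd_structure`.
#' @return integer count.
#' @export
n_atoms <- function(structure) length(structure$symbols)

#' @rdname n_atoms
#' @export
n_fragments <- function(structure) max(structure$fragments)

#' Atom indices belonging to one fragment
#' @param structure an `mbd_structure`.
#' @param f fragment index (1-based).
#' @return integer vector of atom indices.
#' @export
fragment_atoms <- function(structure, f) which(structure$fragments == f)

#' Extract one fragment as a stand-alone structure
#'
#' The sub-geometry keeps the coordinates of the parent complex (rigid
#' fragments), which matches evaluating interaction energies of a complex
#' against its frozen sub-geometries.
#'
#' @param structure an `mbd_structure`.
#' @param f fragment index.
#' @return an `mbd_structure` with a single fragment.
#' @export
extract_fragment <- function(structure, f) {
  idx <- fragment_atoms(structure, f)
  if (length(idx) == 0) stop("no such fragment: ", f)
  mbd_structure(structure$symbols[idx], structure$coords[idx, , drop = FALSE],
                comment = sprintf("fragment %d of: %s", f, structure$comment))
}

#' Assign fragments by distance clustering
#'
#' Connected components of the bond graph obtained with a fixed distance
#' cutoff (default 2.0 angstrom).  Provided as a convenience; chemically
#' defined fragments passed explicitly are always preferable and this is
#' never applied implicitly.
#'
#' @param structure an `mbd_structure`.
#' @param cutoff bond cutoff in angstrom.
#' @return the structure with `fragments` reassigned.
#' @export
autodetect_fragments <- function(structure, cutoff = 2.0) {
  n <- n_atoms(structure)
  cut_b <- angstrom_to_bohr(cutoff)
  d <- as.matrix(stats::dist(structure$coords))
  adj <- d <= cut_b
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      a <- queue[1]; queue <- queue[-1]
      if (comp[a] > 0) next
      comp[a] <- cur
      queue <- c(queue, which(adj[a, ] & comp == 0L))
    }
  }
  structure$fragments <- comp
  structure
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `symbol x y z` row per atom with coordinates in angstrom.  Coordinates
#' are converted to Bohr on input.
#'
#' @param path file path.
#' @param fragments fragment specification: `NULL` (single fragment), a list
#'   of atom-index vectors, or `"auto"` for distance clustering at
#'   `cutoff` angstrom.
#' @param cutoff bond cutoff (angstrom) used when `fragments = "auto"`.
#' @return an `mbd_structure`.
#' @export
read_xyz <- function(path, fragments = NULL, cutoff = 2.0) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ file: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop(sprintf("malformed count line (line 1): '%s'", lines[1]))
  }
  if (length(lines) < 2 + n) {
    stop(sprintf("XYZ declares %d atoms but file has only %d atom rows",
                 n, length(lines) - 2))
  }
  rows <- lines[3:(2 + n)]
  toks <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4)
  if (length(bad) > 0) {
    stop(sprintf("malformed atom row (line %d): '%s'", bad[1] + 2, rows[bad[1]]))
  }
  symbols <- vapply(toks, `[[`, "", 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinate in XYZ file")
  auto <- identical(fragments, "auto")
  st <- mbd_structure(symbols, angstrom_to_bohr(xyz),
                      fragments = if (auto) NULL else fragments,
                      comment = lines[2])
  if (auto) st <- autodetect_fragments(st, cutoff)
  st
}

#' Write an XYZ geometry file
#'
#' Coordinates are written in angstrom.
#'
#' @param structure an `mbd_structure`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_xyz <- function(structure, path) {
  xyz <- bohr_to_angstrom(structure$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n_atoms(structure)), con)
  writeLines(gsub("[\r\n]", " ", structure$comment), con)
  writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                     structure$symbols, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}

#' Read a per-atom Hirshfeld volume-ratio table
#'
#' Whitespace-separated table with one row per atom: an atom index (or an
#' element symbol, used only as a cross-check) followed by the ratio of the
#' atom-in-molecule Hirshfeld volume to the free-atom volume.  A one-column
#' table of bare ratios in structure order is also accepted.
#'
#' @param path file path, or `NULL` with `free_atom = TRUE`.
#' @param structure the `mbd_structure` the ratios belong to.
#' @param free_atom if `TRUE`, return the free-atom limit (all ratios 1).
#' @return numeric vector of ratios, aligned to the structure's atom order.
#' @export
read_volume_ratios <- function(path = NULL, structure, free_atom = FALSE) {
  n <- n_atoms(structure)
  if (free_atom) return(rep(1.0, n))
  if (is.null(path)) stop("either a ratio file or free_atom = TRUE is required")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != n) {
    stop(sprintf("ratio table has %d rows but structure has %d atoms",
                 length(lines), n))
  }
  toks <- strsplit(lines, "\\s+")
  nc <- vapply(toks, length, 1L)
  if (all(nc == 1)) {
    v <- as.numeric(vapply(toks, `[[`, "", 1))
  } else {
    key <- vapply(toks, `[[`, "", 1)
    v <- as.numeric(vapply(toks, `[[`, "", 2))
    if (anyNA(suppressWarnings(as.numeric(key)))) {
      key_sym <- .normalize_symbol(key)
      if (!identical(key_sym, structure$symbols)) {
        stop("element symbols in ratio table do not match structure order")
      }
    } else {
      ord <- order(as.integer(key))
      v <- v[ord]
    }
  }
  if (anyNA(v)) stop("non-numeric ratio in table")
  if (any(v <= 0)) stop("volume ratios must be positive")
  v
}

#' Regular 3-D density grid
#'
#' A scalar field on a regular grid, the container used for charge
#' densities and density differences.  Axis vectors are the columns of a
#' 3 x 3 matrix; voxel volume is `abs(det(axes))`.
#'
#' @param origin length-3 numeric, grid origin (Bohr).
#' @param axes 3 x 3 matrix whose rows are the grid step vectors (Bohr).
#' @param shape 3 positive integers, number of points along each axis.
#' @param values numeric array of dim `shape` (defaults to zeros).
#' @return an object of class `mbd_grid`.
#' @export
mbd_grid <- function(origin, axes, shape, values = NULL) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)),
            length(shape) == 3, all(shape >= 1))
  if (abs(det(axes)) < 1e-14) stop("grid axis vectors are degenerate")
  if (is.null(values)) values <- array(0, dim = shape)
  values <- array(as.numeric(values), dim = shape)
  structure(list(origin = origin, axes = axes, shape = shape,
                 values = values),
            class = "mbd_grid")
}

#' @export
print.mbd_grid <- function(x, ...) {
  cat(sprintf("<mbd_grid: %d x %d x %d points, voxel %.4g Bohr^3>\n",
              x$shape[1], x$shape[2], x$shape[3], voxel_volume(x)))
  invisible(x)
}

#' Voxel volume of a grid (Bohr^3)
#' @param grid an `mbd_grid`.
#' @return scalar volume.
#' @export
voxel_volume <- function(grid) abs(det(grid$axes))

#' Integrate a scalar field over its grid
#' @param grid an `mbd_grid`.
#' @return the Riemann sum `sum(values) * voxel_volume`.
#' @export
grid_integral <- function(grid) sum(grid$values) * voxel_volume(grid)

#' Cartesian coordinates of all grid points
#' @param grid an `mbd_grid`.
#' @return an `prod(shape) x 3` matrix, first axis fastest (column-major,
#'   matching the storage order of `values`).
#' @export
grid_points <- function(grid) {
  i <- seq_len(grid$shape[1]) - 1
  j <- seq_len(grid$shape[2]) - 1
  k <- seq_len(grid$shape[3]) - 1
  idx <- as.matrix(expand.grid(i = i, j = j, k = k))
  sweep(idx %*% grid$axes, 2, grid$origin, "+")
}

#' Write a Gaussian cube file
#'
#' Standard cube dialect: two comment lines, atom count plus origin, three
#' axis records, per-atom `Z  charge  x y z` rows, then the scalar field
#' with the last grid index varying fastest, six values per line, all in
#' Bohr / atomic units.
#'
#' @param grid an `mbd_grid`.
#' @param structure the `mbd_structure` sharing the grid's coordinate frame.
#' @param path output path.
#' @param comment description written into the header.
#' @return invisibly, the path.
#' @export
write_cube <- function(grid, structure, path, comment = "scalar field") {
  if (!all(is.finite(grid$values))) stop("grid contains non-finite values")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "generated by mbdtools (atomic units)"), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", n_atoms(structure),
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (a in 1:3) {
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f", grid$shape[a],
                       grid$axes[a, 1], grid$axes[a, 2], grid$axes[a, 3]), con)
  }
  z <- .element_z[structure$symbols]
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", z, as.numeric(z),
                     structure$coords[, 1], structure$coords[, 2],
                     structure$coords[, 3]), con)
  # cube order: outer loop first axis, inner loop third axis
  flat <- numeric(prod(grid$shape))
  pos <- 1L
  for (i in seq_len(grid$shape[1])) {
    for (j in seq_len(grid$shape[2])) {
      nk <- grid$shape[3]
      flat[pos:(pos + nk - 1)] <- grid$values[i, j, ]
      pos <- pos + nk
    }
  }
  lines <- tapply(sprintf("%19.12e", flat),
                  (seq_along(flat) - 1) %/% 6, paste, collapse = " ")
  writeLines(unname(lines), con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path file path.
#' @return a list with `grid` (an `mbd_grid`) and `structure`
#'   (an `mbd_structure`).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  comment <- lines[1]
  hdr <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  natom <- as.integer(hdr[1])
  origin <- as.numeric(hdr[2:4])
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (a in 1:3) {
    rec <- as.numeric(strsplit(trimws(lines[3 + a]), "\\s+")[[1]])
    shape[a] <- as.integer(rec[1])
    axes[a, ] <- rec[2:4]
  }
  atoms <- lines[7:(6 + natom)]
  arec <- t(vapply(strsplit(trimws(atoms), "\\s+"),
                   function(t) as.numeric(t[1:5]), numeric(5)))
  z <- as.integer(arec[, 1])
  symbols <- names(.element_z)[match(z, .element_z)]
  coords <- arec[, 3:5, drop = FALSE]
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natom))]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape)) {
    stop(sprintf("cube value section has %d entries, expected %d",
                 length(vals), prod(shape)))
  }
  values <- array(0, dim = shape)
  pos <- 1L
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      values[i, j, ] <- vals[pos:(pos + shape[3] - 1)]
      pos <- pos + shape[3]
    }
  }
  st <- mbd_structure(symbols, coords, comment = comment)
  list(grid = mbd_grid(origin, axes, shape, values), structure = st)
}
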