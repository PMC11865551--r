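## Molecular geometry container, XYZ I/O and the programmatic fixture
## generators used by the hydrogen-chain and water studies.

#' Construct a molecular geometry
#'
#' Coordinates are stored in bohr; all energies derived from a geometry are in
#' hartree. Atom ordering is significant: the symmetrically orthogonalized
#' atomic-orbital (SAO) representation used for wave-function transfer indexes
#' orbitals atom-major, so every operation in the package preserves the input
#' atom order.
#'
#' @param atomic_numbers integer vector of atomic numbers
#' @param coordinates numeric matrix, n_atom x 3, in bohr
#' @param charge net molecular charge (integer, default 0)
#' @param masses atomic masses in amu; defaults to standard atomic weights
#' @return an object of class `geometry` with fields `atomic_numbers`,
#'   `coordinates` (bohr), `masses` (amu), `charge`, `n_elec`
#' @export
geometry <- function(atomic_numbers, coordinates, charge = 0L, masses = NULL) {
  atomic_numbers <- as.integer(atomic_numbers)
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  n <- length(atomic_numbers)
  if (nrow(coordinates) != n) stop("coordinates must have one row per atom")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (is.null(masses)) masses <- element_mass(atomic_numbers)
  if (length(masses) != n) stop("masses must have one entry per atom")
  n_elec <- sum(atomic_numbers) - as.integer(charge)
  if (n_elec < 1L) stop("geometry must have at least one electron")
  if (n >= 2L) {
    dmin <- min(stats::dist(coordinates))
    if (dmin < 1e-6) stop("two atoms closer than 1e-6 bohr (minimum distance ",
                          format(dmin), ")")
  }
  structure(list(
    atomic_numbers = atomic_numbers,
    coordinates = coordinates,
    masses = as.numeric(masses),
    charge = as.integer(charge),
    n_elec = as.integer(n_elec)
  ), class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms, charge %d, %d electrons>\n",
              length(x$atomic_numbers), x$charge, x$n_elec))
  invisible(x)
}

n_atoms <- function(geom) length(geom$atomic_numbers)

#' Read a geometry from an XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom. Extended-XYZ
#' files are accepted; extra columns beyond the coordinates are ignored.
#' Coordinates are converted to bohr (1 Angstrom = 1.8897259886 bohr).
#'
#' @param path path to an XYZ file
#' @param charge net charge to assign (XYZ does not carry one)
#' @return a [geometry()]
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 1L) {
    stop("XYZ parse error at line 1: malformed or non-positive atom count '",
         trimws(lines[1]), "'")
  }
  if (length(lines) < nat + 2L) {
    stop("XYZ parse error: expected ", nat + 2L, " lines, found ", length(lines))
  }
  sym <- character(nat)
  xyz <- matrix(0, nat, 3)
  for (i in seq_len(nat)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    }
    sym[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop("XYZ parse error at line ", ln, ": bad coordinate")
    xyz[i, ] <- v
  }
  z <- tryCatch(element_number(sym),
                error = function(e) stop("XYZ parse error: ", conditionMessage(e)))
  geometry(z, xyz * evcont_constants$bohr_per_angstrom, charge = charge)
}

#' Write a geometry to an XYZ file
#'
#' Coordinates are written in Angstrom with 12 decimal places.
#'
#' @param geom a [geometry()]
#' @param path output file path
#' @param comment single-line comment (must not contain a newline)
#' @export
write_xyz <- function(geom, path, comment = "") {
  if (grepl("[\n\r]", comment)) stop("comment must not contain a newline")
  ang <- geom$coordinates / evcont_constants$bohr_per_angstrom
  sym <- element_symbol(geom$atomic_numbers)
  body <- sprintf("%-3s %20.12f %20.12f %20.12f", sym, ang[, 1], ang[, 2], ang[, 3])
  writeLines(c(as.character(n_atoms(geom)), comment, body), con = path)
  invisible(NULL)
}

#' Equidistant linear hydrogen chains at a series of spacings
#'
#' Generates collinear chains of `n_atoms` hydrogens along the x axis with the
#' first atom at the origin, one geometry per requested inter-atomic spacing.
#' These are the symmetric-stretch configurations of the hydrogen-chain
#' benchmark systems.
#'
#' @param n_atoms number of hydrogen atoms (>= 2)
#' @param spacings numeric vector of positive inter-atomic spacings in bohr
#' @return list of [geometry()]
#' @export
symmetric_stretch_series <- function(n_atoms, spacings) {
  if (n_atoms < 2L) stop("n_atoms must be >= 2")
  if (any(spacings <= 0)) stop("spacings must be positive")
  lapply(spacings, function(d) {
    xyz <- cbind((seq_len(n_atoms) - 1) * d, 0, 0)
    geometry(rep(1L, n_atoms), xyz)
  })
}

#' Randomly distorted copies of a base geometry
#'
#' Each sample displaces every atom by exactly `displacement` bohr along an
#' independent uniformly random 3D direction (a normalized standard-normal
#' draw). Reproducible from `seed`; sample i does not depend on `n_samples`.
#'
#' @param base a [geometry()]
#' @param displacement non-negative displacement magnitude in bohr
#' @param n_samples number of distorted geometries to generate
#' @param seed integer seed
#' @return list of [geometry()]
#' @export
random_distortion_set <- function(base, displacement, n_samples, seed) {
  if (displacement < 0) stop("displacement must be non-negative")
  nat <- n_atoms(base)
  out <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    ## per-sample substream: sample i independent of n_samples
    set.seed(as.integer((seed + 7919L * i) %% .Machine$integer.max))
    dirs <- matrix(stats::rnorm(3L * nat), nat, 3)
    nrm <- sqrt(rowSums(dirs^2))
    ## degenerate zero draws are essentially impossible; guard anyway
    nrm[nrm < 1e-300] <- 1
    disp <- dirs / nrm * displacement
    out[[i]] <- geometry(base$atomic_numbers, base$coordinates + disp,
                         charge = base$charge, masses = base$masses)
  }
  out
}

#' Water monomer fixture
#'
#' Gas-phase water at the experimental equilibrium structure (r(OH) = 0.9572
#' Angstrom, HOH angle 104.52 degrees), optionally with both O-H bonds scaled
#' by `stretch`. A stretch of 1.1 reproduces the "stretched initial
#' configuration" used to launch vibrational molecular dynamics.
#'
#' @param stretch multiplicative O-H bond stretch factor (default 1)
#' @return a [geometry()] ordered O, H, H
#' @export
water_geometry <- function(stretch = 1.0) {
  r <- 0.9572 * evcont_constants$bohr_per_angstrom * stretch
  half <- 104.52 / 2 * pi / 180
  xyz <- rbind(
    c(0, 0, 0),
    c(r * sin(half),  r * cos(half), 0),
    c(-r * sin(half), r * cos(half), 0)
  )
  geometry(c(8L, 1L, 1L), xyz)
}

#' Rigidly translate a geometry
#' @param geom a [geometry()]
#' @param shift length-3 numeric displacement in bohr
#' @return translated [geometry()]
#' @export
translate_geometry <- function(geom, shift) {
  geometry(geom$atomic_numbers,
           sweep(geom$coordinates, 2, as.numeric(shift), "+"),
           charge = geom$charge, masses = geom$masses)
}
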