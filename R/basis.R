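## Contracted-Gaussian basis handling. Basis sets live as structured text
## files under inst/extdata/basis (element -> shells -> exponent/coefficient
## rows); build_basis() instantiates shells on a geometry. Shells are ordered
## atom-major with p components ordered x, y, z — the ordering the SAO
## representation inherits.

.basis_registry_dir <- function() {
  system.file("extdata", "basis", package = "evcont")
}

#' List the built-in basis sets
#' @return character vector of basis names (e.g. "sto-3g", "6-31g")
#' @export
list_basis_sets <- function() {
  sub("\\.dat$", "", list.files(.basis_registry_dir(), pattern = "\\.dat$"))
}

## Parse one basis file into list(element -> list of shells(l, exponents, coeffs))
.parse_basis_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur_el <- NULL
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] == "element") {
      cur_el <- tok[2]
      out[[cur_el]] <- list()
      i <- i + 1L
    } else if (tok[1] == "shell") {
      type <- toupper(tok[2])
      np <- as.integer(tok[3])
      rows <- do.call(rbind, lapply(lines[(i + 1L):(i + np)], function(s) {
        as.numeric(strsplit(s, "\\s+")[[1]])
      }))
      if (type == "S") {
        out[[cur_el]] <- c(out[[cur_el]], list(list(l = 0L, exponents = rows[, 1], coeffs = rows[, 2])))
      } else if (type == "P") {
        out[[cur_el]] <- c(out[[cur_el]], list(list(l = 1L, exponents = rows[, 1], coeffs = rows[, 2])))
      } else if (type == "SP") {
        out[[cur_el]] <- c(out[[cur_el]],
                           list(list(l = 0L, exponents = rows[, 1], coeffs = rows[, 2]),
                                list(l = 1L, exponents = rows[, 1], coeffs = rows[, 3])))
      } else {
        stop("unsupported shell type '", type, "' in ", path)
      }
      i <- i + np + 1L
    } else {
      stop("cannot parse basis file line: '", lines[i], "'")
    }
  }
  out
}

## External backends: name -> function(geometry, basis_name) -> ao_integrals.
## Narrow adapter contract for basis sets / angular momenta beyond the
## built-in s/p engine. Registered at runtime; nothing is built in.
.backend_env <- new.env(parent = emptyenv())

#' Register an external integral backend
#'
#' A backend is a function `function(geometry, basis_name)` returning the same
#' structure as [compute_ao_integrals()] (fields `overlap`, `core_h`, `eri`
#' in physicists' notation, `e_nuc`, `L`), in hartree/bohr atomic units.
#' @param name backend name
#' @param fn backend function
#' @export
register_integral_backend <- function(name, fn) {
  stopifnot(is.function(fn))
  assign(name, fn, envir = .backend_env)
  invisible(NULL)
}

get_integral_backend <- function(name) {
  if (!exists(name, envir = .backend_env)) {
    stop("no integral backend registered under '", name, "'")
  }
  get(name, envir = .backend_env)
}

#' Build a contracted-Gaussian basis on a geometry
#'
#' Instantiates the shells of a built-in basis set on every atom of the
#' geometry, ordered by (atom index, shell index, angular component with p
#' ordered x, y, z). Contractions are renormalized so every contracted
#' function has unit self-overlap.
#'
#' @param geom a [geometry()]
#' @param basis_name one of [list_basis_sets()] (case insensitive)
#' @return an object of class `basis_set`: list of shells (fields
#'   `center_atom`, `angular_momentum`, `exponents`, `contraction_coeffs`,
#'   `scale`) with attributes `L` (basis size), `basis_name`, `offsets`,
#'   `fn_atom` (atom index of each basis function)
#' @export
build_basis <- function(geom, basis_name) {
  bname <- tolower(basis_name)
  path <- file.path(.basis_registry_dir(), paste0(bname, ".dat"))
  if (!file.exists(path)) {
    stop("unknown basis '", basis_name, "'; built-in sets: ",
         paste(list_basis_sets(), collapse = ", "),
         ". For other bases configure an external backend (see ",
         "register_integral_backend).")
  }
  tab <- .parse_basis_file(path)
  shells <- list()
  for (a in seq_along(geom$atomic_numbers)) {
    sym <- element_symbol(geom$atomic_numbers[a])
    if (is.null(tab[[sym]])) {
      stop("basis '", basis_name, "' has no entry for element ", sym,
           "; an external backend is required")
    }
    for (sh in tab[[sym]]) {
      if (sh$l > 1L) {
        stop("built-in engine supports s and p shells only; ",
             "external backend required for higher angular momentum")
      }
      ord <- order(-sh$exponents)
      shells[[length(shells) + 1L]] <- list(
        center_atom = a,
        angular_momentum = sh$l,
        exponents = sh$exponents[ord],
        contraction_coeffs = sh$coeffs[ord],
        scale = 1.0
      )
    }
  }
  basis <- structure(shells, class = "basis_set",
                     basis_name = bname)
  ## renormalize each contracted shell to unit self-overlap
  norms <- cpp_shell_self_overlap(.shell_args(geom, basis))
  for (s in seq_along(basis)) basis[[s]]$scale <- 1 / sqrt(norms[s])
  ncart <- vapply(basis, function(s) if (s$angular_momentum == 0L) 1L else 3L, 1L)
  off <- c(0L, cumsum(ncart))
  attr(basis, "L") <- sum(ncart)
  attr(basis, "offsets") <- off[-length(off)]
  attr(basis, "fn_atom") <- rep(vapply(basis, `[[`, 1L, "center_atom"), ncart)
  basis
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set '%s': %d shells, L = %d>\n",
              attr(x, "basis_name"), length(x), attr(x, "L")))
  invisible(x)
}

#' Number of basis functions of a basis set
#' @param basis a `basis_set`
#' @return integer basis size L
#' @export
basis_size <- function(basis) attr(basis, "L")

## Flatten geometry + basis into the argument list the C++ engine expects.
.shell_args <- function(geom, basis) {
  list(
    coords = geom$coordinates,
    zvals = as.numeric(geom$atomic_numbers),
    sh_atom = vapply(basis, `[[`, 1L, "center_atom"),
    sh_l = vapply(basis, `[[`, 1L, "angular_momentum"),
    sh_nprim = vapply(basis, function(s) length(s$exponents), 1L),
    sh_scale = vapply(basis, `[[`, 1.0, "scale"),
    prim_exp = unlist(lapply(basis, `[[`, "exponents")),
    prim_coef = unlist(lapply(basis, `[[`, "contraction_coeffs"))
  )
}
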