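#' Molecular species for energetics and state counting
#'
#' Constructs a `species` object: the unit of all per-molecule energetics
#' (zero-point energy, thermal corrections, state counts) in the package.
#' Electronic energies are relative values on a user-declared reference;
#' the package performs no electronic-structure computation.
#'
#' @param name Species label.
#' @param mass Mass in amu (> 0).
#' @param charge Integer charge in elementary units.
#' @param frequencies Real harmonic vibrational frequencies in cm^-1
#'   (all > 0). A transition state's imaginary mode goes in
#'   `imaginary_frequency`, never here.
#' @param imaginary_frequency Optional magnitude of the single imaginary
#'   frequency of a transition state, cm^-1 (> 0).
#' @param rotational_constants 0-3 rotational constants in cm^-1. None for
#'   an atom; one (or one duplicated) for a linear rotor; three for a
#'   nonlinear rotor. Linearity is decided from how many constants are
#'   supplied, not from the geometry.
#' @param symmetry_number Rotational symmetry number (integer >= 1).
#' @param polarizability Optional isotropic polarizability, Angstrom^3.
#' @param dipole Optional permanent dipole moment, Debye.
#' @param geometry Optional data frame with columns `element`, `x`, `y`,
#'   `z` (Angstrom), e.g. from [read_xyz()].
#' @param electronic_energy Optional electronic energy in eV relative to
#'   `energy_ref`.
#' @param energy_ref Label naming the reference of `electronic_energy`;
#'   species entering one reaction must share it.
#'
#' @return An object of class `species`.
#' @seealso [zpe()], [rrho_thermal_correction()], [reaction_enthalpy()]
#' @export
#' @examples
#' methylamine <- species("CH3NH2", mass = 31.042, dipole = 1.31,
#'                        polarizability = 4.7,
#'                        frequencies = c(300, 900, 1500, 3000),
#'                        rotational_constants = c(3.42, 0.74, 0.72))
#' methylamine
species <- function(name, mass, charge = 0L, frequencies = numeric(),
                    imaginary_frequency = NULL,
                    rotational_constants = numeric(),
                    symmetry_number = 1L, polarizability = NULL,
                    dipole = NULL, geometry = NULL,
                    electronic_energy = NULL, energy_ref = "unset") {
  check_number(mass, "mass", 0, strict = TRUE)
  if (length(frequencies) && any(frequencies <= 0))
    stop("all `frequencies` must be > 0 (imaginary modes are supplied via ",
         "`imaginary_frequency`)", call. = FALSE)
  if (!is.null(imaginary_frequency))
    check_number(imaginary_frequency, "imaginary_frequency", 0, strict = TRUE)
  if (length(rotational_constants) > 3L)
    stop("at most 3 rotational constants are allowed", call. = FALSE)
  if (length(rotational_constants) && any(rotational_constants <= 0))
    stop("rotational constants must be > 0", call. = FALSE)
  if (symmetry_number < 1L)
    stop("`symmetry_number` must be >= 1", call. = FALSE)
  if (!is.null(geometry)) geometry <- validate_geometry(geometry)
  structure(list(
    name = name, mass = mass, charge = as.integer(charge),
    frequencies = as.numeric(frequencies),
    imaginary_frequency = imaginary_frequency,
    rotational_constants = as.numeric(rotational_constants),
    symmetry_number = as.integer(symmetry_number),
    polarizability = polarizability, dipole = dipole,
    geometry = geometry, electronic_energy = electronic_energy,
    energy_ref = energy_ref
  ), class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("<species> %s  (m = %g amu, q = %+d)\n", x$name, x$mass,
              x$charge))
  cat(sprintf("  %d vibrational modes, rotor: %s\n",
              length(x$frequencies), rotor_type(x)))
  if (!is.null(x$imaginary_frequency))
    cat(sprintf("  transition state, imaginary mode %g cm^-1\n",
                x$imaginary_frequency))
  if (!is.null(x$electronic_energy))
    cat(sprintf("  electronic energy %g eV (ref: %s)\n",
                x$electronic_energy, x$energy_ref))
  invisible(x)
}

#' Rotor classification of a species
#'
#' `"atom"` when no rotational constants are supplied, `"linear"` for one
#' constant (or one duplicated), `"nonlinear"` for three.
#'
#' @param x A [species()].
#' @return Character scalar.
#' @export
rotor_type <- function(x) {
  n <- length(x$rotational_constants)
  if (n == 0L) "atom" else if (n <= 2L) "linear" else "nonlinear"
}

validate_geometry <- function(geometry) {
  geometry <- as.data.frame(geometry)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(geometry)))
    stop("geometry needs columns element, x, y, z", call. = FALSE)
  if (nrow(geometry) == 0L)
    stop("geometry has no atoms", call. = FALSE)
  if (!all(vapply(geometry[c("x", "y", "z")], is.numeric, logical(1))))
    stop("geometry coordinates must be numeric", call. = FALSE)
  geometry
}

#' Read a geometry from an XYZ file
#'
#' Parses the conventional XYZ layout: an atom-count line, a comment line,
#' then one `element x y z` row per atom with coordinates in Angstrom.
#'
#' @param path Path to the XYZ file.
#' @return Data frame with columns `element`, `x`, `y`, `z` (Angstrom),
#'   atoms in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "a lone carbon", "C 0 0 0"), f)
#' read_xyz(f)
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty file",
                               call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("XYZ parse error at line 1: atom count is not a positive integer",
         call. = FALSE)
  if (length(lines) < n + 2L)
    stop(sprintf("XYZ parse error: %d atom rows promised but file ends at line %d",
                 n, length(lines)), call. = FALSE)
  rows <- lines[seq(3L, 2L + n)]
  parse_row <- function(i) {
    parts <- strsplit(trimws(rows[i]), "\\s+")[[1L]]
    if (length(parts) < 4L)
      stop(sprintf("XYZ parse error at line %d: expected 'element x y z'",
                   i + 2L), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(xyz))
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                   i + 2L), call. = FALSE)
    data.frame(element = parts[1L], x = xyz[1L], y = xyz[2L], z = xyz[3L])
  }
  do.call(rbind, lapply(seq_len(n), parse_row))
}

#' Write a geometry to an XYZ file
#'
#' @param geometry Data frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param path Output path.
#' @param comment Comment placed on line 2.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  geometry <- validate_geometry(geometry)
  rows <- sprintf("%-3s %14.8f %14.8f %14.8f", geometry$element,
                  geometry$x, geometry$y, geometry$z)
  writeLines(c(as.character(nrow(geometry)), comment, rows), path)
  invisible(path)
}
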