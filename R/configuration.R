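#' Atomic configuration
#'
#' Container for a single molecular geometry: element symbols, Cartesian
#' positions in Angstrom, an optional orthorhombic simulation cell, and
#' optional energy (eV) and forces (eV/Angstrom) attached by a potential
#' evaluation.
#'
#' @param species Character vector of element symbols (length N). Symbols are
#'   canonicalized to standard capitalization ("h" -> "H", "fe" -> "Fe") and
#'   compared case-sensitively afterwards.
#' @param positions Numeric N x 3 matrix of Cartesian coordinates, Angstrom.
#' @param cell Optional 3 x 3 matrix (Angstrom). Diagonal entries must be
#'   strictly positive when set. A length-3 vector is accepted and expanded
#'   to a diagonal (orthorhombic) cell.
#' @param energy Optional scalar energy, eV.
#' @param forces Optional N x 3 matrix of forces, eV/Angstrom.
#' @param label Free-text label carried through I/O.
#'
#' @return An object of class `configuration`.
#' @export
configuration <- function(species, positions, cell = NULL, energy = NULL,
                          forces = NULL, label = "") {
  species <- canonical_species(species)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- length(species)
  if (n < 1L) stop("configuration needs at least one atom")
  if (!is.matrix(positions) || ncol(positions) != 3L || nrow(positions) != n)
    stop("positions must be an N x 3 matrix matching species length")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.null(cell)) {
    if (is.vector(cell) && length(cell) == 3L) cell <- diag(as.numeric(cell))
    cell <- as.matrix(cell)
    if (!identical(dim(cell), c(3L, 3L))) stop("cell must be 3 x 3")
    if (any(diag(cell) <= 0)) stop("cell diagonal must be strictly positive")
  }
  if (!is.null(energy)) {
    energy <- as.numeric(energy)
    if (length(energy) != 1L || !is.finite(energy)) stop("energy must be a finite scalar")
  }
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    storage.mode(forces) <- "double"
    if (!identical(dim(forces), dim(positions)))
      stop("forces shape must match positions")
  }
  structure(
    list(species = species, positions = positions, cell = cell,
         energy = energy, forces = forces, label = as.character(label)[1L]),
    class = "configuration"
  )
}

canonical_species <- function(species) {
  species <- as.character(species)
  if (any(!nzchar(species))) stop("empty species symbol")
  paste0(toupper(substr(species, 1L, 1L)),
         tolower(substr(species, 2L, nchar(species))))
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d atoms (%s)%s\n",
              nrow(x$positions),
              paste(unique(x$species), collapse = ","),
              if (!is.null(x$energy)) sprintf(" E = %.6f eV", x$energy) else ""))
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config A `configuration`.
#' @return Integer atom count.
#' @export
n_atoms <- function(config) nrow(config$positions)

is_configuration <- function(x) inherits(x, "configuration")

stopifnot_configuration <- function(x) {
  if (!is_configuration(x)) stop("expected a `configuration` object")
  invisible(x)
}

# Flatten / restore between N x 3 matrices and length-3N vectors; all
# optimizers work on the flat representation.
flatten_positions <- function(config) as.numeric(t(config$positions))

unflatten_positions <- function(x, n) matrix(x, nrow = n, ncol = 3L, byrow = TRUE)

with_positions <- function(config, pos_vec_or_mat) {
  n <- n_atoms(config)
  pos <- if (is.matrix(pos_vec_or_mat)) pos_vec_or_mat else unflatten_positions(pos_vec_or_mat, n)
  config$positions <- pos
  config$energy <- NULL
  config$forces <- NULL
  config
}

same_composition <- function(a, b) {
  identical(sort(a$species), sort(b$species))
}

pairwise_distances <- function(positions) {
  m <- as.matrix(stats::dist(positions))
  dimnames(m) <- NULL
  m
}
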