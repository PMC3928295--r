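## SystemGeometry: elements + Cartesian coordinates (internal unit Bohr).

#' Create a system geometry
#'
#' The single mutable state all calculations read: element symbols plus
#' Cartesian coordinates.  Coordinates are stored internally in Bohr; supply
#' them either in Angstrom (`coords_ang`, the file-format unit) or directly in
#' Bohr (`coords_bohr`).
#'
#' @param elements character vector of element symbols.
#' @param coords_ang numeric matrix (n x 3) of coordinates in Angstrom.
#' @param coords_bohr numeric matrix (n x 3) of coordinates in Bohr.
#' @param comment optional comment string (kept for XYZ round trips).
#' @return an object of class `system_geometry` with fields `elements`,
#'   `coords` (Bohr) and `atom_count`.
#' @examples
#' g <- system_geometry(c("O", "H", "H"),
#'                      coords_ang = rbind(c(0, 0, 0),
#'                                         c(0.757, 0.586, 0),
#'                                         c(-0.757, 0.586, 0)))
#' g$atom_count
#' @export
system_geometry <- function(elements, coords_ang = NULL, coords_bohr = NULL,
                            comment = "") {
  if (is.null(coords_bohr)) {
    if (is.null(coords_ang)) abort_argument("supply coords_ang or coords_bohr")
    coords_bohr <- ang_to_bohr(as.matrix(coords_ang))
  }
  coords_bohr <- matrix(as.numeric(coords_bohr), ncol = 3)
  elements <- as.character(elements)
  g <- structure(list(elements = elements, coords = coords_bohr,
                      atom_count = length(elements), comment = comment),
                 class = "system_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  if (length(g$elements) < 1L)
    abort_argument("geometry must contain at least one atom")
  if (nrow(g$coords) != length(g$elements))
    abort_argument("elements and coords must have identical length")
  if (!all(is.finite(g$coords)))
    abort_argument("all coordinates must be finite")
  if (g$atom_count > 1L) {
    d <- stats::dist(g$coords)
    if (min(d) < 0.1)
      abort_argument(sprintf(
        "atoms closer than 0.1 Bohr (minimum distance %.3g Bohr)", min(d)))
  }
  invisible(g)
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf("<system_geometry> %d atoms (%s)\n", x$atom_count,
              paste(utils::head(x$elements, 8), collapse = " ")))
  invisible(x)
}

## Replace coordinates (Bohr), revalidating the structural invariants.
set_coords <- function(geometry, coords_bohr) {
  geometry$coords <- coords_bohr
  validate_geometry(geometry)
  geometry
}

atom_distance_bohr <- function(geometry, i, j) {
  sqrt(sum((geometry$coords[i, ] - geometry$coords[j, ])^2))
}

#' Signed reaction coordinate from a breaking and a forming bond
#'
#' The reaction coordinate is the difference in bond length between the
#' breaking pair and the forming pair, `r(breaking) - r(forming)`, in
#' Angstrom.  For a bond-breaking/bond-forming rearrangement this is negative
#' on the reactant side (breaking bond still short) and positive on the
#' product side.
#'
#' @param geometry a [system_geometry()].
#' @param breaking_pair integer vector of two (1-based) atom indices.
#' @param forming_pair integer vector of two (1-based) atom indices.
#' @return signed coordinate in Angstrom.
#' @export
reaction_coordinate <- function(geometry, breaking_pair, forming_pair) {
  idx <- c(breaking_pair, forming_pair)
  if (length(breaking_pair) != 2L || length(forming_pair) != 2L)
    abort_argument("breaking_pair and forming_pair must each contain two atoms")
  if (anyDuplicated(idx))
    abort_argument("reaction coordinate requires four distinct atom indices")
  if (any(idx < 1L) || any(idx > geometry$atom_count))
    abort_index("atom index out of range")
  bohr_to_ang(atom_distance_bohr(geometry, breaking_pair[1], breaking_pair[2]) -
              atom_distance_bohr(geometry, forming_pair[1], forming_pair[2]))
}

## Minimum interatomic distance (Bohr) between two atom index sets.
min_pair_distance_bohr <- function(geometry, atoms_i, atoms_j) {
  ci <- geometry$coords[atoms_i, , drop = FALSE]
  cj <- geometry$coords[atoms_j, , drop = FALSE]
  d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
  sqrt(max(min(d2), 0))
}
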