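## PDB reading (ATOM/HETATM coordinates only) via bio3d, with residue-based
## fragment-group suggestions.  CONECT records are ignored; for altLoc
## alternates the first conformer is kept and a warning is logged.

#' Read a PDB file as a geometry plus suggested fragment groups
#'
#' Parses `ATOM`/`HETATM` records (coordinates in Angstrom) and groups atoms
#' by `(chain, residue number)` to suggest one fragment per residue, the
#' whole-residue fragmentation convention.  Only coordinates are used; CONECT
#' records are ignored.  When alternate locations are present the first
#' conformer (blank or "A" altLoc) is kept with a warning.
#'
#' @param path path to a PDB file.
#' @return a list with `geometry` (a [system_geometry()]) and `groups`
#'   (a list of 1-based atom-index vectors, one per residue, in file order).
#' @export
read_pdb_geometry <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort_parse(
                    sprintf("PDB parse failure in %s: %s", path,
                            conditionMessage(e))))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(atoms) == 0L) abort_parse("no ATOM/HETATM records found")
  alt <- atoms$alt
  if (any(!is.na(alt) & nzchar(alt))) {
    ## bio3d has already discarded non-"A" alternates (rm.alt)
    warning("alternate locations present; keeping first conformer only",
            call. = FALSE)
  }
  keep <- is.na(alt) | !nzchar(alt) | alt == "A"
  atoms <- atoms[keep, , drop = FALSE]
  elements <- atoms$elesy
  missing_el <- is.na(elements) | !nzchar(trimws(elements))
  if (any(missing_el))  # fall back to first letter of the atom name
    elements[missing_el] <- substr(gsub("[^A-Za-z].*", "",
                                        atoms$elety[missing_el]), 1, 2)
  elements <- trimws(elements)
  g <- system_geometry(elements,
                       coords_ang = cbind(atoms$x, atoms$y, atoms$z),
                       comment = basename(path))
  res_id <- paste(atoms$chain, atoms$resno, sep = "/")
  groups <- split(seq_len(nrow(atoms)), factor(res_id, levels = unique(res_id)))
  names(groups) <- NULL
  list(geometry = g, groups = groups)
}
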