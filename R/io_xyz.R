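## XYZ reader/writer (standard 2-header-line dialect, coordinates in Angstrom).
## Multi-frame concatenation is read back as a list of geometries.

#' Read an XYZ file
#'
#' Standard XYZ dialect: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom.  Multi-frame
#' trajectories (concatenated frames) are supported.
#'
#' @param path path to an XYZ file.
#' @param multi if `TRUE`, always return a list of geometries; by default a
#'   single-frame file returns one [system_geometry()].
#' @return a [system_geometry()] or a list of them.
#' @export
read_xyz <- function(path, multi = FALSE) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1L)
      abort_parse(sprintf("line %d: malformed atom-count line '%s'",
                          ln, lines[ln]))
    if (ln + 1L + n > length(lines))
      abort_parse(sprintf("line %d: expected %d atom lines, file truncated",
                          ln + 2L, n))
    comment <- if (ln + 1L <= length(lines)) lines[ln + 1L] else ""
    el <- character(n); xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      fields <- strsplit(trimws(lines[ln + 1L + k]), "\\s+")[[1]]
      if (length(fields) < 4L)
        abort_parse(sprintf("line %d: expected 'element x y z'", ln + 1L + k))
      coords <- suppressWarnings(as.numeric(fields[2:4]))
      if (any(is.na(coords)))
        abort_parse(sprintf("line %d: non-numeric coordinate", ln + 1L + k))
      if (!grepl("^[A-Za-z]{1,2}$", fields[1]))
        abort_parse(sprintf("line %d: unknown element symbol '%s'",
                            ln + 1L + k, fields[1]))
      el[k] <- fields[1]; xyz[k, ] <- coords
    }
    frames[[length(frames) + 1L]] <-
      system_geometry(el, coords_ang = xyz, comment = comment)
    ln <- ln + 2L + n
  }
  if (length(frames) == 0L) abort_parse("no frames found in XYZ file")
  if (length(frames) == 1L && !multi) frames[[1]] else frames
}

#' Write geometries to an XYZ file
#'
#' @param geometry a [system_geometry()] or a list of them (trajectory).
#' @param path output path.
#' @param comment comment line(s); recycled across frames.
#' @return the path, invisibly.
#' @export
write_xyz <- function(geometry, path, comment = NULL) {
  frames <- if (inherits(geometry, "system_geometry")) list(geometry) else geometry
  comment <- comment %||% vapply(frames, function(g) g$comment %||% "", "")
  comment <- rep_len(comment, length(frames))
  out <- character(0)
  for (i in seq_along(frames)) {
    g <- frames[[i]]
    xyz <- bohr_to_ang(g$coords)
    out <- c(out, as.character(g$atom_count), comment[i],
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     g$elements, xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
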