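## Fragmentation and frozen/polarizable/active domain partitioning.

#' Build a validated fragment set
#'
#' Partitions the atoms of a geometry into fragments.  Fragments must be
#' non-empty, disjoint, and jointly cover every atom.  Only closed-shell
#' fragments are supported (multiplicity fixed to 1).
#'
#' @param geometry a [system_geometry()].
#' @param groups list of integer vectors of 1-based atom indices, one per
#'   fragment.
#' @param charges integer vector of fragment charges (elementary charge);
#'   defaults to all zero.
#' @param basis_label optional per-fragment basis label(s); `NA` means "use the
#'   run configuration's RHF basis".
#' @return a `fragment_set`: a tibble with columns `id`, `charge`,
#'   `multiplicity`, `basis_label` and a list-column `atoms`.
#' @export
build_fragments <- function(geometry, groups, charges = NULL,
                            basis_label = NA_character_) {
  if (length(groups) < 1L) abort_partition("at least one fragment required")
  groups <- lapply(groups, function(g) as.integer(g))
  charges <- as.integer(charges %||% rep(0L, length(groups)))
  if (length(charges) != length(groups))
    abort_partition("one charge per fragment required")
  all_atoms <- unlist(groups)
  if (any(vapply(groups, length, 1L) == 0L))
    abort_partition("empty fragment group")
  if (any(all_atoms < 1L) || any(all_atoms > geometry$atom_count))
    abort_index("fragment atom index out of range")
  if (anyDuplicated(all_atoms)) {
    dup <- unique(all_atoms[duplicated(all_atoms)])
    abort_partition(sprintf("fragment groups overlap (atom %s duplicated)",
                            paste(dup, collapse = ", ")))
  }
  if (length(all_atoms) != geometry$atom_count)
    abort_partition(sprintf(
      "fragment groups leave %d atom(s) unassigned",
      geometry$atom_count - length(all_atoms)))
  fs <- tibble::tibble(id = seq_along(groups),
                       charge = charges,
                       multiplicity = 1L,
                       basis_label = rep_len(basis_label, length(groups)),
                       atoms = lapply(groups, sort))
  class(fs) <- c("fragment_set", class(fs))
  fs
}

frag_atoms <- function(fragments, id) fragments$atoms[[match(id, fragments$id)]]
frag_charge <- function(fragments, id) fragments$charge[match(id, fragments$id)]

## Map each atom to the id of the fragment owning it.
atom_fragment_map <- function(fragments, n_atoms) {
  m <- integer(n_atoms)
  for (k in seq_len(nrow(fragments))) m[fragments$atoms[[k]]] <- fragments$id[k]
  m
}

#' Construct a domain partition
#'
#' Assigns fragments to the frozen domain `F` (geometry and densities fixed
#' after first evaluation), the polarizable buffer `b` (frozen geometry,
#' polarizable densities), and the active domain `A` (atoms optimized).  A
#' single high-level fragment `H`, a member of `A`, is treated at the MP2
#' level in hybrid runs.
#'
#' @param frozen,polarizable,active integer vectors of fragment ids.
#' @param high_level single fragment id, must be in `active`.
#' @param fragments optional `fragment_set` to validate coverage against.
#' @return an object of class `domain_partition`.
#' @export
domain_partition <- function(frozen, polarizable, active, high_level,
                             fragments = NULL) {
  frozen <- as.integer(frozen); polarizable <- as.integer(polarizable)
  active <- as.integer(active); high_level <- as.integer(high_level)
  all_ids <- c(frozen, polarizable, active)
  if (anyDuplicated(all_ids))
    abort_partition("domains F, b, A must be pairwise disjoint")
  if (length(active) == 0L)
    abort_partition("active domain must be non-empty")
  if (length(high_level) != 1L || !(high_level %in% active))
    abort_partition("high_level must be a single fragment inside the active domain")
  if (!is.null(fragments) && !setequal(all_ids, fragments$id))
    abort_partition("domains must cover the full fragment id set")
  structure(list(frozen = sort(frozen), polarizable = sort(polarizable),
                 active = sort(active), high_level = high_level),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf("<domain_partition> A = {%s}  b = {%s}  F = {%s}  H = %d\n",
              paste(x$active, collapse = ","),
              paste(x$polarizable, collapse = ","),
              paste(x$frozen, collapse = ","), x$high_level))
  invisible(x)
}

## Domain label ("A", "b", "F") of a fragment id.
domain_of <- function(partition, id) {
  ifelse(id %in% partition$active, "A",
         ifelse(id %in% partition$polarizable, "b", "F"))
}

#' Distance-based domain assignment around a center fragment
#'
#' Fragments with any atom within `active_radius` (Angstrom) of any atom of
#' the center fragment join the active domain `A`; remaining fragments with
#' any atom within `buffer_radius` of any atom of the active domain join the
#' polarizable buffer `b`; everything else is frozen (`F`).  Distances are
#' minimum interatomic distances over all atoms (not heavy atoms only, not
#' centers of mass).  The center fragment becomes the high-level fragment.
#'
#' @param fragments a `fragment_set`.
#' @param geometry a [system_geometry()].
#' @param center_fragment fragment id anchoring the assignment.
#' @param active_radius,buffer_radius radii in Angstrom,
#'   `buffer_radius >= active_radius >= 0`.
#' @return a [domain_partition()].
#' @export
assign_domains <- function(fragments, geometry, center_fragment,
                           active_radius, buffer_radius) {
  if (!(center_fragment %in% fragments$id))
    abort_config("center_fragment is not a valid fragment id")
  if (active_radius < 0 || buffer_radius < active_radius)
    abort_config("require buffer_radius >= active_radius >= 0")
  ra <- ang_to_bohr(active_radius); rb <- ang_to_bohr(buffer_radius)
  center_atoms <- frag_atoms(fragments, center_fragment)
  dist_to <- function(atom_set) vapply(fragments$id, function(id) {
    min_pair_distance_bohr(geometry, frag_atoms(fragments, id), atom_set)
  }, 1.0)
  d_center <- dist_to(center_atoms)
  active <- fragments$id[d_center <= ra]
  active <- union(active, center_fragment)
  active_atoms <- sort(unlist(lapply(active, frag_atoms, fragments = fragments)))
  d_active <- dist_to(active_atoms)
  rest <- setdiff(fragments$id, active)
  buffer <- rest[d_active[match(rest, fragments$id)] <= rb]
  frozen <- setdiff(rest, buffer)
  domain_partition(frozen, buffer, active, center_fragment, fragments)
}

## ---------------------------------------------------------------------------
## Fragment/domain spec file (YAML).  Schema (all atom indices on disk are
## 0-based, half-open ranges [from, to)):
##
##   fragments:
##     - atoms: [0, 3]      # atoms 0,1,2
##       charge: 0
##       domain: A          # optional explicit override: A, b or F
##     - atoms: [3, 6]
##       charge: 0
##   high_level: 0          # 0-based fragment index, optional
##
## Explicit domain overrides, when present on every fragment, define the
## partition directly; otherwise assign_domains() is used downstream.

#' Read a fragment/domain spec file
#'
#' Structured-text (YAML) schema with 0-based half-open atom ranges per
#' fragment, a charge, and an optional explicit domain override (`A`, `b` or
#' `F`), plus an optional 0-based `high_level` fragment index.  Indices are
#' converted to R's 1-based convention on read.
#'
#' @param path path to the YAML spec.
#' @param geometry the [system_geometry()] the spec refers to.
#' @return list with `fragments` (a `fragment_set`), `partition` (a
#'   [domain_partition()] or `NULL` when no overrides are given) and
#'   `high_level` (1-based id or `NULL`).
#' @export
read_fragment_spec <- function(path, geometry) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  spec <- tryCatch(yaml::read_yaml(path),
                   error = function(e) abort_parse(conditionMessage(e)))
  if (is.null(spec$fragments)) abort_parse("spec lacks a 'fragments' list")
  groups <- list(); charges <- integer(0); domains <- character(0)
  for (fr in spec$fragments) {
    rng <- fr$atoms
    if (is.null(rng) || length(rng) != 2L)
      abort_parse("each fragment needs 'atoms: [from, to)' (0-based, half-open)")
    if (rng[2] <= rng[1]) abort_parse("empty atom range in fragment spec")
    groups[[length(groups) + 1L]] <- seq.int(rng[1] + 1L, rng[2])
    charges <- c(charges, as.integer(fr$charge %||% 0L))
    domains <- c(domains, as.character(fr$domain %||% NA_character_))
  }
  fragments <- build_fragments(geometry, groups, charges)
  high_level <- if (!is.null(spec$high_level)) as.integer(spec$high_level) + 1L
  partition <- NULL
  if (all(!is.na(domains))) {
    if (!all(domains %in% c("A", "b", "F")))
      abort_parse("domain overrides must be one of A, b, F")
    hl <- high_level %||% fragments$id[domains == "A"][1]
    partition <- domain_partition(fragments$id[domains == "F"],
                                  fragments$id[domains == "b"],
                                  fragments$id[domains == "A"],
                                  hl, fragments)
  }
  list(fragments = fragments, partition = partition, high_level = high_level)
}

#' Write a fragment/domain spec file
#'
#' Inverse of [read_fragment_spec()]; emits 0-based half-open ranges.  Only
#' fragment sets whose atom indices are contiguous runs can be written.
#'
#' @param fragments a `fragment_set`.
#' @param path output path.
#' @param partition optional [domain_partition()] to record as overrides.
#' @return the path, invisibly.
#' @export
write_fragment_spec <- function(fragments, path, partition = NULL) {
  frs <- lapply(seq_len(nrow(fragments)), function(k) {
    a <- fragments$atoms[[k]]
    if (!all(diff(a) == 1L))
      abort_argument("fragment atom indices must be contiguous to write a range spec")
    fr <- list(atoms = c(a[1] - 1L, a[length(a)]),
               charge = fragments$charge[k])
    if (!is.null(partition)) fr$domain <- domain_of(partition, fragments$id[k])
    fr
  })
  out <- list(fragments = frs)
  if (!is.null(partition)) out$high_level <- partition$high_level - 1L
  yaml::write_yaml(out, path)
  invisible(path)
}
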