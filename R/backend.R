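## Electronic-structure backend contract and the deterministic mock engine.
##
## A backend evaluates a subsystem made of one or more fragment "groups" and
## returns the energy, the MP2 correlation energy (0 at RHF), analytic
## gradients of both, atom-centered partial charges and isotropic atom-
## centered polarizabilities.  Monomers are single-group calls, dimers
## two-group calls, and a whole-system call (all groups) serves as the
## supersystem oracle in tests.  The registry lets a real SCF/MP2 engine be
## plugged in by string key; the shipped "mock" backend is a documented
## closed-form potential so every framework path is testable without one.

.backend_registry <- new.env(parent = emptyenv())

#' Register an electronic-structure backend factory
#'
#' @param name registry key (e.g. `"mock"`).
#' @param factory a function returning a backend object; backend objects must
#'   have a class with a [backend_evaluate()] method.
#' @return `name`, invisibly.
#' @export
register_backend <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = .backend_registry)
  invisible(name)
}

#' Look up a backend by registry key
#'
#' @param name registry key or an already-constructed backend object.
#' @param ... passed to the registered factory.
#' @return a backend object.
#' @export
get_backend <- function(name = "mock", ...) {
  if (inherits(name, "fragopt_backend")) return(name)
  if (!exists(name, envir = .backend_registry))
    abort_backend(sprintf("no backend registered under '%s' (available: %s)",
                          name,
                          paste(ls(.backend_registry), collapse = ", ")))
  get(name, envir = .backend_registry)(...)
}

#' List registered backend names
#' @return character vector of registry keys.
#' @export
list_backends <- function() ls(.backend_registry)

#' Evaluate a subsystem with a backend
#'
#' Generic entry point of the backend contract.
#'
#' @param backend a backend object from [get_backend()].
#' @param elements element symbols of the subsystem atoms.
#' @param coords subsystem coordinates, Bohr (n x 3).
#' @param groups list of index vectors (into the subsystem) defining the
#'   fragment substructure; intra-group terms are "bonded"/correlated, cross-
#'   group terms are the two-body interaction.
#' @param group_ids fragment ids of the groups (for per-fragment overrides).
#' @param group_charges integer fragment charges, one per group.
#' @param level `"RHF"` or `"MP2"`.
#' @param basis_labels basis label per group.
#' @return list with `energy` (Hartree), `correlation_energy` (Hartree, `<= 0`,
#'   0 at RHF), `gradient` and `correlation_gradient` (n x 3, Hartree/Bohr),
#'   `charges` (e) and `polarizabilities` (Bohr^3) per atom.
#' @export
backend_evaluate <- function(backend, elements, coords, groups, group_ids,
                             group_charges, level, basis_labels) {
  UseMethod("backend_evaluate")
}

#' Construct the deterministic mock backend
#'
#' Closed-form potential standing in for an SCF/MP2 engine:
#' \itemize{
#'   \item intra-group: a harmonic term `k/2 (r - r0)^2` on every atom pair,
#'     with reference lengths and force constants from a documented
#'     per-element-pair table (water at its reference geometry is an exact
#'     minimum);
#'   \item cross-group: Lennard-Jones (Lorentz-Berthelot combination of
#'     per-element parameters) plus Coulomb over fixed per-element charges
#'     (shifted uniformly per fragment to reproduce the declared fragment
#'     charge);
#'   \item mock "MP2 correlation": an intra-group dispersion-like sum
#'     `-C6/(r^6 + d^6)` (short-range damped so the surface stays bounded)
#'     scaled by a per-basis factor, so the correlation energy is strictly
#'     negative, smooth, and basis-dependent.
#' }
#' All terms have analytic gradients.  `intra_overrides` replaces the
#' intra-group potential (both levels) of specific fragments; this is how the
#' toy-reaction fixture installs its double-well substrate.
#'
#' @param intra_overrides named list keyed by fragment id (as character); each
#'   element is a function `(elements, coords_bohr) -> list(energy, gradient)`
#'   defining that fragment's intra potential (its correlation part is zero).
#' @return a backend object of class `c("mock_backend", "fragopt_backend")`.
#' @export
mock_backend <- function(intra_overrides = list()) {
  structure(list(name = "mock", version = "1",
                 intra_overrides = intra_overrides),
            class = c("mock_backend", "fragopt_backend"))
}

## Pairwise helper: accumulate energy and gradient of a radial potential
## v(r) with derivative dv(r), over the pair list (i, j).
.accumulate_radial <- function(coords, pairs_i, pairs_j, vfun) {
  n <- nrow(coords)
  grad <- matrix(0, n, 3)
  energy <- 0
  for (k in seq_along(pairs_i)) {
    i <- pairs_i[k]; j <- pairs_j[k]
    d <- coords[i, ] - coords[j, ]
    r <- sqrt(sum(d * d))
    vd <- vfun(k, r)
    energy <- energy + vd[1]
    g <- (vd[2] / r) * d
    grad[i, ] <- grad[i, ] + g
    grad[j, ] <- grad[j, ] - g
  }
  list(energy = energy, grad = grad)
}

## Per-atom mock charges for one group: element charge + uniform shift so the
## sum equals the declared fragment charge.
mock_group_charges <- function(elements, charge) {
  q <- mock_param(elements, "q")
  q + (charge - sum(q)) / length(q)
}

#' @export
backend_evaluate.mock_backend <- function(backend, elements, coords, groups,
                                          group_ids, group_charges, level,
                                          basis_labels) {
  n <- nrow(coords)
  if (length(elements) != n) abort_backend("elements/coords length mismatch")
  if (!level %in% c("RHF", "MP2"))
    abort_backend(sprintf("unsupported level '%s'", level))
  basis_labels <- rep_len(basis_labels, length(groups))
  energy <- 0; corr <- 0
  grad <- matrix(0, n, 3); cgrad <- matrix(0, n, 3)
  charges <- numeric(n)
  group_of <- integer(n)
  for (gi in seq_along(groups)) group_of[groups[[gi]]] <- gi

  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    charges[idx] <- mock_group_charges(elements[idx], group_charges[gi])
    override <- backend$intra_overrides[[as.character(group_ids[gi])]]
    if (!is.null(override)) {
      res <- override(elements[idx], coords[idx, , drop = FALSE])
      energy <- energy + res$energy
      grad[idx, ] <- grad[idx, ] + res$gradient
      next  # override defines the full intra potential; its correlation is 0
    }
    if (length(idx) >= 2L) {
      prs <- utils::combn(idx, 2)
      e1 <- elements[prs[1, ]]; e2 <- elements[prs[2, ]]
      r0 <- mock_bond_r0_bohr(e1, e2); kk <- mock_bond_k(e1, e2)
      res <- .accumulate_radial(coords, prs[1, ], prs[2, ], function(k, r) {
        c(0.5 * kk[k] * (r - r0[k])^2, kk[k] * (r - r0[k]))
      })
      energy <- energy + res$energy; grad <- grad + res$grad
      if (level == "MP2") {
        scale <- mock_basis_scale(basis_labels[gi])
        c6 <- scale * sqrt(mock_param(e1, "c6") * mock_param(e2, "c6"))
        ## short-range-damped dispersion keeps the surface bounded below
        d6 <- .mock_corr_damp^6
        resc <- .accumulate_radial(coords, prs[1, ], prs[2, ], function(k, r) {
          c(-c6[k] / (r^6 + d6), 6 * c6[k] * r^5 / (r^6 + d6)^2)
        })
        corr <- corr + resc$energy; cgrad <- cgrad + resc$grad
      }
    }
  }

  if (length(groups) >= 2L) {  # cross-group Lennard-Jones + Coulomb
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (group_of[i] == group_of[j]) next
      d <- coords[i, ] - coords[j, ]
      r <- sqrt(sum(d * d))
      if (r < 1e-6) abort_backend("coincident inter-fragment atoms")
      sig <- 0.5 * (mock_param(elements[i], "sigma") +
                    mock_param(elements[j], "sigma"))
      eps <- sqrt(mock_param(elements[i], "eps") *
                  mock_param(elements[j], "eps"))
      sr6 <- (sig / r)^6
      qq <- charges[i] * charges[j]
      energy <- energy + 4 * eps * (sr6^2 - sr6) + qq / r
      dv <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r - qq / r^2
      g <- (dv / r) * d
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
  }

  list(energy = energy, correlation_energy = corr,
       gradient = grad, correlation_gradient = cgrad,
       charges = charges,
       polarizabilities = mock_param(elements, "alpha"))
}

register_backend("mock", mock_backend)

#' Closed-form mock energy of an atom subset
#'
#' Convenience wrapper for tests and oracles: evaluates the mock potential on
#' the given atoms of a geometry, treating `groups` as the fragment
#' substructure (one group containing every atom by default).
#'
#' @param geometry a [system_geometry()].
#' @param fragment_atoms atom indices of the subsystem.
#' @param groups optional list of index vectors into `fragment_atoms`.
#' @param level `"RHF"` or `"MP2"`.
#' @param basis_label basis label(s) for the correlation scaling.
#' @param charges fragment charge per group (default 0).
#' @param backend a mock backend instance (for overrides).
#' @return Hartree energy with attributes `gradient` and
#'   `correlation_energy`.
#' @export
mock_backend_energy <- function(geometry, fragment_atoms = NULL, groups = NULL,
                                level = "RHF", basis_label = "6-31G(d)",
                                charges = NULL, backend = mock_backend()) {
  fragment_atoms <- fragment_atoms %||% seq_len(geometry$atom_count)
  groups <- groups %||% list(seq_along(fragment_atoms))
  charges <- charges %||% rep(0L, length(groups))
  res <- backend_evaluate(backend, geometry$elements[fragment_atoms],
                          geometry$coords[fragment_atoms, , drop = FALSE],
                          groups, group_ids = seq_along(groups),
                          group_charges = charges, level = level,
                          basis_labels = basis_label)
  structure(res$energy + res$correlation_energy,
            gradient = res$gradient + res$correlation_gradient,
            correlation_energy = res$correlation_energy)
}
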