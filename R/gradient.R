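## Analytic EFMO/FDD gradient assembly on active-domain atoms, the hybrid
## MP2 term on fragment H, and the central-difference validation oracle.
## Atoms outside the active domain are zero-masked: only active-domain
## geometry is ever optimized, and charges/densities of the buffer and frozen
## domains are constants of the run, so the assembled gradient is exact for
## the implemented energy.

assemble_gradient <- function(geometry, fragments, partition, config,
                              records, pairs, dimers, pair_pol, pol_tot,
                              rec_h = NULL) {
  n <- geometry$atom_count
  active_atoms <- sort(unlist(lapply(partition$active, frag_atoms,
                                     fragments = fragments)))
  terms <- list(monomer = matrix(0, n, 3), qm_dimer = matrix(0, n, 3),
                pair_pol = matrix(0, n, 3), far_pair = matrix(0, n, 3),
                polarization = matrix(0, n, 3), mp2 = matrix(0, n, 3))

  for (id in partition$active) {
    rec <- records[[as.character(id)]]
    terms$monomer[rec$atoms, ] <- terms$monomer[rec$atoms, ] + rec$gradient
  }

  if (nrow(pairs) > 0L) for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    touches_active <- pairs$domain_i[k] == "A" || pairs$domain_j[k] == "A"
    if (!touches_active) next  # gradient lives wholly on frozen atoms
    if (pairs$qm[k]) {
      drec <- dimers[[paste(i, j, sep = "-")]]
      terms$qm_dimer[drec$atoms_i, ] <-
        terms$qm_dimer[drec$atoms_i, ] + drec$gradient_i
      terms$qm_dimer[drec$atoms_j, ] <-
        terms$qm_dimer[drec$atoms_j, ] + drec$gradient_j
      ep <- pair_pol[[paste(i, j, sep = "-")]]
      if (!is.null(ep)) {
        st <- attr(ep, "state"); sites <- attr(ep, "sites")
        aa <- intersect(active_atoms, c(drec$atoms_i, drec$atoms_j))
        if (length(aa) > 0L) {
          gp <- pol_gradient_atoms(st, sites, aa, config$pol_damping)
          terms$pair_pol[aa, ] <- terms$pair_pol[aa, ] - gp
        }
      }
    } else {
      aa <- intersect(active_atoms,
                      c(frag_atoms(fragments, i), frag_atoms(fragments, j)))
      if (length(aa) > 0L)
        terms$far_pair[aa, ] <- terms$far_pair[aa, ] +
          far_pair_gradient(geometry, fragments, records, i, j, aa)
    }
  }

  if (!is.null(pol_tot) && !is.null(attr(pol_tot, "state"))) {
    gt <- pol_gradient_atoms(attr(pol_tot, "state"), attr(pol_tot, "sites"),
                             active_atoms, config$pol_damping)
    terms$polarization[active_atoms, ] <- terms$polarization[active_atoms, ] + gt
  }

  mp2_term <- matrix(0, n, 3)
  if (!is.null(rec_h)) {
    mp2_term[rec_h$atoms, ] <- rec_h$correlation_gradient
    terms$mp2 <- mp2_term
  }

  grad <- Reduce(`+`, terms)
  mask <- setdiff(seq_len(n), active_atoms)
  grad[mask, ] <- 0           # frozen/buffer atoms carry exactly zero
  for (nm in names(terms)) terms[[nm]][mask, ] <- 0

  structure(list(gradient = grad, terms = terms,
                 active_atoms = active_atoms,
                 mp2_term = terms$mp2,
                 max_component = max(abs(grad))),
            class = "gradient_report")
}

#' EFMO/FDD analytic gradient on active-domain atoms
#'
#' Assembles the gradient of [efmo_total_energy()] with respect to the
#' Cartesian coordinates of active-domain atoms: monomer gradients of active
#' fragments, dimer interaction gradients of pairs touching the active
#' domain, classical far-pair and polarization gradients, with every
#' non-active atom zero-masked.  No frozen-domain record is recomputed.
#'
#' @inheritParams efmo_total_energy
#' @return a `gradient_report`: list with `gradient` (n x 3, Hartree/Bohr),
#'   per-term matrices in `terms`, `active_atoms`, `mp2_term` and
#'   `max_component`.
#' @export
efmo_gradient <- function(geometry, fragments, partition, config,
                          cache = NULL, backend = NULL) {
  efmo_assemble(geometry, fragments, partition, config, cache, backend,
                want_gradient = TRUE, hybrid = FALSE)$gradient
}

#' Hybrid EFMO-RHF:MP2 analytic gradient
#'
#' [efmo_gradient()] plus the MP2 correlation gradient of the high-level
#' fragment `H` on `H`'s atoms only; all other contributions are identical to
#' the RHF gradient.
#'
#' @inheritParams efmo_total_energy
#' @return a `gradient_report` (see [efmo_gradient()]).
#' @export
hybrid_gradient <- function(geometry, fragments, partition, config,
                            cache = NULL, backend = NULL) {
  efmo_assemble(geometry, fragments, partition, config, cache, backend,
                want_gradient = TRUE, hybrid = TRUE)$gradient
}

#' Central-difference numerical gradient
#'
#' Validation oracle: `(E(x+h) - E(x-h)) / 2h` per Cartesian component,
#' evaluated only for the requested atoms.
#'
#' @param energy_fn function taking a [system_geometry()] and returning a
#'   scalar energy in Hartree.
#' @param geometry a [system_geometry()].
#' @param atoms atom indices to differentiate (default: all).
#' @param step finite-difference step in Bohr (default 1e-4).
#' @return a `length(atoms)` x 3 matrix in Hartree/Bohr.
#' @export
numerical_gradient <- function(energy_fn, geometry,
                               atoms = seq_len(geometry$atom_count),
                               step = 1e-4) {
  if (step <= 0) abort_argument("finite-difference step must be > 0")
  g <- matrix(0, length(atoms), 3)
  for (p in seq_along(atoms)) for (k in 1:3) {
    gp <- geometry; gm <- geometry
    gp$coords[atoms[p], k] <- gp$coords[atoms[p], k] + step
    gm$coords[atoms[p], k] <- gm$coords[atoms[p], k] - step
    g[p, k] <- (energy_fn(gp) - energy_fn(gm)) / (2 * step)
  }
  g
}

#' @export
print.gradient_report <- function(x, ...) {
  cat(sprintf("<gradient_report> %d active atoms, max |component| %.3e Hartree/Bohr\n",
              length(x$active_atoms), x$max_component))
  invisible(x)
}
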