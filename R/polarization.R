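## Classical many-body polarization: self-consistent induced dipoles over
## atom-centered isotropic polarizabilities.  EFMO-lineage conventions: a site
## feels static fields and dipole coupling only from *other* fragments
## (intra-fragment response is already inside the QM monomer energies), and
## the induction energy is E_pol = -1/2 sum_i mu_i . F_i^static.

#' Build the polarizable-site table for a set of fragments
#'
#' One site per atom, carrying the backend-supplied partial charge and
#' isotropic polarizability of that atom plus its owning fragment id.
#'
#' @param geometry a [system_geometry()].
#' @param fragments a `fragment_set`.
#' @param records named list of `fragment_record`s keyed by fragment id
#'   (as character).
#' @param span_ids fragment ids included in the polarization treatment.
#' @return an object of class `pol_sites`: list with `coords` (Bohr), `q`,
#'   `alpha`, `frag` and `atom` (global atom index).
#' @export
pol_sites <- function(geometry, fragments, records,
                      span_ids = fragments$id) {
  atom <- integer(0); frag <- integer(0); q <- numeric(0); alpha <- numeric(0)
  for (id in sort(span_ids)) {
    rec <- records[[as.character(id)]]
    a <- frag_atoms(fragments, id)
    atom <- c(atom, a)
    frag <- c(frag, rep(id, length(a)))
    q <- c(q, rec$charges)
    alpha <- c(alpha, rec$polarizabilities)
  }
  structure(list(coords = geometry$coords[atom, , drop = FALSE],
                 q = q, alpha = alpha, frag = frag, atom = atom),
            class = "pol_sites")
}

#' Static electric field at polarizable sites
#'
#' Coulomb field at every site from the point charges of all *other*
#' fragments (intra-fragment sources are excluded by convention).
#'
#' @param sites a [pol_sites()] object.
#' @return an n x 3 matrix of field vectors in atomic units.
#' @export
static_field <- function(sites) {
  n <- nrow(sites$coords)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (sites$frag[j] == sites$frag[i] || sites$q[j] == 0) next
      d <- sites$coords[i, ] - sites$coords[j, ]
      r2 <- sum(d * d)
      if (r2 < 1e-12)
        abort_singularity("coincident inter-fragment sites in field evaluation")
      f[i, ] <- f[i, ] + sites$q[j] * d / (r2 * sqrt(r2))
    }
  }
  f
}

## Field at site i from unit dipoles: sum_j T_ij mu_j restricted to
## inter-fragment pairs.  T_ij = (3 d d^T - r^2 I) / r^5.
dipole_field <- function(sites, mu, damping = NULL) {
  n <- nrow(sites$coords)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i || sites$frag[j] == sites$frag[i]) next
      if (all(mu[j, ] == 0)) next
      d <- sites$coords[i, ] - sites$coords[j, ]
      r2 <- sum(d * d); r <- sqrt(r2)
      l3 <- 1; l5 <- 1
      if (!is.null(damping)) {  # Thole-style exponential damping
        u <- r / (sites$alpha[i] * sites$alpha[j])^(1 / 6)
        au3 <- damping * u^3
        l3 <- 1 - exp(-au3)
        l5 <- 1 - (1 + au3) * exp(-au3)
      }
      f[i, ] <- f[i, ] +
        (3 * l5 * sum(d * mu[j, ]) * d / r2 - l3 * mu[j, ]) / (r2 * r)
    }
  }
  f
}

#' Solve for self-consistent induced dipoles
#'
#' Fixed point of `mu_i = alpha_i (F_i^static + sum_j T_ij mu_j)` with the
#' dipole-field tensor `T` restricted to inter-fragment pairs, solved by
#' Jacobi iteration (default) or by a dense linear solve (the oracle used in
#' tests).  The induction energy is `E_pol = -1/2 sum_i mu_i . F_i^static`.
#'
#' @param sites a [pol_sites()] object.
#' @param field optional precomputed static field; defaults to
#'   [static_field()] of `sites`.
#' @param tolerance Jacobi convergence threshold on the maximum dipole change
#'   (a.u.).
#' @param max_iter maximum Jacobi iterations; non-convergence raises a
#'   polarization error reporting the last residual.
#' @param method `"jacobi"` or `"dense"`.
#' @param damping optional Thole-style exponential damping parameter.
#' @return a `pol_state`: list with `induced_dipoles`, `static_field`,
#'   `converged`, `iterations` and `energy` (Hartree).
#' @export
solve_induced_dipoles <- function(sites, field = NULL, tolerance = 1e-10,
                                  max_iter = 200L,
                                  method = c("jacobi", "dense"),
                                  damping = NULL) {
  method <- match.arg(method)
  if (tolerance <= 0) abort_argument("tolerance must be > 0")
  field <- field %||% static_field(sites)
  n <- nrow(sites$coords)
  mu <- matrix(0, n, 3)
  pol <- which(sites$alpha > 0)
  iterations <- 0L
  converged <- TRUE
  if (length(pol) > 0L && any(field[pol, ] != 0)) {
    if (method == "dense") {
      m <- length(pol)
      B <- diag(rep(1 / sites$alpha[pol], each = 3))
      for (a in seq_len(m)) for (b in seq_len(m)) {
        if (a == b) next
        ia <- pol[a]; jb <- pol[b]
        if (sites$frag[ia] == sites$frag[jb]) next
        d <- sites$coords[ia, ] - sites$coords[jb, ]
        r2 <- sum(d * d); r <- sqrt(r2)
        l3 <- 1; l5 <- 1
        if (!is.null(damping)) {
          u <- r / (sites$alpha[ia] * sites$alpha[jb])^(1 / 6)
          au3 <- damping * u^3
          l3 <- 1 - exp(-au3)
          l5 <- 1 - (1 + au3) * exp(-au3)
        }
        Tij <- (3 * l5 * tcrossprod(d) / r2 - l3 * diag(3)) / (r2 * r)
        B[(a - 1) * 3 + 1:3, (b - 1) * 3 + 1:3] <- -Tij
      }
      sol <- solve(B, as.numeric(t(field[pol, , drop = FALSE])))
      mu[pol, ] <- matrix(sol, ncol = 3, byrow = TRUE)
      iterations <- 1L
    } else {
      repeat {
        f_tot <- field + dipole_field(sites, mu, damping)
        mu_new <- sites$alpha * f_tot
        mu_new[sites$alpha == 0, ] <- 0
        delta <- max(abs(mu_new - mu))
        mu <- mu_new
        iterations <- iterations + 1L
        if (delta < tolerance) break
        if (iterations >= max_iter)
          abort_polarization(sprintf(
            "induced dipoles not converged in %d iterations (residual %.3g)",
            max_iter, delta))
      }
    }
  }
  structure(list(induced_dipoles = mu, static_field = field,
                 converged = converged, iterations = iterations,
                 energy = -0.5 * sum(mu * field)),
            class = "pol_state")
}

#' Total classical polarization energy of a system
#'
#' Self-consistent induction energy over the sites of all fragments in the
#' polarization span (all of F, b and A by default; `config$pol_domain =
#' "active_buffer"` restricts to b and A).  Zero for a single fragment or
#' when every static field vanishes.
#'
#' @param geometry a [system_geometry()].
#' @param fragments a `fragment_set`.
#' @param records named list of monomer `fragment_record`s.
#' @param config a [run_config()].
#' @param partition optional [domain_partition()] (required for the
#'   `"active_buffer"` span).
#' @return energy in Hartree, with the full `pol_state` attached as attribute
#'   `"state"`.
#' @export
pol_energy_total <- function(geometry, fragments, records, config,
                             partition = NULL) {
  span <- fragments$id
  if (identical(config$pol_domain, "active_buffer")) {
    if (is.null(partition))
      abort_config("pol_domain 'active_buffer' requires a domain partition")
    span <- sort(c(partition$polarizable, partition$active))
  }
  if (length(span) < 2L) return(structure(0, state = NULL))
  sites <- pol_sites(geometry, fragments, records, span)
  st <- solve_induced_dipoles(sites, tolerance = config$pol_tolerance,
                              max_iter = config$pol_max_iter,
                              damping = config$pol_damping)
  structure(st$energy, state = st, sites = sites)
}

#' Two-body classical polarization energy of a fragment pair
#'
#' The induction energy of the isolated pair `{I, J}`: this is the term
#' subtracted from each quantum-mechanical dimer interaction to avoid double
#' counting polarization that the total classical term already includes.
#'
#' @inheritParams pol_energy_total
#' @param i,j distinct fragment ids.
#' @return energy in Hartree with attributes `"state"` and `"sites"`.
#' @export
pol_energy_pair <- function(geometry, fragments, records, i, j, config) {
  if (i == j) abort_argument("pair polarization requires two distinct fragments")
  sites <- pol_sites(geometry, fragments, records, c(i, j))
  st <- solve_induced_dipoles(sites, tolerance = config$pol_tolerance,
                              max_iter = config$pol_max_iter,
                              damping = config$pol_damping)
  structure(st$energy, state = st, sites = sites)
}

#' Classical electrostatic interaction of a far fragment pair
#'
#' Coulomb interaction of the two fragments' atom-centered point charges;
#' used for pairs beyond the quantum-mechanical dimer cutoff.
#'
#' @inheritParams pol_energy_pair
#' @return energy in Hartree.
#' @export
far_pair_electrostatics <- function(geometry, fragments, records, i, j) {
  ai <- frag_atoms(fragments, i); aj <- frag_atoms(fragments, j)
  qi <- records[[as.character(i)]]$charges
  qj <- records[[as.character(j)]]$charges
  e <- 0
  for (a in seq_along(ai)) for (b in seq_along(aj)) {
    if (qi[a] == 0 || qj[b] == 0) next
    d <- geometry$coords[ai[a], ] - geometry$coords[aj[b], ]
    r <- sqrt(sum(d * d))
    if (r < 1e-6) abort_singularity("coincident atoms in far-pair electrostatics")
    e <- e + qi[a] * qj[b] / r
  }
  e
}

## Gradient of the Coulomb far-pair term on the requested global atoms.
far_pair_gradient <- function(geometry, fragments, records, i, j, atoms) {
  ai <- frag_atoms(fragments, i); aj <- frag_atoms(fragments, j)
  qi <- records[[as.character(i)]]$charges
  qj <- records[[as.character(j)]]$charges
  g <- matrix(0, length(atoms), 3)
  for (a in seq_along(ai)) for (b in seq_along(aj)) {
    qq <- qi[a] * qj[b]
    if (qq == 0) next
    d <- geometry$coords[ai[a], ] - geometry$coords[aj[b], ]
    r <- sqrt(sum(d * d))
    gv <- -qq * d / r^3
    pa <- match(ai[a], atoms); pb <- match(aj[b], atoms)
    if (!is.na(pa)) g[pa, ] <- g[pa, ] + gv
    if (!is.na(pb)) g[pb, ] <- g[pb, ] - gv
  }
  g
}

## Analytic gradient of the converged induction energy with respect to the
## positions of the requested (global) atoms.  Uses the stationarity of the
## converged dipoles: dE = -mu^T dF - 1/2 mu^T dT mu.  Undamped tensors only.
pol_gradient_atoms <- function(state, sites, atoms, damping = NULL) {
  if (!is.null(damping))
    abort_config("analytic polarization gradients require pol_damping = NULL")
  g <- matrix(0, length(atoms), 3)
  if (is.null(state)) return(g)
  mu <- state$induced_dipoles
  n <- nrow(sites$coords)
  has_mu <- rowSums(mu != 0) > 0
  for (p in seq_along(atoms)) {
    a <- match(atoms[p], sites$atom)
    if (is.na(a)) next
    ga <- c(0, 0, 0)
    for (m in seq_len(n)) {
      if (m == a || sites$frag[m] == sites$frag[a]) next
      d <- sites$coords[a, ] - sites$coords[m, ]
      r2 <- sum(d * d); r <- sqrt(r2); r3 <- r2 * r; r5 <- r3 * r2
      ## a as polarizable site, m as charge source: -mu_a . dF_a/dr_a
      if (has_mu[a] && sites$q[m] != 0) {
        ga <- ga - sites$q[m] *
          (mu[a, ] / r3 - 3 * sum(mu[a, ] * d) * d / r5)
      }
      ## a as charge source for site m: -mu_m . dF_m/dr_a
      if (has_mu[m] && sites$q[a] != 0) {
        ## field at m from a depends on r_m - r_a; sign flip of the Jacobian
        ga <- ga + sites$q[a] *
          (mu[m, ] / r3 - 3 * sum(mu[m, ] * d) * d / r5)
      }
      ## dipole-dipole tensor term for the unordered pair {a, m}
      if (has_mu[a] && has_mu[m]) {
        mad <- sum(mu[a, ] * d); mmd <- sum(mu[m, ] * d)
        mam <- sum(mu[a, ] * mu[m, ])
        g3 <- (3 * mmd * mu[a, ] + 3 * mad * mu[m, ] + 3 * mam * d) / r5 -
          15 * mad * mmd * d / (r5 * r2)
        ga <- ga - g3
      }
    }
    g[p, ] <- ga
  }
  g
}
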