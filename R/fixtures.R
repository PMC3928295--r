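## Deterministic synthetic systems: water chains/clusters and a toy
## bond-breaking/bond-forming reaction with a closed-form double-well
## substrate.  A single seeded RNG is used locally (global random state is
## saved and restored), so identical specs give bitwise-identical geometries.

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Reference internal water geometry (Angstrom): r(OH) = 0.9572, H-O-H
## 104.52 deg, derived from the same constants as the mock reference bond
## lengths so it is an exact minimum of the mock intra-fragment potential.
.water_ref_ang <- rbind(
  O = c(0, 0, 0),
  H = c(.water_r_oh_ang * sin(.water_theta_deg * pi / 360),
        .water_r_oh_ang * cos(.water_theta_deg * pi / 360), 0),
  H = c(-.water_r_oh_ang * sin(.water_theta_deg * pi / 360),
        .water_r_oh_ang * cos(.water_theta_deg * pi / 360), 0))

#' Rigid water chain fixture
#'
#' `n` waters at the reference internal geometry, oxygen atoms on the x axis
#' at the given spacing, optionally perturbed atom-wise by seeded uniform
#' noise.  One fragment per molecule.
#'
#' @param n number of waters (>= 1).
#' @param spacing O-O distance in Angstrom (> 0), default 3.0.
#' @param seed RNG seed for the perturbation.
#' @param perturbation uniform perturbation amplitude per coordinate,
#'   Angstrom (default 0: rigid chain).
#' @return list with `geometry` (a [system_geometry()]) and `fragments`
#'   (a `fragment_set`).
#' @export
make_water_chain <- function(n, spacing = 3.0, seed = 1L, perturbation = 0) {
  if (n < 1L) abort_argument("n must be >= 1")
  if (spacing <= 0) abort_argument("spacing must be > 0")
  coords <- do.call(rbind, lapply(seq_len(n) - 1L, function(k) {
    sweep(.water_ref_ang, 2, c(k * spacing, 0, 0), `+`)
  }))
  if (perturbation > 0) {
    noise <- with_local_seed(seed, matrix(
      stats::runif(3L * 3L * n, -perturbation, perturbation), ncol = 3))
    coords <- coords + noise
  }
  elements <- rep(c("O", "H", "H"), n)
  geometry <- system_geometry(elements, coords_ang = coords,
                              comment = sprintf("water chain n=%d", n))
  fragments <- build_fragments(geometry,
                               split(seq_len(3L * n), rep(seq_len(n), each = 3)))
  list(geometry = geometry, fragments = fragments)
}

#' Random water cluster fixture
#'
#' `n` rigid waters at seeded random positions and orientations on a jittered
#' cubic grid, guaranteeing a minimum O-O separation.
#'
#' @param n number of waters (>= 1).
#' @param spacing grid spacing in Angstrom (also the O-O separation scale).
#' @param seed RNG seed.
#' @return list with `geometry` and `fragments` as in [make_water_chain()].
#' @export
make_water_cluster <- function(n, spacing = 3.2, seed = 1L) {
  if (n < 1L) abort_argument("n must be >= 1")
  side <- ceiling(n^(1 / 3))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  coords <- with_local_seed(seed, {
    out <- NULL
    for (k in seq_len(n)) {
      ## random rotation via QR of a normal matrix
      qr_ <- qr(matrix(stats::rnorm(9), 3))
      R <- qr.Q(qr_)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      center <- as.numeric(grid[k, ]) * spacing +
        stats::runif(3, -0.25, 0.25)
      out <- rbind(out, sweep(.water_ref_ang %*% t(R), 2, center, `+`))
    }
    out
  })
  geometry <- system_geometry(rep(c("O", "H", "H"), n), coords_ang = coords,
                              comment = sprintf("water cluster n=%d", n))
  fragments <- build_fragments(geometry,
                               split(seq_len(3L * n), rep(seq_len(n), each = 3)))
  list(geometry = geometry, fragments = fragments)
}

## Toy substrate potential parameters (kcal/mol, Angstrom).  The substrate is
## a 4-atom O-C...C-C chain whose intra potential is a double well in
## R = r1 - r2 (breaking O-C1 minus forming C3-C4):
##   V = a (R^2 - R0^2)^2 + c R + ks/2 (r1 + r2 - s)^2 + kl/2 (rL - L0)^2
## Minimizing over the symmetric stretch and the linker leaves the 1-D
## profile V1(R) = a (R^2 - R0^2)^2 + c R: barrier ~ a R0^4, reaction energy
## ~ 2 c R0 < 0.  The convex variant replaces the double well by kq/2 R^2.
.toy_params <- list(a = 10, R0 = 1.2, c = -2, ks = 600, s = 4.0,
                    kl = 600, L0 = 1.5, kq = 30)

toy_profile_1d <- function(R, kind = "double_well", p = .toy_params) {
  if (kind == "convex") 0.5 * p$kq * R^2
  else p$a * (R^2 - p$R0^2)^2 + p$c * R
}

## Intra-fragment override for the mock backend: energy in Hartree, gradient
## in Hartree/Bohr, coordinates in Bohr, atoms ordered (O, C1, C3, C4).
toy_substrate_potential <- function(kind = "double_well", p = .toy_params) {
  function(elements, coords) {
    r_pairs <- list(r1 = c(1L, 2L), rL = c(2L, 3L), r2 = c(3L, 4L))
    d <- lapply(r_pairs, function(ij) coords[ij[1], ] - coords[ij[2], ])
    r_bohr <- vapply(d, function(v) sqrt(sum(v * v)), 1.0)
    r <- bohr_to_ang(r_bohr)
    R <- r[["r1"]] - r[["r2"]]; S <- r[["r1"]] + r[["r2"]]
    if (kind == "convex") {
      v <- 0.5 * p$kq * R^2
      dVdR <- p$kq * R
    } else {
      v <- p$a * (R^2 - p$R0^2)^2 + p$c * R
      dVdR <- 4 * p$a * R * (R^2 - p$R0^2) + p$c
    }
    v <- v + 0.5 * p$ks * (S - p$s)^2 + 0.5 * p$kl * (r[["rL"]] - p$L0)^2
    dVdS <- p$ks * (S - p$s)
    dVdr <- c(r1 = dVdR + dVdS, rL = p$kl * (r[["rL"]] - p$L0),
              r2 = -dVdR + dVdS)
    grad <- matrix(0, 4, 3)
    for (nm in names(r_pairs)) {
      ij <- r_pairs[[nm]]
      ## kcal/Angstrom -> Hartree/Bohr
      gv <- kcal_to_hartree(dVdr[[nm]]) * .ang_per_bohr *
        d[[nm]] / r_bohr[[nm]]
      grad[ij[1], ] <- grad[ij[1], ] + gv
      grad[ij[2], ] <- grad[ij[2], ] - gv
    }
    list(energy = kcal_to_hartree(v), gradient = grad)
  }
}

#' Toy reaction fixture: double-well substrate among frozen spectators
#'
#' A 4-atom substrate fragment (O-C1 ... C3-C4) whose intra potential is a
#' closed-form double well along the reaction coordinate
#' `R = r(O-C1) - r(C3-C4)`, embedded among three neutral neon spectator
#' fragments assigned to the buffer (`b`) and frozen (`F`) domains.  The
#' substrate is the active, high-level fragment.  The analytic barrier and
#' reaction energy of the isolated 1-D profile are returned for oracle use.
#' The substrate override defines its potential identically at both levels
#' (its correlation term is zero), so the scan probes the optimizer and FDD
#' machinery against the closed form.
#'
#' @param seed RNG seed (reserved for perturbation options; the fixture is
#'   deterministic).
#' @param kind `"double_well"` (default) or `"convex"` (hysteresis-free
#'   harmonic profile for forward/backward scan checks).
#' @return list with `geometry`, `fragments`, `partition`, `backend` (mock
#'   backend with the substrate override installed), `breaking_pair`,
#'   `forming_pair`, and `analytic`: list with `profile` (function of R,
#'   kcal/mol), `barrier_kcal`, `reaction_energy_kcal`, `wells` (reactant and
#'   product R, Angstrom) and `ts` (R at the barrier top).
#' @export
make_toy_reaction <- function(seed = 1L, kind = c("double_well", "convex")) {
  kind <- match.arg(kind)
  p <- .toy_params
  r1 <- (p$s - p$R0) / 2; r2 <- (p$s + p$R0) / 2  # reactant well R = -R0
  coords <- rbind(c(0, 0, 0),                       # O   (breaking partner)
                  c(r1, 0, 0),                      # C1
                  c(r1 + p$L0, 0, 0),               # C3
                  c(r1 + p$L0 + r2, 0, 0),          # C4  (forming partner)
                  c(r1 + p$L0 / 2, 12.0, 0),        # Ne spectator (b)
                  c(r1 + p$L0 / 2, -12.0, 0),       # Ne spectator (F)
                  c(r1 + p$L0 / 2, -12.0, 3.2))     # Ne spectator (F)
  geometry <- system_geometry(c("O", "C", "C", "C", "Ne", "Ne", "Ne"),
                              coords_ang = coords,
                              comment = sprintf("toy reaction (%s)", kind))
  fragments <- build_fragments(geometry, list(1:4, 5L, 6L, 7L))
  partition <- domain_partition(frozen = c(3L, 4L), polarizable = 2L,
                                active = 1L, high_level = 1L, fragments)
  backend <- mock_backend(intra_overrides = list(
    "1" = toy_substrate_potential(kind, p)))

  profile <- function(R) toy_profile_1d(R, kind, p)
  if (kind == "convex") {
    analytic <- list(profile = profile, barrier_kcal = 0,
                     reaction_energy_kcal = 0, wells = c(0, 0), ts = 0)
  } else {
    ## stationary points of V1(R): reactant/product wells and the barrier top
    w_react <- stats::optimize(profile, c(-2 * p$R0, -0.2 * p$R0))$minimum
    w_prod <- stats::optimize(profile, c(0.2 * p$R0, 2 * p$R0))$minimum
    ts <- stats::optimize(profile, c(w_react, w_prod), maximum = TRUE)$maximum
    analytic <- list(
      profile = profile,
      barrier_kcal = profile(ts) - profile(w_react),
      reaction_energy_kcal = profile(w_prod) - profile(w_react),
      wells = c(reactant = w_react, product = w_prod), ts = ts)
  }
  list(geometry = geometry, fragments = fragments, partition = partition,
       backend = backend, breaking_pair = c(1L, 2L), forming_pair = c(3L, 4L),
       analytic = analytic, params = p, seed = seed)
}

#' Default scan targets for the toy reaction
#'
#' Evenly spaced targets in the reaction coordinate, split symmetrically
#' between the breaking and forming distances so the symmetric stretch stays
#' at its relaxed value.  The default range spans the two wells of the
#' double-well profile (`-R0` to `+R0`), so the path endpoints are the
#' reactant and product minima.
#'
#' @param n_points number of scan points (default 21).
#' @param from,to reaction-coordinate range in Angstrom.
#' @param params toy parameter list (internal default).
#' @return data frame with columns `r1_target` and `r2_target` (Angstrom).
#' @export
toy_scan_targets <- function(n_points = 21L, from = -.toy_params$R0,
                             to = .toy_params$R0,
                             params = .toy_params) {
  R <- seq(from, to, length.out = n_points)
  data.frame(r1_target = (params$s + R) / 2, r2_target = (params$s - R) / 2)
}
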