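## Restrained geometry optimization of active-domain atoms (Cartesian BFGS
## with backtracking line search) and adiabatic mapping over a scanned
## reaction coordinate.

#' Create a harmonic distance restraint
#'
#' `E_r = k/2 (r - r0)^2` with `r0` in Angstrom and `k` in
#' kcal mol^-1 Angstrom^-2 (converted to Hartree/Bohr internally).
#'
#' @param atom_i,atom_j 1-based atom indices.
#' @param target target distance `r0` in Angstrom (> 0).
#' @param force_constant `k` in kcal mol^-1 Angstrom^-2 (>= 0), default 500.
#' @return a one-row tibble of class `restraint_set`.
#' @export
restraint <- function(atom_i, atom_j, target, force_constant = 500) {
  if (target <= 0) abort_argument("restraint target distance must be > 0")
  if (force_constant < 0) abort_argument("restraint force constant must be >= 0")
  if (atom_i == atom_j) abort_argument("restraint needs two distinct atoms")
  r <- tibble::tibble(atom_i = as.integer(atom_i), atom_j = as.integer(atom_j),
                      target = target, force_constant = force_constant)
  class(r) <- c("restraint_set", class(r))
  r
}

#' Energy and gradient of a set of harmonic distance restraints
#'
#' @param geometry a [system_geometry()].
#' @param restraints a tibble of [restraint()] rows (may be empty or `NULL`).
#' @return list with `energy` (Hartree) and `gradient`
#'   (`atom_count` x 3, Hartree/Bohr).  Restraints on disjoint pairs are
#'   additive.
#' @export
restraint_energy_gradient <- function(geometry, restraints) {
  n <- geometry$atom_count
  g <- matrix(0, n, 3)
  e <- 0
  if (!is.null(restraints) && nrow(restraints) > 0L)
    for (k in seq_len(nrow(restraints))) {
      i <- restraints$atom_i[k]; j <- restraints$atom_j[k]
      d <- geometry$coords[i, ] - geometry$coords[j, ]
      r_bohr <- sqrt(sum(d * d))
      if (r_bohr < 1e-8)
        abort_singularity("zero interatomic distance in restraint")
      r_ang <- bohr_to_ang(r_bohr)
      kk <- restraints$force_constant[k]
      dr <- r_ang - restraints$target[k]
      e <- e + kcal_to_hartree(0.5 * kk * dr^2)
      ## dE/dr_bohr = dE/dr_ang * ang_per_bohr
      dEdr <- kcal_to_hartree(kk * dr) * .ang_per_bohr
      gv <- (dEdr / r_bohr) * d
      g[i, ] <- g[i, ] + gv
      g[j, ] <- g[j, ] - gv
    }
  list(energy = e, gradient = g)
}

grad_measure <- function(g, measure) {
  if (measure == "rms") sqrt(mean(g^2)) else max(abs(g))
}

## Plain BFGS with Armijo backtracking on the flattened free coordinates.
## Accepted steps are non-increasing in energy by construction.
bfgs_minimize <- function(x0, fn, gr, tol, max_steps, measure = "max",
                          max_step_bohr = 0.5) {
  x <- x0
  f <- fn(x); g <- gr(x)
  n <- length(x)
  Hinv <- diag(n)
  trace_e <- f
  n_steps <- 0L
  converged <- grad_measure(g, measure) <= tol
  while (!converged && n_steps < max_steps) {
    p <- as.numeric(-Hinv %*% g)
    if (sum(p * g) >= 0) { Hinv <- diag(n); p <- -g }
    pmax_ <- max(abs(p))
    if (pmax_ > max_step_bohr) p <- p * (max_step_bohr / pmax_)
    step <- 1; f_new <- Inf; x_new <- x
    gTp <- sum(g * p)
    repeat {
      x_new <- x + step * p
      f_new <- fn(x_new)
      if (f_new <= f + 1e-4 * step * gTp) break
      step <- step / 2
      if (step < 1e-12) { x_new <- x; f_new <- f; break }
    }
    if (identical(x_new, x)) break  # line search failed; gradient too noisy
    g_new <- gr(x_new)
    s <- x_new - x; y <- g_new - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      Hinv <- (I - rho * outer(s, y)) %*% Hinv %*% (I - rho * outer(y, s)) +
        rho * outer(s, s)
    }
    x <- x_new; f <- f_new; g <- g_new
    n_steps <- n_steps + 1L
    trace_e <- c(trace_e, f)
    converged <- grad_measure(g, measure) <= tol
  }
  list(x = x, f = f, g = g, n_steps = n_steps, converged = converged,
       energy_trace = trace_e)
}

#' Restrained optimization of active-domain atoms
#'
#' Minimizes the hybrid EFMO energy (or the pure RHF total when
#' `config$hybrid_enabled = FALSE`) plus the restraint energy over the
#' Cartesian coordinates of active-domain atoms only; frozen and buffer
#' atoms never move.  Quasi-Newton (BFGS) with backtracking line search;
#' convergence when the configured gradient measure (including restraint
#' forces) drops to `config$gradient_tolerance` Hartree/Bohr.
#' Non-convergence within `config$max_opt_steps` returns a result with
#' `converged = FALSE` rather than an error.
#'
#' @inheritParams efmo_total_energy
#' @param restraints a tibble of [restraint()] rows, or `NULL`.
#' @param scan_index bookkeeping index recorded in the result.
#' @param coordinate_pairs optional list with `breaking` and `forming` atom
#'   pairs; when given, the reaction coordinate of the converged geometry is
#'   recorded.
#' @param verbose print one line per accepted step.
#' @return a `path_point`: list with `scan_index`, `targets`, `geometry`
#'   (converged), `reaction_coordinate` (Angstrom or `NA`), `energy_report`
#'   (restraint-free energy at the converged geometry), `n_steps`,
#'   `converged`, `energy_trace` and `max_grad_final`.
#' @export
optimize_active <- function(geometry, fragments, partition, restraints,
                            config, cache = NULL, backend = NULL,
                            scan_index = NA_integer_,
                            coordinate_pairs = NULL, verbose = FALSE) {
  backend <- get_backend(backend %||% config$backend)
  cache <- cache %||% new_fdd_cache()
  free_atoms <- sort(unlist(lapply(partition$active, frag_atoms,
                                   fragments = fragments)))
  nf <- length(free_atoms)
  geom <- geometry
  pack <- function(g) as.numeric(t(g$coords[free_atoms, , drop = FALSE]))
  unpack <- function(x) {
    geom$coords[free_atoms, ] <- matrix(x, nf, 3, byrow = TRUE)
    geom
  }
  eval_point <- function(x, want_gradient) {
    g <- unpack(x)
    res <- efmo_assemble(g, fragments, partition, config, cache, backend,
                         want_gradient = want_gradient,
                         hybrid = config$hybrid_enabled)
    rg <- restraint_energy_gradient(g, restraints)
    e <- res$report$total + rg$energy
    grad <- NULL
    if (want_gradient) {
      gm <- res$gradient$gradient + rg$gradient
      grad <- as.numeric(t(gm[free_atoms, , drop = FALSE]))
    }
    list(energy = e, grad = grad, report = res$report)
  }
  step_counter <- 0L
  fn <- function(x) eval_point(x, FALSE)$energy
  gr <- function(x) {
    ep <- eval_point(x, TRUE)
    if (verbose) {
      step_counter <<- step_counter + 1L
      message(sprintf("opt step %3d  E = %.10f Hartree  max|g| = %.3e",
                      step_counter, ep$energy, max(abs(ep$grad))))
    }
    ep$grad
  }
  res <- bfgs_minimize(pack(geometry), fn, gr,
                       tol = config$gradient_tolerance,
                       max_steps = config$max_opt_steps,
                       measure = config$convergence_measure)
  geom_final <- unpack(res$x)
  report <- efmo_assemble(geom_final, fragments, partition, config, cache,
                          backend, want_gradient = FALSE,
                          hybrid = config$hybrid_enabled)$report
  rc <- NA_real_
  if (!is.null(coordinate_pairs))
    rc <- reaction_coordinate(geom_final, coordinate_pairs$breaking,
                              coordinate_pairs$forming)
  targets <- if (is.null(restraints) || nrow(restraints) == 0L) numeric(0)
             else restraints$target
  structure(list(scan_index = scan_index, targets = targets,
                 geometry = geom_final, reaction_coordinate = rc,
                 energy_report = report, n_steps = res$n_steps,
                 converged = res$converged, energy_trace = res$energy_trace,
                 max_grad_final = grad_measure(res$g, "max")),
            class = "path_point")
}

#' Adiabatic mapping: sequential restrained optimizations along a scan
#'
#' Traces a reaction path by imposing harmonic restraints on the breaking
#' and forming distances at each scan target and optimizing the active
#' domain, each point starting from the previous converged geometry.
#' Unconverged points are flagged and the scan continues.
#'
#' @inheritParams optimize_active
#' @param breaking_pair,forming_pair atom index pairs defining the reaction
#'   coordinate `r(breaking) - r(forming)`.
#' @param scan_targets a matrix/data frame with columns `r1_target`
#'   (breaking) and `r2_target` (forming), Angstrom, one row per point.
#' @return a `reaction_path`: list of `path_point`s with the scan metadata;
#'   use [tidy()] for the path table and [barrier_and_reaction_energy()] for
#'   the barrier summary.
#' @export
scan_reaction_path <- function(geometry, fragments, partition,
                               breaking_pair, forming_pair, scan_targets,
                               config, cache = NULL, backend = NULL,
                               verbose = FALSE) {
  scan_targets <- as.data.frame(scan_targets)
  if (nrow(scan_targets) < 1L) abort_argument("scan_targets must be non-empty")
  if (!all(c("r1_target", "r2_target") %in% names(scan_targets)))
    abort_argument("scan_targets needs columns r1_target and r2_target")
  cache <- cache %||% new_fdd_cache()
  backend <- get_backend(backend %||% config$backend)
  pairs <- list(breaking = breaking_pair, forming = forming_pair)
  points <- vector("list", nrow(scan_targets))
  geom <- geometry
  for (s in seq_len(nrow(scan_targets))) {
    restraints <- rbind(
      restraint(breaking_pair[1], breaking_pair[2],
                scan_targets$r1_target[s], config$restraint_force_constant),
      restraint(forming_pair[1], forming_pair[2],
                scan_targets$r2_target[s], config$restraint_force_constant))
    pt <- optimize_active(geom, fragments, partition, restraints, config,
                          cache, backend, scan_index = s,
                          coordinate_pairs = pairs, verbose = verbose)
    points[[s]] <- pt
    geom <- pt$geometry    # next point starts from the converged structure
  }
  structure(list(points = points, breaking_pair = breaking_pair,
                 forming_pair = forming_pair, scan_targets = scan_targets),
            class = "reaction_path")
}

#' Barrier, reaction energy and transition-state coordinate of a path
#'
#' `barrier = max(E) - E(first)` and
#' `reaction_energy = E(last) - E(first)`, both in kcal/mol, plus the
#' reaction coordinate at the maximum (the transition-state estimate).
#'
#' @param path a `reaction_path`, or a data frame with columns
#'   `energy_hartree` (or `energy_kcal`) and optionally
#'   `reaction_coordinate`.
#' @return list with `barrier_kcal`, `reaction_energy_kcal` and
#'   `ts_coordinate` (Angstrom, `NA` when unavailable).
#' @export
barrier_and_reaction_energy <- function(path) {
  if (inherits(path, "reaction_path")) {
    e_h <- vapply(path$points, function(p) p$energy_report$total, 1.0)
    rc <- vapply(path$points, function(p) p$reaction_coordinate, 1.0)
    e_kcal <- hartree_to_kcal(e_h)
  } else {
    df <- as.data.frame(path)
    e_kcal <- if ("energy_kcal" %in% names(df)) df$energy_kcal
              else hartree_to_kcal(df$energy_hartree)
    rc <- if ("reaction_coordinate" %in% names(df)) df$reaction_coordinate
          else rep(NA_real_, length(e_kcal))
  }
  if (length(e_kcal) < 2L) abort_argument("path must contain at least 2 points")
  imax <- which.max(e_kcal)
  list(barrier_kcal = e_kcal[imax] - e_kcal[1],
       reaction_energy_kcal = e_kcal[length(e_kcal)] - e_kcal[1],
       ts_coordinate = rc[imax])
}
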